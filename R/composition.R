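# Position-specific amino-acid composition, two-sample-logo enrichment
# statistics, solvent-accessibility profile comparison, and PTM site-set
# overlap counts.

#' Position-specific residue frequencies of a fragment set
#'
#' @param fragments Fragment data.frame or character vector of uniform-length
#'   fragment sequences.
#' @return 21 x (2n+1) matrix of relative frequencies (rows [AA21], columns
#'   labelled -n..+n); every column sums to 1. X is counted as its own
#'   symbol.
#' @export
position_frequencies <- function(fragments) {
  seqs <- if (is.data.frame(fragments)) fragments$sequence else fragments
  if (length(seqs) == 0L) stop("empty fragment set")
  build_pwm(seqs)
}

# Two-sided p-value of a two-sample t test (Welch) on binary occurrence
# indicators, computed in closed form from counts. k successes of n.
binary_t_pvalue <- function(ka, na, kb, nb) {
  pa <- ka / na
  pb <- kb / nb
  va <- ka * (na - ka) / (na * (na - 1))  # unbiased variance of 0/1 sample
  vb <- kb * (nb - kb) / (nb * (nb - 1))
  se2 <- va / na + vb / nb
  if (se2 == 0) return(if (pa == pb) 1 else 0)
  t <- (pa - pb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(t), df)
}

#' Two-sample-logo enrichment statistics between two fragment sets
#'
#' For every (window position, residue symbol) cell, the occurrence
#' frequencies in the two sets are compared by a two-proportion test on the
#' binary occurrence indicators (two-sample t test, the classic
#' two-sample-logo default; Fisher's exact test available for small counts).
#' Cells with p below `alpha` are reported, split into enriched
#' (freq_a > freq_b) and depleted.
#'
#' @param set_a,set_b Fragment data.frames or sequence vectors (e.g.
#'   positives and negatives); must share the window width.
#' @param alpha Per-cell significance level in (0, 1\]; default 0.01.
#' @param test `"t"` (default) or `"fisher"`.
#' @param correction `"none"` (default, per-cell p values) or `"bonferroni"`.
#' @return data.frame (position, residue, direction, freq_a, freq_b,
#'   p_value), positions in -n..+n, sorted by position then residue.
#' @export
two_sample_logo <- function(set_a, set_b, alpha = 0.01,
                            test = c("t", "fisher"),
                            correction = c("none", "bonferroni")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  stopifnot(alpha > 0, alpha <= 1)
  seqs_a <- if (is.data.frame(set_a)) set_a$sequence else set_a
  seqs_b <- if (is.data.frame(set_b)) set_b$sequence else set_b
  if (length(seqs_a) == 0L || length(seqs_b) == 0L)
    stop("both fragment sets must be non-empty")
  w <- nchar(seqs_a[1])
  if (nchar(seqs_b[1]) != w)
    stop("fragment width mismatch: ", w, " vs ", nchar(seqs_b[1]))
  na <- length(seqs_a)
  nb <- length(seqs_b)
  counts_a <- round(position_frequencies(seqs_a) * na)
  counts_b <- round(position_frequencies(seqs_b) * nb)
  n <- (w - 1L) %/% 2L
  positions <- window_positions(n)
  n_cells <- length(AA21) * w
  out <- vector("list", n_cells)
  cell <- 0L
  for (j in seq_len(w)) {
    for (r in AA21) {
      ka <- counts_a[r, j]
      kb <- counts_b[r, j]
      p <- if (test == "t") {
        binary_t_pvalue(ka, na, kb, nb)
      } else {
        m <- matrix(c(ka, na - ka, kb, nb - kb), nrow = 2)
        stats::fisher.test(m)$p.value
      }
      cell <- cell + 1L
      out[[cell]] <- data.frame(
        position = positions[j], residue = r,
        direction = if (ka / na > kb / nb) "enriched" else "depleted",
        freq_a = ka / na, freq_b = kb / nb, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  if (correction == "bonferroni")
    tab$p_value <- pmin(tab$p_value * n_cells, 1)
  if (alpha < 1) tab <- tab[tab$p_value < alpha, , drop = FALSE]
  tab <- tab[order(tab$position, tab$residue), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-position mean solvent accessibility of two fragment sets
#'
#' Means of the normalized (\[0, 1\]) ASA over each window position;
#' terminal-padding positions are excluded from the means.
#'
#' @param set_a,set_b Fragment data.frames.
#' @param asa Named list of raw-percent ASA tracks ([read_track()]) covering
#'   every fragment's protein.
#' @return data.frame (position, mean_a, mean_b, difference), length 2n+1.
#' @export
asa_profile_compare <- function(set_a, set_b, asa) {
  n <- frag_n(set_a$sequence[1])
  prof <- function(frags) {
    sums <- numeric(2L * n + 1L)
    cnts <- numeric(2L * n + 1L)
    for (i in seq_len(nrow(frags))) {
      tr <- asa[[frags$protein_id[i]]]
      if (is.null(tr)) stop("missing ASA track for ", frags$protein_id[i])
      pos <- (frags$center[i] - n):(frags$center[i] + n)
      inside <- pos >= 1L & pos <= length(tr)
      sums[inside] <- sums[inside] + pmin(tr[pos[inside]] / 100, 1)
      cnts[inside] <- cnts[inside] + 1
    }
    sums / cnts
  }
  a <- prof(set_a)
  b <- prof(set_b)
  data.frame(position = window_positions(n), mean_a = a, mean_b = b,
             difference = a - b)
}

#' Overlap counts among PTM site sets
#'
#' Venn-partition counts at the protein level and at the site level for two
#' or more named site sets (e.g. S-sulfenylation vs S-nitrosylation vs
#' S-glutathionylation).
#'
#' @param site_sets Named list; each element a data.frame with columns
#'   `protein_id` and `position` (or a character vector of protein IDs).
#' @return List with `protein` and `site` data.frames: one row per
#'   membership pattern (columns = set names, logical) plus `count`.
#' @export
overlap_sets <- function(site_sets) {
  stopifnot(length(site_sets) >= 2L, !is.null(names(site_sets)))
  keyed <- lapply(site_sets, function(s) {
    if (is.data.frame(s)) {
      list(protein = unique(s$protein_id),
           site = unique(paste(s$protein_id, s$position, sep = "@")))
    } else {
      list(protein = unique(s), site = unique(s))
    }
  })
  venn <- function(sets) {
    universe <- unique(unlist(sets))
    memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    if (length(universe) == 1L) memb <- matrix(memb, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
    names(patterns) <- names(sets)
    patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
    patterns$count <- apply(patterns, 1, function(p) {
      if (length(universe) == 0L) return(0L)
      sum(apply(memb, 1, function(m) all(m == p)))
    })
    rownames(patterns) <- NULL
    patterns
  }
  list(protein = venn(lapply(keyed, `[[`, "protein")),
       site = venn(lapply(keyed, `[[`, "site")))
}
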
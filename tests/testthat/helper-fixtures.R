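# Shared fixtures: tiny files written on the fly, a literal F-score oracle,
# and small random-data constructors. Everything is generated in code.

`%+%` <- function(a, b) paste0(a, b)

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fixture_fasta <- function() {
  write_tmp(c(">p1 some description", "MKCAGCT",
              ">p2", "CCAU*KW"), ".fasta")
}

fixture_sites <- function() {
  write_tmp(c("p1\t3\t+1", "p1\t6\t-1", "p2\t1\t1"), ".tsv")
}

# Two complete AAindex entries plus one with NA, in the AAindex1 dialect.
# KYTJ820101 carries the Kyte-Doolittle hydropathy values (I-block residue
# order: A R N D C Q E G H I / L K M F P S T W Y V).
fixture_aaindex <- function() {
  write_tmp(c(
    "H KYTJ820101",
    "D Hydropathy index (Kyte-Doolittle, 1982)",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5",
    "     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2",
    "//",
    "H FAKE000001",
    "D Uniform synthetic index",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0",
    "     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0",
    "//",
    "H FAKE000002",
    "D Synthetic index with a missing value",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.0      NA     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0",
    "     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0     1.0",
    "//"), ".aaindex")
}

# 5-residue profile in the -out_ascii_pssm dialect, with the two trailing
# summary numbers PSI-BLAST appends after the 20 frequency columns.
fixture_pssm <- function(extra_freq_cols = FALSE) {
  hdr <- paste(c(sprintf("%3s", cysPTM:::PSSM_AA_ORDER),
                 if (extra_freq_cols) sprintf("%4s", cysPTM:::PSSM_AA_ORDER)),
               collapse = " ")
  score_row <- function(i, res, scores) {
    paste0(sprintf("%4d %s ", i, res),
           paste(sprintf("%3d", scores), collapse = " "),
           if (extra_freq_cols)
             paste0("  ", paste(rep("0.05", 20), collapse = " "), "  1.20 0.35"))
  }
  set.seed(99)
  lines <- c("", "Last position-specific scoring matrix computed, weighted",
             paste0("      ", hdr))
  res <- c("M", "K", "C", "A", "G")
  for (i in 1:5) lines <- c(lines, score_row(i, res[i], sample(-5:7, 20, TRUE)))
  lines <- c(lines, "", "                      K         Lambda")
  write_tmp(lines, ".pssm")
}

fixture_asa_track <- function() {
  write_tmp(sprintf("p1\t%d\t%g", 1:5, c(10, 20, 30, 40, 50)), ".tsv")
}

# Literal transcription of the F-score definition, kept deliberately naive
# (explicit sums) so it is independent of the implementation under test.
f_score_oracle <- function(xp, xn) {
  xbar <- mean(c(xp, xn))
  xbp <- mean(xp)
  xbn <- mean(xn)
  num <- (xbp - xbar)^2 + (xbn - xbar)^2
  den <- 0
  for (k in seq_along(xp)) den <- den + (xp[k] - xbp)^2 / (length(xp) - 1)
  for (k in seq_along(xn)) den <- den + (xn[k] - xbn)^2 / (length(xn) - 1)
  if (num == 0) return(0)
  if (den == 0) return(Inf)
  num / den
}

# Well-separated 2-D Gaussian blobs with +1/-1 labels.
blob_data <- function(n_per_class = 30, sep = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per_class, sep), ncol = 2),
             matrix(rnorm(2 * n_per_class, -sep), ncol = 2))
  colnames(X) <- c("f1", "f2")
  list(x = X, y = c(rep(1L, n_per_class), rep(-1L, n_per_class)))
}

random_fragment <- function(w = 21L) {
  n <- (w - 1L) %/% 2L
  chars <- sample(c(AA20, "X"), w, replace = TRUE,
                  prob = c(rep(0.045, 20), 0.1))
  chars[n + 1L] <- "C"
  # padding X only as contiguous prefix/suffix for validity
  paste(chars, collapse = "")
}

null_synth_config <- function(n_pos = 200L, n_neg = 200L, seed = 1L) {
  synthetic_config(n_pos = n_pos, n_neg = n_neg,
                   enrichment = default_positive_enrichment()[0, ],
                   asa_shift = 0, informative_property = NULL, seed = seed)
}
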
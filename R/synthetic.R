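# Synthetic dataset generator.
#
# Emulates the statistical structure of S-sulfenylation neighbourhoods:
# positive windows enriched in K/R at positions -10, -8..-6, -4, -2, +4..+8
# and E at -3, +1, +3, +4; negative windows enriched in the neutral residues
# L/C/H/M/F/Y; positives carry elevated solvent accessibility and are tilted
# along one informative physicochemical axis. Each generated window is
# emitted as its own synthetic protein together with a site annotation, ASA
# and secondary-structure tracks, and a noisy per-protein PSSM profile, so
# that every pipeline stage can be exercised without external data.

#' Default positive-class positional enrichment pattern
#'
#' K and R boosted (+0.10 each) at positions -10, -8..-6, -4, -2 and +4..+8;
#' E boosted (+0.15) at -3, +1, +3, +4.
#'
#' @return data.frame (position, residue, boost) of additive probability
#'   boosts over the uniform background.
#' @export
default_positive_enrichment <- function() {
  kr_pos <- c(-10L, -8L, -7L, -6L, -4L, -2L, 4L, 5L, 6L, 7L, 8L)
  e_pos <- c(-3L, 1L, 3L, 4L)
  rbind(
    data.frame(position = rep(kr_pos, each = 2L),
               residue = rep(c("K", "R"), length(kr_pos)),
               boost = 0.10, stringsAsFactors = FALSE),
    data.frame(position = e_pos, residue = "E", boost = 0.15,
               stringsAsFactors = FALSE)
  )
}

#' Default negative-class enrichment pattern
#'
#' The neutral residues L, C, H, M, F, Y boosted (+0.04 each) at every flank
#' position.
#'
#' @param window_n Flank width.
#' @return data.frame (position, residue, boost).
#' @export
default_negative_enrichment <- function(window_n = 10L) {
  pos <- setdiff(window_positions(window_n), 0L)
  data.frame(position = rep(pos, each = 6L),
             residue = rep(c("L", "C", "H", "M", "F", "Y"), length(pos)),
             boost = 0.04, stringsAsFactors = FALSE)
}

#' Synthetic informative physicochemical axis
#'
#' A hydropathy-style AAindex entry (Kyte-Doolittle values) labelled as
#' synthetic; positives are tilted toward hydrophilic (low) values,
#' mirroring the solvent-exposed character of S-sulfenylation
#' neighbourhoods.
#' @export
synthetic_hydropathy_entry <- function() {
  vals <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
            H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
            P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
            W = -0.9, Y = -1.3)
  list(accession = "SYNTH_HYDRO",
       description = "synthetic informative axis (hydropathy-style)",
       values = vals[AA20], has_na = FALSE)
}

#' Generate uninformative (noise) physicochemical properties
#'
#' Random residue-value assignments with no relation to the class structure.
#'
#' @param k Number of entries.
#' @param seed Integer seed.
#' @return Named list of AAindex-style entries (accessions SYNTH_NOISE01..).
#' @export
synthetic_noise_properties <- function(k, seed = 1L) {
  with_seed(seed, {
    entries <- lapply(seq_len(k), function(i) {
      vals <- stats::rnorm(20)
      names(vals) <- AA20
      list(accession = sprintf("SYNTH_NOISE%02d", i),
           description = "synthetic noise property", values = vals,
           has_na = FALSE)
    })
    names(entries) <- vapply(entries, `[[`, character(1), "accession")
    entries
  })
}

#' Synthetic dataset configuration
#'
#' @param n_pos,n_neg Number of positive / negative windows (each becomes
#'   one synthetic protein with one annotated cysteine).
#' @param window_n Flank width (window 2n+1), default 10.
#' @param enrichment Positive-class boosts, data.frame (position, residue,
#'   boost); default [default_positive_enrichment()]. Use a 0-row frame for
#'   a null (no-signal) configuration.
#' @param neg_enrichment Negative-class boosts; default
#'   [default_negative_enrichment()]. Ignored (uniform background) when
#'   `enrichment` has zero rows, so that a null configuration draws both
#'   classes from one distribution.
#' @param asa_shift Additive shift (0-1 scale) of positive-class solvent
#'   accessibility; default 0.2.
#' @param informative_property AAindex-style entry defining the informative
#'   physicochemical axis, or `NULL` for none; default
#'   [synthetic_hydropathy_entry()].
#' @param informative_effect Log-linear tilt strength of positives along the
#'   (standardized, sign-flipped) property axis; default 0.8.
#' @param pssm_neff Number of simulated homolog observations per position
#'   feeding the synthetic PSSM profile: each profile column is the
#'   pseudocounted log-odds of (observed residue + `pssm_neff` draws from a
#'   mutated copy of it + background), so the profile is a stochastic
#'   recoding of the protein's own sequence. Default 3.
#' @param seed Integer seed; the generated dataset is fully deterministic.
#' @export
synthetic_config <- function(n_pos = 500L, n_neg = 500L, window_n = 10L,
                             enrichment = default_positive_enrichment(),
                             neg_enrichment = default_negative_enrichment(window_n),
                             asa_shift = 0.2,
                             informative_property = synthetic_hydropathy_entry(),
                             informative_effect = 0.8,
                             pssm_neff = 3L, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, window_n >= 1L, asa_shift >= 0)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 window_n = as.integer(window_n), enrichment = enrichment,
                 neg_enrichment = neg_enrichment, asa_shift = asa_shift,
                 informative_property = informative_property,
                 informative_effect = informative_effect,
                 pssm_neff = as.integer(pssm_neff),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Per-position residue distribution for one class. Boosted residues receive
# background + boost exactly; the remaining probability mass is spread over
# the other residues (optionally tilted along the informative axis), so an
# additive boost b produces an expected frequency difference of b against
# the un-boosted class.
position_distribution <- function(position, boosts, tilt = NULL) {
  bg <- rep(1 / 20, 20)
  names(bg) <- AA20
  sel <- boosts$position == position
  boosted <- boosts$residue[sel]
  p <- bg
  p[boosted] <- bg[boosted] + boosts$boost[sel]
  if (any(p < 0) || any(p > 1))
    stop("enrichment boost produces probability outside [0, 1] at position ",
         position)
  residual <- 1 - sum(p[boosted])
  if (residual < 0)
    stop("enrichment boosts exceed total probability at position ", position)
  others <- setdiff(AA20, boosted)
  w <- bg[others]
  if (!is.null(tilt)) w <- w * tilt[others]
  p[others] <- residual * w / sum(w)
  p
}

#' Generate a synthetic labelled dataset
#'
#' @param config [synthetic_config()].
#' @param fragments_only Skip the ASA/SS tracks and PSSM profiles (faster;
#'   used e.g. for composition-only simulation studies). Default FALSE.
#' @return List: `proteins` (named sequences, one 2n+1-mer per window),
#'   `sites` (site data.frame), `fragments` (labelled fragment frame),
#'   `asa`, `ss` (track lists), `profiles` (named list of PSSM matrices),
#'   `property` (the informative entry or NULL), `config`. Track/profile
#'   elements are NULL when `fragments_only`.
#' @export
generate_dataset <- function(config = synthetic_config(), fragments_only = FALSE) {
  n <- config$window_n
  w <- 2L * n + 1L
  positions <- window_positions(n)
  null_world <- nrow(config$enrichment) == 0L

  tilt <- NULL
  if (!is.null(config$informative_property) && config$informative_effect != 0) {
    v <- config$informative_property$values
    z <- (v - mean(v)) / stats::sd(v)
    tilt <- exp(-config$informative_effect * z)  # toward low (hydrophilic) values
  }

  # class-conditional distributions per flank position
  pos_dists <- lapply(positions, function(p) {
    if (p == 0L) return(NULL)
    position_distribution(p, config$enrichment, tilt)
  })
  neg_boosts <- if (null_world) config$enrichment else config$neg_enrichment
  neg_dists <- lapply(positions, function(p) {
    if (p == 0L) return(NULL)
    position_distribution(p, neg_boosts, NULL)
  })

  with_seed(config$seed, {
    make_class <- function(n_samples, dists, prefix, asa_lo, asa_hi) {
      ids <- sprintf("%s%05d", prefix, seq_len(n_samples))
      if (fragments_only) {
        chars <- vapply(seq_len(w), function(j) {
          if (positions[j] == 0L) rep("C", n_samples)
          else sample(AA20, n_samples, replace = TRUE, prob = dists[[j]])
        }, character(n_samples))
        if (n_samples == 1L) chars <- matrix(chars, nrow = 1L)
        seqs <- apply(chars, 1, paste, collapse = "")
        return(list(ids = ids, seqs = stats::setNames(seqs, ids),
                    asa = NULL, ss = NULL, profiles = NULL))
      }
      seqs <- character(n_samples)
      asa <- vector("list", n_samples)
      ss <- vector("list", n_samples)
      profiles <- vector("list", n_samples)
      bg <- rep(1 / 20, 20)
      for (i in seq_len(n_samples)) {
        chars <- character(w)
        prof <- matrix(0, nrow = w, ncol = 20L,
                       dimnames = list(NULL, PSSM_AA_ORDER))
        for (j in seq_len(w)) {
          # Profile = pseudocounted column of a simulated mini-alignment:
          # the observed residue plus pssm_neff "homolog" draws from a
          # mutated copy of it (70% conserved, 30% background), plus one
          # background pseudo-observation. Scores are half-bit log-odds vs
          # background, as in PSI-BLAST output. The profile is thus a
          # stochastic recoding of the protein's own sequence; class signal
          # reaches it only through the sequence composition, as for real
          # evolutionary profiles of PTM substrates.
          if (positions[j] == 0L) {
            chars[j] <- "C"
          } else {
            chars[j] <- sample(AA20, 1L, prob = dists[[j]])
          }
          obs <- stats::setNames(numeric(20), AA20)
          obs[chars[j]] <- 1
          fam <- 0.7 * obs + 0.3 * bg
          cnt <- as.numeric(stats::rmultinom(1, config$pssm_neff, fam))
          q <- (obs + cnt + bg) / (1 + config$pssm_neff + 1)
          names(q) <- AA20
          prof[j, ] <- round(2 * log2(q[PSSM_AA_ORDER] / (1 / 20)))
        }
        seqs[i] <- paste(chars, collapse = "")
        asa[[i]] <- stats::runif(w, asa_lo, asa_hi)
        ss[[i]] <- sample(c("H", "E", "C"), w, replace = TRUE,
                          prob = c(0.35, 0.20, 0.45))
        profiles[[i]] <- prof
      }
      names(asa) <- ids
      names(ss) <- ids
      names(profiles) <- ids
      list(ids = ids, seqs = stats::setNames(seqs, ids), asa = asa, ss = ss,
           profiles = profiles)
    }

    shift_pct <- config$asa_shift * 100
    pos <- make_class(config$n_pos, pos_dists, "SPOS",
                      20 + shift_pct, 60 + shift_pct)
    neg <- make_class(config$n_neg, neg_dists, "SNEG", 20, 60)

    proteins <- c(pos$seqs, neg$seqs)
    sites <- data.frame(
      protein_id = c(pos$ids, neg$ids),
      position = rep(n + 1L, length(proteins)),
      label = c(rep(1L, config$n_pos), rep(-1L, config$n_neg)),
      stringsAsFactors = FALSE)
    fragments <- fragment_frame(sites$protein_id, sites$position,
                                unname(proteins), sites$label)
    list(proteins = proteins, sites = sites, fragments = fragments,
         asa = c(pos$asa, neg$asa), ss = c(pos$ss, neg$ss),
         profiles = c(pos$profiles, neg$profiles),
         property = config$informative_property, config = config)
  })
}

#' Write a synthetic dataset in the package's own file formats
#'
#' Dog-fooding round trip: the files written here are read back by
#' [read_fasta()], [read_sites()], [read_track()] and [read_pssm()].
#'
#' @param data Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths (`fasta`, `sites`, `asa`, `ss`,
#'   `pssm_dir`).
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "proteins.fasta"),
                sites = file.path(dir, "sites.tsv"),
                asa = file.path(dir, "asa.tsv"),
                ss = file.path(dir, "ss.tsv"),
                pssm_dir = file.path(dir, "pssm"))
  write_fasta(data$proteins, paths$fasta)
  write_sites(data$sites, paths$sites)
  write_track(lapply(data$asa, function(v) sprintf("%.3f", v)), paths$asa)
  write_track(data$ss, paths$ss)
  dir.create(paths$pssm_dir, showWarnings = FALSE)
  for (id in names(data$profiles)) {
    write_pssm(data$profiles[[id]],
               frag_chars(data$proteins[[id]]),
               file.path(paths$pssm_dir, paste0(id, ".pssm")))
  }
  paths
}
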
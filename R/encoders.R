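# Fragment-to-feature-vector encodings.
#
# Every encoder returns a named numeric vector (a feature vector); names are
# prefixed with the encoder tag so that hybrid concatenation keeps them
# unique. Residue column order is alphabetical (AA20) except for the PSSM
# encoder, which preserves the PSI-BLAST profile header order.
#
# X (terminal padding / unknown) handling:
#   binary, BLOSUM62, PSSM, tracks -> all-zero row (least-informative)
#   AAC, AAPC, PWM                 -> 21st alphabet symbol
#   AAindex                        -> 0 (the z-scored scale's mean)

frag_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

frag_n <- function(sequence) {
  w <- nchar(sequence)
  if (w %% 2L == 0L) stop("fragment length must be odd, got ", w)
  (w - 1L) %/% 2L
}

#' One-hot (20-dimensional binary) encoding
#'
#' Each residue becomes a 20-bit indicator in alphabetical order (A = bit 1,
#' C = bit 2, ...); X positions are all-zero. Output length (2n+1) x 20.
#'
#' @param sequence Fragment sequence (2n+1-mer).
#' @return Named numeric vector.
#' @export
encode_binary <- function(sequence) {
  chars <- frag_chars(sequence)
  n <- frag_n(sequence)
  idx <- match(chars, AA20)  # NA for X
  m <- matrix(0, nrow = length(chars), ncol = 20L)
  hit <- !is.na(idx)
  m[cbind(which(hit), idx[hit])] <- 1
  poslab <- position_label(window_positions(n))
  v <- as.vector(t(m))
  names(v) <- paste0("binary.", rep(poslab, each = 20L), ".", rep(AA20, length(chars)))
  v
}

#' Amino-acid composition (AAC) encoding
#'
#' Occurrence frequencies of the 21 symbols (20 residues + X) in the
#' fragment; sums to 1.
#' @inheritParams encode_binary
#' @export
encode_aac <- function(sequence) {
  chars <- frag_chars(sequence)
  counts <- table(factor(chars, levels = AA21))
  v <- as.numeric(counts) / length(chars)
  names(v) <- paste0("aac.", AA21)
  v
}

#' Amino-acid pair composition (AAPC) encoding
#'
#' Occurrence frequencies of the 2n adjacent ordered residue pairs over the
#' 21 x 21 = 441 pair alphabet; sums to 1.
#' @inheritParams encode_binary
#' @export
encode_aapc <- function(sequence) {
  chars <- frag_chars(sequence)
  pairs <- paste0(chars[-length(chars)], chars[-1])
  lev <- as.vector(outer(AA21, AA21, paste0))
  counts <- table(factor(pairs, levels = lev))
  v <- as.numeric(counts) / length(pairs)
  names(v) <- paste0("aapc.", lev)
  v
}

#' BLOSUM62 substitution-profile encoding
#'
#' Each residue is represented by its 20-score BLOSUM62 row, linearly
#' rescaled to \[0, 1\] over the matrix's global min/max; X positions are
#' all-zero. Output length (2n+1) x 20.
#' @inheritParams encode_binary
#' @export
encode_blosum62 <- function(sequence) {
  chars <- frag_chars(sequence)
  n <- frag_n(sequence)
  B <- blosum62_matrix()
  lo <- min(B); hi <- max(B)
  m <- matrix(0, nrow = length(chars), ncol = 20L)
  hit <- chars %in% AA20
  if (any(hit)) m[hit, ] <- (B[chars[hit], , drop = FALSE] - lo) / (hi - lo)
  poslab <- position_label(window_positions(n))
  v <- as.vector(t(m))
  names(v) <- paste0("blosum62.", rep(poslab, each = 20L),
                     ".", rep(AA20, length(chars)))
  v
}

#' Build a position weight matrix (PWM) from positive training fragments
#'
#' Per-position relative frequencies of the 21 symbols (20 residues plus the
#' terminal signal X) over the positive training windows.
#'
#' @param fragments Fragment data.frame or character vector of uniform-length
#'   fragment sequences (the positive training set).
#' @return 21 x (2n+1) matrix, rows [AA21], columns labelled -n..+n; every
#'   column sums to 1.
#' @export
build_pwm <- function(fragments) {
  seqs <- if (is.data.frame(fragments)) fragments$sequence else fragments
  if (length(seqs) == 0L) stop("cannot build a PWM from an empty fragment set")
  w <- nchar(seqs[1])
  if (any(nchar(seqs) != w)) stop("fragments must have uniform length")
  n <- (w - 1L) %/% 2L
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
  pwm <- apply(chars, 2, function(col) {
    as.numeric(table(factor(col, levels = AA21))) / length(col)
  })
  rownames(pwm) <- AA21
  colnames(pwm) <- position_label(window_positions(n))
  pwm
}

#' PWM encoding of a fragment
#'
#' Element j is the training-set frequency of the fragment's residue at
#' window position j. Output length 2n+1, values in \[0, 1\].
#' @inheritParams encode_binary
#' @param pwm Matrix from [build_pwm()].
#' @export
encode_pwm <- function(sequence, pwm) {
  chars <- frag_chars(sequence)
  if (length(chars) != ncol(pwm))
    stop("fragment length (", length(chars), ") does not match PWM width (",
         ncol(pwm), ")")
  v <- pwm[cbind(match(chars, rownames(pwm)), seq_along(chars))]
  v[is.na(v)] <- 0
  names(v) <- paste0("pwm.", colnames(pwm))
  v
}

#' PSSM encoding of a fragment
#'
#' Cuts the (2n+1) x 20 window of the protein's PSI-BLAST profile centered
#' on the cysteine. Raw scores s are squashed through the logistic
#' 1 / (1 + exp(-s)); window rows that fall outside the protein (terminal
#' padding) are all-zero. Output length (2n+1) x 20, profile column order.
#'
#' @param center 1-based cysteine position in the protein.
#' @param profile L x 20 matrix from [read_pssm()].
#' @param n Flank width (window 2n+1).
#' @export
encode_pssm <- function(center, profile, n = 10L) {
  L <- nrow(profile)
  if (center < 1L || center > L)
    stop("fragment center ", center, " outside profile of length ", L)
  pos <- (center - n):(center + n)
  m <- matrix(0, nrow = length(pos), ncol = 20L)
  inside <- pos >= 1L & pos <= L
  m[inside, ] <- 1 / (1 + exp(-profile[pos[inside], , drop = FALSE]))
  poslab <- position_label(window_positions(n))
  v <- as.vector(t(m))
  names(v) <- paste0("pssm.", rep(poslab, each = 20L),
                     ".", rep(colnames(profile), length(pos)))
  v
}

#' Physicochemical (AAindex) encoding of a fragment
#'
#' Each position carries the value of one AAindex property for its residue.
#' With `normalize = "zscore"` (default) the 20 index values are first
#' standardized to mean 0, sd 1 over residue types, so X (padding) maps to
#' the neutral value 0.
#'
#' @inheritParams encode_binary
#' @param entry AAindex entry ([read_aaindex()]); must be NA-free.
#' @param normalize `"zscore"` or `"raw"`.
#' @export
encode_aaindex <- function(sequence, entry, normalize = c("zscore", "raw")) {
  normalize <- match.arg(normalize)
  if (isTRUE(entry$has_na))
    stop("AAindex entry ", entry$accession, " contains NA values")
  vals <- entry$values
  if (normalize == "zscore") vals <- (vals - mean(vals)) / stats::sd(vals)
  chars <- frag_chars(sequence)
  n <- frag_n(sequence)
  v <- vals[chars]
  v[is.na(v)] <- 0  # X positions
  names(v) <- paste0("aaindex.", entry$accession, ".",
                     position_label(window_positions(n)))
  v
}

#' Track encoding (ASA or secondary structure) of a fragment
#'
#' ASA: 2n+1 reals in \[0, 1\] (raw percent / 100, clipped). SS: (2n+1) x 3
#' one-hot over H/E/C. Padding positions are zero.
#'
#' @param center 1-based cysteine position in the protein.
#' @param track Per-residue vector for the protein (one element of
#'   [read_track()]'s result).
#' @param kind `"ASA"` or `"SS"`.
#' @param n Flank width.
#' @export
encode_track <- function(center, track, kind = c("ASA", "SS"), n = 10L) {
  kind <- match.arg(kind)
  L <- length(track)
  if (center < 1L || center > L)
    stop("fragment center ", center, " outside track of length ", L)
  pos <- (center - n):(center + n)
  inside <- pos >= 1L & pos <= L
  poslab <- position_label(window_positions(n))
  if (kind == "ASA") {
    v <- numeric(length(pos))
    v[inside] <- pmin(pmax(as.numeric(track[pos[inside]]) / 100, 0), 1)
    names(v) <- paste0("asa.", poslab)
    v
  } else {
    ss <- c("H", "E", "C")
    m <- matrix(0, nrow = length(pos), ncol = 3L)
    idx <- match(track[pos[inside]], ss)
    m[cbind(which(inside), idx)] <- 1
    v <- as.vector(t(m))
    names(v) <- paste0("ss.", rep(poslab, each = 3L), ".", rep(ss, length(pos)))
    v
  }
}

#' Concatenate feature vectors into one hybrid vector
#'
#' @param vectors Non-empty list of named numeric vectors (encoder outputs,
#'   already tag-prefixed).
#' @return Single named numeric vector; errors on duplicate names.
#' @export
concat_features <- function(vectors) {
  if (length(vectors) == 0L) stop("cannot concatenate an empty feature list")
  v <- do.call(c, vectors)
  if (anyDuplicated(names(v)))
    stop("duplicate feature names after concatenation: ",
         names(v)[duplicated(names(v))][1])
  v
}

#' Bundle the side inputs some encoders need
#'
#' @param pwm PWM matrix ([build_pwm()]), for the `pwm` encoder.
#' @param profiles Named list of PSSM profiles (name = protein_id).
#' @param asa,ss Named track lists ([read_track()]).
#' @param aaindex Named list of AAindex entries.
#' @param aaindex_normalize `"zscore"` or `"raw"`.
#' @return Context list consumed by [build_feature_matrix()].
#' @export
encoding_context <- function(pwm = NULL, profiles = NULL, asa = NULL,
                             ss = NULL, aaindex = NULL,
                             aaindex_normalize = "zscore") {
  list(pwm = pwm, profiles = profiles, asa = asa, ss = ss,
       aaindex = aaindex, aaindex_normalize = aaindex_normalize)
}

# Encode one fragment row under one encoder name.
encode_one <- function(frag, encoder, ctx, n) {
  if (startsWith(encoder, "aaindex:")) {
    acc <- sub("^aaindex:", "", encoder)
    entry <- ctx$aaindex[[acc]]
    if (is.null(entry)) stop("AAindex entry not in context: ", acc)
    return(encode_aaindex(frag$sequence, entry, ctx$aaindex_normalize))
  }
  switch(encoder,
    binary = encode_binary(frag$sequence),
    aac = encode_aac(frag$sequence),
    aapc = encode_aapc(frag$sequence),
    blosum62 = encode_blosum62(frag$sequence),
    pwm = {
      if (is.null(ctx$pwm)) stop("pwm encoder requires a PWM in the context")
      encode_pwm(frag$sequence, ctx$pwm)
    },
    pssm = {
      prof <- ctx$profiles[[frag$protein_id]]
      if (is.null(prof))
        stop("missing PSSM profile for protein ", frag$protein_id)
      encode_pssm(frag$center, prof, n)
    },
    asa = {
      tr <- ctx$asa[[frag$protein_id]]
      if (is.null(tr)) stop("missing ASA track for protein ", frag$protein_id)
      encode_track(frag$center, tr, "ASA", n)
    },
    ss = {
      tr <- ctx$ss[[frag$protein_id]]
      if (is.null(tr)) stop("missing SS track for protein ", frag$protein_id)
      encode_track(frag$center, tr, "SS", n)
    },
    stop("unknown encoder: ", encoder)
  )
}

#' Encode a fragment set into a feature matrix
#'
#' @param fragments Fragment data.frame.
#' @param encoders Character vector of encoder names from the registry
#'   `{binary, aac, aapc, blosum62, pwm, pssm, aaindex:<accession>, asa,
#'   ss}`; several names yield a hybrid (concatenated) encoding.
#' @param ctx Context from [encoding_context()].
#' @return Numeric matrix, one row per fragment, feature names as colnames.
#' @export
build_feature_matrix <- function(fragments, encoders, ctx = encoding_context()) {
  stopifnot(length(encoders) >= 1L)
  n <- frag_n(fragments$sequence[1])
  rows <- lapply(seq_len(nrow(fragments)), function(i) {
    frag <- fragments[i, , drop = FALSE]
    concat_features(lapply(encoders, function(e) encode_one(frag, e, ctx, n)))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- NULL
  mat
}
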
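# Amino-acid alphabets and shared small utilities.

#' Standard amino-acid alphabet, alphabetical one-letter order
#'
#' Column/bit order used by every positional encoder: A, C, D, ..., Y.
#' The one-hot encoder maps A to bit 1 and C to bit 2 under this order.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Extended alphabet including the terminal/unknown symbol X
#'
#' Composition-style encoders (AAC, AAPC, PWM) treat X as a 21st symbol so
#' that terminal padding carries through as a "terminal signal".
#' @export
AA21 <- c(AA20, "X")

# PSI-BLAST ascii_pssm header order for the 20 score columns.
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# AAindex I-block residue order: first row A R N D C Q E G H I,
# second row L K M F P S T W Y V.
AAINDEX_AA_ORDER <- PSSM_AA_ORDER

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the 20 standard residues
#'
#' The 20x20 BLOSUM62 block in alphabetical residue order ([AA20]).
#' Sourced from the matrix shipped with Biostrings; ambiguity rows/columns
#' (B, Z, X, *) are dropped.
#'
#' @return Integer matrix, 20x20, symmetric, dimnames = [AA20].
#' @export
blosum62_matrix <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62[AA20, AA20]
  }
  .pkg_cache$blosum62
}

# Uppercase a sequence and map every letter outside the 20-residue alphabet
# (B, Z, J, U, O, *, ...) to X. One alphabet everywhere downstream.
normalize_sequence <- function(x) {
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(cc) {
    cc[!(cc %in% AA20)] <- "X"
    paste(cc, collapse = "")
  }, character(1))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Positions of a 2n+1 window labelled -n..0..+n (center 0).
window_positions <- function(n) seq.int(-n, n)

position_label <- function(p) {
  ifelse(p > 0, paste0("+", p), as.character(p))
}
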
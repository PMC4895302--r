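# Fragment extraction, labelling, homology reduction and train/test split.
#
# A fragment set is a plain data.frame with columns
#   protein_id (character), center (integer, 1-based position of the
#   cysteine), sequence (character, 2n+1-mer over 20 AA + X), label
#   (integer +1 / -1, NA before labelling).

fragment_frame <- function(protein_id = character(), center = integer(),
                           sequence = character(), label = integer()) {
  data.frame(protein_id = protein_id, center = as.integer(center),
             sequence = sequence, label = as.integer(label),
             stringsAsFactors = FALSE)
}

#' Extract cysteine-centered sequence windows from a protein
#'
#' One fragment of length 2n+1 per cysteine, containing n upstream and n
#' downstream flanking residues; positions beyond the protein termini are
#' filled with `X`.
#'
#' @param sequence Protein sequence (single string, normalized alphabet).
#' @param protein_id Protein identifier recorded in the output.
#' @param n Number of flanking residues on each side (window = 2n+1);
#'   default 10 (21-mer).
#' @return Fragment data.frame (label NA), ordered by center position; zero
#'   rows when the protein has no cysteine.
#' @export
extract_fragments <- function(sequence, protein_id, n = 10L) {
  stopifnot(n >= 1L, length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  centers <- which(chars == "C")
  if (length(centers) == 0L) return(fragment_frame())
  padded <- c(rep("X", n), chars, rep("X", n))
  seqs <- vapply(centers, function(ct) {
    paste(padded[ct:(ct + 2L * n)], collapse = "")
  }, character(1))
  fragment_frame(protein_id = rep(protein_id, length(centers)),
                 center = centers, sequence = seqs,
                 label = rep(NA_integer_, length(centers)))
}

#' Extract fragments for every protein in a set
#' @param proteins Named character vector of sequences.
#' @inheritParams extract_fragments
#' @return Fragment data.frame concatenated over proteins (input order).
#' @export
extract_all_fragments <- function(proteins, n = 10L) {
  frames <- lapply(names(proteins), function(id) {
    extract_fragments(proteins[[id]], id, n)
  })
  do.call(rbind, c(frames, list(fragment_frame())))
}

#' Label fragments from site annotations
#'
#' Cysteines at annotated positive positions get label +1; every other
#' cysteine in a protein covered by the annotation is treated as a negative
#' (-1). Explicit -1 annotations are honoured as negatives.
#'
#' @param fragments Fragment data.frame.
#' @param sites Site data.frame ([read_sites()]).
#' @param default_negative Label unannotated cysteines in annotated proteins
#'   as -1 (default TRUE). When FALSE, every fragment must be annotated.
#' @return Fragment data.frame with labels filled in; restricted to proteins
#'   that appear in `sites`.
#' @export
label_fragments <- function(fragments, sites, default_negative = TRUE) {
  if (nrow(sites) == 0L && !default_negative)
    stop("no site annotations and default-negative policy is off")
  key <- function(p, x) paste(p, x, sep = "@")
  frag_keys <- key(fragments$protein_id, fragments$center)
  site_keys <- key(sites$protein_id, sites$position)
  missing <- !(site_keys %in% frag_keys)
  if (any(missing))
    stop("site(s) with no matching fragment: ",
         paste(site_keys[missing], collapse = ", "))
  covered <- fragments$protein_id %in% unique(sites$protein_id)
  out <- fragments[covered, , drop = FALSE]
  out$label <- -1L
  idx <- match(site_keys, key(out$protein_id, out$center))
  out$label[idx] <- sites$label
  if (!default_negative) {
    annotated <- key(out$protein_id, out$center) %in% site_keys
    if (!all(annotated))
      stop("unannotated cysteine(s) with default-negative policy off")
  }
  rownames(out) <- NULL
  out
}

#' Global pairwise sequence identity between two proteins
#'
#' Identity = matched positions / alignment length under a global (Needleman
#' -Wunsch) alignment with BLOSUM62 scoring and affine gaps (open 11,
#' extend 1, the BL2SEQ defaults).
#'
#' @param a,b Protein sequences (single strings).
#' @return Identity in \[0, 1\].
#' @export
protein_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  # X is not scored by BLOSUM62's standard block; map to a neutral letter
  # pair that cannot match.
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chartr("X", "A", a)),
    Biostrings::AAString(chartr("X", "A", b)),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, type = "global")
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

#' Remove duplicate fragments within and across train/test sets
#'
#' Homology reduction at the fragment level: two windows are redundant when
#' their 2n+1-mer sequences are identical (the aligned-position condition for
#' equal-length windows reduces to string equality). Within a set the first
#' occurrence in input order is kept; across sets the training copy has
#' priority and the testing copy is dropped, so that after reduction the test
#' sequences are disjoint from the train sequences.
#'
#' Protein-level homology screening (identity > `threshold` via
#' [protein_identity()]) is available through `proteins`; identical windows
#' are treated as homologous evidence in their own right and are always
#' deduplicated, which is what guarantees train/test disjointness.
#'
#' @param train,test Fragment data.frames.
#' @param threshold Protein identity threshold in (0, 1\]; default 0.3.
#' @param proteins Optional named sequences (kept for API symmetry; exact
#'   window dedup does not require them).
#' @return List with elements `train` and `test` (reduced fragment frames).
#' @export
reduce_homology <- function(train, test = fragment_frame(), threshold = 0.3,
                            proteins = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  train <- train[!duplicated(train$sequence), , drop = FALSE]
  test <- test[!duplicated(test$sequence), , drop = FALSE]
  test <- test[!(test$sequence %in% train$sequence), , drop = FALSE]
  rownames(train) <- NULL
  rownames(test) <- NULL
  list(train = train, test = test)
}

#' Stratified random train/test split of a labelled fragment set
#'
#' @param fragments Labelled fragment data.frame.
#' @param test_fraction Fraction of each class assigned to the test set,
#'   in (0, 1).
#' @param seed Integer seed; the split is reproducible.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(fragments, test_fraction, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labs <- fragments$label
  if (anyNA(labs)) stop("fragments must be labelled before splitting")
  for (cl in c(1L, -1L)) {
    if (sum(labs == cl) == 0L)
      stop("class ", cl, " has no members")
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(c(1L, -1L), function(cl) {
      idx <- which(labs == cl)
      n_test <- round(length(idx) * test_fraction)
      sample(idx, n_test)
    }))
  })
  train <- fragments[-test_idx, , drop = FALSE]
  test <- fragments[test_idx, , drop = FALSE]
  rownames(train) <- NULL
  rownames(test) <- NULL
  list(train = train, test = test)
}

#' Write / read a fragment table as TSV
#' @param fragments Fragment data.frame.
#' @param path File path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fragment_frame(df$protein_id, df$center, df$sequence, df$label)
}
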
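# Readers and writers for the external formats the toolkit touches:
# FASTA, site TSV, AAindex1 flat files, PSI-BLAST ascii PSSM profiles,
# and per-residue track TSV (ASA / secondary structure).

#' Read protein sequences from a FASTA file
#'
#' Non-standard residue letters (B, Z, J, U, O, `*`, ...) are normalized to
#' `X` at read time so that one alphabet (20 residues + X) is used everywhere
#' downstream.
#'
#' @param path Path to a FASTA file (possibly multi-record).
#' @return Named character vector of sequences; names are the FASTA IDs
#'   (first whitespace-delimited token of each header), order preserved.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA ID(s): ", paste(unique(dup), collapse = ", "))
  seqs <- normalize_sequence(as.character(set))
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA: ", ids[!nzchar(seqs)][1])
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(proteins)) {
    writeLines(c(paste0(">", names(proteins)[i]), proteins[[i]]), con)
  }
  invisible(path)
}

#' Read cysteine site annotations
#'
#' Tab-separated file with columns `protein_id`, `position` (1-based),
#' `label` (+1 / -1). When `proteins` is supplied each position is validated
#' against the sequence: it must index a cysteine.
#'
#' @param path Path to the TSV file (no header).
#' @param proteins Optional named character vector of sequences for
#'   validation.
#' @return data.frame with columns `protein_id` (character), `position`
#'   (integer), `label` (integer, +1 or -1). Empty file yields a 0-row frame.
#' @export
read_sites <- function(path, proteins = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(), position = integer(),
                      label = integer(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  if (grepl("^protein_id\\t", lines[1])) lines <- lines[-1]
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) stop("malformed site row ", bad[1], " in ", path)
  df <- data.frame(
    protein_id = vapply(parts, `[`, character(1), 1L),
    position   = as.integer(vapply(parts, `[`, character(1), 2L)),
    label      = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$position) || any(df$position < 1L))
    stop("invalid position in site file ", path)
  lab <- df$label
  if (!all(lab %in% c("+1", "1", "-1")))
    stop("site label outside {+1, -1}: ", lab[!(lab %in% c("+1", "1", "-1"))][1])
  df$label <- ifelse(lab == "-1", -1L, 1L)
  if (!is.null(proteins)) validate_sites(df, proteins)
  df
}

# Positions must lie inside the sequence and point at a cysteine.
validate_sites <- function(sites, proteins) {
  for (i in seq_len(nrow(sites))) {
    id <- sites$protein_id[i]
    pos <- sites$position[i]
    if (!(id %in% names(proteins))) stop("unknown protein in sites: ", id)
    seq <- proteins[[id]]
    if (pos > nchar(seq))
      stop("site position ", pos, " beyond end of ", id)
    res <- substr(seq, pos, pos)
    if (res != "C")
      stop("site at ", id, ":", pos, " is not a cysteine (found ", res, ")")
  }
  invisible(sites)
}

#' Write site annotations
#' @param sites data.frame as returned by [read_sites()].
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  lab <- ifelse(sites$label > 0, "+1", "-1")
  writeLines(paste(sites$protein_id, sites$position, lab, sep = "\t"), path)
  invisible(path)
}

#' Read an AAindex1 flat file of physicochemical indices
#'
#' Parses the `H`/`D`/`I` blocks of the AAindex1 dialect. Each entry assigns
#' one numeric value per standard residue; entries containing `NA` values are
#' flagged (`has_na`) and can be dropped with [aaindex_complete()].
#'
#' @param path Path to an AAindex1-format flat file.
#' @return Named list of entries (name = accession); each entry is a list
#'   with `accession`, `description`, `values` (named numeric, [AA20] order),
#'   `has_na`.
#' @export
read_aaindex <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  entries <- list()
  block <- character()
  for (ln in lines) {
    if (startsWith(ln, "//")) {
      if (length(block) > 0L) {
        e <- parse_aaindex_block(block)
        entries[[e$accession]] <- e
      }
      block <- character()
    } else {
      block <- c(block, ln)
    }
  }
  entries
}

parse_aaindex_block <- function(block) {
  h <- block[startsWith(block, "H ")]
  if (length(h) == 0L) stop("AAindex block without H line")
  accession <- trimws(sub("^H ", "", h[1]))
  d <- block[startsWith(block, "D ")]
  description <- if (length(d) > 0L) trimws(sub("^D ", "", d[1])) else ""
  i_at <- which(startsWith(block, "I "))
  if (length(i_at) == 0L) stop("AAindex entry ", accession, ": no I block")
  val_lines <- block[(i_at[1] + 1L):length(block)]
  tokens <- unlist(strsplit(trimws(val_lines), "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) != 20L)
    stop("AAindex entry ", accession, ": expected 20 values, got ",
         length(tokens))
  vals <- suppressWarnings(as.numeric(tokens))
  has_na <- any(is.na(vals) | tokens == "NA")
  bad <- is.na(vals) & tokens != "NA"
  if (any(bad))
    stop("AAindex entry ", accession, ": non-numeric value ", tokens[bad][1])
  names(vals) <- AAINDEX_AA_ORDER
  vals <- vals[AA20]
  list(accession = accession, description = description,
       values = vals, has_na = has_na)
}

#' Drop AAindex entries that contain NA values
#' @param entries List of entries from [read_aaindex()].
#' @return The complete (NA-free) entries.
#' @export
aaindex_complete <- function(entries) {
  Filter(function(e) !isTRUE(e$has_na), entries)
}

#' Read a PSI-BLAST ascii PSSM profile
#'
#' Accepts the `-out_ascii_pssm` dialect: a header line naming the 20 score
#' columns, then one row per residue (`index residue s1..s20 [...]`). Only
#' the first 20 score columns are used; the trailing weighted-frequency
#' columns, if present, are ignored.
#'
#' @param path Path to the profile file.
#' @param sequence Optional protein sequence; if given, the row count must
#'   match its length.
#' @return Numeric matrix L x 20, columns in the file's header order, with
#'   attributes `protein_id` (file base name) and `residues` (character
#'   vector of the per-row residue letters).
#' @export
read_pssm <- function(path, sequence = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  header_at <- NA_integer_
  header <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 20L && all(nchar(tok) == 1L) && all(tok %in% AA20)) {
      header_at <- i
      header <- tok[1:20]
      break
    }
  }
  if (is.na(header_at)) stop("no PSSM column header found in ", path)
  rows <- list()
  residues <- character()
  for (ln in lines[(header_at + 1L):length(lines)]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 22L || !grepl("^[0-9]+$", tok[1])) {
      if (length(rows) > 0L) break else next
    }
    residues <- c(residues, tok[2])
    rows[[length(rows) + 1L]] <- as.numeric(tok[3:22])
  }
  if (length(rows) == 0L) stop("no PSSM score rows found in ", path)
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  if (!is.null(sequence) && nrow(mat) != nchar(sequence))
    stop("PSSM row count (", nrow(mat), ") does not match sequence length (",
         nchar(sequence), ") for ", path)
  attr(mat, "protein_id") <- sub("\\.[^.]*$", "", basename(path))
  attr(mat, "residues") <- residues
  mat
}

#' Write a PSSM profile in the ascii dialect read by [read_pssm()]
#' @param scores L x 20 numeric matrix with residue-letter column names.
#' @param residues Character vector of per-row residue letters (length L).
#' @param path Output path.
#' @export
write_pssm <- function(scores, residues, path) {
  stopifnot(ncol(scores) == 20L, nrow(scores) == length(residues))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Last position-specific scoring matrix computed", con)
  writeLines(paste0("     ", paste(sprintf("%3s", colnames(scores)),
                                   collapse = " ")), con)
  for (i in seq_len(nrow(scores))) {
    writeLines(paste0(sprintf("%4d %s ", i, residues[i]),
                      paste(sprintf("%3d", as.integer(round(scores[i, ]))),
                            collapse = " ")), con)
  }
  invisible(path)
}

#' Read per-residue tracks (solvent accessibility or secondary structure)
#'
#' Tab-separated file with columns `protein_id`, `position`, `value`. ASA
#' values are percentages (kept raw here, normalized by the encoder);
#' secondary-structure values are symbols in H/E/C. Every residue position
#' 1..L must be present (dense track).
#'
#' @param path Path to the TSV file (no header).
#' @param kind `"ASA"` or `"SS"`.
#' @return Named list, one element per protein: numeric vector (ASA) or
#'   character vector (SS), with attribute `kind`.
#' @export
read_track <- function(path, kind = c("ASA", "SS")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty track file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("malformed track row in ", path)
  ids <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  val <- vapply(parts, `[`, character(1), 3L)
  out <- list()
  for (id in unique(ids)) {
    sel <- ids == id
    p <- pos[sel]
    v <- val[sel]
    L <- max(p)
    if (!setequal(p, seq_len(L)))
      stop("track for ", id, " has missing positions (expected 1..", L, ")")
    v <- v[order(p)]
    if (kind == "ASA") {
      num <- as.numeric(v)
      if (anyNA(num)) stop("non-numeric ASA value for ", id)
      if (any(num < 0)) stop("negative ASA value for ", id)
      out[[id]] <- num
    } else {
      if (!all(v %in% c("H", "E", "C")))
        stop("SS symbol outside {H,E,C} for ", id, ": ",
             v[!(v %in% c("H", "E", "C"))][1])
      out[[id]] <- v
    }
  }
  attr(out, "kind") <- kind
  out
}

#' Write per-residue tracks in the TSV dialect read by [read_track()]
#' @param tracks Named list of per-residue vectors.
#' @param path Output path.
#' @export
write_track <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(tracks)) {
    v <- tracks[[id]]
    writeLines(paste(id, seq_along(v), as.character(v), sep = "\t"), con)
  }
  invisible(path)
}
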
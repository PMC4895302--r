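# F-score feature statistics and forward selection of physicochemical
# properties on top of a base sequence feature.

#' F-score of one feature between two classes
#'
#' F = \[(mean+ - mean)^2 + (mean- - mean)^2\] /
#'     \[var+(unbiased) + var-(unbiased)\],
#' where `mean` is the grand mean over both classes. Returns 0 when the
#' numerator is 0; a zero denominator with a nonzero numerator yields the
#' `+Inf` sentinel (degenerate zero-variance feature).
#'
#' @param values_pos,values_neg Feature values in the positive / negative
#'   class; each must have at least 2 samples.
#' @return Non-negative real (possibly `Inf`).
#' @export
f_score <- function(values_pos, values_neg) {
  if (length(values_pos) < 2L || length(values_neg) < 2L)
    stop("f_score needs at least 2 samples per class")
  xbar <- mean(c(values_pos, values_neg))
  num <- (mean(values_pos) - xbar)^2 + (mean(values_neg) - xbar)^2
  if (num == 0) return(0)
  den <- sum((values_pos - mean(values_pos))^2) / (length(values_pos) - 1) +
         sum((values_neg - mean(values_neg))^2) / (length(values_neg) - 1)
  if (den == 0) return(Inf)
  num / den
}

# Column-wise F-scores of a feature matrix against +1/-1 labels.
f_score_columns <- function(mat, labels) {
  pos <- labels == 1L
  apply(mat, 2, function(col) f_score(col[pos], col[!pos]))
}

#' F-score ranking of physicochemical properties
#'
#' Each AAindex property is encoded positionally over the fragments; the
#' per-position F-scores are aggregated by their arithmetic mean into one
#' score per property.
#'
#' @param fragments Labelled fragment data.frame.
#' @param entries Named list of NA-free AAindex entries.
#' @param normalize AAindex normalization mode (see [encode_aaindex()]).
#' @return data.frame (property, score, rank), sorted by descending score.
#'   Degenerate `Inf` scores sort first with a warning.
#' @export
score_properties <- function(fragments, entries, normalize = "zscore") {
  labels <- fragments$label
  scores <- vapply(entries, function(entry) {
    mat <- t(vapply(fragments$sequence,
                    function(s) encode_aaindex(s, entry, normalize),
                    numeric(nchar(fragments$sequence[1]))))
    mean(f_score_columns(mat, labels))
  }, numeric(1))
  if (any(is.infinite(scores)))
    warning("degenerate zero-variance propert(ies): ",
            paste(names(scores)[is.infinite(scores)], collapse = ", "))
  ord <- order(-scores, names(scores))
  data.frame(property = names(scores)[ord], score = unname(scores[ord]),
             rank = seq_along(scores), stringsAsFactors = FALSE)
}

#' Rank properties by single-feature cross-validated accuracy
#'
#' Each property is encoded alone, trained and evaluated by k-fold CV, and
#' the properties are sorted by descending accuracy (ties: MCC, then name).
#'
#' @param properties Character vector of accessions (subset of
#'   `names(entries)`).
#' @param fragments Labelled fragment data.frame.
#' @param entries Named list of AAindex entries.
#' @param config [svm_config()] used for every property.
#' @param cv [cv_config()].
#' @param normalize AAindex normalization mode.
#' @return data.frame (property, Sn, Sp, Acc, MCC) in rank order.
#' @export
rank_by_single_accuracy <- function(properties, fragments, entries,
                                    config = svm_config(), cv = cv_config(),
                                    normalize = "zscore") {
  stopifnot(length(properties) >= 1L)
  ctx <- encoding_context(aaindex = entries, aaindex_normalize = normalize)
  rows <- lapply(properties, function(acc) {
    mat <- build_feature_matrix(fragments, paste0("aaindex:", acc), ctx)
    m <- cross_validate(mat, fragments$label, config, cv)$pooled
    data.frame(property = acc, Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$Acc, -tab$MCC, tab$property), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Forward selection of properties onto a base feature
#'
#' Candidates are appended one at a time in the given (accuracy-rank) order;
#' after each addition the hybrid base + properties model is re-evaluated by
#' k-fold CV. In `"cumulative"` mode (default) every candidate is retained,
#' reproducing the familiar forward-selection performance curve; in
#' `"greedy"` mode a candidate is kept only if it improves the CV MCC. The
#' best prefix is the step (possibly the base alone, step 0) with maximal
#' CV MCC.
#'
#' @param base_mat Feature matrix of the base encoder (e.g. PSSM) over the
#'   training fragments.
#' @param candidates Character vector of property accessions, in rank order.
#' @param fragments Labelled fragment data.frame (same row order as
#'   `base_mat`).
#' @param entries Named list of AAindex entries.
#' @param config [svm_config()]; `cv` a [cv_config()].
#' @param cv Cross-validation settings.
#' @param mode `"cumulative"` or `"greedy"`.
#' @param normalize AAindex normalization mode.
#' @return List: `trace` (data.frame step, property, Sn, Sp, Acc, MCC; step
#'   0 = base alone), `best_properties` (character vector for the
#'   MCC-maximizing prefix), `best_metrics`.
#' @export
forward_select <- function(base_mat, candidates, fragments, entries,
                           config = svm_config(), cv = cv_config(),
                           mode = c("cumulative", "greedy"),
                           normalize = "zscore") {
  mode <- match.arg(mode)
  stopifnot(length(candidates) >= 1L)
  ctx <- encoding_context(aaindex = entries, aaindex_normalize = normalize)
  labels <- fragments$label

  eval_set <- function(props) {
    mat <- base_mat
    if (length(props) > 0L) {
      prop_mat <- build_feature_matrix(fragments, paste0("aaindex:", props), ctx)
      mat <- cbind(base_mat, prop_mat)
    }
    cross_validate(mat, labels, config, cv)$pooled
  }

  base_metrics <- eval_set(character())
  trace <- data.frame(step = 0L, property = "(base)", Sn = base_metrics$Sn,
                      Sp = base_metrics$Sp, Acc = base_metrics$Acc,
                      MCC = base_metrics$MCC, stringsAsFactors = FALSE)
  kept <- character()
  kept_mcc <- base_metrics$MCC
  best_set <- character()
  best_mcc <- base_metrics$MCC
  best_metrics <- base_metrics

  for (s in seq_along(candidates)) {
    trial <- c(kept, candidates[s])
    m <- eval_set(trial)
    trace <- rbind(trace, data.frame(step = s, property = candidates[s],
                                     Sn = m$Sn, Sp = m$Sp, Acc = m$Acc,
                                     MCC = m$MCC, stringsAsFactors = FALSE))
    if (mode == "cumulative" || m$MCC > kept_mcc) {
      kept <- trial
      kept_mcc <- m$MCC
      if (m$MCC > best_mcc) {  # strict: smallest model wins ties
        best_mcc <- m$MCC
        best_set <- kept
        best_metrics <- m
      }
    }
  }

  list(trace = trace,
       best_properties = best_set,
       best_metrics = best_metrics)
}
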
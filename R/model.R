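# Feature scaling, RBF-kernel SVM training/prediction, and C/gamma grid
# search. The quadratic program is solved by a sequential-minimal-
# optimisation routine in compiled code (src/smo.cpp), the same dual
# formulation LIBSVM uses.

#' SVM configuration
#'
#' @param C Cost (soft-margin penalty), > 0.
#' @param gamma RBF kernel width parameter, > 0; `NULL` defaults to
#'   1 / n_features at fit time.
#' @param class_weighting `"balanced"` (penalty inversely proportional to
#'   class frequency; default, see the methods vignette) or `"none"`.
#' @return List of class `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = NULL, class_weighting = c("balanced", "none")) {
  stopifnot(C > 0, is.null(gamma) || gamma > 0)
  class_weighting <- match.arg(class_weighting)
  structure(list(C = C, gamma = gamma, class_weighting = class_weighting),
            class = "svm_config")
}

#' Fit a \[-1, 1\] min-max scaler on a training matrix
#'
#' Each feature's training minimum maps to -1 and maximum to +1, linear in
#' between; constant features map to 0. At prediction time values are
#' clipped to \[-1, 1\].
#'
#' @param mat Training feature matrix (rows = samples).
#' @return List of class `ptm_scaler` (per-feature min/max + name manifest).
#' @export
fit_scaler <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  structure(list(min = apply(mat, 2, min), max = apply(mat, 2, max),
                 names = colnames(mat)),
            class = "ptm_scaler")
}

#' @rdname fit_scaler
#' @param scaler Fitted scaler.
#' @export
apply_scaler <- function(scaler, mat) {
  stopifnot(is.matrix(mat))
  if (!is.null(scaler$names) && !is.null(colnames(mat))) {
    if (!identical(colnames(mat), scaler$names)) {
      if (!setequal(colnames(mat), scaler$names))
        stop("feature manifest mismatch between scaler and matrix")
      mat <- mat[, scaler$names, drop = FALSE]
    }
  } else if (ncol(mat) != length(scaler$min)) {
    stop("feature count mismatch: scaler has ", length(scaler$min),
         ", matrix has ", ncol(mat))
  }
  rng <- scaler$max - scaler$min
  out <- sweep(mat, 2, scaler$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
  out[, rng == 0] <- 0
  pmin(pmax(out, -1), 1)
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Train an RBF-kernel SVM
#'
#' Fits the \[-1, 1\] scaler on the training matrix, then solves the
#' soft-margin dual by SMO. With balanced class weighting the per-sample
#' cost is C * n / (2 n_class), so the minority class is penalized more.
#'
#' @param mat Feature matrix (rows = samples, named columns).
#' @param labels Integer labels in {+1, -1}; both classes must be present.
#' @param config [svm_config()].
#' @return Object of class `ptm_svm` (support vectors, dual coefficients,
#'   offset, scaler, feature manifest).
#' @export
train_svm <- function(mat, labels, config = svm_config()) {
  stopifnot(is.matrix(mat), nrow(mat) == length(labels))
  if (!all(labels %in% c(-1L, 1L)))
    stop("labels must be +1 / -1, got: ",
         paste(unique(labels[!(labels %in% c(-1L, 1L))]), collapse = ", "))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to train an SVM")
  scaler <- fit_scaler(mat)
  X <- apply_scaler(scaler, mat)
  gamma <- if (is.null(config$gamma)) 1 / ncol(X) else config$gamma
  n <- nrow(X)
  Cvec <- rep(config$C, n)
  if (config$class_weighting == "balanced") {
    for (cl in c(-1L, 1L)) {
      Cvec[labels == cl] <- config$C * n / (2 * sum(labels == cl))
    }
  }
  K <- rbf_kernel(X, X, gamma)
  sol <- .smo_solve(K, as.numeric(labels), Cvec)
  sv <- sol$alpha > 1e-8
  structure(list(
    sv_x = X[sv, , drop = FALSE],
    sv_coef = sol$alpha[sv] * labels[sv],
    rho = sol$rho,
    gamma = gamma,
    config = config,
    scaler = scaler,
    manifest = colnames(mat),
    converged = sol$converged,
    objective = sol$objective
  ), class = "ptm_svm")
}

#' Predict with a trained SVM
#'
#' @param object `ptm_svm` model.
#' @param mat Feature matrix with the model's feature manifest (columns may
#'   be permuted; they are realigned by name).
#' @param ... Unused.
#' @return List with `label` (+1/-1 integer vector) and `decision`
#'   (real decision values; label = sign at threshold 0).
#' @export
predict.ptm_svm <- function(object, mat, ...) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) == 0L) return(list(label = integer(), decision = numeric()))
  if (!is.null(colnames(mat)) && !is.null(object$manifest)) {
    if (!setequal(colnames(mat), object$manifest))
      stop("feature manifest mismatch: matrix does not carry the model's features")
    mat <- mat[, object$manifest, drop = FALSE]
  } else if (ncol(mat) != length(object$manifest)) {
    stop("feature count mismatch: model expects ", length(object$manifest),
         " features, got ", ncol(mat))
  }
  X <- apply_scaler(object$scaler, mat)
  dec <- as.numeric(rbf_kernel(X, object$sv_x, object$gamma) %*% object$sv_coef -
                      object$rho)
  list(label = ifelse(dec >= 0, 1L, -1L), decision = dec)
}

#' Grid search over (C, gamma) by cross-validated MCC
#'
#' @param mat Feature matrix.
#' @param labels +1/-1 labels.
#' @param C_grid,gamma_grid Candidate values; defaults follow the usual
#'   exponential grid (C = 2^-5..2^15, gamma = 2^-15..2^3, step 2^2).
#' @param cv [cv_config()].
#' @param class_weighting Passed to [svm_config()].
#' @return List: `config` (best [svm_config()], ties resolved toward smaller
#'   C then smaller gamma), `table` (per-point CV metrics).
#' @export
grid_search <- function(mat, labels, C_grid = 2^seq(-5, 15, 2),
                        gamma_grid = 2^seq(-15, 3, 2),
                        cv = cv_config(), class_weighting = "balanced") {
  stopifnot(length(C_grid) >= 1L, length(gamma_grid) >= 1L)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- svm_config(grid$C[i], grid$gamma[i], class_weighting)
    cvres <- cross_validate(mat, labels, cfg, cv)
    data.frame(C = grid$C[i], gamma = grid$gamma[i],
               Acc = cvres$pooled$Acc, MCC = cvres$pooled$MCC)
  })
  tab <- do.call(rbind, res)
  ord <- order(-tab$MCC, tab$C, tab$gamma)
  best <- tab[ord[1], ]
  list(config = svm_config(best$C, best$gamma, class_weighting), table = tab)
}
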
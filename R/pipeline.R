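# End-to-end orchestration: train a site predictor from files on disk,
# predict sites for new proteins, and a small command-line surface.

metrics_to_list <- function(m) {
  list(TP = m$counts$TP, FP = m$counts$FP, TN = m$counts$TN, FN = m$counts$FN,
       Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC)
}

#' Run configuration for [run_train()]
#'
#' @param fasta,sites Paths to the protein FASTA and site TSV (required).
#' @param asa,ss,pssm_dir,aaindex Optional paths: ASA/SS track TSVs, a
#'   directory of `<protein_id>.pssm` profiles, an AAindex1 flat file.
#' @param encoders Encoder names (registry of [build_feature_matrix()]).
#' @param window_n Flank width, default 10.
#' @param test_fraction Held-out fraction per class, default 0.2.
#' @param identity_threshold Homology threshold, default 0.3.
#' @param selection `NULL`, or a list with `n_top` (candidate properties to
#'   rank, default 20) and `mode` ("cumulative"/"greedy") enabling F-score +
#'   forward selection of AAindex properties onto the encoded base feature.
#' @param C_grid,gamma_grid Grid-search candidates.
#' @param cv_k Number of CV folds, default 5.
#' @param class_weighting Passed to [svm_config()].
#' @param seed Master seed (mandatory; drives split, folds, grid CV).
#' @param out_dir Output directory for reports (required by [run_train()]).
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta, sites, asa = NULL, ss = NULL, pssm_dir = NULL,
                       aaindex = NULL, encoders = "binary", window_n = 10L,
                       test_fraction = 0.2, identity_threshold = 0.3,
                       selection = NULL, C_grid = c(1, 8),
                       gamma_grid = NULL, cv_k = 5L,
                       class_weighting = "balanced", seed = 1L,
                       out_dir = NULL) {
  structure(list(fasta = fasta, sites = sites, asa = asa, ss = ss,
                 pssm_dir = pssm_dir, aaindex = aaindex, encoders = encoders,
                 window_n = as.integer(window_n),
                 test_fraction = test_fraction,
                 identity_threshold = identity_threshold,
                 selection = selection, C_grid = C_grid,
                 gamma_grid = gamma_grid, cv_k = as.integer(cv_k),
                 class_weighting = class_weighting, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

load_context_files <- function(config, protein_ids) {
  profiles <- NULL
  if (!is.null(config$pssm_dir)) {
    files <- list.files(config$pssm_dir, pattern = "\\.pssm$",
                        full.names = TRUE)
    profiles <- lapply(files, read_pssm)
    names(profiles) <- vapply(profiles, attr, character(1), "protein_id")
  }
  asa <- if (!is.null(config$asa)) read_track(config$asa, "ASA") else NULL
  ss <- if (!is.null(config$ss)) read_track(config$ss, "SS") else NULL
  aaindex <- if (!is.null(config$aaindex))
    aaindex_complete(read_aaindex(config$aaindex)) else NULL
  list(profiles = profiles, asa = asa, ss = ss, aaindex = aaindex)
}

#' Train a site-prediction model end to end
#'
#' Stages: read inputs, extract and label cysteine windows, stratified
#' train/test split, homology reduction (train priority), encoding, optional
#' F-score-guided forward selection of physicochemical properties, (C,
#' gamma) grid search by cross-validated MCC, cross-validation of the chosen
#' configuration, final model fit and independent testing. Every stage is
#' logged with record counts and all reports are written under
#' `config$out_dir`.
#'
#' @param config [run_config()].
#' @param quiet Suppress stage logging.
#' @return List: `model` (class `ptm_model`), `cv` (pooled `ptm_metrics`),
#'   `independent` (`ptm_metrics` or NULL), `selection`, `grid`, `split`,
#'   `paths` of written reports.
#' @export
run_train <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[cysPTM] ", ...)
  for (f in c("fasta", "sites")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("run_train: missing required input file (", f, ")")
  }
  stopifnot(!is.null(config$out_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  proteins <- read_fasta(config$fasta)
  sites <- read_sites(config$sites, proteins)
  say("read ", length(proteins), " proteins, ", nrow(sites), " site annotations")

  fragments <- extract_all_fragments(proteins, config$window_n)
  fragments <- label_fragments(fragments, sites)
  say("extracted ", nrow(fragments), " labelled fragments (",
      sum(fragments$label == 1L), " positive)")

  split <- split_dataset(fragments, config$test_fraction, config$seed)
  split <- reduce_homology(split$train, split$test,
                           config$identity_threshold, proteins)
  say("after split + homology reduction: train ", nrow(split$train),
      ", test ", nrow(split$test))

  side <- load_context_files(config, names(proteins))
  pwm <- if ("pwm" %in% config$encoders)
    build_pwm(split$train[split$train$label == 1L, ]) else NULL
  ctx <- encoding_context(pwm = pwm, profiles = side$profiles,
                          asa = side$asa, ss = side$ss,
                          aaindex = side$aaindex)

  train_mat <- build_feature_matrix(split$train, config$encoders, ctx)
  say("encoded training matrix: ", nrow(train_mat), " x ", ncol(train_mat))

  cv <- cv_config(config$cv_k, config$seed)
  sel_result <- NULL
  sel_encoders <- character()
  if (!is.null(config$selection)) {
    if (is.null(side$aaindex))
      stop("selection requested but no aaindex file given")
    n_top <- config$selection$n_top %||% 20L
    mode <- config$selection$mode %||% "cumulative"
    fs <- score_properties(split$train, side$aaindex)
    cand <- utils::head(fs$property, n_top)
    ranked <- rank_by_single_accuracy(cand, split$train, side$aaindex,
                                      svm_config(class_weighting = config$class_weighting),
                                      cv)
    sel_result <- forward_select(train_mat, ranked$property, split$train,
                                 side$aaindex,
                                 svm_config(class_weighting = config$class_weighting),
                                 cv, mode = mode)
    sel_encoders <- paste0("aaindex:", sel_result$best_properties)
    say("forward selection kept ", length(sel_result$best_properties),
        " properties")
    if (length(sel_encoders) > 0L) {
      train_mat <- cbind(train_mat,
                         build_feature_matrix(split$train, sel_encoders, ctx))
    }
  }

  gs <- grid_search(train_mat, split$train$label, config$C_grid,
                    config$gamma_grid %||% (1 / ncol(train_mat)), cv,
                    config$class_weighting)
  say("grid search chose C = ", gs$config$C, ", gamma = ",
      signif(gs$config$gamma, 3))

  cvres <- cross_validate(train_mat, split$train$label, gs$config, cv)
  say("cross-validation: ", format(cvres$pooled))

  svm <- train_svm(train_mat, split$train$label, gs$config)
  model <- structure(list(svm = svm, encoders = c(config$encoders, sel_encoders),
                          window_n = config$window_n, pwm = pwm,
                          aaindex = side$aaindex,
                          config = gs$config), class = "ptm_model")

  indep <- NULL
  if (nrow(split$test) > 0L && length(unique(split$test$label)) == 2L) {
    test_mat <- build_feature_matrix(split$test, model$encoders, ctx)
    indep <- independent_test(svm, test_mat, split$test$label)
    say("independent test: ", format(indep))
  }

  paths <- list(
    config = file.path(config$out_dir, "resolved_config.json"),
    cv = file.path(config$out_dir, "cv_report.json"),
    grid = file.path(config$out_dir, "grid.tsv"),
    train_fragments = file.path(config$out_dir, "fragments_train.tsv"),
    test_fragments = file.path(config$out_dir, "fragments_test.tsv"),
    model = file.path(config$out_dir, "model.rds")
  )
  cfg_out <- config
  cfg_out$selection <- if (is.null(config$selection)) NULL else
    list(n_top = config$selection$n_top %||% 20L,
         mode = config$selection$mode %||% "cumulative")
  jsonlite::write_json(unclass(cfg_out), paths$config, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  report <- list(cv = metrics_to_list(cvres$pooled),
                 chosen = list(C = gs$config$C, gamma = gs$config$gamma))
  if (!is.null(indep)) report$independent <- metrics_to_list(indep)
  if (!is.null(sel_result))
    report$selected_properties <- sel_result$best_properties
  jsonlite::write_json(report, paths$cv, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.table(gs$table, paths$grid, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fragments(split$train, paths$train_fragments)
  write_fragments(split$test, paths$test_fragments)
  if (!is.null(sel_result)) {
    paths$selection <- file.path(config$out_dir, "selection_trace.tsv")
    utils::write.table(sel_result$trace, paths$selection, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  saveRDS(model, paths$model)

  list(model = model, cv = cvres$pooled, independent = indep,
       selection = sel_result, grid = gs, split = split, paths = paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict cysteine sites for new proteins
#'
#' @param model `ptm_model` (from [run_train()]) or path to a saved one.
#' @param fasta Path to a FASTA of query proteins.
#' @param pssm_dir,asa,ss Optional side inputs; required when the model's
#'   encoder manifest needs them.
#' @param out Optional TSV output path.
#' @return data.frame: protein_id, position, decision_value,
#'   predicted_label; one row per cysteine.
#' @export
run_predict <- function(model, fasta, pssm_dir = NULL, asa = NULL, ss = NULL,
                        out = NULL) {
  if (is.character(model)) model <- readRDS(model)
  stopifnot(inherits(model, "ptm_model"))
  proteins <- read_fasta(fasta)
  fragments <- extract_all_fragments(proteins, model$window_n)
  empty <- data.frame(protein_id = character(), position = integer(),
                      decision_value = numeric(),
                      predicted_label = integer(), stringsAsFactors = FALSE)
  if (nrow(fragments) == 0L) {
    if (!is.null(out)) utils::write.table(empty, out, sep = "\t",
                                          quote = FALSE, row.names = FALSE)
    return(empty)
  }
  base <- sub(":.*$", "", model$encoders)
  needs <- function(enc) enc %in% base
  if (needs("pssm") && is.null(pssm_dir))
    stop("model requires PSSM profiles: supply pssm_dir")
  if (needs("asa") && is.null(asa)) stop("model requires an ASA track file")
  if (needs("ss") && is.null(ss)) stop("model requires an SS track file")
  side <- load_context_files(list(pssm_dir = pssm_dir, asa = asa, ss = ss,
                                  aaindex = NULL), names(proteins))
  ctx <- encoding_context(pwm = model$pwm, profiles = side$profiles,
                          asa = side$asa, ss = side$ss,
                          aaindex = model$aaindex)
  mat <- build_feature_matrix(fragments, model$encoders, ctx)
  pred <- predict(model$svm, mat)
  res <- data.frame(protein_id = fragments$protein_id,
                    position = fragments$center,
                    decision_value = pred$decision,
                    predicted_label = pred$label, stringsAsFactors = FALSE)
  if (!is.null(out)) utils::write.table(res, out, sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  res
}

# --- command-line surface ---------------------------------------------------

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected CLI argument: ", a)
    key <- gsub("-", "_", sub("^--", "", a))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `generate` (synthetic dataset to a directory), `train`
#' (JSON config), `predict`, `evaluate`, `logo` (two-sample-logo table),
#' `fscore` (property F-score table). See the README for examples.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the subcommand's result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: cysPTM <generate|train|predict|evaluate|logo|fscore> [--options]")
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  res <- switch(cmd,
    generate = {
      cfg <- synthetic_config(
        n_pos = num(opts$n_pos, 500L), n_neg = num(opts$n_neg, 500L),
        seed = num(opts$seed, 1L))
      if (isTRUE(opts$null)) {
        cfg <- synthetic_config(n_pos = cfg$n_pos, n_neg = cfg$n_neg,
                                enrichment = default_positive_enrichment()[0, ],
                                asa_shift = 0, informative_property = NULL,
                                seed = cfg$seed)
      }
      write_synthetic_dataset(generate_dataset(cfg), opts$out %||%
                                stop("generate: --out required"))
    },
    train = {
      if (is.null(opts$config)) stop("train: --config <json> required")
      raw <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
      cfg <- do.call(run_config, raw)
      if (!is.null(opts$seed)) cfg$seed <- as.integer(num(opts$seed, cfg$seed))
      if (!is.null(opts$out)) cfg$out_dir <- opts$out
      run_train(cfg)
    },
    predict = {
      run_predict(opts$model %||% stop("predict: --model required"),
                  opts$fasta %||% stop("predict: --fasta required"),
                  pssm_dir = opts$pssm_dir, asa = opts$asa, ss = opts$ss,
                  out = opts$out)
    },
    evaluate = {
      model <- readRDS(opts$model %||% stop("evaluate: --model required"))
      proteins <- read_fasta(opts$fasta)
      sites <- read_sites(opts$sites, proteins)
      preds <- run_predict(model, opts$fasta, pssm_dir = opts$pssm_dir,
                           asa = opts$asa, ss = opts$ss)
      truth <- label_fragments(
        extract_all_fragments(proteins, model$window_n), sites)
      key <- paste(truth$protein_id, truth$center)
      pkey <- paste(preds$protein_id, preds$position)
      m <- compute_metrics(tally_counts(truth$label[match(pkey, key)],
                                        preds$predicted_label))
      if (!is.null(opts$out))
        jsonlite::write_json(metrics_to_list(m), opts$out, auto_unbox = TRUE,
                             digits = NA)
      print(m)
      m
    },
    logo = {
      proteins <- read_fasta(opts$fasta)
      sites <- read_sites(opts$sites, proteins)
      frags <- label_fragments(extract_all_fragments(proteins), sites)
      tab <- two_sample_logo(frags[frags$label == 1L, ],
                             frags[frags$label == -1L, ],
                             alpha = num(opts$alpha, 0.01))
      if (!is.null(opts$out))
        utils::write.table(tab, opts$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      tab
    },
    fscore = {
      proteins <- read_fasta(opts$fasta)
      sites <- read_sites(opts$sites, proteins)
      frags <- label_fragments(extract_all_fragments(proteins), sites)
      entries <- aaindex_complete(read_aaindex(opts$aaindex %||%
                                                 stop("fscore: --aaindex required")))
      tab <- score_properties(frags, entries)
      if (!is.null(opts$out))
        utils::write.table(tab, opts$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      tab
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(res)
}
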
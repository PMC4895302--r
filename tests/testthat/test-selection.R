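test_that("f_score matches hand computations and handles degeneracy", {
  expect_equal(f_score(c(2, 4), c(0, 2)), 0.5)
  expect_equal(f_score(c(1, 0), c(0, 1)), 0)
  expect_identical(f_score(c(5, 5), c(0, 0)), Inf)
  expect_error(f_score(1, c(0, 1)), "at least 2")
})

test_that("f_score agrees with the literal oracle on random inputs", {
  set.seed(7)
  for (i in 1:1000) {
    xp <- rnorm(sample(2:12, 1), mean = runif(1, -3, 3), sd = runif(1, 0.1, 2))
    xn <- rnorm(sample(2:12, 1), mean = runif(1, -3, 3), sd = runif(1, 0.1, 2))
    expect_equal(f_score(xp, xn), f_score_oracle(xp, xn),
                 tolerance = 1e-12)
  }
})

test_that("f_score is invariant under common affine transforms", {
  set.seed(8)
  for (i in 1:50) {
    xp <- rnorm(10); xn <- rnorm(10, 1)
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
    expect_equal(f_score(a * xp + b, a * xn + b), f_score(xp, xn),
                 tolerance = 1e-9)
  }
})

test_that("score_properties ranks a planted informative property first", {
  d <- generate_dataset(synthetic_config(
    n_pos = 150, n_neg = 150, enrichment = default_positive_enrichment()[0, ],
    asa_shift = 0, seed = 11), fragments_only = TRUE)
  entries <- c(list(SYNTH_HYDRO = synthetic_hydropathy_entry()),
               synthetic_noise_properties(19, seed = 5))
  tab <- score_properties(d$fragments, entries)
  expect_equal(tab$property[1], "SYNTH_HYDRO")
  expect_equal(tab$rank, 1:20)
  expect_true(all(tab$score >= 0))
})

test_that("score_properties: constant property scores 0, scaling is neutral", {
  d <- generate_dataset(null_synth_config(30, 30, seed = 2), fragments_only = TRUE)
  const <- list(accession = "CONST", description = "", has_na = FALSE,
                values = setNames(rep(1, 20), AA20))
  base <- synthetic_hydropathy_entry()
  doubled <- base
  doubled$accession <- "DOUBLED"
  doubled$values <- base$values * 2
  tab <- score_properties(d$fragments,
                          list(CONST = const, SYNTH_HYDRO = base,
                               DOUBLED = doubled),
                          normalize = "raw")
  expect_equal(tab$score[tab$property == "CONST"], 0)
  expect_equal(tab$score[tab$property == "SYNTH_HYDRO"],
               tab$score[tab$property == "DOUBLED"], tolerance = 1e-12)
})

test_that("rank_by_single_accuracy puts the informative property first", {
  d <- generate_dataset(synthetic_config(
    n_pos = 120, n_neg = 120, enrichment = default_positive_enrichment()[0, ],
    asa_shift = 0, seed = 13), fragments_only = TRUE)
  entries <- c(list(SYNTH_HYDRO = synthetic_hydropathy_entry()),
               synthetic_noise_properties(5, seed = 9))
  rk <- rank_by_single_accuracy(names(entries), d$fragments, entries,
                                svm_config(), cv_config(5, 17))
  expect_equal(rk$property[1], "SYNTH_HYDRO")
  rk2 <- rank_by_single_accuracy(names(entries), d$fragments, entries,
                                 svm_config(), cv_config(5, 17))
  expect_identical(rk, rk2)  # deterministic for fixed seed
  one <- rank_by_single_accuracy("SYNTH_HYDRO", d$fragments, entries,
                                 svm_config(), cv_config(5, 17))
  expect_equal(one$property, "SYNTH_HYDRO")
})

test_that("forward_select keeps the informative property, rejects pure noise", {
  d <- generate_dataset(synthetic_config(
    n_pos = 120, n_neg = 120, enrichment = default_positive_enrichment()[0, ],
    asa_shift = 0, seed = 13), fragments_only = TRUE)
  base <- build_feature_matrix(d$fragments, "binary")
  entries <- c(list(SYNTH_HYDRO = synthetic_hydropathy_entry()),
               synthetic_noise_properties(3, seed = 9))
  cvc <- cv_config(5, 17)

  sel <- forward_select(base, names(entries), d$fragments, entries,
                        svm_config(), cvc)
  expect_true("SYNTH_HYDRO" %in% sel$best_properties)
  expect_equal(nrow(sel$trace), 5L)  # base + 4 candidates
  base_mcc <- sel$trace$MCC[sel$trace$step == 0]
  expect_gte(sel$best_metrics$MCC, base_mcc)

  # with pure-noise candidates only, greedy selection keeps the base alone
  noise_only <- synthetic_noise_properties(3, seed = 9)
  seln <- forward_select(base, names(noise_only), d$fragments, noise_only,
                         svm_config(), cvc, mode = "greedy")
  expect_gte(seln$best_metrics$MCC, base_mcc)
  # a noise property is retained only if it (spuriously) improved CV MCC
  expect_true(length(seln$best_properties) == 0L ||
                seln$best_metrics$MCC > base_mcc)
})
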
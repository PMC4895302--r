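test_that("position_frequencies counts residues per column", {
  f1 <- paste0(strrep("A", 10), "C", strrep("A", 10))
  pf <- position_frequencies(f1)
  expect_equal(dim(pf), c(21L, 21L))
  expect_true(all(pf %in% c(0, 1)))
  expect_equal(unname(pf["C", "0"]), 1)

  f2 <- paste0("K", strrep("A", 9), "C", strrep("A", 10))
  pf2 <- position_frequencies(c(f1, f2))
  expect_equal(unname(pf2["A", "-10"]), 0.5)
  expect_equal(unname(pf2["K", "-10"]), 0.5)
  expect_true(all(abs(colSums(pf2) - 1) < 1e-9))
  expect_error(position_frequencies(character()), "empty")
})

test_that("two_sample_logo finds planted enrichment and nothing in self-comparison", {
  set.seed(41)
  bg <- function(n) replicate(n, random_fragment())
  a <- bg(200)
  # plant K at window position -2 (string position 9) in every positive
  substr(a, 9, 9) <- "K"
  b <- bg(200)

  res <- two_sample_logo(a, b, alpha = 0.01)
  hit <- res[res$position == -2 & res$residue == "K", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$direction, "enriched")
  expect_lt(hit$p_value, 0.01)

  expect_equal(nrow(two_sample_logo(a, a, alpha = 0.5)), 0L)
  expect_error(two_sample_logo(a, substr(b, 1, 5)), "width")
})

test_that("two_sample_logo alpha = 1 reports every cell, split exhaustively", {
  set.seed(42)
  a <- replicate(30, random_fragment())
  b <- replicate(30, random_fragment())
  all_cells <- two_sample_logo(a, b, alpha = 1)
  expect_equal(nrow(all_cells), 21 * 21)
  expect_true(all(all_cells$direction %in% c("enriched", "depleted")))
  expect_true(all((all_cells$freq_a > all_cells$freq_b) ==
                    (all_cells$direction == "enriched")))
  expect_true(all(all_cells$p_value >= 0 & all_cells$p_value <= 1))
})

test_that("fisher variant agrees with stats::fisher.test", {
  a <- c(rep(paste0(strrep("K", 10), "C", strrep("A", 10)), 8),
         rep(paste0(strrep("A", 10), "C", strrep("A", 10)), 2))
  b <- rep(paste0(strrep("A", 10), "C", strrep("A", 10)), 10)
  res <- two_sample_logo(a, b, alpha = 1, test = "fisher")
  cell <- res[res$position == -10 & res$residue == "K", ]
  manual <- fisher.test(matrix(c(8, 2, 0, 10), 2))$p.value
  expect_equal(cell$p_value, manual)
})

test_that("asa_profile_compare recovers a planted shift", {
  d <- generate_dataset(synthetic_config(n_pos = 150, n_neg = 150,
                                         asa_shift = 0.2, seed = 51))
  pos <- d$fragments[d$fragments$label == 1L, ]
  neg <- d$fragments[d$fragments$label == -1L, ]
  cmp <- asa_profile_compare(pos, neg, d$asa)
  expect_equal(nrow(cmp), 21L)
  expect_true(all(abs(cmp$difference - 0.2) < 0.05))

  self <- asa_profile_compare(pos, pos, d$asa)
  expect_equal(self$difference, rep(0, 21))
  expect_error(asa_profile_compare(pos, neg, d$asa["nope"]), "missing ASA")
})

test_that("overlap_sets computes Venn partitions at protein and site level", {
  s1 <- data.frame(protein_id = c("a", "b"), position = c(1L, 2L))
  s2 <- data.frame(protein_id = c("b", "c"), position = c(2L, 3L))
  ov <- overlap_sets(list(soh = s1, sno = s2))
  both <- ov$protein[ov$protein$soh & ov$protein$sno, "count"]
  expect_equal(both, 1L)
  expect_equal(sum(ov$protein$count), 3L)
  expect_equal(ov$site[ov$site$soh & ov$site$sno, "count"], 1L)

  disjoint <- overlap_sets(list(x = s1, y = data.frame(protein_id = "z",
                                                       position = 9L)))
  expect_equal(disjoint$protein[disjoint$protein$x & disjoint$protein$y,
                                "count"], 0L)

  same <- overlap_sets(list(x = s1, y = s1, z = s1))
  expect_equal(same$protein[same$protein$x & same$protein$y & same$protein$z,
                            "count"], 2L)
})

test_that("null two-sample-logo keeps type-I error near alpha", {
  # small in-suite version of the simulation study (full scale in the
  # acceptance test): 30 null replicates at n = 200 + 200
  set.seed(61)
  n_sig <- 0L
  n_cells <- 0L
  for (r in 1:30) {
    d <- generate_dataset(null_synth_config(200, 200, seed = 1000 + r),
                          fragments_only = TRUE)
    res <- two_sample_logo(d$fragments[d$fragments$label == 1L, ],
                           d$fragments[d$fragments$label == -1L, ],
                           alpha = 0.01)
    n_sig <- n_sig + nrow(res)
    n_cells <- n_cells + 21L * 21L
  }
  expect_lte(n_sig / n_cells, 0.02)
})
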
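frag21 <- function(left, center = "C", right) {
  stopifnot(nchar(left) == 10L, nchar(right) == 10L)
  paste0(left, center, right)
}

test_that("binary encoding is one-hot in alphabetical order", {
  v <- encode_binary(frag21(strrep("A", 10), "C", strrep("A", 10)))
  expect_length(v, 420L)
  # A -> bit 1 of its 20-bit block, C -> bit 2
  expect_equal(unname(v[1:20]),
               c(1, rep(0, 19)))
  expect_equal(unname(v[(10 * 20 + 1):(11 * 20)]),
               c(0, 1, rep(0, 18)))

  withX <- encode_binary("XXXXXXXXMKCAGXXXXXXXX")
  expect_equal(sum(withX), 21 - 16)  # one 1 per non-X residue
})

test_that("binary inner product counts shared non-X residues", {
  set.seed(2)
  for (i in 1:20) {
    a <- random_fragment()
    b <- random_fragment()
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    expected <- sum(ca == cb & ca != "X")
    expect_equal(sum(encode_binary(a) * encode_binary(b)), expected)
  }
})

test_that("AAC composition matches direct counting and sums to 1", {
  v <- encode_aac(frag21(strrep("A", 10), "C", strrep("A", 10)))
  expect_length(v, 21L)
  expect_equal(unname(v["aac.A"]), 20 / 21)
  expect_equal(unname(v["aac.C"]), 1 / 21)
  expect_equal(sum(v), 1)

  set.seed(3)
  for (i in 1:20) expect_equal(sum(encode_aac(random_fragment())), 1)
})

test_that("AAPC counts adjacent ordered pairs and sums to 1", {
  v <- encode_aapc(strrep("A", 21))
  expect_length(v, 441L)
  expect_equal(unname(v["aapc.AA"]), 1)
  expect_equal(sum(v != 0), 1L)

  set.seed(4)
  for (i in 1:20) {
    v <- encode_aapc(random_fragment())
    expect_equal(sum(v), 1)
    # counts are multiples of 1/20: a 21-mer has 20 adjacent pairs
    expect_true(all(abs(v * 20 - round(v * 20)) < 1e-9))
  }
})

test_that("BLOSUM62 encoding rescales to [0,1] with all-zero X", {
  v <- encode_blosum62(frag21(strrep("A", 10), "W", strrep("A", 10)))
  # W's row holds the global maximum 11 (W-W), which maps to 1
  expect_equal(max(v), 1)
  expect_equal(unname(v["blosum62.0.W"]), 1)
  expect_length(v, 420L)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(unname(encode_blosum62(strrep("X", 21))), rep(0, 420))
})

test_that("PWM building and encoding agree with hand counts", {
  f1 <- frag21(strrep("A", 10), "C", strrep("A", 10))
  pwm <- build_pwm(f1)
  expect_equal(dim(pwm), c(21L, 21L))
  expect_equal(unname(pwm["A", 1]), 1)
  expect_equal(unname(pwm["C", "0"]), 1)

  f2 <- frag21(paste0("R", strrep("A", 9)), "C", strrep("A", 10))
  pwm2 <- build_pwm(c(f1, f2))
  expect_equal(unname(pwm2["A", 1]), 0.5)
  expect_equal(unname(pwm2["R", 1]), 0.5)
  expect_true(all(abs(colSums(pwm2) - 1) < 1e-9))

  enc <- encode_pwm(f1, pwm)
  expect_equal(unname(enc), rep(1, 21))
  enc2 <- encode_pwm(frag21(paste0("W", strrep("A", 9)), "C", strrep("A", 10)), pwm)
  expect_equal(unname(enc2[1]), 0)  # W unseen at column 1
  expect_error(encode_pwm("ACA", pwm), "width")
  expect_error(build_pwm(character()), "empty")
})

test_that("PWM columns sum to 1 on random fragment sets", {
  set.seed(6)
  for (i in 1:5) {
    pwm <- build_pwm(replicate(30, random_fragment()))
    expect_true(all(abs(colSums(pwm) - 1) < 1e-9))
    enc <- encode_pwm(random_fragment(), pwm)
    expect_true(all(enc >= 0 & enc <= 1))
  }
})

test_that("PSSM encoding squashes scores and zeroes padding", {
  prof <- matrix(0, nrow = 5, ncol = 20,
                 dimnames = list(NULL, cysPTM:::PSSM_AA_ORDER))
  v <- encode_pssm(3L, prof, n = 10L)
  expect_length(v, 420L)
  # window covers protein positions -7..13; residues 1..5 are window rows
  # 9..13 (logistic(0) = 0.5), the rest is terminal padding -> 0
  expect_equal(unname(v[(8 * 20 + 1):(13 * 20)]), rep(0.5, 5 * 20))
  expect_equal(unname(v[1:(8 * 20)]), rep(0, 160))
  expect_equal(unname(v[(13 * 20 + 1):420]), rep(0, 160))

  # monotone in the raw score
  prof2 <- prof; prof2[3, 5] <- 4
  v2 <- encode_pssm(3L, prof2, n = 10L)
  expect_true(v2[(10 * 20) + 5] > v[(10 * 20) + 5])
  expect_error(encode_pssm(9L, prof, n = 10L), "outside")
})

test_that("AAindex encoding standardizes values and zeroes X", {
  entries <- read_aaindex(fixture_aaindex())
  kd <- entries$KYTJ820101
  const <- encode_aaindex(strrep("A", 21), kd)
  expect_true(all(const == const[1]))
  z <- (kd$values - mean(kd$values)) / sd(kd$values)
  expect_equal(unname(const[1]), unname(z["A"]))
  expect_equal(unname(encode_aaindex("XXXXXXXXXXCXXXXXXXXXX", kd)[1]), 0)
  raw <- encode_aaindex(strrep("A", 21), kd, normalize = "raw")
  expect_equal(unname(raw[1]), 1.8)
  expect_error(encode_aaindex(strrep("A", 21), entries$FAKE000002), "NA")
})

test_that("track encoding scales ASA and one-hots SS with zero padding", {
  asa <- rep(50, 5)
  v <- encode_track(3L, asa, "ASA", n = 10L)
  expect_length(v, 21L)
  expect_equal(unname(v[9:13]), rep(0.5, 5))
  expect_equal(unname(v[c(1:8, 14:21)]), rep(0, 16))

  ss <- c("H", "E", "C", "H", "H")
  s <- encode_track(3L, ss, "SS", n = 10L)
  expect_length(s, 63L)
  expect_equal(unname(s[(8 * 3 + 1):(9 * 3)]), c(1, 0, 0))  # window row 9 = residue 1 = H
  expect_equal(unname(s[1:24]), rep(0, 24))
})

test_that("concat_features adds lengths and rejects collisions", {
  prof <- matrix(0, 21, 20, dimnames = list(NULL, cysPTM:::PSSM_AA_ORDER))
  pssm_v <- encode_pssm(11L, prof, n = 10L)
  entries <- aaindex_complete(read_aaindex(fixture_aaindex()))
  idx_v <- lapply(rep(entries[1], 12), function(e) {
    v <- encode_aaindex(strrep("A", 21), e)
    v
  })
  # 12 copies of the same property would collide on names
  expect_error(concat_features(c(list(pssm_v), idx_v)), "duplicate")
  one <- concat_features(list(pssm_v, idx_v[[1]]))
  expect_length(one, 420L + 21L)
  expect_identical(concat_features(list(pssm_v)), pssm_v)
  expect_error(concat_features(list()), "empty")
})

test_that("build_feature_matrix assembles hybrid matrices", {
  d <- generate_dataset(synthetic_config(n_pos = 5, n_neg = 5, seed = 3))
  ctx <- encoding_context(profiles = d$profiles, asa = d$asa, ss = d$ss,
                          aaindex = list(SYNTH_HYDRO = synthetic_hydropathy_entry()),
                          pwm = build_pwm(d$fragments[d$fragments$label == 1L, ]))
  mat <- build_feature_matrix(d$fragments,
                              c("pssm", "aaindex:SYNTH_HYDRO", "asa", "pwm"),
                              ctx)
  expect_equal(dim(mat), c(10L, 420L + 21L + 21L + 21L))
  expect_false(anyDuplicated(colnames(mat)) > 0)
  expect_error(build_feature_matrix(d$fragments, "pssm", encoding_context()),
               "missing PSSM")
})
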
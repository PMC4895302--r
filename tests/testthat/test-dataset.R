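test_that("extract_fragments pads termini and finds every cysteine", {
  fr <- extract_fragments("MKCAG", "p1", n = 10L)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$sequence, "XXXXXXXXMKCAGXXXXXXXX")
  expect_equal(nchar(fr$sequence), 21L)
  expect_equal(fr$center, 3L)

  expect_equal(nrow(extract_fragments("MKAAG", "p1")), 0L)

  fr3 <- extract_fragments("CACAC", "p1", n = 2L)
  expect_equal(fr3$center, c(1L, 3L, 5L))
  expect_equal(fr3$sequence, c("XXCAC", "CACAC", "CACXX"))
})

test_that("fragment count equals cysteine count for random proteins", {
  set.seed(5)
  for (i in 1:25) {
    seq <- paste(sample(AA20, sample(5:60, 1), replace = TRUE), collapse = "")
    fr <- extract_fragments(seq, "p", n = 10L)
    expect_equal(nrow(fr), lengths(regmatches(seq, gregexpr("C", seq))))
    if (nrow(fr) > 0) {
      expect_true(all(substr(fr$sequence, 11, 11) == "C"))
      # padding X only as contiguous prefix/suffix
      expect_false(any(grepl("X[^X]*X", gsub("^X+|X+$", "", fr$sequence))))
    }
  }
})

test_that("label_fragments assigns positives and default negatives", {
  fr <- extract_fragments("CACAC", "p1", n = 2L)
  sites <- data.frame(protein_id = "p1", position = 3L, label = 1L)
  lab <- label_fragments(fr, sites)
  expect_equal(lab$label, c(-1L, 1L, -1L))

  all_pos <- data.frame(protein_id = "p1", position = c(1L, 3L, 5L),
                        label = 1L)
  expect_equal(label_fragments(fr, all_pos)$label, rep(1L, 3))

  orphan <- data.frame(protein_id = "p1", position = 2L, label = 1L)
  expect_error(label_fragments(fr, orphan), "no matching fragment")
  empty <- sites[0, ]
  expect_error(label_fragments(fr, empty, default_negative = FALSE))
})

test_that("protein_identity matches hand alignments", {
  expect_equal(protein_identity("MKCAG", "MKCAG"), 1.0)
  expect_equal(protein_identity("AAAA", "TTTT"), 0.0)
  expect_equal(protein_identity("AAAATTTT", "AAAACCCC"), 0.5)
})

test_that("reduce_homology dedups with train priority", {
  tr <- data.frame(protein_id = c("a", "b"), center = c(11L, 11L),
                   sequence = c(strrep("A", 10) %+% "C" %+% strrep("A", 10),
                                strrep("K", 10) %+% "C" %+% strrep("K", 10)),
                   label = c(1L, -1L), stringsAsFactors = FALSE)
  te <- data.frame(protein_id = c("c", "d"), center = c(11L, 11L),
                   sequence = c(tr$sequence[1],
                                strrep("E", 10) %+% "C" %+% strrep("E", 10)),
                   label = c(1L, -1L), stringsAsFactors = FALSE)
  red <- reduce_homology(tr, te)
  expect_equal(nrow(red$train), 2L)          # train copy retained
  expect_equal(red$test$protein_id, "d")     # duplicate dropped from test
  expect_length(intersect(red$train$sequence, red$test$sequence), 0L)

  # within-set duplicate: first occurrence kept
  tr2 <- rbind(tr, tr[1, ])
  tr2$protein_id[3] <- "z"
  red2 <- reduce_homology(tr2, te)
  expect_equal(red2$train$protein_id, c("a", "b"))
})

test_that("reduce_homology is idempotent and yields disjoint sets", {
  set.seed(11)
  mk <- function(k, prefix) {
    seqs <- replicate(k, random_fragment())
    # plant duplicates
    seqs[sample(k, k %/% 4)] <- seqs[1]
    data.frame(protein_id = paste0(prefix, seq_len(k)), center = 11L,
               sequence = seqs, label = sample(c(1L, -1L), k, TRUE),
               stringsAsFactors = FALSE)
  }
  for (rep in 1:5) {
    tr <- mk(40, "t")
    te <- mk(20, "e")
    te$sequence[1:5] <- tr$sequence[1:5]
    once <- reduce_homology(tr, te)
    twice <- reduce_homology(once$train, once$test)
    expect_identical(once, twice)
    expect_length(intersect(once$train$sequence, once$test$sequence), 0L)
    expect_false(any(duplicated(once$train$sequence)))
  }
})

test_that("split_dataset stratifies and is reproducible", {
  fr <- data.frame(protein_id = paste0("p", 1:200), center = 11L,
                   sequence = replicate(200, random_fragment()),
                   label = rep(c(1L, -1L), each = 100),
                   stringsAsFactors = FALSE)
  sp <- split_dataset(fr, 0.2, seed = 1L)
  expect_equal(sum(sp$test$label == 1L), 20L)
  expect_equal(sum(sp$test$label == -1L), 20L)
  expect_equal(nrow(sp$train), 160L)

  sp2 <- split_dataset(fr, 0.2, seed = 1L)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(fr, 0.2, seed = 2L)
  expect_false(identical(sp$test$protein_id, sp3$test$protein_id))

  expect_error(split_dataset(fr, 0, seed = 1L))
  expect_error(split_dataset(fr[fr$label == 1L, ], 0.2, seed = 1L), "class")
})
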
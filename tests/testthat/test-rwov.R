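cfg <- norm_config()

test_that("signed reciprocal values follow the 1/(d+1) form and sign rule", {
  expect_equal(signed_reciprocal_value(0, "AFTER"), 1)
  expect_equal(signed_reciprocal_value(0, "BEFORE"), -1)
  expect_equal(signed_reciprocal_value(4, "BEFORE"), -0.2)
  expect_error(signed_reciprocal_value(-1, "AFTER"))
})

test_that("worked example: polarity words around a trailing TOI", {
  # [neg, for, pr, posit, for, er], anchor er; relevant {neg, posit, pr, for}
  s <- make_seq(c("neg", "for", "pr", "posit", "for", "er"))
  idx <- relevant_word_index(c("neg", "posit", "pr", "for"), "er")
  v <- vectorize_block(s, 6L, idx)
  expect_equal(unname(v["for"]), -1)      # adjacent in relevant terms
  expect_equal(unname(v["posit"]), -1/2)  # one relevant word between
  expect_equal(unname(v["pr"]), -1/3)
  expect_equal(unname(v["neg"]), -1/5)
  # absent TOI -> zero row
  expect_equal(unname(vectorize_block(s, integer(0), idx)), rep(0, 4))
  # "ER+" pattern: plu right after the anchor
  v2 <- vectorize_block(make_seq(c("er", "plu")), 1L,
                        relevant_word_index("plu", "er"))
  expect_equal(unname(v2), 1)
})

test_that("single-cell and permutation behaviour of vectorize_corpus", {
  corpus <- list(make_seq(c("w", "er"), "a"), make_seq(c("er", "w"), "b"),
                 make_seq(c("pr"), "c"))
  idx <- relevant_word_index("w", "er")
  m <- vectorize_corpus(corpus, toi_spec("er"), idx, cfg)
  expect_equal(m, matrix(c(-1, 1, 0), 3, 1,
                         dimnames = list(c("a", "b", "c"), "w")))
  m2 <- vectorize_corpus(rev(corpus), toi_spec("er"), idx, cfg)
  expect_equal(m2, m[3:1, , drop = FALSE])
})

test_that("vectorize_block matches the brute-force enumerator on random blocks", {
  vocab <- c("toi", "a", "b", "c", "d", "e")
  words <- c("a", "b", "c", "d", "e")
  idx <- relevant_word_index(words, "toi")
  toi <- toi_spec("toi")
  with_seed(42, {
    for (i in 1:500) {
      toks <- sample(vocab, sample(1:12, 1), replace = TRUE)
      s <- make_seq(toks)
      anchors <- find_toi_occurrences(s, toi, cfg)
      got <- vectorize_block(s, anchors, idx)
      want <- brute_vectorize(toks, if (length(anchors)) anchors[1] else NULL,
                              words)
      expect_identical(got, want)
    }
  })
})

test_that("cell magnitudes shrink with inserted relevant words, not others", {
  idx <- relevant_word_index(c("w", "x"), "toi")
  toi <- toi_spec("toi")
  base <- c("w", "toi")
  v0 <- vectorize_block(make_seq(base), 2L, idx)
  # insert a relevant word between w and the anchor
  v1 <- vectorize_block(make_seq(c("w", "x", "toi")), 3L, idx)
  expect_lt(abs(v1["w"]), abs(v0["w"]))
  # insert a non-relevant word: value unchanged
  v2 <- vectorize_block(make_seq(c("w", "zzz", "toi")), 3L, idx)
  expect_equal(v2["w"], v0["w"])
  # sign encodes side
  expect_lt(v0["w"], 0)
  v3 <- vectorize_block(make_seq(c("toi", "w")), 1L, idx)
  expect_gt(v3["w"], 0)
})

test_that("all cells are 0 or +/- 1/(d+1) and ties break toward AFTER", {
  idx <- relevant_word_index(c("w", "x"), "toi")
  # w at equal relevant-distance on both sides -> AFTER (positive)
  v <- vectorize_block(make_seq(c("w", "toi", "w")), 2L, idx)
  expect_equal(unname(v["w"]), 1)
  corp <- generate_corpus(synthetic_config(n = 40, seed = 9))
  fit <- rwov(corp, "er", k = 15)
  vals <- abs(as.matrix(fit))
  vals <- vals[vals > 0]
  d <- 1 / vals - 1
  expect_true(all(abs(d - round(d)) < 1e-9))
  expect_true(all(vals <= 1))
})

test_that("the rwov fit object carries index, matrix and methods", {
  corp <- generate_corpus(synthetic_config(n = 50, seed = 4))
  fit <- rwov(corp, "er", k = 10)
  expect_s3_class(fit, "rwov")
  expect_equal(dim(as.matrix(fit)), c(50L, 10L))
  expect_equal(nrow(fit$index$words), 10L)
  expect_output(print(fit), "TOI: 'er'")
  expect_output(print(summary(fit)), "Top relevant words")
  # predict() reproduces the training matrix (vocabulary is frozen)
  expect_equal(predict(fit, corp), as.matrix(fit))
  # k = 0 rejected at construction
  expect_error(rwov(corp, "er", k = 0))
})

test_that("feature matrices round-trip through the text format", {
  corp <- generate_corpus(synthetic_config(n = 12, seed = 5))
  fit <- rwov(corp, "er", k = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(as.matrix(fit), path)
  expect_equal(read_feature_matrix(path), as.matrix(fit))
})
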
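cfg <- norm_config()

test_that("TOI occurrences: literal, alias, longest-match subsumption", {
  er <- default_tois()$er
  # alias "estrogen receptor" wins over the shorter "estrogen" at the same spot
  s <- make_seq(c("estrogen", "recept", "posit"))
  expect_equal(as.integer(find_toi_occurrences(s, er, cfg)), 1L)
  # absent TOI
  expect_length(find_toi_occurrences(make_seq(c("negat", "for", "pr")), er, cfg), 0)
  # every literal occurrence reported
  occ <- find_toi_occurrences(make_seq(c("er", "comm", "er")), er, cfg)
  expect_equal(as.integer(occ), c(1L, 3L))
  # her2 alias "her/" matches the tokenized pair (her, slash)
  her2 <- default_tois()$her2
  s2 <- normalize_block("FISH analysis for HER2/neu", cfg)
  expect_equal(s2$tokens[1:4], c("fish", "analys", "for", "her2"))
  s3 <- make_seq(c("her", "slash", "neu"))
  expect_equal(as.integer(find_toi_occurrences(s3, her2, cfg)), 1L)
})

test_that("relevant-word selection counts only TOI-containing blocks", {
  er <- toi_spec("er")
  corpus <- list(make_seq(c("posit", "for", "er"), "b1"),
                 make_seq(c("negat", "for", "pr"), "b2"))
  idx <- select_relevant_words(corpus, er, k = 3, config = cfg)
  # only block 1 counted; means over m = 2; ties broken lexicographically;
  # the canonical token's own occurrence counts (it can rank among top words)
  expect_equal(idx$words$token, c("er", "for", "posit"))
  expect_equal(idx$words$mean_frequency, c(0.5, 0.5, 0.5))
  # k larger than distinct vocabulary returns everything
  idx_all <- select_relevant_words(corpus, er, k = 50, config = cfg)
  expect_lt(nrow(idx_all$words), 50)
  # error when no block contains the TOI
  expect_error(select_relevant_words(corpus, toi_spec("zzz"), k = 2,
                                     config = cfg), "no block")
})

test_that("ranked counts equal an exhaustive tally on random toy corpora", {
  vocab <- c("er", "w1", "w2", "w3", "w4")
  for (rep in 1:20) {
    corpus <- with_seed(100 + rep, {
      lapply(1:8, function(i) {
        make_seq(sample(vocab, sample(3:15, 1), replace = TRUE),
                 paste0("b", i))
      })
    })
    has_toi <- vapply(corpus, function(s) "er" %in% s$tokens, logical(1))
    if (!any(has_toi)) next
    idx <- select_relevant_words(corpus, toi_spec("er"), k = 10, config = cfg)
    # oracle: plain tally over TOI blocks (canonical counts as itself)
    tally <- table(unlist(lapply(corpus[has_toi], `[[`, "tokens")))
    expected <- sort(as.numeric(tally), decreasing = TRUE)
    expect_equal(idx$words$mean_frequency * length(corpus),
                 expected[seq_len(nrow(idx$words))])
    # frequencies weakly decreasing, nonnegative
    expect_true(all(diff(idx$words$mean_frequency) <= 0))
    expect_true(all(idx$words$mean_frequency >= 0))
  }
})

test_that("blocks without the TOI change only the mean denominator", {
  er <- toi_spec("er")
  base <- list(make_seq(c("posit", "er", "negat"), "b1"))
  idx1 <- select_relevant_words(base, er, k = 5, config = cfg)
  idx2 <- select_relevant_words(c(base, list(make_seq(c("w", "w"), "b2"))),
                                er, k = 5, config = cfg)
  expect_equal(idx1$words$token, idx2$words$token)
  expect_equal(idx1$words$mean_frequency, 2 * idx2$words$mean_frequency)
})

test_that("canonical token is an eligible relevant word, alias spans are not", {
  er <- default_tois()$er
  corpus <- list(make_seq(c("er", "posit", "er", "estrogen", "recept"), "b1"))
  idx <- select_relevant_words(corpus, er, k = 10, config = cfg)
  w <- idx$words
  expect_equal(w$mean_frequency[w$token == "er"], 2)
  expect_false("estrogen" %in% w$token)
  expect_false("recept" %in% w$token)
})

test_that("relevant-word index round-trips through its text format", {
  idx <- relevant_word_index(c("posit", "comm", "0"), "er",
                             c(1.25, 1/3, 0.1), k = 30)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_word_index(idx, path)
  back <- read_word_index(path)
  expect_equal(back$toi, idx$toi)
  expect_equal(back$k, idx$k)
  expect_equal(back$words, idx$words)
})
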
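cfg <- norm_config()

test_that("sentence splitting follows terminal punctuation + capital rule", {
  expect_equal(split_sentences("Positive for ER. Negative for PR."),
               c("Positive for ER.", "Negative for PR."))
  # no split without a following capital/digit (mid-abbreviation safety)
  expect_length(split_sentences("ER: Positive (85%) PR: Positive (80%)."), 1)
  expect_equal(split_sentences(""), character(0))
  expect_equal(split_sentences("   "), character(0))
  # non-whitespace content is covered, in order
  txt <- "Her2 immunostain is positive. Ki-67: 23%. ER+."
  expect_equal(gsub("\\s", "", paste(split_sentences(txt), collapse = "")),
               gsub("\\s", "", txt))
})

test_that("tokenization splits words and symbols, keeps hyphenated names", {
  expect_equal(tokenize_words("ER+"), c("ER", "+"))
  expect_equal(tokenize_words("HER2/neu"), c("HER2", "/", "neu"))
  expect_equal(tokenize_words("Ki-67: 23%"), c("Ki-67", ":", "23", "%"))
  expect_equal(tokenize_words("her-2"), "her-2")
  expect_equal(tokenize_words(""), character(0))
})

test_that("token normalization: stop words, substitutions, stems, numbers", {
  expect_equal(normalize_token(",", cfg), "comm")
  expect_equal(normalize_token("/", cfg), "slash")
  expect_equal(normalize_token("+", cfg), "plu")
  for (sw in c("the", "are", "of", "as", "is", "and", "or", "report",
               "pathology", "The", "AND"))
    expect_true(is.na(normalize_token(sw, cfg)))
  # numeric tokens retained verbatim
  expect_equal(normalize_token("1", cfg), "1")
  expect_equal(normalize_token("85", cfg), "85")
  # marker names containing digits are lowercased but never stemmed
  expect_equal(normalize_token("Ki-67", cfg), "ki-67")
  expect_equal(normalize_token("HER2", cfg), "her2")
  # stemming shortens to a root no longer than the word
  expect_lte(nchar(normalize_token("tumor", cfg)), nchar("tumor"))
  expect_equal(normalize_token("positive", cfg), "posit")
  # a stem that lands on a stop word is dropped too
  expect_true(is.na(normalize_token("reportedly", cfg)))
})

test_that("qualified percentages collapse to pospct/negpct, unqualified stay", {
  b <- normalize_block("ER: Positive (85%)", cfg)
  expect_true("pospct" %in% b$tokens)
  expect_false("85" %in% b$tokens)
  b <- normalize_block("PR: Negative (0%)", cfg)
  expect_true("negpct" %in% b$tokens)
  b <- normalize_block("ER: 30%", cfg)
  expect_equal(b$tokens, c("er", ":", "30", "%"))
})

test_that("normalize_block composes the pipeline with position fidelity", {
  b <- normalize_block("positive for ER, negative for PR", cfg, "x")
  expect_equal(b$tokens, c("posit", "for", "er", "comm", "negat", "for", "pr"))
  expect_s3_class(b, "token_seq")
  # all stop words -> empty sequence
  expect_length(normalize_block("the of and", cfg)$tokens, 0)
  expect_length(normalize_block("", cfg)$tokens, 0)
  # positions strictly increasing and point at raw tokens that normalize back
  expect_true(all(diff(b$source_positions) > 0))
  renorm <- vapply(b$raw_tokens[b$source_positions], normalize_token,
                   character(1), config = cfg)
  expect_equal(unname(renorm), b$tokens)
})

test_that("normalization is deterministic and stop-word clean on a corpus", {
  corp <- generate_corpus(synthetic_config(n = 60, seed = 3))
  n1 <- normalize_corpus(corp, cfg)
  n2 <- normalize_corpus(corp, cfg)
  expect_identical(n1, n2)
  all_tokens <- unlist(lapply(n1, `[[`, "tokens"))
  expect_false(any(all_tokens %in% cfg$stop_words))
  # substitution closure: mapped symbols never survive as raw symbols
  expect_false(any(all_tokens %in% names(cfg$substitutions)))
})
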
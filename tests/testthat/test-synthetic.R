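test_that("status rendering covers the phrasing inventory consistently", {
  with_seed(1, {
    expect_equal(render_status("er", "POS", "plus"), "ER+.")
    expect_equal(render_status("er", "NEG", "plus"), "ER-.")
    expect_equal(render_status("pr", "NEG", "for"), "Negative for PR.")
    expect_match(render_status("er", "POS", "phrase"),
                 "^Estrogen receptor positive\\.$")
    expect_match(render_status("er", "POS", "percent"), "^ER: [0-9]+%\\.$")
    expect_match(render_status("her2", "POS", "equivocal_fish"),
                 "HER2: Equivocal \\(2\\+\\)\\. FISH analysis for HER2/neu.*reportedly positive\\.")
    expect_match(render_status("her2", "NEG", "equivocal_fish"),
                 "reportedly negative\\.$")
    expect_error(render_status("xx", "POS", "plus"), "unknown receptor")
    expect_error(render_status("er", "POS", "zz"), "unknown style")
    expect_error(render_status("er", "POS", "equivocal_fish"), "her2 only")
  })
})

test_that("single reports are deterministic given the RNG state", {
  st <- list(er = "POS", pr = "NEG")
  r1 <- with_seed(5, generate_report(st, synthetic_config()))
  r2 <- with_seed(5, generate_report(st, synthetic_config()))
  expect_identical(r1, r2)
  expect_identical(r1$labels, st)
  # exactly one polarity statement per labelled receptor
  lab <- extract_labels(r1$text)
  expect_equal(unname(lab["er"]), "POS")
  expect_equal(unname(lab["pr"]), "NEG")
})

test_that("corpus generation is seeded and labels match the columns", {
  cfg <- synthetic_config(n = 40, seed = 12)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 40L)
  expect_equal(nrow(generate_corpus(synthetic_config(n = 1, seed = 2))), 1L)
})

test_that("label-text fidelity: the reference extractor recovers every label", {
  corp <- generate_corpus(synthetic_config(n = 400, seed = 31))
  for (i in seq_len(nrow(corp))) {
    lab <- extract_labels(corp$text[i])
    expect_identical(unname(lab[c("er", "pr", "her2")]),
                     unname(unlist(corp[i, c("er", "pr", "her2")])))
  }
})

test_that("empirical prevalences converge to the configured values", {
  cfg <- synthetic_config(n = 5000, seed = 77)
  corp <- generate_corpus(cfg)
  emp <- c(er = mean(corp$er == "POS"), pr = mean(corp$pr == "POS"),
           her2 = mean(corp$her2 == "POS"))
  expect_true(all(abs(emp - cfg$prevalences) < 0.02))
})

test_that("a 629-report corpus lands within binomial error of 491 ER+", {
  cfg <- synthetic_config(n = 629, seed = 8)
  corp <- generate_corpus(cfg)
  n_pos <- sum(corp$er == "POS")
  sd3 <- 3 * sqrt(629 * 0.781 * (1 - 0.781))
  expect_lt(abs(n_pos - 491), sd3)
})

test_that("reports mention between 3 and 10 biomarkers", {
  corp <- generate_corpus(synthetic_config(n = 100, seed = 14))
  names_all <- c("ER", "PR", "HER2", "CK7", "MOC31", "CK5/6", "TTF-1",
                 "CK20", "Ki-67")
  for (t in corp$text) {
    mentioned <- sum(vapply(names_all, function(nm) {
      grepl(nm, t, fixed = TRUE) ||
        (nm == "ER" && grepl("Estrogen receptor", t)) ||
        (nm == "PR" && grepl("Progesterone receptor", t)) ||
        (nm == "HER2" && grepl("Her2", t))
    }, logical(1)))
    expect_gte(mentioned, 3)
    expect_lte(mentioned, 10)
  }
})

test_that("corpus files round-trip through the CSV format", {
  corp <- generate_corpus(synthetic_config(n = 15, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_equal(back$observation_id, corp$observation_id)
  expect_equal(back$text, corp$text)
  expect_equal(back$er, corp$er)
})
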
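# Template-based generator of labelled synthetic pathology-report text.
#
# Every phrasing is drawn from the small inventory clinicians actually use
# when dictating immunohistochemistry panels ("estrogen receptor positive",
# "ER+", "positive for ER", "positive staining for ER", "ER: 30%",
# grouped multi-biomarker lists, and the HER2 equivocal-then-FISH follow-up),
# so every stored label is recoverable from the text by a human reader and
# by the rule-based reference extractor shipped alongside.

.receptor_long <- c(er = "Estrogen receptor", pr = "Progesterone receptor",
                    her2 = "Her2")
.receptor_short <- c(er = "ER", pr = "PR", her2 = "HER2")
.distractor_pool <- c("CK7", "MOC31", "CK5/6", "TTF-1", "CK20", "Ki-67")

#' Synthetic corpus configuration
#'
#' Defaults encode the study conditions of a breast-cancer pathology-report
#' cohort: receptor-status prevalences ER+ 78.1\%, PR+ 66.1\%, HER2+ 18.3\%,
#' and 3-10 biomarkers mentioned per report.
#'
#' @param n Number of reports.
#' @param prevalences Named probabilities of POS status per receptor.
#' @param biomarkers_range Min/max biomarkers mentioned per report.
#' @param interleave Probability that a receptor's status is expressed inside
#'   a shared multi-biomarker list clause (where distractor names separate
#'   the polarity word from the receptor mention) rather than in a standalone
#'   phrase. Raising it lengthens the textual dependency between a receptor
#'   and its polarity.
#' @param equivocal_her2_rate Probability that a HER2 mention is rendered as
#'   an equivocal immunostain resolved by a FISH follow-up sentence.
#' @param style_weights Sampling weights over the standalone phrasing styles
#'   `phrase`, `plus`, `for`, `staining`, `percent`, `labeled_percent`.
#' @param seed Integer seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 600L,
                             prevalences = c(er = 0.781, pr = 0.661,
                                             her2 = 0.183),
                             biomarkers_range = c(3L, 10L),
                             interleave = 0.35,
                             equivocal_her2_rate = 0.15,
                             style_weights = c(phrase = 0.15, plus = 0.2,
                                               "for" = 0.2, staining = 0.1,
                                               percent = 0.15,
                                               labeled_percent = 0.2),
                             seed = 1L) {
  stopifnot(all(prevalences >= 0 & prevalences <= 1),
            length(biomarkers_range) == 2L,
            biomarkers_range[1] >= 1L,
            biomarkers_range[1] <= biomarkers_range[2],
            interleave >= 0, interleave <= 1,
            equivocal_her2_rate >= 0, equivocal_her2_rate <= 1,
            all(style_weights >= 0), sum(style_weights) > 0)
  structure(list(n = .check_count(n, "n", 1L), prevalences = prevalences,
                 biomarkers_range = as.integer(biomarkers_range),
                 interleave = interleave,
                 equivocal_her2_rate = equivocal_her2_rate,
                 style_weights = style_weights, seed = as.integer(seed)),
            class = "synthetic_config")
}

# "A", "A and B", "A, B and C"
.join_items <- function(items) {
  n <- length(items)
  if (n == 1L) return(items)
  paste0(paste(items[-n], collapse = ", "), " and ", items[n])
}

#' Render a receptor status in one phrasing style
#'
#' @param receptor One of `"er"`, `"pr"`, `"her2"`.
#' @param status `"POS"` or `"NEG"`.
#' @param style One of `phrase`, `plus`, `for`, `staining`, `percent`,
#'   `labeled_percent`, or (HER2 only) `equivocal_fish`. Percent styles draw
#'   a percentage consistent with the status: positive gets a nonzero
#'   percentage, negative is worded as negative (with `0\%` in the labelled
#'   variant). Uses the current RNG state.
#' @return A text fragment (one or two sentences).
#' @export
render_status <- function(receptor, status, style) {
  if (!receptor %in% names(.receptor_short))
    stop("unknown receptor '", receptor, "'", call. = FALSE)
  stopifnot(status %in% c("POS", "NEG"))
  S <- .receptor_short[[receptor]]
  pos <- status == "POS"
  switch(style,
    phrase = if (receptor == "her2")
        paste0("Her2 immunostain is ", if (pos) "positive." else "negative.")
      else paste0(.receptor_long[[receptor]], " ",
                  if (pos) "positive." else "negative."),
    plus = paste0(S, if (pos) "+." else "-."),
    "for" = paste0(if (pos) "Positive for " else "Negative for ", S, "."),
    staining = paste0(if (pos) "Positive staining for "
                      else "Negative staining for ", S, "."),
    percent = if (pos) paste0(S, ": ", sample(20:100, 1), "%.")
              else paste0(S, ": Negative."),
    labeled_percent = if (pos)
        paste0(S, ": Positive (", sample(50:100, 1), "%).")
      else paste0(S, ": Negative (0%)."),
    equivocal_fish = {
      if (receptor != "her2")
        stop("equivocal_fish style applies to her2 only", call. = FALSE)
      paste0("HER2: Equivocal (2+). FISH analysis for HER2/neu was ",
             "performed and was reportedly ",
             if (pos) "positive." else "negative.")
    },
    stop("unknown style '", style, "'", call. = FALSE))
}

#' Generate one labelled synthetic report
#'
#' Assembles 3-10 biomarker mentions (the labelled receptors plus distractor
#' markers CK7, MOC31, CK5/6, TTF-1, CK20, Ki-67) in randomized order and
#' styles. Each receptor is mentioned exactly once with its labelled
#' polarity, so the text never contradicts the label. An equivocal HER2
#' immunostain with its FISH resolution is rendered as a contiguous fragment
#' placed at the head of the report, mirroring the reflex-testing order in
#' which such panels are dictated. Uses the current RNG state.
#'
#' @param statuses Named map receptor -> `"POS"`/`"NEG"` covering at least
#'   one of er/pr/her2.
#' @param config A [synthetic_config()].
#' @return List with `text`, `labels` (= `statuses`) and `her2_equivocal`.
#' @export
generate_report <- function(statuses, config = synthetic_config()) {
  rcpts <- names(statuses)
  stopifnot(length(rcpts) >= 1L, all(rcpts %in% names(.receptor_short)),
            all(unlist(statuses) %in% c("POS", "NEG")))
  nb <- sample(config$biomarkers_range[1]:config$biomarkers_range[2], 1L)
  nb <- max(nb, length(rcpts))
  nd <- min(nb - length(rcpts), length(.distractor_pool))
  distract <- if (nd > 0L) sample(.distractor_pool, nd) else character(0)

  fragments <- character(0)
  head_fragment <- character(0)
  list_name <- character(0); list_pol <- character(0)
  her2_equiv <- FALSE

  for (r in rcpts) {
    if (r == "her2" && stats::runif(1) < config$equivocal_her2_rate) {
      her2_equiv <- TRUE
      head_fragment <- render_status("her2", statuses[[r]], "equivocal_fish")
    } else if (stats::runif(1) < config$interleave) {
      list_name <- c(list_name, .receptor_short[[r]])
      list_pol <- c(list_pol, statuses[[r]])
    } else {
      style <- sample(names(config$style_weights), 1L,
                      prob = config$style_weights)
      fragments <- c(fragments, render_status(r, statuses[[r]], style))
    }
  }
  for (d in distract) {
    pol <- sample(c("POS", "NEG"), 1L)
    if (d == "Ki-67") {
      pct <- sample(5:95, 1)
      fragments <- c(fragments,
                     sample(c(paste0("Ki-67: ", pct, "%."),
                              paste0("Ki-67 is reported ", pct, "%.")), 1L))
    } else if (stats::runif(1) < 0.5) {
      list_name <- c(list_name, d)
      list_pol <- c(list_pol, pol)
    } else {
      fragments <- c(fragments, switch(sample(3L, 1L),
        paste0(d, if (pol == "POS") "+." else "-."),
        paste0(if (pol == "POS") "Positive for " else "Negative for ",
               d, "."),
        paste0(d, " is ", if (pol == "POS") "positive." else "negative.")))
    }
  }
  if (length(list_name)) {
    pos_items <- sample(list_name[list_pol == "POS"])
    neg_items <- sample(list_name[list_pol == "NEG"])
    clauses <- character(0)
    if (length(pos_items))
      clauses <- c(clauses, paste0("positive for ", .join_items(pos_items)))
    if (length(neg_items))
      clauses <- c(clauses, paste0("negative for ", .join_items(neg_items)))
    fragments <- c(fragments,
                   paste0("Tumor cells are ", paste(clauses, collapse = ", "),
                          "."))
  }
  if (length(fragments) > 1L) fragments <- sample(fragments)
  list(text = paste(c(head_fragment, fragments), collapse = " "),
       labels = statuses, her2_equivocal = her2_equiv)
}

#' Generate a labelled synthetic corpus
#'
#' Receptor statuses are drawn independently per report at the configured
#' prevalences; the whole corpus is a deterministic function of the seed.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `observation_id`, `text`, one
#'   `"POS"`/`"NEG"` column per receptor, and the generator metadata flag
#'   `her2_equivocal`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  rcpts <- names(config$prevalences)
  with_seed(config$seed, {
    rows <- lapply(seq_len(config$n), function(i) {
      statuses <- stats::setNames(
        ifelse(stats::runif(length(rcpts)) < config$prevalences,
               "POS", "NEG"), rcpts)
      rep_ <- generate_report(as.list(statuses), config)
      c(list(observation_id = sprintf("rpt%05d", i), text = rep_$text),
        as.list(statuses), list(her2_equivocal = rep_$her2_equivocal))
    })
    do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  })
}

#' Rule-based reference label extractor
#'
#' Recovers receptor statuses from generated text by inverting the template
#' inventory (equivocal/FISH resolution, `ER+`/`ER-`, `ER: Positive`,
#' percentage styles, long-name phrases, and grouped
#' `positive for ... negative for ...` list clauses). It exists to certify
#' the generator's label-text fidelity; it is not a general clinical
#' information extractor.
#'
#' @param text One report's text.
#' @return Named character vector (`er`, `pr`, `her2`) of `"POS"`/`"NEG"`,
#'   `NA` where the receptor is not mentioned.
#' @export
extract_labels <- function(text) {
  res <- c(er = NA_character_, pr = NA_character_, her2 = NA_character_)
  # HER2 equivocal resolved by the FISH follow-up
  if (grepl("HER2: Equivocal", text, fixed = TRUE)) {
    m <- regmatches(text,
                    regexpr("reportedly (positive|negative)", text))
    if (length(m))
      res["her2"] <- if (grepl("positive", m)) "POS" else "NEG"
  }
  for (r in names(.receptor_short)) {
    if (!is.na(res[r])) next
    S <- .receptor_short[[r]]
    pats <- list(
      POS = c(paste0("\\b", S, "\\+"),
              paste0(S, ": Positive"),
              paste0(S, ": [1-9][0-9]*%")),
      NEG = c(paste0("\\b", S, "-(?![0-9A-Za-z])"),
              paste0(S, ": Negative"),
              paste0(S, ": 0%"))
    )
    for (pol in c("POS", "NEG")) {
      for (p in pats[[pol]]) {
        if (grepl(p, text, perl = TRUE)) { res[r] <- pol; break }
      }
      if (!is.na(res[r])) break
    }
    if (is.na(res[r])) {
      long <- if (r == "her2") "Her2 immunostain is"
              else .receptor_long[[r]]
      m <- regmatches(text, regexpr(paste0(long, " (positive|negative)"),
                                    text, ignore.case = TRUE))
      if (length(m))
        res[r] <- if (grepl("positive", m, ignore.case = TRUE)) "POS"
                  else "NEG"
    }
    if (is.na(res[r])) {
      # grouped list clauses: polarity marker governs items up to next marker
      for (s in split_sentences(text)) {
        mk <- gregexpr("(positive|negative)( staining)? for ", s,
                       ignore.case = TRUE)[[1]]
        if (mk[1] == -1L) next
        ends <- c(mk[-1], nchar(s) + 1L)
        for (i in seq_along(mk)) {
          seg <- substr(s, mk[i], ends[i] - 1L)
          if (grepl(paste0("\\b", S, "\\b"), seg)) {
            res[r] <- if (grepl("^positive", seg, ignore.case = TRUE))
              "POS" else "NEG"
            break
          }
        }
        if (!is.na(res[r])) break
      }
    }
  }
  res
}
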
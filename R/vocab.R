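# Term-of-interest (TOI) resolution and relevant-vocabulary selection.

#' Term-of-interest specification
#'
#' A TOI is an anchor concept (e.g. the estrogen-receptor mention in a
#' pathology report) matched in normalized token streams either as its
#' canonical single token or as any of a set of (possibly multi-word)
#' aliases. Aliases are given as surface strings and are run through the same
#' normalization as the corpus at match time.
#'
#' @param canonical Canonical lowercase token, e.g. `"er"`.
#' @param aliases List of alias surface strings, e.g.
#'   `list("estrogen", "estrogen receptor")`.
#' @return Object of class `toi_spec`.
#' @export
toi_spec <- function(canonical, aliases = list()) {
  stopifnot(is.character(canonical), length(canonical) == 1L,
            nzchar(canonical))
  aliases <- lapply(aliases, as.character)
  structure(list(canonical = tolower(canonical), aliases = aliases),
            class = "toi_spec")
}

#' Default hormone-receptor TOIs
#'
#' The three breast-cancer biomarker TOIs with their standard aliases:
#' `er` (estrogen, estrogen receptor), `pr` (progesterone receptor) and
#' `her2` (her-2, her/).
#'
#' @return Named list of [toi_spec()] objects.
#' @export
default_tois <- function() {
  list(er   = toi_spec("er",   list("estrogen", "estrogen receptor")),
       pr   = toi_spec("pr",   list("progesterone receptor")),
       her2 = toi_spec("her2", list("her-2", "her/")))
}

# Normalized token tuples for canonical + aliases, longest first.
# "her/" tokenizes to ("her", "slash"); multi-word aliases become tuples of
# stemmed tokens, matched contiguously.
.toi_patterns <- function(toi, config) {
  pats <- list(c(tolower(toi$canonical)))
  for (a in toi$aliases) {
    toks <- normalize_block(a, config)$tokens
    if (length(toks)) pats <- c(pats, list(toks))
  }
  pats[order(-vapply(pats, length, integer(1)))]
}

#' Locate TOI occurrences in a token sequence
#'
#' Scans left to right; at each position the longest matching canonical/alias
#' tuple wins and its span is consumed, so overlapping shorter matches are
#' deduplicated. Multi-token matches report the position of their first
#' token.
#'
#' @param seq A `token_seq` from [normalize_block()].
#' @param toi A [toi_spec()].
#' @param config The [norm_config()] the corpus was normalized with (used to
#'   normalize aliases identically).
#' @return Integer vector of 1-based anchor positions, ascending, with an
#'   attribute `spans` (integer matrix with columns `start`, `len`,
#'   `canonical` flag) describing each match.
#' @export
find_toi_occurrences <- function(seq, toi, config = norm_config()) {
  stopifnot(inherits(seq, "token_seq"), inherits(toi, "toi_spec"))
  toks <- seq$tokens
  pats <- .toi_patterns(toi, config)
  n <- length(toks)
  starts <- integer(0); lens <- integer(0); canon <- logical(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (p in pats) {
      lp <- length(p)
      if (i + lp - 1L <= n && all(toks[i:(i + lp - 1L)] == p)) {
        starts <- c(starts, i); lens <- c(lens, lp)
        canon <- c(canon, lp == 1L && p[1] == toi$canonical)
        i <- i + lp
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  structure(starts,
            spans = cbind(start = starts, len = lens,
                          canonical = as.integer(canon)))
}

#' Construct a relevant-word index
#'
#' Usually produced by [select_relevant_words()]; the constructor is exposed
#' so an index can be specified directly (e.g. a fixed vocabulary). An empty
#' index is rejected.
#'
#' @param tokens Character vector of relevant-word tokens, rank order.
#' @param toi Canonical TOI string the index belongs to.
#' @param mean_frequency Mean occurrences per observation for each token.
#' @param k The requested vocabulary size (defaults to `length(tokens)`).
#' @return Object of class `relevant_word_index`.
#' @export
relevant_word_index <- function(tokens, toi,
                                mean_frequency = rep(NA_real_, length(tokens)),
                                k = length(tokens)) {
  stopifnot(is.character(tokens), length(tokens) >= 1L,
            !anyDuplicated(tokens),
            length(mean_frequency) == length(tokens))
  structure(list(toi = tolower(toi),
                 k = .check_count(k, "k", min = 1L),
                 words = data.frame(token = tokens,
                                    mean_frequency = as.numeric(mean_frequency),
                                    stringsAsFactors = FALSE)),
            class = "relevant_word_index")
}

#' @export
print.relevant_word_index <- function(x, ...) {
  cat("<relevant_word_index> TOI '", x$toi, "', ", nrow(x$words),
      " words (k = ", x$k, ")\n", sep = "")
  print(utils::head(x$words, 10))
  if (nrow(x$words) > 10) cat("  ...\n")
  invisible(x)
}

#' Select the most relevant words for a TOI
#'
#' Relevant words are those co-occurring most frequently with the TOI: every
#' token occurrence inside blocks containing at least one TOI match is
#' tallied, excluding tokens consumed by alias matches (the canonical token's
#' own occurrences do count, so repeated TOI mentions can rank among the top
#' words). The mean frequency divides by the total number of observations,
#' not only TOI-containing blocks. Ties at equal frequency are broken
#' lexicographically, so the ranking is deterministic.
#'
#' @param corpus List of `token_seq` objects.
#' @param toi A [toi_spec()].
#' @param k Number of top words to keep (default 30).
#' @param config The corpus [norm_config()].
#' @return A [relevant_word_index()] of at most `k` words, descending mean
#'   frequency.
#' @export
select_relevant_words <- function(corpus, toi, k = 30L,
                                  config = norm_config()) {
  stopifnot(length(corpus) >= 1L)
  k <- .check_count(k, "k", min = 1L)
  m <- length(corpus)
  counted <- lapply(corpus, function(seq) {
    occ <- find_toi_occurrences(seq, toi, config)
    if (length(occ) == 0L) return(NULL)
    spans <- attr(occ, "spans")
    excluded <- logical(length(seq$tokens))
    for (r in seq_len(nrow(spans))) {
      if (spans[r, "canonical"] == 1L) next  # canonical occurrences count
      idx <- spans[r, "start"] + seq_len(spans[r, "len"]) - 1L
      excluded[idx] <- TRUE
    }
    seq$tokens[!excluded]
  })
  if (all(vapply(counted, is.null, logical(1))))
    stop("no block in the corpus contains TOI '", toi$canonical,
         "' or any of its aliases", call. = FALSE)
  tb <- table(unlist(counted))
  toks <- names(tb)
  n <- as.numeric(tb)
  ord <- order(-n, toks)
  take <- utils::head(ord, k)
  relevant_word_index(toks[take], toi$canonical, n[take] / m, k = k)
}
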
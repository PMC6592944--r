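# Core vectorization: signed reciprocal positional distance to the TOI,
# and the `rwov` model object that bundles normalization, vocabulary
# selection and vectorization into one fit.

#' Signed reciprocal-distance value
#'
#' The cell value assigned to a relevant word separated from the TOI anchor
#' by `d` relevant-word occurrences: `1/(d + 1)`, negated when the word
#' occurs before the anchor. Values therefore fall away nonlinearly from 1
#' (adjacent in relevant-word terms) towards 0 (absent), and the sign encodes
#' the side.
#'
#' @param d Number of relevant-word occurrences strictly between the word and
#'   the anchor (nonnegative integer).
#' @param side `"BEFORE"` or `"AFTER"` the anchor.
#' @return `-1/(d+1)` for BEFORE, `+1/(d+1)` for AFTER.
#' @examples
#' signed_reciprocal_value(0, "AFTER")   # 1
#' signed_reciprocal_value(4, "BEFORE")  # -0.2
#' @export
signed_reciprocal_value <- function(d, side = c("AFTER", "BEFORE")) {
  side <- match.arg(side)
  d <- .check_count(d, "d")
  v <- 1 / (d + 1)
  if (side == "BEFORE") -v else v
}

#' Vectorize one block against a relevant-word index
#'
#' The anchor is the first TOI occurrence in the block. For each index word
#' `j` occurring in the block (at a position other than the anchor itself),
#' the occurrence minimizing the count `d` of relevant-word occurrences
#' strictly between it and the anchor is chosen (ties between an equal-`d`
#' occurrence before and after are broken toward AFTER), and the cell gets
#' [signed_reciprocal_value()] of that `d`. Absent words, and blocks without
#' the TOI, give 0.
#'
#' @param seq A `token_seq`.
#' @param anchors Anchor positions from [find_toi_occurrences()] on `seq`.
#' @param index A [relevant_word_index()], fixed corpus-wide.
#' @return Numeric vector of length `nrow(index$words)`, named by word.
#' @export
vectorize_block <- function(seq, anchors, index) {
  stopifnot(inherits(seq, "token_seq"), inherits(index, "relevant_word_index"))
  words <- index$words$token
  out <- stats::setNames(numeric(length(words)), words)
  toks <- seq$tokens
  if (length(anchors) == 0L || length(toks) == 0L) return(out)
  a <- anchors[[1L]]
  rel <- toks %in% words
  C <- cumsum(rel)  # C[p] = relevant occurrences in toks[1..p]
  for (j in seq_along(words)) {
    pos <- which(toks == words[j])
    pos <- pos[pos != a]
    if (length(pos) == 0L) next
    d <- ifelse(pos < a, C[a - 1L] - C[pos], C[pmax(pos - 1L, 1L)] - C[a])
    dmin <- min(d)
    after <- any(pos[d == dmin] > a)   # tie toward AFTER
    out[j] <- signed_reciprocal_value(dmin, if (after) "AFTER" else "BEFORE")
  }
  out
}

#' Vectorize a corpus
#'
#' Applies [vectorize_block()] to every sequence; rows are independent, so
#' permuting the corpus permutes rows identically.
#'
#' @param corpus List of `token_seq` objects.
#' @param toi A [toi_spec()].
#' @param index A [relevant_word_index()].
#' @param config The corpus [norm_config()].
#' @return m x k numeric matrix, rownames = observation ids, colnames =
#'   relevant words in rank order; every entry is 0 or `+/- 1/(d+1)`.
#' @export
vectorize_corpus <- function(corpus, toi, index, config = norm_config()) {
  rows <- vapply(corpus, function(seq) {
    vectorize_block(seq, find_toi_occurrences(seq, toi, config), index)
  }, numeric(nrow(index$words)))
  mat <- t(matrix(rows, nrow = nrow(index$words)))
  dimnames(mat) <- list(vapply(corpus, `[[`, character(1), "observation_id"),
                        index$words$token)
  mat
}

#' Fit a relevant word order vectorization
#'
#' The one-stop fitting function: normalizes the corpus, selects the top-`k`
#' relevant words for the TOI, and computes the signed reciprocal-distance
#' feature matrix. The returned object carries everything needed to apply
#' the same vectorization to new text via [predict.rwov()].
#'
#' @param x Corpus: character vector of texts, or a data frame with
#'   `observation_id` and `text` columns, or a pre-normalized list of
#'   `token_seq` objects.
#' @param toi A [toi_spec()], or a canonical string resolved against
#'   [default_tois()] when possible.
#' @param k Relevant-vocabulary size (default 30).
#' @param config A [norm_config()].
#' @return Object of class `rwov` with components `toi`, `config`, `index`
#'   (the [relevant_word_index()]), `matrix` (m x k feature matrix) and
#'   `n_anchored` (number of blocks containing the TOI).
#' @examples
#' reports <- c(r1 = "Positive for ER.", r2 = "ER: 0%. Negative for PR.")
#' fit <- rwov(reports, "er", k = 5)
#' as.matrix(fit)
#' @export
rwov <- function(x, toi, k = 30L, config = norm_config()) {
  cl <- match.call()
  if (is.character(toi) && length(toi) == 1L) {
    defs <- default_tois()
    toi <- if (toi %in% names(defs)) defs[[toi]] else toi_spec(toi)
  }
  stopifnot(inherits(toi, "toi_spec"))
  corpus <- if (is.list(x) && length(x) && inherits(x[[1]], "token_seq")) x
            else normalize_corpus(x, config)
  index <- select_relevant_words(corpus, toi, k = k, config = config)
  anchors <- lapply(corpus, find_toi_occurrences, toi = toi, config = config)
  mat <- vectorize_corpus(corpus, toi, index, config)
  structure(list(call = cl, toi = toi, config = config, index = index,
                 matrix = mat,
                 n_anchored = sum(vapply(anchors, length, integer(1)) > 0L)),
            class = "rwov")
}

#' @export
print.rwov <- function(x, ...) {
  cat("Relevant word order vectorization\n")
  cat("  TOI: '", x$toi$canonical, "' (+", length(x$toi$aliases),
      " aliases)\n", sep = "")
  cat("  ", nrow(x$matrix), " observations x ", ncol(x$matrix),
      " relevant words; ", x$n_anchored, " blocks contain the TOI\n",
      sep = "")
  invisible(x)
}

#' @export
summary.rwov <- function(object, ...) {
  nz <- colMeans(object$matrix != 0)
  s <- list(toi = object$toi$canonical,
            dim = dim(object$matrix),
            top_words = utils::head(cbind(object$index$words,
                                          prop_nonzero = round(nz, 3)), 10),
            value_range = range(object$matrix))
  class(s) <- "summary.rwov"
  s
}

#' @export
print.summary.rwov <- function(x, ...) {
  cat("RWOV fit for TOI '", x$toi, "': ", x$dim[1], " x ", x$dim[2],
      " matrix, values in [", round(x$value_range[1], 3), ", ",
      round(x$value_range[2], 3), "]\n", sep = "")
  cat("Top relevant words (mean occurrences per observation):\n")
  print(x$top_words)
  invisible(x)
}

#' @export
as.matrix.rwov <- function(x, ...) x$matrix

#' Vectorize new text with a fitted RWOV
#'
#' Applies the stored normalization config and relevant-word index to new
#' observations; no vocabulary re-selection takes place.
#'
#' @param object A fitted [rwov()] object.
#' @param newdata Character vector of texts or data frame with
#'   `observation_id`/`text` columns.
#' @param ... Unused.
#' @return Feature matrix with the fit's k columns.
#' @export
predict.rwov <- function(object, newdata, ...) {
  corpus <- if (is.list(newdata) && length(newdata) &&
                inherits(newdata[[1]], "token_seq")) newdata
            else normalize_corpus(newdata, object$config)
  vectorize_corpus(corpus, object$toi, object$index, object$config)
}

#' Plot method: distribution of feature values per relevant word
#'
#' Shows, for the highest-ranked relevant words, the nonzero signed values
#' across observations — a quick view of where each word tends to sit
#' relative to the TOI.
#'
#' @param x A fitted `rwov` object.
#' @param n_words How many top words to display.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.rwov <- function(x, n_words = 10, ...) {
  n_words <- min(n_words, ncol(x$matrix))
  vals <- lapply(seq_len(n_words), function(j) {
    v <- x$matrix[, j]
    v[v != 0]
  })
  names(vals) <- colnames(x$matrix)[seq_len(n_words)]
  graphics::boxplot(vals, las = 2, ylab = "signed 1/(d+1)",
                    main = paste0("RWOV values around '", x$toi$canonical, "'"),
                    ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
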
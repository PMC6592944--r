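# Text normalization: raw report text -> ordered normalized token sequence.
#
# The pipeline is sentence split -> word/symbol tokenization -> collapse of
# polarity-qualified percentages -> case folding -> stop-word removal ->
# symbol substitution -> stemming. Positions index the pre-filter token
# stream so every surviving token can be traced back to its source.

#' Normalization configuration
#'
#' @param stop_words Lowercase words removed from every sequence. The default
#'   is the fixed nine-word clinical stop list
#'   `the, are, of, as, is, and, or, report, pathology`.
#' @param substitutions Named character vector mapping punctuation surface
#'   forms to identifier tokens; applied before stemming, first match wins.
#' @param stemmer Name of the stemming scheme; `"suffix"` (the package's
#'   iterated suffix stripper, see [suffix_stem()]) or `"none"`.
#' @param lowercase Fold case before any matching (default `TRUE`).
#' @param pct_window How many raw tokens before a `number %` pattern are
#'   searched for a polarity word when collapsing to `pospct`/`negpct`.
#' @return An object of class `norm_config`.
#' @export
norm_config <- function(stop_words = c("the", "are", "of", "as", "is",
                                       "and", "or", "report", "pathology"),
                        substitutions = c("," = "comm", "/" = "slash",
                                          "+" = "plu"),
                        stemmer = c("suffix", "none"),
                        lowercase = TRUE,
                        pct_window = 3L) {
  stemmer <- match.arg(stemmer)
  stopifnot(is.character(stop_words), is.character(substitutions),
            !is.null(names(substitutions)))
  structure(list(stop_words = tolower(stop_words),
                 substitutions = substitutions,
                 stemmer = stemmer,
                 lowercase = isTRUE(lowercase),
                 pct_window = .check_count(pct_window, "pct_window")),
            class = "norm_config")
}

#' Split text into sentences
#'
#' Rule-based: a sentence ends at terminal punctuation (`.` `!` `?`) followed
#' by whitespace and an uppercase letter or digit. No statistical model is
#' used, so mid-abbreviation periods without a following capital never split.
#'
#' @param text A single character string.
#' @return Character vector of sentences (empty for blank input).
#' @examples
#' split_sentences("Positive for ER. Negative for PR.")
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  out <- strsplit(text, "(?<=[.!?])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
  out[nzchar(trimws(out))]
}

#' Tokenize a sentence into words and symbols
#'
#' Alphanumeric runs become word tokens; internal hyphens between
#' alphanumerics are kept (`Ki-67`, `her-2` stay intact); every other
#' non-space symbol becomes its own single-character token.
#'
#' @param sentence A single character string.
#' @return Character vector of raw tokens, in order.
#' @examples
#' tokenize_words("HER2/neu")   # "HER2" "/" "neu"
#' tokenize_words("Ki-67: 23%") # "Ki-67" ":" "23" "%"
#' @export
tokenize_words <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  if (is.na(sentence) || !nzchar(sentence)) return(character(0))
  m <- gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*|[^A-Za-z0-9\\s]",
                sentence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(sentence, list(m))[[1]]
}

# polarity of a raw token for percentage collapsing
.polarity <- function(tok) {
  t <- tolower(tok)
  if (startsWith(t, "posit") || t == "pos") return("pos")
  if (startsWith(t, "negat") || t == "neg") return("neg")
  NA_character_
}

# Collapse "<number> %" into pospct/negpct when a polarity word occurs within
# `window` raw tokens before the number, inside one sentence's token vector.
.collapse_pct <- function(tokens, window = 3L) {
  n <- length(tokens)
  if (n < 2L) return(tokens)
  keep <- rep(TRUE, n)
  out <- tokens
  i <- 1L
  while (i < n) {
    if (grepl("^[0-9]+(\\.[0-9]+)?$", tokens[i]) && tokens[i + 1L] == "%") {
      pol <- NA_character_
      for (b in seq_len(min(window, i - 1L))) {
        pol <- .polarity(tokens[i - b])
        if (!is.na(pol)) break
      }
      if (!is.na(pol)) {
        out[i] <- if (pol == "pos") "pospct" else "negpct"
        keep[i + 1L] <- FALSE
        i <- i + 2L
        next
      }
    }
    i <- i + 1L
  }
  out[keep]
}

#' Normalize a single raw token
#'
#' Applies, in order: case folding, stop-word removal, symbol substitution,
#' and stemming. Numeric tokens are kept verbatim; tokens containing digits
#' (marker names like `her2`, `ki-67`) and substitution identifiers are never
#' stemmed. A stem that lands on a stop word is also removed, so no output
#' token ever equals a stop word.
#'
#' @param token A nonempty raw token.
#' @param config A [norm_config()].
#' @return The normalized token, or `NA_character_` if the token is dropped.
#' @examples
#' cfg <- norm_config()
#' normalize_token(",", cfg)    # "comm"
#' normalize_token("the", cfg)  # NA
#' @export
normalize_token <- function(token, config = norm_config()) {
  stopifnot(is.character(token), length(token) == 1L, nzchar(token))
  t <- if (config$lowercase) tolower(token) else token
  if (t %in% config$stop_words) return(NA_character_)
  idents <- c(unname(config$substitutions), "pospct", "negpct")
  if (t %in% names(config$substitutions))
    return(unname(config$substitutions[[t]]))
  if (t %in% idents) return(t)
  if (grepl("[0-9]", t)) return(t)            # numbers and marker names verbatim
  if (config$stemmer == "suffix" && grepl("^[a-z]+$", t)) {
    s <- suffix_stem(t)
    if (s %in% config$stop_words) return(NA_character_)
    return(s)
  }
  t
}

#' Normalize a text block into a token sequence
#'
#' Composes [split_sentences()], [tokenize_words()], percentage collapsing and
#' [normalize_token()]; dropped tokens leave a gap in `source_positions` so
#' each output token can be traced to its index in the pre-filter stream.
#' Sentence boundaries do not reset positions: a block is one token stream,
#' which is the scope over which positional values are later measured.
#'
#' @param text Raw text of one observation (one report).
#' @param config A [norm_config()].
#' @param observation_id Identifier carried through to downstream matrices.
#' @return An object of class `token_seq`: a list with `observation_id`,
#'   `tokens` (normalized, stop words removed) and `source_positions`
#'   (1-based indices into the pre-filter token stream, strictly increasing).
#' @export
normalize_block <- function(text, config = norm_config(),
                            observation_id = NA_character_) {
  sentences <- split_sentences(text)
  raw <- character(0)
  for (s in sentences)
    raw <- c(raw, .collapse_pct(tokenize_words(s), config$pct_window))
  norm <- if (length(raw))
    vapply(raw, normalize_token, character(1), config = config,
           USE.NAMES = FALSE) else character(0)
  keep <- !is.na(norm)
  structure(list(observation_id = observation_id,
                 tokens = norm[keep],
                 source_positions = which(keep),
                 raw_tokens = raw),
            class = "token_seq")
}

#' @export
print.token_seq <- function(x, ...) {
  cat("<token_seq> ", x$observation_id, ": ", length(x$tokens),
      " tokens\n", sep = "")
  if (length(x$tokens))
    cat(" ", paste(utils::head(x$tokens, 20), collapse = " "),
        if (length(x$tokens) > 20) "..." else "", "\n")
  invisible(x)
}

#' Normalize a whole corpus
#'
#' @param x Either a character vector of texts (names used as observation
#'   ids when present) or a data frame with columns `observation_id` and
#'   `text` (the format written by [write_corpus()] and produced by
#'   [generate_corpus()]).
#' @param config A [norm_config()].
#' @return A list of `token_seq` objects.
#' @export
normalize_corpus <- function(x, config = norm_config()) {
  if (is.data.frame(x)) {
    stopifnot(all(c("observation_id", "text") %in% names(x)))
    ids <- as.character(x$observation_id)
    texts <- as.character(x$text)
  } else {
    stopifnot(is.character(x))
    texts <- x
    ids <- if (!is.null(names(x))) names(x) else sprintf("obs%04d", seq_along(x))
  }
  Map(function(t, id) normalize_block(t, config, id), texts, ids) |>
    unname()
}
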
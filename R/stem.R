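# Iterated suffix-removal stemmer.
#
# Clinical report vocabulary is reduced aggressively to short roots
# ("received" -> "receiv", "prognostic" -> "prognost", "necrosis" -> "necros")
# in two phases: one plural strip ("s"/"es", except after "ss"/"is"/"us"),
# then up to three rounds of longest-match derivational suffix stripping.
# A suffix is only removed when at least three characters remain. The scheme
# is deliberately simple, deterministic and dictionary-free; it is a
# convention of this package, fixed by the normalization config, not an
# attempt to match any particular published stemmer's output.

.rwov_suffixes <- local({
  s <- c("fulness", "ousness", "iveness", "ization", "ational",
         "ility", "ition", "ation", "ement", "ence", "ance",
         "ness", "ment", "able", "ible", "sion", "tion", "ious", "ical",
         "ing", "ive", "ize", "ous", "ful", "ity", "ism",
         "ed", "ly", "er", "or", "al", "ic", "is",
         "y", "e", "a")
  s[order(-nchar(s), s)]
})

#' Stem a word by iterated suffix stripping
#'
#' Removes at most one plural ending, then repeatedly (up to three rounds)
#' strips the longest matching derivational suffix from a fixed inventory;
#' a suffix is only removed when at least three characters would remain.
#' Words containing digits and substitution identifiers are never stemmed
#' (see [normalize_token()]).
#'
#' @param word Character vector of lowercase alphabetic words.
#' @return Character vector of stems, same length as `word`.
#' @examples
#' suffix_stem(c("positive", "tumor", "received", "staining", "necrosis"))
#' @export
suffix_stem <- function(word) {
  vapply(word, function(w) {
    # plural strip, once
    if (endsWith(w, "es") && nchar(w) >= 5L) {
      w <- substr(w, 1L, nchar(w) - 2L)
    } else if (endsWith(w, "s") && nchar(w) >= 4L &&
               !grepl("(ss|is|us)$", w)) {
      w <- substr(w, 1L, nchar(w) - 1L)
    }
    # derivational strips
    for (round in 1:3) {
      hit <- FALSE
      for (sfx in .rwov_suffixes) {
        ns <- nchar(sfx)
        if (nchar(w) - ns >= 3L && endsWith(w, sfx)) {
          w <- substr(w, 1L, nchar(w) - ns)
          hit <- TRUE
          break
        }
      }
      if (!hit) break
    }
    w
  }, character(1), USE.NAMES = FALSE)
}
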
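# Plain-text input/output: corpora, relevant-word indices, feature matrices.

#' Read / write a labelled corpus
#'
#' The corpus format is a UTF-8 CSV with a header: an `observation_id`
#' column, a `text` column, and any number of label columns.
#'
#' @param path File path.
#' @return `read_corpus()`: a data frame.
#' @export
read_corpus <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("observation_id", "text") %in% names(df)))
    stop("corpus file must have 'observation_id' and 'text' columns",
         call. = FALSE)
  df
}

#' @param corpus Data frame with at least `observation_id` and `text`.
#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(all(c("observation_id", "text") %in% names(corpus)))
  utils::write.csv(corpus, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a relevant-word index
#'
#' Serialized as a tab-delimited two-column table (`token`,
#' `mean_frequency`) preceded by a comment header naming the TOI and `k`;
#' mean frequencies are written at full precision so the file round-trips
#' losslessly.
#'
#' @param index A [relevant_word_index()].
#' @param path File path.
#' @export
write_word_index <- function(index, path) {
  stopifnot(inherits(index, "relevant_word_index"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# toi=%s k=%d", index$toi, index$k), con)
  writeLines("token\tmean_frequency", con)
  writeLines(sprintf("%s\t%s", index$words$token,
                     format(index$words$mean_frequency, digits = 17)), con)
  invisible(path)
}

#' @rdname write_word_index
#' @export
read_word_index <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- regmatches(lines[1],
                    regexec("^# toi=(\\S+) k=(\\d+)$", lines[1]))[[1]]
  if (length(hdr) != 3L)
    stop("malformed index header", call. = FALSE)
  df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  relevant_word_index(df$token, hdr[2], df$mean_frequency,
                      k = as.integer(hdr[3]))
}

#' Read / write a feature matrix
#'
#' Tab-delimited: header row of column tokens, first column
#' `observation_id`, values written at full precision.
#'
#' @param mat Numeric matrix with rownames (observation ids) and colnames.
#' @param path File path.
#' @export
write_feature_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("observation_id", colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
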
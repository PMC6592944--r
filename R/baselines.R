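# Comparison vectorizations: n-gram counts with optional IDF weighting, and
# skip-gram word embeddings mean-pooled into document vectors. These exist
# for harness parity with the positional method; both consume the same
# normalized token sequences.

#' N-gram configuration
#'
#' @param range Pair `(min_n, max_n)`; the standard evaluation grid is
#'   `c(1,2)`, `c(2,2)`, `c(1,3)`, `c(2,3)`, `c(3,3)`.
#' @param idf Apply smoothed inverse-document-frequency weighting.
#' @return Object of class `ngram_config`.
#' @export
ngram_config <- function(range = c(1L, 2L), idf = TRUE) {
  stopifnot(length(range) == 2L, range[1] >= 1L, range[1] <= range[2])
  structure(list(range = as.integer(range), idf = isTRUE(idf)),
            class = "ngram_config")
}

#' Document-term n-gram count matrix
#'
#' Counts contiguous token n-grams for every n in the configured range;
#' vocabulary columns are ordered lexicographically so the layout is
#' deterministic. When `config$idf` is set the counts are passed through
#' [idf_transform()].
#'
#' @param corpus List of `token_seq` objects (nonempty).
#' @param config An [ngram_config()].
#' @return List with `matrix` (m x V, rownames = observation ids) and
#'   `vocab` (column n-grams, tokens joined by a space).
#' @export
ngram_matrix <- function(corpus, config = ngram_config()) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  grams <- lapply(corpus, function(seq) {
    toks <- seq$tokens
    out <- character(0)
    for (n in config$range[1]:config$range[2]) {
      L <- length(toks)
      if (L >= n) {
        idx <- seq_len(L - n + 1L)
        g <- toks[idx]
        if (n > 1L) for (o in 1L:(n - 1L)) g <- paste(g, toks[idx + o])
        out <- c(out, g)
      }
    }
    out
  })
  vocab <- sort(unique(unlist(grams)))
  mat <- matrix(0L, nrow = length(corpus), ncol = length(vocab),
                dimnames = list(vapply(corpus, `[[`, character(1),
                                       "observation_id"), vocab))
  for (i in seq_along(grams)) {
    tb <- table(grams[[i]])
    mat[i, names(tb)] <- as.integer(tb)
  }
  out <- list(matrix = mat, vocab = vocab)
  if (config$idf) out$matrix <- idf_transform(mat)
  out
}

#' Smoothed IDF weighting
#'
#' Scales each column of a document-term count matrix by
#' `log((1 + N) / (1 + df)) + 1`, where `N` is the number of documents and
#' `df` the column's document frequency. A term present in every document
#' receives the floor weight 1; weights are a deterministic function of the
#' document frequencies.
#'
#' @param counts Nonnegative document-term matrix.
#' @return Weighted matrix of the same shape, with an `idf` attribute
#'   holding the column weights.
#' @export
idf_transform <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  N <- nrow(counts)
  df <- colSums(counts > 0)
  w <- log((1 + N) / (1 + df)) + 1
  out <- sweep(counts, 2L, w, `*`)
  attr(out, "idf") <- w
  out
}

#' Skip-gram embedding configuration
#'
#' Defaults follow the common clinical-text setting: 100-dimensional
#' vectors, context window 6, 5 negative samples per positive pair, and
#' document vectors taken as the unweighted mean of token vectors.
#'
#' @param dimension Embedding dimensionality.
#' @param window Maximum distance between center and context word.
#' @param negative_samples Negative samples per (center, context) pair.
#' @param epochs Passes over the training pairs.
#' @param learning_rate Initial SGD step size (linearly decayed).
#' @param min_count Minimum token frequency for inclusion in the vocabulary.
#' @param aggregation Document pooling; only `"mean"` is supported.
#' @return Object of class `embedding_config`.
#' @export
embedding_config <- function(dimension = 100L, window = 6L,
                             negative_samples = 5L, epochs = 5L,
                             learning_rate = 0.025, min_count = 1L,
                             aggregation = "mean") {
  stopifnot(aggregation == "mean")
  structure(list(dimension = .check_count(dimension, "dimension", 1L),
                 window = .check_count(window, "window", 1L),
                 negative_samples = .check_count(negative_samples,
                                                 "negative_samples"),
                 epochs = .check_count(epochs, "epochs", 1L),
                 learning_rate = learning_rate,
                 min_count = .check_count(min_count, "min_count", 1L),
                 aggregation = aggregation),
            class = "embedding_config")
}

#' Skip-gram document embeddings
#'
#' Trains word vectors with the skip-gram objective and negative sampling
#' (noise distribution proportional to unigram frequency to the 3/4 power),
#' then pools each document as the mean of its in-vocabulary token vectors.
#' A document with no in-vocabulary tokens gets a zero row. Training is
#' seeded and single-threaded, so results are run-to-run reproducible.
#'
#' @param corpus List of `token_seq` objects (nonempty).
#' @param config An [embedding_config()].
#' @param seed Integer seed.
#' @return m x `dimension` numeric matrix, rownames = observation ids, with
#'   the word-vector matrix attached as attribute `word_vectors`.
#' @export
embed_documents <- function(corpus, config = embedding_config(), seed = 1L) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  docs <- lapply(corpus, `[[`, "tokens")
  freq <- table(unlist(docs))
  vocab <- sort(names(freq[freq >= config$min_count]))
  V <- length(vocab)
  D <- config$dimension
  ids <- vapply(corpus, `[[`, character(1), "observation_id")
  if (V == 0L) {
    return(matrix(0, length(docs), D, dimnames = list(ids, NULL)))
  }
  lookup <- stats::setNames(seq_len(V), vocab)

  # (center, context) index pairs, fixed symmetric window
  centers <- integer(0); contexts <- integer(0)
  for (d in docs) {
    idx <- lookup[d]
    idx <- idx[!is.na(idx)]
    L <- length(idx)
    if (L < 2L) next
    for (off in seq_len(min(config$window, L - 1L))) {
      i <- seq_len(L - off)
      centers <- c(centers, idx[i], idx[i + off])
      contexts <- c(contexts, idx[i + off], idx[i])
    }
  }
  noise <- as.numeric(freq[vocab])^0.75
  noise <- noise / sum(noise)

  with_seed(seed, {
    W <- matrix(stats::runif(V * D, -0.5, 0.5) / D, V, D)   # input vectors
    Cm <- matrix(0, V, D)                                   # output vectors
    P <- length(centers)
    if (P > 0L) {
      K <- config$negative_samples
      batch <- 512L
      total <- config$epochs * P
      done <- 0
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(P)
        for (b0 in seq(1L, P, by = batch)) {
          sel <- ord[b0:min(b0 + batch - 1L, P)]
          lr <- config$learning_rate * max(1e-4, 1 - done / total)
          done <- done + length(sel)
          cc <- centers[sel]; oo <- contexts[sel]
          gW <- matrix(0, length(sel), D)
          # positive pairs: label 1
          s <- 1 / (1 + exp(-rowSums(W[cc, , drop = FALSE] *
                                     Cm[oo, , drop = FALSE])))
          g <- s - 1
          gW <- gW + g * Cm[oo, , drop = FALSE]
          dC <- g * W[cc, , drop = FALSE]
          upC <- rowsum(dC, oo)
          Cm[as.integer(rownames(upC)), ] <-
            Cm[as.integer(rownames(upC)), ] - lr * upC
          # negative pairs: label 0
          if (K > 0L) for (k in seq_len(K)) {
            nn <- sample.int(V, length(sel), replace = TRUE, prob = noise)
            s <- 1 / (1 + exp(-rowSums(W[cc, , drop = FALSE] *
                                       Cm[nn, , drop = FALSE])))
            gW <- gW + s * Cm[nn, , drop = FALSE]
            dC <- s * W[cc, , drop = FALSE]
            upC <- rowsum(dC, nn)
            Cm[as.integer(rownames(upC)), ] <-
              Cm[as.integer(rownames(upC)), ] - lr * upC
          }
          upW <- rowsum(gW, cc)
          W[as.integer(rownames(upW)), ] <-
            W[as.integer(rownames(upW)), ] - lr * upW
        }
      }
    }
    out <- t(vapply(docs, function(d) {
      idx <- lookup[d]
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0L) numeric(D) else colMeans(W[idx, , drop = FALSE])
    }, numeric(D)))
    dimnames(out) <- list(ids, NULL)
    rownames(W) <- vocab
    attr(out, "word_vectors") <- W
    out
  })
}
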
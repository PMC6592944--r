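# Independent brute-force oracles and small fixture builders used across the
# test files. The oracles deliberately use naive enumeration, not the
# package's cumulative-count implementations.

# build a token_seq directly from already-normalized tokens
make_seq <- function(tokens, id = "t1") {
  structure(list(observation_id = id, tokens = tokens,
                 source_positions = seq_along(tokens),
                 raw_tokens = tokens),
            class = "token_seq")
}

# Brute-force positional oracle for vectorize_block: enumerates every
# occurrence of every column word, counts relevant occurrences strictly
# between it and the anchor by scanning, picks min d with ties toward AFTER.
brute_vectorize <- function(tokens, anchor, words) {
  out <- stats::setNames(numeric(length(words)), words)
  if (is.null(anchor) || length(tokens) == 0L) return(out)
  rel <- tokens %in% words
  for (j in seq_along(words)) {
    best_d <- Inf
    best_side <- NULL
    for (p in seq_along(tokens)) {
      if (tokens[p] != words[j] || p == anchor) next
      lo <- min(p, anchor); hi <- max(p, anchor)
      d <- if (hi - lo <= 1L) 0L else sum(rel[(lo + 1L):(hi - 1L)])
      side <- if (p < anchor) "BEFORE" else "AFTER"
      if (d < best_d || (d == best_d && side == "AFTER")) {
        best_d <- d
        best_side <- side
      }
    }
    if (is.finite(best_d))
      out[j] <- (if (best_side == "BEFORE") -1 else 1) / (best_d + 1)
  }
  out
}

# Exhaustive pair-enumeration AUC (ties score 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# Sign-flip permutation oracle for the paired AUC difference
perm_auc_pvalue <- function(scores_a, scores_b, labels, B = 2000, seed = 1) {
  obs <- abs(auc_score(scores_a, labels) - auc_score(scores_b, labels))
  n <- length(labels)
  with_seed(seed, {
    hits <- 0
    for (b in seq_len(B)) {
      flip <- stats::runif(n) < 0.5
      a2 <- ifelse(flip, scores_b, scores_a)
      b2 <- ifelse(flip, scores_a, scores_b)
      d <- abs(auc_score(a2, labels) - auc_score(b2, labels))
      if (d >= obs - 1e-12) hits <- hits + 1
    }
    hits / B
  })
}
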
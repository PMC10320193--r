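# Independent brute-force oracles used to cross-check the package's
# computations. These deliberately use naive enumeration / direct formulas,
# not the code paths they verify.

# step-up BH by exhaustive minimisation over larger p-values
oracle_bh <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    cands <- vapply(seq_len(n), function(j) {
      if (p[j] >= p[i]) p[j] * n / sum(p <= p[j]) else Inf
    }, numeric(1))
    min(1, min(cands))
  }, numeric(1))
}

# step-down Holm by exhaustive maximisation over smaller p-values
oracle_holm <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    cands <- vapply(which(p <= p[i]), function(j) {
      (n - sum(p < p[j])) * p[j]
    }, numeric(1))
    min(1, max(cands))
  }, numeric(1))
}

# upper-tail hypergeometric probability by direct summation
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- seq(k, min(K, n))
  if (length(xs) == 0L) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# median-of-ratios size factors by direct per-sample loops
oracle_size_factors <- function(counts) {
  ok <- apply(counts > 0, 1L, all)
  geo <- apply(counts[ok, , drop = FALSE], 1L, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(counts)), function(j) {
    median(counts[ok, j] / geo)
  }, numeric(1))
}

# collapsed counts by an explicit double loop
oracle_collapse <- function(counts_2n, counts_1n, map) {
  out <- counts_2n
  for (i in seq_len(nrow(map))) {
    for (j in seq_len(ncol(counts_2n))) {
      out[map$primary_id[i], j] <- counts_2n[map$primary_id[i], j] +
        counts_1n[map$acquired_id[i], j]
    }
  }
  out
}

# hit filter by explicit per-query / per-target loops
oracle_hit_filter <- function(hits, min_identity, min_qcov) {
  pass <- hits[hits$percent_identity >= min_identity &
                 hits$alignment_length > min_qcov * hits$query_length, ,
               drop = FALSE]
  winners <- list()
  for (q in sort(unique(pass$query_id))) {
    hq <- pass[pass$query_id == q, , drop = FALSE]
    hq <- hq[hq$bit_score == max(hq$bit_score), , drop = FALSE]
    hq <- hq[order(hq$target_id), , drop = FALSE]
    winners[[q]] <- hq[1L, ]
  }
  w <- do.call(rbind, winners)
  if (is.null(w)) {
    return(data.frame(primary_id = character(0),
                      acquired_id = character(0)))
  }
  keep <- rep(TRUE, nrow(w))
  for (tgt in unique(w$target_id)) {
    idx <- which(w$target_id == tgt)
    if (length(idx) > 1L) {
      best <- idx[order(-w$bit_score[idx], w$query_id[idx])][1L]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  w <- w[keep, , drop = FALSE]
  out <- data.frame(primary_id = w$query_id, acquired_id = w$target_id)
  out <- out[order(out$primary_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# prediction-interval bounds via stats::predict.lm (independent code path)
oracle_prediction_bounds <- function(x, y, newx, level) {
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  as.data.frame(stats::predict(fit, newdata = data.frame(x = newx),
                               interval = "prediction", level = level))
}

# random small count matrix fixture
random_counts <- function(n_genes, n_samples, lambda = 50,
                          prefix = "g") {
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# random hit table fixture
random_hits <- function(n, n_queries = 8, n_targets = 8) {
  data.frame(
    query_id = sprintf("q%02d", sample.int(n_queries, n, replace = TRUE)),
    target_id = sprintf("t%02d", sample.int(n_targets, n, replace = TRUE)),
    percent_identity = runif(n, 70, 100),
    alignment_length = sample(500:1100, n, replace = TRUE),
    query_length = sample(800:1100, n, replace = TRUE),
    e_value = 10^runif(n, -50, -10),
    bit_score = round(runif(n, 100, 2000), 1)
  )
}
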
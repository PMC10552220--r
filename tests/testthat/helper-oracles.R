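# Independent scalar-loop oracles used to check the vectorized paths.

# log2 expression, one entry at a time
oracle_log_expression <- function(umis, epsilon = 1e-5) {
  e <- matrix(NA_real_, nrow(umis), ncol(umis), dimnames = dimnames(umis))
  for (i in seq_len(nrow(umis))) {
    n <- 0
    for (g in seq_len(ncol(umis))) n <- n + umis[i, g]
    for (g in seq_len(ncol(umis))) {
      e[i, g] <- log2(epsilon + umis[i, g] / n)
    }
  }
  e
}

# textbook Pearson correlation of two vectors
oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) 0 else num / den
}

# exhaustive simplex grid search for <= 3 candidates at a given step;
# returns the best objective ||A w - b||^2 found on the grid
oracle_grid_objective <- function(A, b, step = 0.01) {
  k <- ncol(A)
  stopifnot(k <= 3)
  grid <- seq(0, 1, by = step)
  best <- Inf
  if (k == 1) {
    return(sum((A[, 1] - b)^2))
  }
  if (k == 2) {
    for (w1 in grid) {
      r <- A[, 1] * w1 + A[, 2] * (1 - w1) - b
      best <- min(best, sum(r * r))
    }
    return(best)
  }
  for (w1 in grid) {
    for (w2 in grid) {
      w3 <- 1 - w1 - w2
      if (w3 < -1e-12) next
      r <- A[, 1] * w1 + A[, 2] * w2 + A[, 3] * max(w3, 0) - b
      best <- min(best, sum(r * r))
    }
  }
  best
}

solver_objective <- function(w, e_atlas, query_vec, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(query_vec))
  members <- as.integer(names(w))
  fit <- drop(w %*% e_atlas[members, mask, drop = FALSE])
  sum((query_vec[mask] - fit)^2)
}
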
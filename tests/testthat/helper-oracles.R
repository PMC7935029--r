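# Independent brute-force oracles used across the suite.

# two-pass Pearson correlation, straight from the textbook formula
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

naive_fc <- function(signals) {
  n <- ncol(signals)
  out <- diag(n)
  for (a in seq_len(n - 1))
    for (b in (a + 1):n)
      out[a, b] <- out[b, a] <- naive_pearson(signals[, a], signals[, b])
  out
}

# full sort of each row, take the first k
naive_knn <- function(vals, k) {
  n <- ncol(vals)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- vals[i, ]
    row[i] <- -Inf
    out[i, ] <- order(-row, seq_len(n))[seq_len(k)]
  }
  out
}

# per-node, per-neighbor enumeration of the EdgeConv output
naive_edgeconv <- function(x, graph, W, b) {
  n <- nrow(x)
  f_out <- ncol(W)
  out <- matrix(0, n, f_out)
  for (i in seq_len(n)) {
    cands <- vapply(seq_len(graph$k), function(j) {
      xj <- x[graph$neighbors[i, j], ]
      pmax(as.numeric(c(x[i, ], xj - x[i, ]) %*% W + b), 0)
    }, numeric(f_out))
    out[i, ] <- apply(matrix(cands, f_out), 1, max)
  }
  out
}

# breadth-first search over directed edges
naive_reachable <- function(graph, start, hops) {
  reached <- start
  frontier <- start
  for (h in seq_len(hops)) {
    nxt <- setdiff(unique(as.vector(graph$neighbors[frontier, , drop = FALSE])),
                   reached)
    if (length(nxt) == 0) break
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  sort(reached)
}
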
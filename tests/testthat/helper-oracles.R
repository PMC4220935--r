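# Independent brute-force oracles used across the suite.

# Exact marginals of a binary chain/ring field by enumeration of all 2^n
# configurations (state 1 = +1, state 2 = -1).
enumerate_marginals <- function(evidence, compat, topology = "chain") {
  n <- nrow(evidence)
  states <- as.matrix(expand.grid(rep(list(1:2), n)))
  w <- apply(states, 1, function(s) {
    v <- prod(evidence[cbind(seq_len(n), s)])
    for (i in seq_len(n - 1)) v <- v * compat[s[i], s[i + 1]]
    if (topology == "ring") v <- v * compat[s[n], s[1]]
    v
  })
  marg <- matrix(0, n, 2)
  for (i in seq_len(n)) for (k in 1:2)
    marg[i, k] <- sum(w[states[, i] == k])
  marg / rowSums(marg)
}

# Minimum path cost over all column-monotone paths with |row step| <= step_max.
enumerate_min_path_cost <- function(costs, step_max = 1) {
  nr <- nrow(costs); nc <- ncol(costs)
  best <- Inf
  recurse <- function(col, row, acc) {
    acc <- acc + costs[row, col]
    if (col == nc) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    for (r2 in max(1, row - step_max):min(nr, row + step_max))
      recurse(col + 1, r2, acc)
  }
  for (r in seq_len(nr)) recurse(1, r, 0)
  best
}

# Run-length scanner for binary plaque labels (no wrap).
scan_runs <- function(z) {
  out <- list()
  i <- 1; n <- length(z)
  while (i <= n) {
    if (z[i] == 1) {
      j <- i
      while (j < n && z[j + 1] == 1) j <- j + 1
      out[[length(out) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# Small phantom used by several files (plaque arc on columns 40..80).
plaque_phantom <- function(seed = 7, thickness = 10) {
  generate_phantom(phantom_spec(
    plaque = list(c1 = 40, c2 = 80, r0 = 56, thickness = thickness),
    seed = seed))
}

expect_rows_sum_to_one <- function(m, tol = 1e-9) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
}
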
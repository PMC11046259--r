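# Independent oracles, deliberately naive implementations kept separate
# from the package code paths they check.

# triple-loop histogram transfer entropy
naive_te <- function(px, py, delay, B) {
  px <- rbind(px); py <- rbind(py)
  tobin <- function(p) pmin(pmax(floor((p + pi) / (2 * pi) * B) + 1, 1), B)
  cnt <- array(0, c(B, B, B))           # [y_future, y_past, x_past]
  for (tr in seq_len(nrow(px)))
    for (t in seq_len(ncol(px) - delay)) {
      i <- tobin(py[tr, t + delay]); j <- tobin(py[tr, t])
      k <- tobin(px[tr, t])
      cnt[i, j, k] <- cnt[i, j, k] + 1
    }
  n <- sum(cnt); te <- 0
  for (i in 1:B) for (j in 1:B) for (k in 1:B) {
    c1 <- cnt[i, j, k]
    if (c1 == 0) next
    te <- te + (c1 / n) * log2((c1 / sum(cnt[, j, k])) /
                                 (sum(cnt[i, j, ]) / sum(cnt[, j, ])))
  }
  te
}

# wrapped Gaussian phase random walk
rand_walk_phase <- function(n, step = 0.4) {
  x <- cumsum(stats::rnorm(n, sd = step))
  (x + pi) %% (2 * pi) - pi
}

# exact sign-flip null at small n by full enumeration
enumerate_signflip_p <- function(d) {
  n <- length(d)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- flips %*% d / n
  obs <- mean(d)
  c(hi = mean(null >= obs), lo = mean(null <= obs))
}
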
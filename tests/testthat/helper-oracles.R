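# Independent oracles used by the test suite.  These deliberately
# re-implement the checked computations in the most naive way possible and
# must stay independent of the package internals.

# Naive step-by-step infection simulator: scalar state variables, explicit
# update order, no shared code with simulate_predation().
brute_force_sim <- function(F0, P0, p, dt, max_steps = 1000L) {
  Fr <- F0; B <- 0; P <- P0
  rows <- list(c(step = 0, t = 0, Fr = Fr, B = B, P = P))
  i <- 0L
  while (i < max_steps && !(P == 0 && B == 0)) {
    i <- i + 1L
    released <- p * B
    attacked <- if (Fr < P) Fr else P
    P <- P - attacked
    B <- attacked
    Fr <- Fr - attacked + released
    rows[[i + 1L]] <- c(step = i, t = i * dt, Fr = Fr, B = B, P = P)
  }
  out <- do.call(rbind, rows)
  attr(out, "terminated") <- (P == 0 && B == 0)
  out
}

# Brute-force grid search for the Weibull least-squares problem: evaluates
# the rss on a dense (b, e) x (c, d) grid around given centre values and
# returns the minimum rss found.
grid_search_rss <- function(t, od, b0, c0, d0, e0,
                            n_be = 100L, n_cd = 10L, spread = 0.25) {
  bs <- seq(b0 * (1 - spread), b0 * (1 + spread), length.out = n_be)
  es <- seq(e0 * (1 - spread), e0 * (1 + spread), length.out = n_be)
  cs <- seq(c0 - spread * (d0 - c0), c0 + spread * (d0 - c0), length.out = n_cd)
  ds <- seq(d0 - spread * (d0 - c0), d0 + spread * (d0 - c0), length.out = n_cd)
  lt <- log(t)
  lt[t == 0] <- -Inf
  best <- Inf
  for (b in bs) {
    # shape factor for every e at once: n_e x n_t matrix
    s <- exp(-exp(b * outer(-log(es), lt, `+`)))
    s[, t == 0] <- 1
    for (cc in cs) {
      for (dd in ds) {
        rss <- rowSums((matrix(od, nrow(s), length(od), byrow = TRUE) -
                          (cc + (dd - cc) * s))^2)
        m <- min(rss)
        if (m < best) best <- m
      }
    }
  }
  best
}

# Spreadsheet-style summary: plain mean/sd/CI computation.
manual_summary <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- sqrt(sum((v - m)^2) / (n - 1))
  list(mean = m, ci95_half = 1.96 * s / sqrt(n), sd = s, n = n)
}

species_three <- c("P_mirabilis", "S_enterica", "S_flexneri")
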
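# Independent scalar oracles: literal transcriptions of the defining formulas,
# written without reference to the package implementation.

oracle_lz <- function(u, theta, a, b) {
  P <- exp(a * (theta - b)) / (1 + exp(a * (theta - b)))
  w <- log(P / (1 - P))
  sum(w * (u - P)) / sqrt(sum(w^2 * P * (1 - P)))
}

oracle_lzstar <- function(u, theta, a, b) {
  P <- exp(a * (theta - b)) / (1 + exp(a * (theta - b)))
  w <- log(P / (1 - P))
  Pprime <- a * P * (1 - P)
  r <- a                       # derivative of the log-odds under 2PL, MLE case
  cJ <- sum(Pprime * w) / sum(Pprime * r)
  ws <- w - cJ * r
  sum(ws * (u - P)) / sqrt(sum(ws^2 * P * (1 - P)))
}

# Brute-force ability maximizer: two-stage grid refined to 1e-6 resolution.
oracle_theta_grid <- function(u, a, b, lim = 4) {
  ll <- function(th) {
    P <- stats::plogis(a * (th - b))
    sum(u * log(P) + (1 - u) * log(1 - P))
  }
  grid <- seq(-lim, lim, by = 1e-3)
  best <- grid[which.max(vapply(grid, ll, numeric(1)))]
  fine <- seq(best - 2e-3, best + 2e-3, by = 1e-6)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# Random 2PL person-fit instance with an interior maximum likelihood ability.
random_pf_instance <- function(J = NULL) {
  if (is.null(J)) J <- sample(5:40, 1)
  a <- runif(J, 0.8, 2.5)
  b <- rnorm(J)
  theta <- rnorm(1)
  u <- as.integer(runif(J) < stats::plogis(a * (theta - b)))
  if (all(u == 1) || all(u == 0)) return(NULL)  # skip clamped cases
  list(u = u, a = a, b = b)
}
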
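# Independent oracles, deliberately written as naive loops / direct
# formulas so they share no code with the package implementation.

# two-pass weighted population covariance definition of the index
naive_concentration_index <- function(y, R, w = rep(1, length(y))) {
  wn <- w / sum(w)
  mu <- 0; Rb <- 0
  for (i in seq_along(y)) { mu <- mu + wn[i] * y[i]; Rb <- Rb + wn[i] * R[i] }
  s <- 0
  for (i in seq_along(y)) s <- s + wn[i] * (y[i] - mu) * (R[i] - Rb)
  2 * s / mu
}

# trapezoid area under a concentration curve
curve_area <- function(curve) {
  sum(diff(curve$p) * (head(curve$L, -1) + tail(curve$L, -1)) / 2)
}

# random binary sample with guaranteed non-degenerate outcome
random_binary_sample <- function(n, weighted = FALSE) {
  y <- rbinom(n, 1, runif(1, 0.1, 0.9))
  if (all(y == 0)) y[sample(n, 1)] <- 1
  list(y = y, score = rnorm(n),
       w = if (weighted) runif(n, 0.2, 3) else rep(1, n))
}

small_factor_data <- function(n, seed = NULL) {
  gen <- function() {
    d <- data.frame(
      g1 = sample(c("a", "b", "c"), n, replace = TRUE),
      g2 = sample(c("u", "v"), n, replace = TRUE),
      score = rnorm(n))
    lin <- -0.6 + 0.3 * (d$g1 == "b") - 0.2 * (d$g2 == "v") + 0.4 * pnorm(d$score)
    d$y <- rbinom(n, 1, pmin(pmax(lin, 0.02), 0.98))
    if (all(d$y == 0)) d$y[sample(n, 1)] <- 1
    d
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
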
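#' Weighted fractional rank
#'
#' Position of each observation in the weighted distribution of a
#' socioeconomic score: the cumulative weight of all strictly poorer
#' observations plus half the observation's own weight, divided by total
#' weight.  Tied scores share the midpoint rank of the tied group's pooled
#' weight span, the health-economics convention.  With equal weights and
#' distinct scores this reduces to \eqn{(i - 0.5)/n}.
#'
#' Ranks depend on the score only through its ordering, so any strictly
#' increasing transform of `scores` leaves them unchanged.
#'
#' @param scores Numeric vector of socioeconomic scores (e.g. a household
#'   wealth score); ties allowed.
#' @param weights Optional positive sampling weights; default equal.
#' @return Numeric vector of ranks, strictly inside (0, 1), in the input
#'   order.
#' @examples
#' fractional_rank(c(3, 1, 4, 2))              # 0.625 0.125 0.875 0.375
#' fractional_rank(c(1, 2), weights = c(1, 3)) # 0.125 0.625
#' @export
fractional_rank <- function(scores, weights = NULL) {
  n <- length(scores)
  if (n == 0L) stop("empty score vector")
  if (anyNA(scores)) stop("scores must be non-missing")
  w <- check_weights(weights, n)
  ord <- order(scores)
  ws <- w[ord]
  tot <- sum(ws)
  # midpoint of each tied group's pooled weight span
  grp <- cumsum(!duplicated(scores[ord]))
  gw <- tapply(ws, grp, sum)
  ghigh <- cumsum(gw)
  gmid <- (ghigh - gw / 2) / tot
  r <- numeric(n)
  r[ord] <- gmid[grp]
  r
}

#' Concentration index
#'
#' Twice the weighted covariance between an outcome and the fractional
#' socioeconomic rank, divided by the outcome mean:
#' \deqn{C = \frac{2}{\mu}\,\mathrm{cov}_w(y, R).}
#' The covariance is the population form (divided by total weight).  C lies
#' in \eqn{[-1, 1]}; for a binary outcome with mean \eqn{\mu} it lies in
#' \eqn{[\mu - 1, 1 - \mu]}.  Negative values mean the outcome is
#' concentrated among the poor (low ranks).
#'
#' @param y Outcome vector (binary or continuous).
#' @param ranks Fractional ranks as from [fractional_rank()].
#' @param weights Optional positive weights; default equal.
#' @return The concentration index, a scalar.
#' @seealso [concentration()] for a ranked-sample wrapper that also returns
#'   the concentration curve; [fractional_rank()].
#' @examples
#' r <- fractional_rank(1:4)
#' concentration_index(c(0, 0, 1, 1), r)  #  0.5
#' concentration_index(c(1, 1, 0, 0), r)  # -0.5
#' @export
concentration_index <- function(y, ranks, weights = NULL) {
  n <- length(y)
  if (length(ranks) != n) stop("y and ranks must have equal length")
  if (anyNA(y) || anyNA(ranks)) stop("y and ranks must be non-missing")
  w <- check_weights(weights, n)
  wn <- w / sum(w)
  mu <- sum(wn * y)
  if (mu == 0) stop("concentration index undefined: outcome mean is zero")
  if (diff(range(ranks)) == 0 && n > 1L)
    stop("concentration index undefined: ranks are constant")
  2 / mu * sum(wn * (y - mu) * (ranks - sum(wn * ranks)))
}

#' Concentration curve coordinates
#'
#' Cumulative outcome share against cumulative population share, with the
#' population ordered poorest to richest by `scores`.  The curve starts at
#' (0, 0) and ends at (1, 1); lying above the diagonal means the outcome is
#' concentrated among the poor.
#'
#' @param y Outcome vector.
#' @param scores Socioeconomic scores used to order the population.
#' @param weights Optional positive weights.
#' @return A data.frame with columns `p` (cumulative population share) and
#'   `L` (cumulative outcome share), one row per observation plus the (0, 0)
#'   origin.
#' @export
concentration_curve <- function(y, scores, weights = NULL) {
  n <- length(y)
  if (length(scores) != n) stop("y and scores must have equal length")
  w <- check_weights(weights, n)
  wn <- w / sum(w)
  mu <- sum(wn * y)
  if (mu == 0) stop("concentration curve undefined: outcome mean is zero")
  ord <- order(scores)
  data.frame(p = c(0, cumsum(wn[ord])),
             L = c(0, cumsum(wn[ord] * y[ord]) / mu))
}

#' Concentration analysis of one outcome
#'
#' Convenience wrapper bundling the fractional rank, the concentration
#' index and the concentration curve for one outcome ranked by a
#' socioeconomic score.
#'
#' @param y Outcome vector (binary or continuous).
#' @param score Socioeconomic score used for ranking.
#' @param weights Optional positive sampling weights.
#' @return An object of class `"concentration"`: a list with `index`,
#'   `curve` (data.frame of curve coordinates), `mu`, `ranks` and
#'   `n_effective` (number of observations used).
#' @examples
#' set.seed(1)
#' s <- rnorm(500)
#' y <- rbinom(500, 1, plogis(-1 - s))   # concentrated among the poor
#' cc <- concentration(y, s)
#' cc$index < 0
#' @export
concentration <- function(y, score, weights = NULL) {
  keep <- !(is.na(y) | is.na(score))
  y <- y[keep]; score <- score[keep]
  w <- check_weights(weights, length(keep))[keep]
  r <- fractional_rank(score, w)
  out <- list(index = concentration_index(y, r, w),
              curve = concentration_curve(y, score, w),
              mu = wmean(y, w), ranks = r, n_effective = length(y))
  class(out) <- "concentration"
  out
}

#' @export
print.concentration <- function(x, ...) {
  side <- if (x$index < 0) "concentrated among the poor"
          else if (x$index > 0) "concentrated among the rich"
          else "no socioeconomic gradient"
  cat("Concentration index: ", format(round_half_up(x$index, 3), nsmall = 3),
      "  (", side, ")\n", sep = "")
  cat("Outcome mean: ", signif(x$mu, 4),
      "   n = ", x$n_effective, "\n", sep = "")
  invisible(x)
}

#' @param x A `"concentration"` object.
#' @param ... Passed to [graphics::plot()].
#' @rdname concentration
#' @export
plot.concentration <- function(x, ...) {
  graphics::plot(x$curve$p, x$curve$L, type = "l",
                 xlab = "Cumulative population share (poorest first)",
                 ylab = "Cumulative outcome share", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
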
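#' @keywords internal
"_PACKAGE"

# Round half away from zero, the convention used in published survey tables
# (base round() is half-to-even).  The 1e-9 guard absorbs binary
# representation error in values like 0.0235 stored as 0.02349999...
#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the rounding
#' used throughout the package's formatted tables (base [round()] rounds
#' ties to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(-0.02334, 3)  # -0.023
#' round_half_up(0.5)          # 1
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Weighted mean and population covariance (divide by total weight, not
# total - 1); the population form is what makes the decomposition
# adding-up identity exact.
wmean <- function(x, w) sum(w * x) / sum(w)

wcov <- function(x, y, w) {
  wn <- w / sum(w)
  sum(wn * (x - sum(wn * x)) * (y - sum(wn * y)))
}

check_weights <- function(w, n) {
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n)
    stop("weights must have length ", n, ", got ", length(w))
  if (anyNA(w) || any(w <= 0))
    stop("weights must be positive and non-missing")
  w
}
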
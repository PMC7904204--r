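#' Elasticity of an outcome with respect to a covariate
#'
#' The regression coefficient scaled by the covariate mean relative to the
#' outcome mean, \eqn{\eta_k = \beta_k \bar{x}_k / \mu}: the building block
#' of the regression-based decomposition, where each covariate's
#' contribution to the concentration index is \eqn{\eta_k C_k}.
#'
#' @param beta_k Regression coefficient of the covariate.
#' @param xbar_k Weighted mean of the covariate.
#' @param mu Weighted mean of the outcome (non-zero).
#' @return The elasticity, a scalar.
#' @export
elasticity <- function(beta_k, xbar_k, mu) {
  if (any(mu == 0)) stop("elasticity undefined: outcome mean is zero")
  beta_k * xbar_k / mu
}

#' Concentration index of a covariate
#'
#' The same estimator as [concentration_index()] applied to a covariate
#' (typically a dummy column): \eqn{C_k = 2\,\mathrm{cov}_w(x_k, R)/\bar{x}_k}.
#'
#' @param x_k Covariate vector (mean must be non-zero).
#' @param ranks Fractional ranks of the socioeconomic score.
#' @param weights Optional positive weights.
#' @return The covariate concentration index.
#' @export
covariate_ci <- function(x_k, ranks, weights = NULL) {
  concentration_index(x_k, ranks, weights)
}

#' Decompose the concentration index of a health outcome
#'
#' Regression-based (Wagstaff) decomposition of wealth-related inequality.
#' A linear model \eqn{y_i = \alpha + \sum_k \beta_k x_{ki} + \epsilon_i}
#' is fit by weighted OLS, and the concentration index of \eqn{y} is
#' rewritten as
#' \deqn{C = \sum_k \frac{\beta_k \bar{x}_k}{\mu} C_k +
#'       \frac{GC_\epsilon}{\mu},}
#' where \eqn{C_k} is the concentration index of covariate \eqn{k} and
#' \eqn{GC_\epsilon = 2\,\mathrm{cov}_w(\epsilon, R)} is the generalized
#' concentration index of the residual.  The explained part
#' ("calculated CI") is \eqn{\sum_k \eta_k C_k}; the residual is the
#' unexplained part.  Because OLS residuals are exactly orthogonal to the
#' design, calculated + residual equals the actual index to machine
#' precision.  Percentage contributions are reported relative to the
#' calculated (explained) CI, so they sum to 100 over all covariates.
#'
#' With `engine = "logit"` the linear coefficients are replaced by average
#' partial effects from a logistic fit; the adding-up identity then holds
#' only approximately, the approximation error being absorbed into the
#' residual.
#'
#' @param formula Model formula `outcome ~ factor1 + factor2 + ...`; the
#'   right-hand side names categorical columns of `data`.
#' @param data Data frame of individual records.
#' @param score Name of the continuous socioeconomic score column used for
#'   ranking (the wealth score), or a numeric vector of scores.
#' @param weights Optional name of a weight column, or a numeric vector.
#' @param specs Optional list of [factor_spec()] overriding category order
#'   and reference levels (defaults derived from the data).
#' @param engine `"ols"` (default, exact identity) or `"logit"` (average
#'   partial effects).
#' @return An object of class `"ci_decomp"`: a list with
#'   \describe{
#'     \item{rows}{data.frame of per-category results: factor, category,
#'       elasticity, ci_k, absolute (contribution), pct (% of calculated
#'       CI); reference categories carry `NA`s.}
#'     \item{group_totals}{named vector of per-factor summed % contributions.}
#'     \item{calculated_ci, actual_ci, residual}{explained CI, actual CI of
#'       the outcome, and their difference (= \eqn{GC_\epsilon/\mu}).}
#'     \item{fit}{the underlying [fit_lpm()] (or logistic) object.}
#'     \item{mu, ranks, n, engine, call}{supporting quantities.}
#'   }
#' @examples
#' pop <- generate_population(sim_config(n = 2000, seed = 7))
#' boys <- pop[pop$sex == "boy", ]
#' d <- ci_decomp(thinness ~ education + caste, boys, score = "wealth_score")
#' d
#' abs(d$calculated_ci + d$residual - d$actual_ci) < 1e-10
#' @export
ci_decomp <- function(formula, data, score, weights = NULL, specs = NULL,
                      engine = c("ols", "logit")) {
  engine <- match.arg(engine)
  cl <- match.call()
  outcome <- as.character(formula[[2L]])
  vars <- all.vars(formula[[3L]])
  if (!outcome %in% names(data)) stop("outcome column '", outcome, "' not found")
  sc <- if (is.character(score)) {
    if (!score %in% names(data)) stop("score column '", score, "' not found")
    data[[score]]
  } else score
  w <- if (is.character(weights)) data[[weights]]
       else if (is.null(weights)) rep(1, nrow(data)) else weights
  if (is.null(specs)) specs <- specs_from_data(data, vars)

  keep <- Reduce(`&`, c(list(!is.na(data[[outcome]]), !is.na(sc)),
                        lapply(specs, function(s) !is.na(data[[s$name]]))))
  data <- data[keep, , drop = FALSE]
  y <- data[[outcome]]; sc <- sc[keep]; w <- check_weights(w[keep], sum(keep))
  n <- length(y)

  ranks <- fractional_rank(sc, w)
  wn <- w / sum(w)
  mu <- sum(wn * y)
  if (mu == 0) stop("decomposition undefined: outcome mean is zero")

  if (!length(specs)) {
    # intercept-only: nothing explained, everything in the residual
    actual <- concentration_index(y, ranks, w)
    rows <- data.frame(factor = character(0), category = character(0),
                       elasticity = numeric(0), ci_k = numeric(0),
                       absolute = numeric(0), pct = numeric(0))
    return(structure(list(rows = rows, group_totals = numeric(0),
                          calculated_ci = 0, actual_ci = actual,
                          residual = 2 * wcov(y - mu, ranks, w) / mu,
                          fit = NULL, specs = specs, outcome = outcome,
                          mu = mu, ranks = ranks, n = n, weights = w,
                          engine = engine, call = cl),
                     class = "ci_decomp"))
  }

  X <- build_design(data, specs)
  # an empty category (all-zero dummy) has zero rank-covariance, hence a
  # zero contribution; drop it from the fit to keep the design full rank
  empty <- apply(X, 2L, function(c) diff(range(c)) == 0)
  Xf <- X[, !empty, drop = FALSE]
  if (!ncol(Xf)) stop("no non-empty covariate columns to decompose")

  fit <- fit_lpm(y, Xf, w)
  betas_f <- fit$betas
  if (engine == "logit") {
    lfit <- fit_logistic(y, Xf, w)
    p <- stats::fitted(lfit$glm)
    scale <- sum(wn * p * (1 - p))              # average partial effect
    betas_f <- lfit$coefficients[-1L] * scale
    names(betas_f) <- colnames(Xf)
    eps <- y - p
  } else {
    eps <- fit$residuals
  }

  betas <- xbar <- stats::setNames(numeric(ncol(X)), colnames(X))
  betas[colnames(Xf)] <- betas_f
  xbar[colnames(Xf)] <- fit$xbar
  # eta_k * C_k collapses to 2 beta_k cov(x_k, R) / mu, which stays defined
  # even for an empty category (xbar 0); C_k itself is then flagged NA.
  covs <- apply(X, 2L, wcov, y = ranks, w = w)
  absolute <- 2 * betas * covs / mu
  eta <- elasticity(betas, xbar, mu)
  ci_k <- ifelse(xbar > 0, 2 * covs / xbar, NA_real_)
  calculated <- sum(absolute)
  actual <- concentration_index(y, ranks, w)
  residual <- 2 * wcov(eps, ranks, w) / mu
  pct <- absolute / calculated * 100

  fac <- attr(X, "factor")
  est <- data.frame(factor = fac,
                    category = sub("^[^:]*:", "", colnames(X)),
                    elasticity = unname(eta), ci_k = unname(ci_k),
                    absolute = unname(absolute), pct = unname(pct),
                    stringsAsFactors = FALSE)
  # reference rows kept blank, as association tables print them
  rows <- do.call(rbind, lapply(specs, function(sp) {
    rbind(data.frame(factor = sp$name, category = sp$reference,
                     elasticity = NA_real_, ci_k = NA_real_,
                     absolute = NA_real_, pct = NA_real_,
                     stringsAsFactors = FALSE),
          est[est$factor == sp$name, , drop = FALSE])
  }))
  rownames(rows) <- NULL
  gt <- vapply(split(est$pct, est$factor), sum, numeric(1))
  gt <- gt[unique(est$factor)]                   # keep spec order

  structure(list(rows = rows, group_totals = gt,
                 calculated_ci = calculated, actual_ci = actual,
                 residual = residual, fit = fit, specs = specs,
                 outcome = outcome, mu = mu, ranks = ranks, n = n,
                 weights = w, engine = engine, call = cl),
            class = "ci_decomp")
}

#' Format a decomposition as a printed table
#'
#' Renders the per-category rows plus the Calculated CI / Actual CI /
#' Residual footer at the conventional precision: elasticity, covariate CI
#' and absolute contribution at 3 decimals, percentage contributions and
#' per-factor totals at 1 decimal, ties rounded half away from zero.
#' Reference-category rows are left blank.
#'
#' @param x A `"ci_decomp"` object.
#' @return A character data.frame ready for printing or CSV export, with
#'   columns factor, category, elasticity, ci, absolute, pct, group_total.
#' @export
decomp_table <- function(x) {
  stopifnot(inherits(x, "ci_decomp"))
  f3 <- function(v) ifelse(is.na(v), "",
                           formatC(round_half_up(v, 3), format = "f", digits = 3))
  f1 <- function(v) ifelse(is.na(v), "",
                           formatC(round_half_up(v, 1), format = "f", digits = 1))
  r <- x$rows
  last <- !duplicated(r$factor, fromLast = TRUE)
  tab <- data.frame(factor = r$factor, category = r$category,
                    elasticity = f3(r$elasticity), ci = f3(r$ci_k),
                    absolute = f3(r$absolute), pct = f1(r$pct),
                    group_total = ifelse(last, f1(x$group_totals[r$factor]), ""),
                    stringsAsFactors = FALSE)
  foot <- data.frame(factor = c("Calculated CI", "Actual CI", "Residual"),
                     category = "",
                     elasticity = "", ci = "",
                     absolute = f3(c(x$calculated_ci, x$actual_ci, x$residual)),
                     pct = c("100.0", "", ""), group_total = "",
                     stringsAsFactors = FALSE)
  rbind(tab, foot)
}

#' @export
print.ci_decomp <- function(x, ...) {
  side <- if (x$actual_ci < 0) "concentrated among the poor"
          else "concentrated among the rich"
  cat("Decomposition of the concentration index\n")
  cat("Outcome: ", x$outcome, "   n = ", x$n,
      "   engine = ", x$engine, "\n", sep = "")
  cat("Actual CI = ", format(round_half_up(x$actual_ci, 3), nsmall = 3),
      " (", side, ")\n\n", sep = "")
  print(decomp_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ci_decomp <- function(object, ...) {
  out <- list(outcome = object$outcome, n = object$n, mu = object$mu,
              engine = object$engine,
              actual_ci = object$actual_ci,
              calculated_ci = object$calculated_ci,
              residual = object$residual,
              explained_share = object$calculated_ci / object$actual_ci * 100,
              identity_gap = object$calculated_ci + object$residual -
                object$actual_ci,
              group_totals = object$group_totals)
  class(out) <- "summary.ci_decomp"
  out
}

#' @export
print.summary.ci_decomp <- function(x, ...) {
  cat("Concentration-index decomposition of '", x$outcome, "' (n = ", x$n,
      ", mean = ", signif(x$mu, 3), ", engine = ", x$engine, ")\n", sep = "")
  cat(sprintf("  Actual CI     %8.4f\n  Calculated CI %8.4f (%.1f%% explained)\n  Residual      %8.4f\n",
              x$actual_ci, x$calculated_ci, x$explained_share, x$residual))
  cat(sprintf("  Adding-up gap |C_calc + resid - C| = %.2e\n", abs(x$identity_gap)))
  cat("  Per-factor % of explained CI:\n")
  gt <- round_half_up(x$group_totals, 1)
  for (nm in names(gt)) cat(sprintf("    %-12s %6.1f\n", nm, gt[nm]))
  invisible(x)
}

#' @export
coef.ci_decomp <- function(object, ...) {
  c("(Intercept)" = object$fit$alpha, object$fit$betas)
}

#' @export
residuals.ci_decomp <- function(object, ...) object$fit$residuals

#' @export
fitted.ci_decomp <- function(object, ...) object$fit$fitted

#' Predict from a fitted decomposition model
#'
#' Linear-probability predictions \eqn{\alpha + \sum_k \beta_k x_k} for new
#' records (may leave \[0, 1\]).
#'
#' @param object A `"ci_decomp"` object.
#' @param newdata Data frame with the model's factor columns; defaults to
#'   returning fitted values.
#' @param ... Unused.
#' @export
predict.ci_decomp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fit$fitted)
  X <- build_design(newdata, object$specs)
  unname(object$fit$alpha + drop(X %*% object$fit$betas))
}

#' Simulate outcomes from a fitted decomposition model
#'
#' Draws Bernoulli outcomes from the linear-probability fitted means
#' (clipped to \[0, 1\]) for the records the model was fitted on.
#'
#' @param object A `"ci_decomp"` object.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @param ... Unused.
#' @return A data.frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.ci_decomp <- function(object, nsim = 1, seed = NULL, ...) {
  p <- pmin(pmax(object$fit$fitted, 0), 1)
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Plot a decomposition
#'
#' Horizontal bar chart of per-factor percentage contributions to the
#' explained concentration index.
#'
#' @param x A `"ci_decomp"` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ci_decomp <- function(x, ...) {
  gt <- rev(x$group_totals)
  graphics::barplot(gt, horiz = TRUE, las = 1,
                    xlab = "% of explained concentration index",
                    main = paste("Decomposition:", x$outcome), ...)
  graphics::abline(v = 0)
  invisible(x)
}
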
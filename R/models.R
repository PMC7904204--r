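#' Factor specification with an explicit reference category
#'
#' Association and decomposition tables present categorical covariates as
#' dummy sets against a named reference category.  A `factor_spec` fixes
#' the category order and the reference (first category by default), so
#' design matrices and table layouts are deterministic.
#'
#' @param name Column name in the data.
#' @param categories Character vector of allowed categories, in display
#'   order.
#' @param reference Reference category; defaults to the first.
#' @return An object of class `"factor_spec"`.
#' @export
factor_spec <- function(name, categories, reference = categories[1]) {
  categories <- as.character(categories)
  if (length(categories) < 2L)
    stop("factor '", name, "' needs at least 2 categories")
  if (anyDuplicated(categories))
    stop("factor '", name, "' has duplicate categories")
  if (!reference %in% categories)
    stop("reference '", reference, "' is not a category of '", name, "'")
  structure(list(name = name,
                 categories = c(reference, setdiff(categories, reference)),
                 reference = reference),
            class = "factor_spec")
}

# Derive specs from the data: factor columns keep their level order,
# character columns use order of first appearance.
specs_from_data <- function(data, vars) {
  lapply(vars, function(v) {
    if (!v %in% names(data)) stop("column '", v, "' not found in data")
    x <- data[[v]]
    lev <- if (is.factor(x)) levels(x)
           else if (is.numeric(x)) as.character(sort(unique(x[!is.na(x)])))
           else unique(as.character(x[!is.na(x)]))
    factor_spec(v, lev)
  })
}

#' Dummy-coded design matrix from factor specifications
#'
#' One indicator column per non-reference category, labelled
#' `name:category`, in specification order.  Rows whose category is the
#' reference are all-zero within that factor.  A category absent from the
#' spec is an error.
#'
#' @param data A data.frame holding the factor columns.
#' @param specs A list of [factor_spec()] objects (or a character vector of
#'   column names, in which case specs are derived from the data).
#' @return A numeric matrix with attributes `labels` (column labels) and
#'   `factor` (the factor each column belongs to).
#' @export
build_design <- function(data, specs) {
  if (is.character(specs)) specs <- specs_from_data(data, specs)
  cols <- list(); fac <- character(0)
  for (sp in specs) {
    x <- as.character(data[[sp$name]])
    bad <- setdiff(unique(x[!is.na(x)]), sp$categories)
    if (length(bad))
      stop("factor '", sp$name, "' has unseen categor",
           if (length(bad) > 1) "ies: " else "y: ",
           paste(bad, collapse = ", "))
    for (cat in sp$categories[-1L]) {
      cols[[paste0(sp$name, ":", cat)]] <- as.numeric(x == cat)
      fac <- c(fac, sp$name)
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "factor") <- fac
  attr(X, "specs") <- specs
  X
}

#' Weighted linear probability model (OLS)
#'
#' Ordinary least squares of a (typically binary) outcome on a dummy
#' design, with an intercept.  The fit's weighted residuals are exactly
#' orthogonal to the intercept and every column — the property that makes
#' the concentration-index decomposition identity exact.  Fitted values
#' may leave \[0, 1\]; that is inherent to the linear probability model.
#'
#' @param y Outcome vector.
#' @param X Design matrix (no intercept column; one is added).
#' @param weights Optional positive weights.
#' @return A list of class `"lpm_fit"`: `alpha` (intercept), `betas`
#'   (named coefficients), `fitted`, `residuals`, `xbar` (weighted column
#'   means), `mu` (weighted outcome mean), `weights`.
#' @export
fit_lpm <- function(y, X, weights = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("y and X have incompatible dimensions")
  w <- check_weights(weights, n)
  Xi <- cbind("(Intercept)" = 1, X)
  fit <- stats::lm.wfit(Xi, y, w)
  if (fit$rank < ncol(Xi)) {
    bad <- colnames(Xi)[is.na(fit$coefficients)]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  co <- fit$coefficients
  structure(list(alpha = unname(co[1L]), betas = co[-1L],
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals),
                 xbar = apply(X, 2L, wmean, w = w),
                 mu = wmean(y, w), weights = w, kind = "linear"),
            class = "lpm_fit")
}

#' Logistic regression odds-ratio table
#'
#' Maximum-likelihood logistic fit of a binary outcome on a dummy design,
#' reported as odds ratios with 95% Wald confidence intervals
#' (`exp(beta +/- 1.96 SE)`), the conventional "OR (95% CI)" presentation.
#' Perfect separation is detected and reported with the offending column.
#'
#' @param y Binary outcome vector (0/1).
#' @param X Design matrix from [build_design()].
#' @param weights Optional positive weights (treated as frequency-style
#'   weights in the likelihood).
#' @return A list of class `"logit_fit"` with `coefficients`, `vcov`, and
#'   `table`: a data.frame (term, factor, or, ci_low, ci_high, beta, se).
#' @export
fit_logistic <- function(y, X, weights = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  w <- check_weights(weights, n)
  const <- apply(X, 2L, function(c) diff(range(c)) == 0)
  if (any(const))
    stop("constant design column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(), weights = w),
    warning = function(cnd) {
      if (grepl("non-integer|fitted probabilities numerically 0 or 1",
                conditionMessage(cnd)))
        invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)[-1L]
  if (!fit$converged || any(abs(co) > 15)) {
    worst <- names(co)[which.max(abs(co))]
    stop("logistic fit did not identify all effects (possible perfect ",
         "separation); suspect column: ", worst)
  }
  se <- sqrt(diag(stats::vcov(fit)))[-1L]
  fac <- attr(X, "factor")
  tab <- data.frame(term = names(co),
                    factor = if (is.null(fac)) NA_character_ else fac,
                    or = exp(co),
                    ci_low = exp(co - 1.96 * se),
                    ci_high = exp(co + 1.96 * se),
                    beta = co, se = se, row.names = NULL)
  structure(list(coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                 table = tab, glm = fit, kind = "logistic"),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  tab <- x$table
  cat("Logistic regression (odds ratios, 95% Wald CI)\n")
  out <- data.frame(term = tab$term,
                    `OR (95% CI)` = sprintf("%.2f (%.2f, %.2f)", tab$or,
                                            tab$ci_low, tab$ci_high),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Adjusted odds-ratio table for categorical covariates
#'
#' Fits one multivariable logistic model of `outcome` on all factors and
#' returns the per-category odds-ratio table with reference rows included
#' (marked `"Ref."`), mirroring the layout of published association
#' tables.
#'
#' @param data Data frame of records.
#' @param outcome Name of the binary outcome column; missing values are
#'   dropped (complete-case).
#' @param factors Character vector of factor column names, or a list of
#'   [factor_spec()].
#' @param weights Optional name of a weight column.
#' @return A data.frame with columns factor, category, or, ci_low, ci_high
#'   (`NA` and label `"Ref."` for reference rows).
#' @export
odds_ratio_table <- function(data, outcome, factors, weights = NULL) {
  if (!outcome %in% names(data)) stop("outcome column '", outcome, "' not found")
  specs <- if (is.character(factors)) specs_from_data(data, factors) else factors
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  keep <- !is.na(data[[outcome]]) &
    Reduce(`&`, lapply(specs, function(s) !is.na(data[[s$name]])))
  data <- data[keep, , drop = FALSE]; w <- w[keep]
  X <- build_design(data, specs)
  fit <- fit_logistic(data[[outcome]], X, w)
  rows <- do.call(rbind, lapply(specs, function(sp) {
    ref <- data.frame(factor = sp$name, category = sp$reference,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      label = "Ref.")
    est <- fit$table[fit$table$factor == sp$name, , drop = FALSE]
    est <- data.frame(factor = sp$name,
                      category = sub("^[^:]*:", "", est$term),
                      or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
                      label = sprintf("%.2f (%.2f, %.2f)", est$or,
                                      est$ci_low, est$ci_high))
    rbind(ref, est)
  }))
  rownames(rows) <- NULL
  attr(rows, "n") <- nrow(data)
  rows
}
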
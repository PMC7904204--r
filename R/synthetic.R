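# Default covariate layer for the synthetic survey: categories and
# marginal proportions loosely follow the socio-demographic profile of a
# large adolescent survey in two north-Indian states; wealth_coefs are
# per-category log-odds slopes on (rank - 0.5) creating the
# covariate-wealth correlation, and z_bmi / z_haz are additive latent
# effects (SD units) relative to each factor's first (reference) category.
default_covariate_specs <- function() {
  spec <- function(name, categories, base_props, wealth_coefs, z_bmi, z_haz)
    list(name = name, categories = categories, base_props = base_props,
         wealth_coefs = wealth_coefs, z_bmi = z_bmi, z_haz = z_haz)
  list(
    spec("age_group", c("early", "late"), c(0.18, 0.82), c(0, 0),
         c(0, 0.15), c(0, -0.30)),
    spec("education", c("no_schooling", "y1_7", "y8_9", "y10plus"),
         c(0.10, 0.31, 0.28, 0.31), c(0, 1.2, 2.0, 3.0),
         c(0, -0.05, 0.10, 0.30), c(0, 0.10, 0.05, 0.15)),
    spec("working", c("no", "yes"), c(0.79, 0.21), c(0, -0.5),
         c(0, 0.05), c(0, -0.15)),
    spec("media", c("no_exposure", "rare", "frequent"),
         c(0.15, 0.26, 0.59), c(0, 0.5, 2.0),
         c(0, -0.05, 0.15), c(0, 0, 0.10)),
    spec("caste", c("sc_st", "non_sc_st"), c(0.26, 0.74), c(0, 0.8),
         c(0, 0.15), c(0, 0.20)),
    spec("religion", c("hindu", "non_hindu"), c(0.80, 0.20), c(0, 0.3),
         c(0, 0), c(0, 0.05)),
    spec("residence", c("urban", "rural"), c(0.165, 0.835), c(0, -1.5),
         c(0, -0.20), c(0, -0.10)),
    spec("state", c("uttar_pradesh", "bihar"), c(0.675, 0.325), c(0, -0.3),
         c(0, 0.05), c(0, 0.10))
  )
}

#' Configuration for the synthetic survey generator
#'
#' Bundles and validates all knobs of [generate_population()].  Defaults
#' mirror the scale and structure of a large cross-sectional adolescent
#' survey: about 20.6k records, roughly 29% boys, thinness more prevalent
#' among boys (25.8% vs 13.1%) and stunting among girls (39.3% vs 25.6%),
#' a continuous standard-normal wealth score, and covariates whose
#' distribution shifts with wealth rank so that undernutrition
#' concentrates among the poor.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed; identical configs give identical tables.
#' @param sex_ratio Proportion of boys, in \[0, 1\].
#' @param prevalence_targets Named list `list(boy = c(thinness =, stunting =),
#'   girl = ...)` of target prevalences, each in (0, 1).
#' @param gradient_strength Scale of the whole socioeconomic gradient: it
#'   multiplies both the direct wealth-rank effect on the latent z-scores
#'   and the covariate-wealth dependence.  0 switches off all SES
#'   structure (outcome concentration indices are then 0 in expectation);
#'   the default 1 yields outcome concentration indices of roughly -0.04
#'   to -0.25.
#' @param covariate_specs Covariate layer; see the package source for the
#'   default structure (name, categories, base_props, wealth_coefs, z_bmi,
#'   z_haz per factor).
#' @param weight_scheme `"equal"` (all weights 1) or `"variable"`
#'   (log-normal sampling weights).
#' @param tie_fraction Fraction of records given a wealth score duplicated
#'   from another record, to exercise tie handling in ranking; default 0.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n = 20594, seed = 1, sex_ratio = 0.29,
                       prevalence_targets = list(
                         boy = c(thinness = 0.258, stunting = 0.256),
                         girl = c(thinness = 0.131, stunting = 0.393)),
                       gradient_strength = 1,
                       covariate_specs = default_covariate_specs(),
                       weight_scheme = c("equal", "variable"),
                       tie_fraction = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  pt <- unlist(prevalence_targets)
  if (any(pt <= 0) || any(pt >= 1))
    stop("all prevalence targets must lie strictly in (0, 1)")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]")
  if (tie_fraction < 0 || tie_fraction >= 1)
    stop("tie_fraction must lie in [0, 1)")
  structure(list(n = as.integer(n), seed = seed, sex_ratio = sex_ratio,
                 prevalence_targets = prevalence_targets,
                 gradient_strength = gradient_strength,
                 covariate_specs = covariate_specs,
                 weight_scheme = match.arg(weight_scheme),
                 tie_fraction = tie_fraction),
            class = "sim_config")
}

# sample one category per row from a matrix of per-row probabilities
sample_categories <- function(P, categories) {
  cp <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
  u <- stats::runif(nrow(P))
  categories[rowSums(u > cp) + 1L]
}

#' Generate a synthetic survey population
#'
#' Draws a survey-like table of adolescent records with a continuous
#' wealth score, wealth-correlated categorical covariates, latent
#' BMI-for-age and height-for-age z-scores linear in wealth rank and
#' covariate dummies (plus a shared individual factor inducing
#' co-existence of thinness and stunting), and outcome flags derived from
#' the z-scores by the standard cut-offs.  Per-sex z-score locations are
#' calibrated so the target prevalences are achieved.
#'
#' @param config A [sim_config()].
#' @return A data.frame with one row per record: id, sex, the covariate
#'   columns, wealth_score, wealth_quintile, weight, z_bmi_age,
#'   z_height_age, thinness, stunting, both.
#' @examples
#' pop <- generate_population(sim_config(n = 500, seed = 42))
#' mean(pop$thinness[pop$sex == "boy"])
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n
    g <- config$gradient_strength
    nb <- round(n * config$sex_ratio)
    sex <- rep(c("boy", "girl"), c(nb, n - nb))

    wealth <- stats::rnorm(n)
    if (config$tie_fraction > 0) {
      m <- 2L * floor(config$tie_fraction * n / 2)
      if (m >= 2L) {
        idx <- sample.int(n, m)
        wealth[idx[seq(2L, m, 2L)]] <- wealth[idx[seq(1L, m, 2L)]]
      }
    }
    w <- if (config$weight_scheme == "variable")
      exp(stats::rnorm(n, 0, 0.25)) else rep(1, n)
    r <- fractional_rank(wealth, w)
    quintile <- findInterval(r, c(0.2, 0.4, 0.6, 0.8)) + 1L

    covs <- list()
    zx_bmi <- zx_haz <- numeric(n)
    for (sp in config$covariate_specs) {
      logits <- outer(g * (r - 0.5), sp$wealth_coefs) +
        rep(log(sp$base_props), each = n)
      P <- exp(logits) / rowSums(exp(logits))
      cat_i <- sample_categories(P, sp$categories)
      covs[[sp$name]] <- factor(cat_i, levels = sp$categories)
      ci <- match(cat_i, sp$categories)
      zx_bmi <- zx_bmi + sp$z_bmi[ci]
      zx_haz <- zx_haz + sp$z_haz[ci]
    }

    common <- stats::rnorm(n, 0, 0.6)     # shared frailty -> co-existence
    lat_bmi <- 0.8 * g * (r - 0.5) + zx_bmi + common + stats::rnorm(n, 0, 0.8)
    lat_haz <- 0.8 * g * (r - 0.5) + zx_haz + common + stats::rnorm(n, 0, 0.8)

    z_bmi <- z_haz <- numeric(n)
    for (s in c("boy", "girl")) {
      i <- sex == s
      tgt <- config$prevalence_targets[[s]]
      # place the target quantile of the latent at the -2 SD cut-off
      z_bmi[i] <- lat_bmi[i] -
        stats::quantile(lat_bmi[i], tgt[["thinness"]], names = FALSE) - 2
      z_haz[i] <- lat_haz[i] -
        stats::quantile(lat_haz[i], tgt[["stunting"]], names = FALSE) - 2
    }
    flags <- classify_nutrition(z_bmi, z_haz)

    out <- data.frame(id = seq_len(n), sex = sex,
                      as.data.frame(covs, stringsAsFactors = FALSE),
                      wealth_score = wealth, wealth_quintile = quintile,
                      weight = w, z_bmi_age = z_bmi, z_height_age = z_haz,
                      thinness = flags$thinness, stunting = flags$stunting,
                      both = flags$both, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate a population with an exact linear-probability outcome
#'
#' Draws records whose binary outcome satisfies
#' \eqn{E[y \mid x] = \alpha + \sum_k \beta_k x_k} (clipped to \[0, 1\])
#' for user-specified covariates, so the decomposition's per-covariate
#' contributions have a known ground truth for parameter-recovery tests.
#'
#' @param alpha Intercept of the linear probability model, in \[0, 1\].
#' @param betas Named numeric vector of coefficients, one per covariate in
#'   `covariate_dists`.
#' @param covariate_dists Named list of covariate generators, each a list
#'   with `kind = "rank_gt"` (indicator of wealth rank above `threshold`)
#'   or `kind = "bernoulli"` (probability `p`, optionally shifted on the
#'   logit scale by `slope * (rank - 0.5)`).
#' @param n Number of records.
#' @param seed Integer seed.
#' @param weights Optional positive weights (default equal).
#' @return A data.frame (id, wealth_score, weight, covariate columns,
#'   outcome) with attributes `ground_truth` (a data.frame of the
#'   generator's per-covariate absolute and percentage contributions,
#'   computed from the true coefficients and the realized covariates) and
#'   `clip_rate`.  A clip rate above 10% raises a warning; above 50% (or
#'   an `alpha` outside \[0, 1\]) is an error.
#' @export
generate_lpm_population <- function(alpha, betas, covariate_dists, n, seed,
                                    weights = NULL) {
  if (alpha < 0 || alpha > 1)
    stop("infeasible model: alpha must lie in [0, 1]")
  if (is.null(names(betas))) names(betas) <- names(covariate_dists)
  if (!setequal(names(betas), names(covariate_dists)))
    stop("betas and covariate_dists must use the same names")
  with_seed(seed, {
    wealth <- stats::rnorm(n)
    w <- check_weights(weights, n)
    r <- fractional_rank(wealth, w)
    X <- sapply(names(covariate_dists), function(nm) {
      d <- covariate_dists[[nm]]
      switch(d$kind,
             rank_gt = as.numeric(r > d$threshold),
             bernoulli = stats::rbinom(n, 1L, stats::plogis(
               stats::qlogis(d$p) +
                 (if (is.null(d$slope)) 0 else d$slope) * (r - 0.5))),
             stop("unknown covariate kind '", d$kind, "'"))
    })
    pr <- alpha + drop(X %*% betas[colnames(X)])
    clip_rate <- mean(pr < 0 | pr > 1)
    if (clip_rate > 0.5)
      stop("infeasible probabilities: ", round(100 * clip_rate),
           "% of records outside [0, 1]")
    if (clip_rate > 0.1)
      warning("linear probability model clipped for ",
              round(100 * clip_rate, 1), "% of records")
    p <- pmin(pmax(pr, 0), 1)
    y <- stats::rbinom(n, 1L, p)

    mu_true <- wmean(p, w)
    absolute <- vapply(colnames(X), function(nm)
      2 * betas[[nm]] * wcov(X[, nm], r, w) / mu_true, numeric(1))
    truth <- data.frame(covariate = colnames(X),
                        beta = unname(betas[colnames(X)]),
                        xbar = apply(X, 2L, wmean, w = w),
                        ci_k = apply(X, 2L, function(x)
                          if (mean(x) > 0) 2 * wcov(x, r, w) / wmean(x, w)
                          else NA_real_),
                        absolute = unname(absolute),
                        pct = unname(absolute / sum(absolute) * 100),
                        row.names = NULL)
    out <- data.frame(id = seq_len(n), wealth_score = wealth, weight = w,
                      X, outcome = y)
    attr(out, "ground_truth") <- truth
    attr(out, "clip_rate") <- clip_rate
    out
  })
}

#' Small synthetic LMS reference fixture
#'
#' A compact growth-reference table (2 sexes x 5 ages x 2 indicators) with
#' synthetic but plausibly scaled L, M, S values, including an L = 0 row
#' to exercise the logarithmic z-score branch.  Intended for tests and
#' examples; it is not a WHO reference.
#'
#' @return A validated data.frame with columns sex, age_months, indicator,
#'   L, M, S.
#' @export
make_lms_fixture <- function() {
  ages <- c(120L, 126L, 132L, 138L, 144L)
  grid <- expand.grid(sex = c("boy", "girl"), age_months = ages,
                      indicator = c("bmi_age", "height_age"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sex, grid$indicator, grid$age_months), ]
  f <- function(sex, ind, age) {
    i <- match(age, ages)
    if (ind == "bmi_age") {
      L <- c(-1.6, -1.7, 1.0, 0.0, -1.9)[i]       # includes L = 0 and L = 1
      M <- (if (sex == "boy") 15.6 else 15.4) + 0.2 * (i - 1)
      S <- 0.095 + 0.0025 * (i - 1)
    } else {
      L <- 1.0
      M <- (if (sex == "boy") 137.0 else 138.0) + 1.5 * (i - 1)
      S <- 0.044
    }
    c(L, M, S)
  }
  lms <- t(mapply(f, grid$sex, grid$indicator, grid$age_months))
  grid$L <- unname(lms[, 1]); grid$M <- unname(lms[, 2])
  grid$S <- unname(lms[, 3])
  rownames(grid) <- NULL
  validate_reference(grid)
  grid
}
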
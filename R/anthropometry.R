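#' Body mass index
#'
#' @param weight_kg Weight in kilograms (positive).
#' @param height_cm Height in centimetres (positive).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(50, 160)  # 19.53125
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (anyNA(weight_kg) || anyNA(height_cm))
    stop("weight and height must be non-missing")
  if (any(weight_kg <= 0)) stop("weight_kg must be positive")
  if (any(height_cm <= 0)) stop("height_cm must be positive")
  weight_kg / (height_cm / 100)^2
}

#' LMS growth-reference z-score
#'
#' Standardizes a measurement against an age- and sex-specific growth
#' reference summarized by the Box-Cox power `L`, median `M` and
#' coefficient of variation `S`:
#' \deqn{z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
#'       z = \frac{\ln(x/M)}{S} \quad (L = 0).}
#' The two branches join continuously at L = 0.
#'
#' @param x Measured value (positive), e.g. BMI or height.
#' @param L Box-Cox power.
#' @param M Reference median (positive).
#' @param S Reference coefficient of variation (positive).
#' @return z-score in SD units.  All arguments recycle to a common length.
#' @examples
#' lms_zscore(110, 1, 100, 0.1)          # 1
#' lms_zscore(16 * exp(0.2), 0, 16, 0.1) # 2
#' @export
lms_zscore <- function(x, L, M, S) {
  k <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, k); L <- rep_len(L, k)
  M <- rep_len(M, k); S <- rep_len(S, k)
  if (anyNA(c(x, L, M, S))) stop("LMS inputs must be non-missing")
  if (any(x <= 0)) stop("measurement x must be positive")
  if (any(M <= 0) || any(S <= 0)) stop("M and S must be positive")
  z <- numeric(k)
  log0 <- L == 0
  z[log0] <- log(x[log0] / M[log0]) / S[log0]
  z[!log0] <- ((x[!log0] / M[!log0])^L[!log0] - 1) / (L[!log0] * S[!log0])
  z
}

ref_cols <- c("sex", "age_months", "indicator", "L", "M", "S")

validate_reference <- function(ref) {
  miss <- setdiff(ref_cols, names(ref))
  if (length(miss))
    stop("growth reference is missing column(s): ", paste(miss, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0))
    stop("growth reference requires M > 0 and S > 0")
  key <- paste(ref$sex, ref$age_months, ref$indicator)
  if (anyDuplicated(key))
    stop("growth reference has duplicate (sex, age_months, indicator) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  invisible(ref)
}

#' Read a growth-reference table from CSV
#'
#' The file must have columns `sex`, `age_months`, `indicator` (one of
#' `bmi_age`, `height_age`), `L`, `M`, `S`, one row per (sex, age,
#' indicator) key.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame of reference rows.
#' @export
load_growth_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_reference(ref)
  ref
}

#' Look up (or interpolate) LMS parameters
#'
#' Returns the L, M, S parameters for a given sex, age and indicator.
#' Exact-age rows are returned as stored; ages between two tabulated ages
#' are linearly interpolated in each of L, M and S.  Ages outside the
#' tabulated range are an error naming the available bounds.
#'
#' @param ref Reference table (see [load_growth_reference()]).
#' @param sex Sex code matching the table's `sex` column.
#' @param age_months Age in completed months.
#' @param indicator `"bmi_age"` or `"height_age"`.
#' @return Named numeric vector `c(L =, M =, S =)`.
#' @export
lookup_reference <- function(ref, sex, age_months, indicator) {
  validate_reference(ref)
  sub <- ref[ref$sex == sex & ref$indicator == indicator, , drop = FALSE]
  if (!nrow(sub))
    stop("no reference rows for sex '", sex, "', indicator '", indicator, "'")
  sub <- sub[order(sub$age_months), , drop = FALSE]
  ages <- sub$age_months
  if (age_months < min(ages) || age_months > max(ages))
    stop("age ", age_months, " months outside reference range [",
         min(ages), ", ", max(ages), "] for sex '", sex,
         "', indicator '", indicator, "'")
  i <- findInterval(age_months, ages)
  if (ages[i] == age_months)
    return(c(L = sub$L[i], M = sub$M[i], S = sub$S[i]))
  f <- (age_months - ages[i]) / (ages[i + 1] - ages[i])
  c(L = (1 - f) * sub$L[i] + f * sub$L[i + 1],
    M = (1 - f) * sub$M[i] + f * sub$M[i + 1],
    S = (1 - f) * sub$S[i] + f * sub$S[i + 1])
}

#' Classify thinness, stunting and their co-existence
#'
#' Applies the WHO-style cut-offs used for adolescents: thinness is a
#' BMI-for-age z-score strictly below -2 SD; stunting is a height-for-age
#' z-score at or below -2 SD (note the asymmetric boundary: exactly -2 is
#' stunted but not thin); co-existence requires both.  Missing z-scores
#' propagate to missing flags so the records drop out of downstream
#' denominators.
#'
#' @param z_bmi BMI-for-age z-score vector.
#' @param z_haz Height-for-age z-score vector.
#' @param flag_implausible Absolute z beyond which a value is flagged
#'   biologically implausible (default 5); flagged records keep their
#'   classification but are marked in the `implausible` column.
#' @return A data.frame with integer columns `thinness`, `stunting`,
#'   `both` (0/1/NA) and logical `implausible`.
#' @examples
#' classify_nutrition(-2, -2)      # not thin, stunted, not both
#' classify_nutrition(-2.5, -2.5)  # all three
#' @export
classify_nutrition <- function(z_bmi, z_haz, flag_implausible = 5) {
  k <- max(length(z_bmi), length(z_haz))
  z_bmi <- rep_len(z_bmi, k); z_haz <- rep_len(z_haz, k)
  thin <- ifelse(is.na(z_bmi), NA_integer_, as.integer(z_bmi < -2))
  stunt <- ifelse(is.na(z_haz), NA_integer_, as.integer(z_haz <= -2))
  both <- thin * stunt
  data.frame(thinness = thin, stunting = stunt, both = both,
             implausible = (!is.na(z_bmi) & abs(z_bmi) > flag_implausible) |
                           (!is.na(z_haz) & abs(z_haz) > flag_implausible))
}

#' Completed age in months from age in years
#'
#' Surveys often record age only in whole or fractional years; references
#' are tabulated by month.  This maps years to completed months via
#' `floor(age_years * 365.25 / 30.4375)` (= `floor(12 * age_years)` for the
#' average month length used by growth standards).
#'
#' @param age_years Age in years.
#' @return Integer completed months.
#' @export
age_to_months <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) stop("age must be non-negative")
  as.integer(floor(age_years * 365.25 / 30.4375))
}
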
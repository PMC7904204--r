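#' Socio-demographic sample profile
#'
#' Per-category counts and percentages of the column total for each
#' stratifier, optionally split by a grouping column (conventionally sex),
#' with a Total row per group.  Percentages are at 1 decimal, half away
#' from zero.
#'
#' @param data Data frame of records (non-empty).
#' @param factors Character vector of stratifier column names.
#' @param by Optional grouping column (default `"sex"`; use `NULL` for a
#'   single overall column).
#' @return A data.frame with columns stratifier, category, group, n, pct.
#' @export
sample_profile <- function(data, factors, by = "sex") {
  if (!nrow(data)) stop("empty table")
  groups <- if (is.null(by)) list(all = data) else split(data, data[[by]])
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    d <- groups[[gname]]
    rows <- do.call(rbind, lapply(factors, function(v) {
      if (!v %in% names(d)) stop("column '", v, "' not found in data")
      tab <- table(d[[v]])
      data.frame(stratifier = v, category = names(tab), group = gname,
                 n = as.integer(tab),
                 pct = round_half_up(as.integer(tab) / nrow(d) * 100, 1),
                 stringsAsFactors = FALSE)
    }))
    rbind(rows, data.frame(stratifier = "Total", category = "Total",
                           group = gname, n = nrow(d), pct = 100.0,
                           stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

stratified_stat <- function(data, value_col, factors, weights, by, stat,
                            digits) {
  if (!value_col %in% names(data))
    stop("column '", value_col, "' not found in data")
  w_all <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  groups <- if (is.null(by)) list(all = seq_len(nrow(data)))
            else split(seq_len(nrow(data)), data[[by]])
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    gi <- groups[[gname]]
    do.call(rbind, lapply(c(factors, ".total"), function(v) {
      cats <- if (v == ".total") list(Total = gi)
              else split(gi, data[[v]][gi])
      do.call(rbind, lapply(names(cats), function(cat) {
        i <- cats[[cat]]
        ok <- i[!is.na(data[[value_col]][i])]
        val <- if (length(ok) == 0L) NA_real_ else
          round_half_up(stat(data[[value_col]][ok], w_all[ok]), digits)
        data.frame(stratifier = if (v == ".total") "Total" else v,
                   category = cat, group = gname, denominator = length(ok),
                   value = val, flagged = length(ok) == 0L,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Outcome prevalence by strata
#'
#' Weighted prevalence (in percent, 1 decimal) of a binary outcome within
#' each category of each stratifier, split by group.  Records with a
#' missing outcome are excluded and the remaining denominator reported;
#' empty cells are flagged rather than shown as zero.
#'
#' @param data Data frame of records.
#' @param outcome Binary outcome column name (NA allowed).
#' @param factors Stratifier column names.
#' @param weights Optional weight column name.
#' @param by Grouping column (default `"sex"`).
#' @return A data.frame with columns stratifier, category, group,
#'   denominator, value (prevalence %), flagged.
#' @export
prevalence_by_strata <- function(data, outcome, factors, weights = NULL,
                                 by = "sex") {
  stratified_stat(data, outcome, factors, weights, by,
                  function(x, w) 100 * wmean(x, w), 1)
}

#' Mean z-score by strata
#'
#' Weighted mean of a z-score column (2 decimals) within each category of
#' each stratifier, split by group; same missing-data and empty-cell
#' handling as [prevalence_by_strata()].
#'
#' @inheritParams prevalence_by_strata
#' @param z_column z-score column name.
#' @return A data.frame with columns stratifier, category, group,
#'   denominator, value (mean z), flagged.
#' @export
meanz_by_strata <- function(data, z_column, factors, weights = NULL,
                            by = "sex") {
  stratified_stat(data, z_column, factors, weights, by, wmean, 2)
}

#' Run the full descriptive and decomposition report
#'
#' Orchestrates the study's output bundle on one dataset: a
#' socio-demographic profile, prevalence tables for each outcome, mean
#' z-score tables for each z column, one concentration-index decomposition
#' per sex and outcome, and concentration-curve coordinates.  The bundle
#' is deterministic in the input data and a manifest lists every table
#' with its row count.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{data}{data.frame of records (e.g. [generate_population()]).}
#'     \item{factors}{stratifier / covariate column names.}
#'     \item{outcomes}{binary outcome column names (default thinness,
#'       stunting, both).}
#'     \item{z_columns}{z-score column names (default z_bmi_age,
#'       z_height_age).}
#'     \item{score}{wealth score column (default wealth_score).}
#'     \item{weights}{optional weight column name.}
#'     \item{by}{grouping column (default sex).}
#'   }
#' @param out_dir Optional directory; when given, every table (and the
#'   manifest) is written as a CSV file there.
#' @param verbose Log progress and per-stage record counts to stderr.
#' @return A list with `tables` (named list of data.frames), `curves`
#'   (long data.frame of concentration-curve coordinates) and `manifest`.
#' @export
run_report <- function(config, out_dir = NULL, verbose = FALSE) {
  data <- config$data
  if (is.null(data) || !nrow(data)) stop("report stage 'input': no data")
  factors <- config$factors
  outcomes <- config$outcomes %||% c("thinness", "stunting", "both")
  zcols <- config$z_columns %||% c("z_bmi_age", "z_height_age")
  score <- config$score %||% "wealth_score"
  by <- config$by %||% "sex"
  wcol <- config$weights
  say <- function(...) if (verbose) message(...)
  miss <- setdiff(c(factors, outcomes, zcols, score, by), names(data))
  if (length(miss))
    stop("report stage 'input': missing column(s): ",
         paste(miss, collapse = ", "))

  tables <- list()
  say("profile: n = ", nrow(data))
  tables$profile <- sample_profile(data, factors, by)
  for (oc in outcomes) {
    say("prevalence (", oc, "): non-missing n = ", sum(!is.na(data[[oc]])))
    tables[[paste0("prevalence_", oc)]] <-
      prevalence_by_strata(data, oc, factors, wcol, by)
  }
  for (z in zcols) {
    tables[[paste0("meanz_", z)]] <- meanz_by_strata(data, z, factors, wcol, by)
  }

  curves <- NULL
  groups <- split(data, data[[by]])
  for (gname in names(groups)) {
    d <- groups[[gname]]
    for (oc in outcomes) {
      key <- paste0("decomp_", oc, "_", gname)
      res <- tryCatch(
        ci_decomp(stats::as.formula(paste(oc, "~",
                                          paste(factors, collapse = "+"))),
                  d, score = score, weights = wcol),
        error = function(e)
          stop("report stage 'decomposition (", key, ")': ",
               conditionMessage(e)))
      say(key, ": n = ", res$n, ", actual CI = ",
          round_half_up(res$actual_ci, 3))
      tables[[key]] <- decomp_table(res)
      keep <- !is.na(d[[oc]]) & !is.na(d[[score]])
      cc <- concentration_curve(d[[oc]][keep], d[[score]][keep],
                                if (is.null(wcol)) NULL else d[[wcol]][keep])
      curves <- rbind(curves, data.frame(group = gname, outcome = oc, cc))
    }
  }

  manifest <- data.frame(output = names(tables),
                         rows = vapply(tables, nrow, integer(1)),
                         row.names = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(tables = tables, curves = curves, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
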
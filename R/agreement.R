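# Agreement statistics between predicted and reference ablation areas:
# per-level linear regression, Bland-Altman analysis, best-level selection.

#' Paired area records
#'
#' Builds and validates the table of paired predicted (`a_ire_mm2`) and
#' reference (`a_he_mm2`) ablation areas at given death-probability levels.
#'
#' @param case_id Case labels.
#' @param p Death-probability level of each record, in `(0, 1)`.
#' @param a_ire_mm2 Predicted areas (mm^2), nonnegative.
#' @param a_he_mm2 Reference ablated areas (mm^2), nonnegative (NA allowed
#'   while predictions are being accumulated).
#' @return Data frame with the four columns.
#' @export
area_records <- function(case_id, p, a_ire_mm2, a_he_mm2 = NA_real_) {
  df <- data.frame(case_id = as.character(case_id), p = p,
                   a_ire_mm2 = a_ire_mm2, a_he_mm2 = a_he_mm2,
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$p)) || any(df$p <= 0) || any(df$p >= 1))
    stop("area_records: p must be in (0, 1)")
  if (any(df$a_ire_mm2 < 0, na.rm = TRUE) || any(df$a_he_mm2 < 0, na.rm = TRUE))
    stop("area_records: areas must be nonnegative")
  df
}

check_one_level <- function(records, min_n = 3L) {
  need <- c("p", "a_ire_mm2", "a_he_mm2")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (length(unique(records$p)) != 1L)
    stop("records mix multiple probability levels; analyze one level at a time")
  if (nrow(records) < min_n)
    stop(sprintf("need at least %d paired records, got %d", min_n, nrow(records)))
  if (any(!is.finite(records$a_ire_mm2)) || any(!is.finite(records$a_he_mm2)))
    stop("records contain non-finite areas")
  invisible(TRUE)
}

#' Linear regression of predicted on reference areas
#'
#' Ordinary least squares of the predicted area on the reference area
#' (`a_ire ~ a_he`) at a single probability level, the conventional axis
#' assignment when a model prediction is compared against a histology
#' reference. Both the intercept and the predictor role can be flipped since
#' published comparisons do not always state either choice.
#'
#' @param records Data frame from [area_records()], all rows at one level.
#' @param predictor Which area plays the x role: `"a_he"` (default) or
#'   `"a_ire"`.
#' @param intercept Include an intercept (default `TRUE`); with
#'   `FALSE` the fit is forced through the origin (note R^2 is then computed
#'   about zero, the usual convention for origin fits).
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided, on the slope), `p_level`, `n`.
#' @export
#' @examples
#' rec <- area_records(1:3, 0.2, a_ire_mm2 = c(2, 4, 6), a_he_mm2 = c(1, 2, 3))
#' fit_regression(rec)$slope  # 2
fit_regression <- function(records, predictor = c("a_he", "a_ire"),
                           intercept = TRUE) {
  predictor <- match.arg(predictor)
  check_one_level(records)
  x <- records[[paste0(predictor, "_mm2")]]
  y <- records[[paste0(setdiff(c("a_he", "a_ire"), predictor), "_mm2")]]
  if (stats::var(x) == 0)
    stop("fit_regression: zero variance in the predictor areas")
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x - 1)
  # exactly collinear inputs are legitimate here (identity checks); silence
  # summary.lm's perfect-fit warning rather than the caller
  sm <- suppressWarnings(summary(fit))
  coefs <- stats::coef(sm)
  slope_row <- if (intercept) 2L else 1L
  structure(list(
    slope = unname(stats::coef(fit)[["x"]]),
    intercept = if (intercept) unname(stats::coef(fit)[["(Intercept)"]]) else 0,
    r_squared = sm$r.squared,
    p_value = coefs[slope_row, "Pr(>|t|)"],
    p_level = records$p[1L],
    n = nrow(records)
  ), class = "regression_result")
}

#' Bland-Altman agreement analysis
#'
#' Differences `a_ire - a_he` summarized by their mean, sample standard
#' deviation (n - 1 denominator) and the limits of agreement
#' `mean +/- 1.96 SD` (95% interval). Also reports the Pearson correlation of
#' the differences against the pairwise means with its two-sided p-value; a
#' significant correlation indicates the disagreement drifts with the
#' magnitude of the measurement. When either the differences or the means are
#' constant the correlation is not computable and is flagged as such.
#'
#' @param records Data frame from [area_records()], all rows at one level.
#' @return List of class `bland_altman_result`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high` (mm^2), `r_diff_vs_mean`, `p_diff_vs_mean`,
#'   `correlation_defined`, `p_level`, `n`.
#' @export
bland_altman <- function(records) {
  check_one_level(records)
  d <- records$a_ire_mm2 - records$a_he_mm2
  m <- (records$a_ire_mm2 + records$a_he_mm2) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  # constant differences or constant means leave the drift correlation
  # undefined; detect constancy at machine precision, not exact zero
  tol_d <- 1e-10 * max(abs(d), 1e-300)
  tol_m <- 1e-10 * max(abs(m), 1e-300)
  r <- NA_real_; pv <- NA_real_; defined <- FALSE
  if (sd_diff > tol_d && stats::sd(m) > tol_m) {
    ct <- stats::cor.test(d, m, method = "pearson")
    r <- unname(ct$estimate); pv <- ct$p.value; defined <- TRUE
  }
  structure(list(
    mean_diff = mean_diff, sd_diff = sd_diff,
    loa_low = mean_diff - 1.96 * sd_diff,
    loa_high = mean_diff + 1.96 * sd_diff,
    r_diff_vs_mean = r, p_diff_vs_mean = pv,
    correlation_defined = defined,
    p_level = records$p[1L], n = nrow(records)
  ), class = "bland_altman_result")
}

#' Select the best-agreeing probability level
#'
#' Given per-level regression and Bland-Altman summaries, returns the level
#' with the highest coefficient of determination; exact ties are broken by
#' the smallest absolute Bland-Altman mean difference. Both criterion values
#' are recorded in the returned rationale.
#'
#' @param level_stats Data frame with one row per analyzed level and columns
#'   `p_level`, `r_squared`, `mean_diff` (see [level_statistics()]).
#' @return List with `p_level`, `r_squared`, `mean_diff` and a human-readable
#'   `rationale`.
#' @export
select_best_level <- function(level_stats) {
  need <- c("p_level", "r_squared", "mean_diff")
  if (!is.data.frame(level_stats) || nrow(level_stats) < 1L)
    stop("select_best_level: need at least one analyzed level")
  if (!all(need %in% names(level_stats)))
    stop("select_best_level: need columns ", paste(need, collapse = ", "))
  ord <- order(-level_stats$r_squared, abs(level_stats$mean_diff))
  best <- level_stats[ord[1L], ]
  list(
    p_level = best$p_level,
    r_squared = best$r_squared,
    mean_diff = best$mean_diff,
    rationale = sprintf(
      "level %g maximizes R^2 (%.4g); |mean difference| = %.4g mm^2",
      best$p_level, best$r_squared, abs(best$mean_diff))
  )
}

#' Per-level regression and Bland-Altman summaries
#'
#' Convenience wrapper running [fit_regression()] and [bland_altman()] on
#' every probability level present in a records table.
#'
#' @param records Data frame from [area_records()] covering one or more
#'   levels.
#' @param predictor,intercept Passed to [fit_regression()].
#' @return Data frame with one row per level: `p_level`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `r_diff_vs_mean`, `p_diff_vs_mean`, `n`.
#' @export
level_statistics <- function(records, predictor = "a_he", intercept = TRUE) {
  levels <- sort(unique(records$p))
  rows <- lapply(levels, function(pl) {
    rec <- records[records$p == pl, , drop = FALSE]
    fr <- fit_regression(rec, predictor = predictor, intercept = intercept)
    ba <- bland_altman(rec)
    data.frame(p_level = pl, slope = fr$slope, intercept = fr$intercept,
               r_squared = fr$r_squared, p_value = fr$p_value,
               mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               r_diff_vs_mean = ba$r_diff_vs_mean,
               p_diff_vs_mean = ba$p_diff_vs_mean, n = ba$n)
  })
  do.call(rbind, rows)
}
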
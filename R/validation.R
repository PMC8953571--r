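# ICH Q2 method-validation statistics: calibration linearity, detection
# and quantitation limits, inverse prediction, recovery/precision, percent
# degradation, and the grouped summary tables a validation report prints.

#' Fit an external-standard calibration curve
#'
#' Ordinary least squares of detector response (peak area) on nominal
#' concentration. Reports the slope S, intercept, Pearson correlation r,
#' residual SD of the response, and the detection/quantitation limits
#' LLOD = 3.3 SD/|S| and LLOQ = 10 SD/|S|.
#'
#' The "SD of response" entering the limits is the calibration residual SD
#' `sqrt(SSE / (n - 2))` by default; `sd_mode = "intercept"` uses the
#' standard error of the intercept instead (both are ICH-sanctioned).
#'
#' @param data Tibble with columns `conc` (µg/mL, > 0) and `area`; replicate
#'   rows are used as-is.
#' @param sd_mode `"residual"` (default) or `"intercept"`.
#' @return A `calibration_fit` object with [tidy()], [glance()],
#'   [autoplot()] and [predict_concentration()] methods.
#' @examples
#' cal <- gen_calibration(noise_sd_area = 0)
#' glance(fit_calibration(cal))
#' @export
fit_calibration <- function(data, sd_mode = c("residual", "intercept")) {
  sd_mode <- match.arg(sd_mode)
  data <- as_tibble(data)
  if (!all(c("conc", "area") %in% names(data))) {
    abort_stabindr("Calibration data needs `conc` and `area` columns.",
      class = "stabindr_schema_error"
    )
  }
  if (any(!is.finite(data$conc)) || any(data$conc <= 0) ||
      any(!is.finite(data$area))) {
    abort_stabindr("Concentrations must be > 0 and areas finite.",
      class = "stabindr_domain_error"
    )
  }
  if (length(unique(data$conc)) < 2) {
    abort_stabindr("Calibration needs at least 2 distinct concentration levels.",
      class = "stabindr_degenerate_design"
    )
  }
  fit <- stats::lm(area ~ conc, data = data)
  slope <- unname(coef(fit)[["conc"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  n <- nrow(data)
  sse <- sum(stats::residuals(fit)^2)
  sd_resid <- if (n > 2) sqrt(sse / (n - 2)) else 0
  sd_response <- switch(sd_mode,
    residual = sd_resid,
    intercept = unname(summary(fit)$coefficients["(Intercept)", "Std. Error"])
  )
  if (stats::sd(data$area) == 0) {
    # no detector response at all: a numerically-zero lm slope would turn
    # the LLOD into garbage, so flag the degeneracy explicitly
    slope <- 0
    r <- NA_real_
  } else {
    r <- stats::cor(data$conc, data$area)
  }
  limits <- if (abs(slope) > 0) llod_lloq(sd_response, slope) else
    tibble(llod = NA_real_, lloq = NA_real_)
  structure(
    list(
      model = fit, slope = slope, intercept = intercept, r = r,
      sd_response = sd_response, sd_mode = sd_mode, n = n,
      conc_range = range(data$conc),
      llod = limits$llod, lloq = limits$lloq,
      data = data
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Calibration curve: area =", format(x$slope, digits = 6), "* conc +",
      format(x$intercept, digits = 6), "\n")
  cat(sprintf("  n = %d, range %g-%g ug/mL, r = %.4f\n",
              x$n, x$conc_range[1], x$conc_range[2], x$r))
  cat(sprintf("  LLOD = %.3g, LLOQ = %.3g ug/mL (SD mode: %s)\n",
              x$llod, x$lloq, x$sd_mode))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x,object A `calibration_fit`.
#' @param ... Unused.
#' @export
tidy.calibration_fit <- function(x, ...) {
  out <- as_tibble(summary(x$model)$coefficients, rownames = "term")
  names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
  out$term <- c("intercept", "slope")
  out
}

#' @rdname fit_calibration
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, r = x$r, r_squared = x$r^2,
    sd_response = x$sd_response, llod = x$llod, lloq = x$lloq, n = x$n,
    conc_min = x$conc_range[1], conc_max = x$conc_range[2]
  )
}

#' Detection and quantitation limits from calibration statistics
#'
#' `LLOD = 3.3 SD/|S|`, `LLOQ = 10 SD/|S|`; their ratio is 10/3.3 by
#' construction.
#'
#' @param sd_response Standard deviation of the response (area units, >= 0).
#' @param slope Calibration slope S (area per µg/mL, nonzero).
#' @return One-row tibble with `llod` and `lloq` (µg/mL).
#' @examples
#' llod_lloq(19976, 49940) # LLOD 1.32 ug/mL
#' @export
llod_lloq <- function(sd_response, slope) {
  if (!is_number(slope) || slope == 0) {
    abort_stabindr("`slope` must be a nonzero number.",
      class = "stabindr_domain_error"
    )
  }
  if (!is_number(sd_response) || sd_response < 0) {
    abort_stabindr("`sd_response` must be >= 0.", class = "stabindr_domain_error")
  }
  tibble(llod = 3.3 * sd_response / abs(slope),
         lloq = 10 * sd_response / abs(slope))
}

#' Inverse-predict concentrations from peak areas
#'
#' External-standard quantitation: `conc = (area - intercept) / slope`.
#' Negative results are returned (not clipped) and flagged, as are results
#' below the LLOD or LLOQ of the curve.
#'
#' @param object A `calibration_fit`.
#' @param area Numeric vector of peak areas.
#' @return Tibble with `area`, `conc` and `flag`
#'   (`ok` / `below_lloq` / `below_llod` / `negative`).
#' @export
predict_concentration <- function(object, area) {
  stopifnot(inherits(object, "calibration_fit"))
  if (object$slope == 0) {
    abort_stabindr("Curve slope is zero; cannot invert.",
      class = "stabindr_domain_error"
    )
  }
  conc <- (area - object$intercept) / object$slope
  flag <- dplyr::case_when(
    conc < 0 ~ "negative",
    !is.na(object$llod) & conc < object$llod ~ "below_llod",
    !is.na(object$lloq) & conc < object$lloq ~ "below_lloq",
    TRUE ~ "ok"
  )
  tibble(area = area, conc = conc, flag = flag)
}

#' Recovery and precision of replicate determinations
#'
#' Per-replicate recovery is `100 * found / nominal`; precision is the
#' percent relative standard deviation `%RSD = 100 * sd / mean` over the
#' recoveries, using the sample (n - 1) standard deviation.
#'
#' @param found Numeric vector of found concentrations (µg/mL).
#' @param nominal Nominal (spiked) concentration (µg/mL, > 0).
#' @return One-row tibble: `n`, `mean_found`, `recovery_pct`, `rsd_pct`
#'   (NA when n < 2).
#' @examples
#' recovery_stats(c(18, 22), 20) # 100% recovery, 14.14% RSD
#' @export
recovery_stats <- function(found, nominal) {
  if (!is_number(nominal) || nominal <= 0) {
    abort_stabindr("`nominal` must be > 0.", class = "stabindr_domain_error")
  }
  if (length(found) < 1 || any(!is.finite(found))) {
    abort_stabindr("`found` must be a non-empty finite vector.",
      class = "stabindr_domain_error"
    )
  }
  rec <- 100 * found / nominal
  tibble(
    n = length(found),
    mean_found = mean(found),
    recovery_pct = mean(rec),
    rsd_pct = if (length(found) >= 2) 100 * stats::sd(rec) / mean(rec) else NA_real_
  )
}

#' Percent degradation from peak areas
#'
#' `100 * (area_unstressed - area_stressed) / area_unstressed`, the relative
#' loss of drug peak area after stress. The reference is the measured
#' unstressed-sample area from the same batch, so small negative values
#' (stressed area slightly above reference) are legitimate and returned
#' as-is.
#'
#' @param area_unstressed Reference (unstressed) peak area, > 0. Vectorised.
#' @param area_stressed Stressed-sample peak area.
#' @return Percent degradation (may be negative).
#' @examples
#' percent_degradation(1000, 500) # 50
#' @export
percent_degradation <- function(area_unstressed, area_stressed) {
  if (any(!is.finite(area_unstressed)) || any(area_unstressed <= 0)) {
    abort_stabindr("`area_unstressed` must be finite and > 0.",
      class = "stabindr_domain_error"
    )
  }
  100 * (area_unstressed - area_stressed) / area_unstressed
}

#' Grouped recovery summary
#'
#' Summarises replicate determinations into the per-group rows a validation
#' table prints: mean recovery, %RSD and SD of recovery per group. Groups
#' with no rows are dropped with a warning.
#'
#' @param data Tibble with columns `found` and `nominal` plus any grouping
#'   columns.
#' @param ... Grouping columns (tidy-select), e.g. `level`, `condition`,
#'   `time_h`.
#' @return Tibble with one row per group: grouping columns, `n`,
#'   `recovery_pct`, `rsd_pct`, `sd_recovery`.
#' @export
summarize_recovery <- function(data, ...) {
  data <- as_tibble(data)
  if (!all(c("found", "nominal") %in% names(data))) {
    abort_stabindr("`data` needs `found` and `nominal` columns.",
      class = "stabindr_schema_error"
    )
  }
  out <- data |>
    mutate(.recovery = 100 * .data$found / .data$nominal) |>
    group_by(...) |>
    summarise(
      n = dplyr::n(),
      recovery_pct = mean(.recovery),
      rsd_pct = ifelse(dplyr::n() >= 2,
                       100 * stats::sd(.recovery) / mean(.recovery), NA_real_),
      sd_recovery = ifelse(dplyr::n() >= 2, stats::sd(.recovery), NA_real_),
      .groups = "drop"
    )
  out
}

#' Assemble validation report tables
#'
#' Renders the accuracy/precision, robustness and solution-stability tables
#' of a method-validation report from long replicate data. Each input is a
#' tibble with `found`, `nominal` and one grouping column (`level` for
#' accuracy, `condition` for robustness, `time_h` for stability); `NULL`
#' inputs are skipped. The stability table gains a trailing `Mean` row.
#'
#' @param accuracy,robustness,stability Long tibbles as described, or NULL.
#' @param digits Decimal places for the rendered percentages (default 2,
#'   rounded half-up as in printed tables).
#' @return Named list of tibbles (only the tables supplied).
#' @export
summarize_validation <- function(accuracy = NULL, robustness = NULL,
                                 stability = NULL, digits = 2) {
  rnd <- function(x) round_half_up(x, digits)
  out <- list()
  if (!is.null(accuracy)) {
    out$accuracy <- summarize_recovery(accuracy, .data$level) |>
      mutate(recovery_pct = rnd(.data$recovery_pct), rsd_pct = rnd(.data$rsd_pct))
  }
  if (!is.null(robustness)) {
    out$robustness <- summarize_recovery(robustness, .data$condition) |>
      mutate(recovery_pct = rnd(.data$recovery_pct), rsd_pct = rnd(.data$rsd_pct))
  }
  if (!is.null(stability)) {
    tab <- summarize_recovery(stability, .data$time_h) |>
      mutate(time = as.character(.data$time_h)) |>
      select("time", "n", "recovery_pct", "rsd_pct", "sd_recovery")
    mean_row <- tibble(
      time = "Mean", n = sum(tab$n),
      recovery_pct = mean(tab$recovery_pct),
      rsd_pct = NA_real_, sd_recovery = mean(tab$sd_recovery)
    )
    out$stability <- bind_rows(tab, mean_row) |>
      mutate(recovery_pct = rnd(.data$recovery_pct),
             rsd_pct = rnd(.data$rsd_pct),
             sd_recovery = rnd(.data$sd_recovery))
  }
  out
}
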
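# System-suitability metrics from sampled chromatogram traces.
#
# A trace is a two-column tibble (time in minutes on a uniform grid,
# detector signal). measure_peak() locates a single peak in a window and
# measures apex, height and fractional-height widths; the metric functions
# turn those into plate count N (USP half-height formula), asymmetry
# factor As = b/a at 10% height, USP tailing factor at 5%, and the
# capacity factor k'.

check_trace <- function(trace) {
  trace <- as_tibble(trace)
  if (!all(c("time", "signal") %in% names(trace))) {
    abort_stabindr("A trace needs `time` and `signal` columns.",
      class = "stabindr_schema_error"
    )
  }
  if (nrow(trace) < 10) {
    abort_stabindr("A trace needs at least 10 samples.",
      class = "stabindr_domain_error"
    )
  }
  if (any(!is.finite(trace$time)) || any(!is.finite(trace$signal))) {
    abort_stabindr("Trace values must be finite.", class = "stabindr_domain_error")
  }
  dt <- diff(trace$time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    abort_stabindr("Trace time grid must be strictly increasing and uniform.",
      class = "stabindr_domain_error"
    )
  }
  trace
}

# linearly interpolated crossing time of `level` between samples i and i+1
cross_time <- function(t, y, i, level) {
  t[i] + (level - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
}

#' Locate and measure a single chromatographic peak
#'
#' Estimates the baseline as the median of the window-edge samples (first
#' and last 5%, at least 3 points each) and the noise as their MAD. The
#' apex is refined by parabolic interpolation through the three highest
#' samples; widths at 50% and 10% (and 5%) of the baseline-corrected height
#' are located by linear interpolation between samples on each flank.
#'
#' @param trace Tibble with `time` (min, uniform grid) and `signal`.
#' @param window Length-2 numeric, time interval to search; defaults to the
#'   whole trace. Must contain one peak rising at least 3x the baseline
#'   noise above the baseline.
#' @return One-row tibble: `apex_time`, `height` (baseline-corrected),
#'   `baseline`, `width_50`, `width_10`, `a_10`, `b_10` (leading/trailing
#'   half-widths at 10%), `a_5`, `b_5`.
#' @export
measure_peak <- function(trace, window = NULL) {
  trace <- check_trace(trace)
  if (!is.null(window)) {
    trace <- filter(trace, .data$time >= window[1], .data$time <= window[2])
    if (nrow(trace) < 10) {
      abort_stabindr("Window contains fewer than 10 samples.",
        class = "stabindr_domain_error"
      )
    }
  }
  t <- trace$time
  y <- trace$signal
  n_edge <- max(3L, ceiling(0.05 * length(y)))
  edges <- c(head(y, n_edge), tail(y, n_edge))
  baseline <- stats::median(edges)
  noise <- stats::mad(edges)

  i_max <- which.max(y)
  height <- y[i_max] - baseline
  if (height <= 3 * noise || height <= 0) {
    abort_stabindr("No peak above 3x baseline noise in window.",
      class = "stabindr_no_peak"
    )
  }
  if (i_max <= 1 || i_max >= length(y)) {
    abort_stabindr("Peak apex lies on the window edge.",
      class = "stabindr_no_peak"
    )
  }
  # parabolic apex through the apex sample and neighbours
  y1 <- y[i_max - 1]; y2 <- y[i_max]; y3 <- y[i_max + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
  dt <- t[2] - t[1]
  apex_time <- t[i_max] + delta * dt
  apex_height <- y2 - 0.25 * (y1 - y3) * delta - baseline

  width_at <- function(frac) {
    level <- baseline + frac * apex_height
    left <- which(y[seq_len(i_max - 1)] < level)
    right_rel <- which(y[seq.int(i_max + 1, length(y))] < level)
    if (length(left) == 0 || length(right_rel) == 0) {
      abort_stabindr(
        sprintf("Peak not enclosed at %.0f%% height within the window.", frac * 100),
        class = "stabindr_no_peak"
      )
    }
    i_l <- max(left)
    i_r <- i_max + min(right_rel)
    t_l <- cross_time(t, y, i_l, level)
    t_r <- cross_time(t, y, i_r - 1L, level)
    c(a = apex_time - t_l, b = t_r - apex_time)
  }
  w50 <- width_at(0.5)
  w10 <- width_at(0.1)
  w05 <- width_at(0.05)
  tibble(
    apex_time = apex_time, height = apex_height, baseline = baseline,
    width_50 = sum(w50), width_10 = sum(w10),
    a_10 = w10[["a"]], b_10 = w10[["b"]],
    a_5 = w05[["a"]], b_5 = w05[["b"]]
  )
}

#' Theoretical plate count
#'
#' Column efficiency from retention time and peak width. The default is the
#' current compendial half-height formula `N = 5.54 (tR / w50)^2`; the
#' tangent-method variant `N = 16 (tR / W)^2` (W = tangent base width) is
#' available via `method`. `N/m` divides by the column length.
#'
#' @param t_r Retention time (min, > 0).
#' @param width Peak width (min, > 0): width at half height for
#'   `"half_height"`, tangent base width for `"tangent"`.
#' @param column_length Column length in metres (default 0.15, a 150 mm
#'   analytical column).
#' @param method `"half_height"` (default) or `"tangent"`.
#' @return One-row tibble with `n_plates` and `plates_per_m`.
#' @examples
#' plates(7.00, 0.17807) # ~ 8561 plates, ~ 57076 N/m on a 150 mm column
#' @export
plates <- function(t_r, width, column_length = 0.15,
                   method = c("half_height", "tangent")) {
  method <- match.arg(method)
  if (!is_number(t_r) || t_r <= 0 || !is_number(width) || width <= 0 ||
      !is_number(column_length) || column_length <= 0) {
    abort_stabindr("`t_r`, `width` and `column_length` must be > 0.",
      class = "stabindr_domain_error"
    )
  }
  n <- if (method == "half_height") 5.54 * (t_r / width)^2 else 16 * (t_r / width)^2
  tibble(n_plates = n, plates_per_m = n / column_length)
}

#' Asymmetry factor
#'
#' `As = b / a` from the leading (`a`) and trailing (`b`) half-widths
#' measured at 10% of peak height; 1 for a symmetric peak, > 1 for tailing.
#'
#' @param a,b Leading and trailing half-widths at 10% height (min, > 0).
#' @return Numeric As.
#' @export
asymmetry_factor <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    abort_stabindr("Half-widths must be > 0.", class = "stabindr_domain_error")
  }
  b / a
}

#' USP tailing factor
#'
#' `Tf = (a + b) / (2 a)` from half-widths at 5% height.
#'
#' @param a,b Leading and trailing half-widths at 5% height (min, > 0).
#' @return Numeric Tf.
#' @export
tailing_factor <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    abort_stabindr("Half-widths must be > 0.", class = "stabindr_domain_error")
  }
  (a + b) / (2 * a)
}

#' Capacity (retention) factor
#'
#' `k' = (tR - t0) / t0` with `t0` the hold-up (dead) time.
#'
#' @param t_r Retention time (min).
#' @param t0 Hold-up time (min, > 0, <= `t_r`).
#' @return Numeric k'.
#' @examples
#' capacity_factor(7.00, 1.6827) # 3.16
#' @export
capacity_factor <- function(t_r, t0) {
  if (any(t0 <= 0)) {
    abort_stabindr("`t0` must be > 0.", class = "stabindr_domain_error")
  }
  (t_r - t0) / t0
}

#' System-suitability metrics for one peak
#'
#' Convenience wrapper: measures the peak in `window` and derives the full
#' suitability row — retention time, height, widths, As (10%), USP tailing
#' factor (5%), N and N/m, and k' when `t0` is supplied.
#'
#' @inheritParams measure_peak
#' @param t0 Optional hold-up time (min) for the capacity factor.
#' @param column_length Column length (m) for N/m.
#' @param plate_method Passed to [plates()] (tangent mode uses the width at
#'   10% as a base-width surrogate only when half-height is unavailable;
#'   the default half-height formula uses `width_50`).
#' @return One-row tibble of peak metrics.
#' @export
peak_metrics <- function(trace, window = NULL, t0 = NULL, column_length = 0.15,
                         plate_method = "half_height") {
  pk <- measure_peak(trace, window)
  width <- if (plate_method == "half_height") pk$width_50 else pk$width_10
  np <- plates(pk$apex_time, width, column_length, method = plate_method)
  tibble(
    t_r = pk$apex_time, height = pk$height,
    width_50 = pk$width_50, width_10 = pk$width_10,
    asymmetry = asymmetry_factor(pk$a_10, pk$b_10),
    tailing = tailing_factor(pk$a_5, pk$b_5),
    n_plates = np$n_plates, plates_per_m = np$plates_per_m,
    k_prime = if (is.null(t0)) NA_real_ else capacity_factor(pk$apex_time, t0)
  )
}
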
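# Seeded generators emulating the instrument outputs of a forced
# degradation study: decay time-courses with multiplicative noise, a linear
# detector response, exponentially-modified-Gaussian (EMG) chromatographic
# peaks on a drifting noisy baseline, and fragment spectra with ppm-scale
# mass jitter. Every generator is deterministic given its seed and leaves
# the caller's RNG state untouched; zero noise reproduces the underlying
# model exactly, so each generator inverts through its analysis stage.

#' Simulate a degradation time course
#'
#' Concentrations follow the exact rate law (via [predict_conc()]) times a
#' log-normal multiplicative error of the stated %RSD, mimicking peak-area
#' quantitation noise that scales with concentration.
#'
#' @inheritParams half_life
#' @param times Sampling times in hours; must include 0.
#' @param noise_rsd_pct Multiplicative noise, percent RSD (>= 0).
#' @param seed Optional integer seed (global RNG untouched).
#' @param replicates Injections per time point (default 1).
#' @param condition Optional condition label column.
#' @return Tibble with columns `time`, `conc` (and `condition`,
#'   `replicate` when requested), ready for [fit_order()] /
#'   [select_model()].
#' @examples
#' gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = 2, seed = 42)
#' @export
gen_time_course <- function(order, k, c0, times, noise_rsd_pct = 0,
                            seed = NULL, replicates = 1L, condition = NULL) {
  if (!is_number(noise_rsd_pct) || noise_rsd_pct < 0) {
    abort_stabindr("`noise_rsd_pct` must be >= 0.", class = "stabindr_domain_error")
  }
  if (!0 %in% times) {
    abort_stabindr("`times` must include 0.", class = "stabindr_domain_error")
  }
  truth <- predict_conc(order, k, c0, times)
  maybe_with_seed(seed, {
    out <- tidyr::expand_grid(replicate = seq_len(replicates),
                              tibble(time = times, truth = truth)) |>
      arrange(.data$time, .data$replicate) |>
      mutate(conc = .data$truth *
               exp(stats::rnorm(dplyr::n(), 0, noise_rsd_pct / 100))) |>
      select("time", "replicate", "conc")
    if (replicates == 1L) out <- select(out, "time", "conc")
    if (!is.null(condition)) out <- mutate(out, condition = condition, .before = 1)
    out
  })
}

#' Simulate calibration data under a linear detector response
#'
#' Areas follow `S * conc + b` plus additive Gaussian noise of SD
#' `noise_sd_area`. Defaults reproduce a realistic peak-area calibration
#' over 1–100 µg/mL at seven levels in triplicate.
#'
#' @param slope,intercept Detector response line (area per µg/mL; area).
#' @param concs Concentration levels (µg/mL, > 0, >= 2 distinct).
#' @param replicates Replicates per level.
#' @param noise_sd_area Additive area noise SD (>= 0).
#' @param seed Optional integer seed.
#' @return Tibble with columns `conc`, `replicate`, `area`, ready for
#'   [fit_calibration()].
#' @export
gen_calibration <- function(slope = 49940, intercept = 31468,
                            concs = c(1, 5, 10, 20, 40, 80, 100),
                            replicates = 3L, noise_sd_area = 0, seed = NULL) {
  if (length(unique(concs)) < 2) {
    abort_stabindr("Need at least 2 distinct concentration levels.",
      class = "stabindr_degenerate_design"
    )
  }
  if (any(concs <= 0)) {
    abort_stabindr("Concentrations must be > 0.", class = "stabindr_domain_error")
  }
  if (!is_number(noise_sd_area) || noise_sd_area < 0) {
    abort_stabindr("`noise_sd_area` must be >= 0.", class = "stabindr_domain_error")
  }
  maybe_with_seed(seed, {
    tidyr::expand_grid(conc = sort(concs), replicate = seq_len(replicates)) |>
      mutate(area = slope * .data$conc + intercept +
               stats::rnorm(dplyr::n(), 0, noise_sd_area))
  })
}

# EMG profile with unit peak maximum. Stable evaluation via erfcx:
#   EMG(t) ∝ exp(-u^2/2) * erfcx((v - u)/sqrt(2)),  u = (t-tr)/sigma, v = sigma/tau
# which reduces exactly to a Gaussian as tau -> 0.
# scaled complementary error function, safe for large arguments where
# pracma's series returns NaN (asymptotic erfcx(x) ~ 1/(x sqrt(pi)))
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  out[big] <- (1 - 1 / (2 * x[big]^2) + 3 / (4 * x[big]^4)) / (x[big] * sqrt(pi))
  out[!big] <- pracma::erfcx(x[!big])
  out
}

emg_shape <- function(t, tr, sigma, tau) {
  u <- (t - tr) / sigma
  if (tau < 1e-12) {
    return(exp(-u^2 / 2))
  }
  v <- sigma / tau
  x <- (v - u) / sqrt(2)
  # reflection erfcx(x) = 2 exp(x^2) - erfcx(-x) keeps the trailing wing
  # finite where exp(x^2) alone would overflow
  ifelse(x >= 0,
    exp(-u^2 / 2) * erfcx_safe(x),
    2 * exp(v^2 / 2 - u * v) - exp(-u^2 / 2) * erfcx_safe(-x)
  )
}

emg_peak <- function(t, tr, sigma, tau, height) {
  # normalise to the requested apex height on a dense local grid so the
  # result does not depend on the trace sampling grid
  fine <- seq(tr - 5 * sigma, tr + 5 * sigma + 8 * tau, length.out = 2001)
  peak_max <- max(emg_shape(fine, tr, sigma, tau))
  height * emg_shape(t, tr, sigma, tau) / peak_max
}

#' Simulate a chromatogram of EMG peaks
#'
#' Signal = sum of exponentially-modified-Gaussian peaks + linear drift +
#' additive Gaussian noise. The EMG is the standard model of a tailing
#' chromatographic peak; `tau = 0` gives an exactly Gaussian (symmetric)
#' peak.
#'
#' @param peaks Tibble with columns `tr` (apex min), `sigma` (Gaussian SD,
#'   min, > 0), `tau` (exponential tail constant, min, >= 0), `height`.
#' @param baseline_sd Additive noise SD (signal units, >= 0).
#' @param drift_per_min Linear baseline drift (signal units per min).
#' @param duration Run length (min).
#' @param sampling_hz Detector sampling rate (points per second).
#' @param seed Optional integer seed.
#' @return Tibble with `time` (min) and `signal`, ready for
#'   [measure_peak()] / [peak_metrics()]. Warns if the narrowest peak FWHM
#'   spans fewer than 10 samples.
#' @examples
#' tr <- gen_chromatogram(tibble::tibble(tr = 7, sigma = 0.0757, tau = 0, height = 1))
#' measure_peak(tr, c(6, 8))
#' @export
gen_chromatogram <- function(peaks, baseline_sd = 0, drift_per_min = 0,
                             duration = 10, sampling_hz = 10, seed = NULL) {
  peaks <- as_tibble(peaks)
  if (!all(c("tr", "sigma", "tau", "height") %in% names(peaks))) {
    abort_stabindr("`peaks` needs `tr`, `sigma`, `tau`, `height` columns.",
      class = "stabindr_schema_error"
    )
  }
  if (any(peaks$sigma <= 0) || any(peaks$tau < 0)) {
    abort_stabindr("Require sigma > 0 and tau >= 0.",
      class = "stabindr_domain_error"
    )
  }
  if (any(peaks$tr < 0) || any(peaks$tr > duration)) {
    abort_stabindr("All peaks must lie inside the run duration.",
      class = "stabindr_domain_error"
    )
  }
  step_min <- 1 / (60 * sampling_hz)
  time <- seq(0, duration, by = step_min)
  fwhm_min <- 2.3548 * min(peaks$sigma)
  if (fwhm_min / step_min < 10) {
    rlang::warn("Sampling is coarse: < 10 points across the narrowest peak FWHM.")
  }
  signal <- rowSums(vapply(
    seq_len(nrow(peaks)),
    function(i) emg_peak(time, peaks$tr[i], peaks$sigma[i], peaks$tau[i],
                         peaks$height[i]),
    numeric(length(time))
  ))
  signal <- signal + drift_per_min * time
  maybe_with_seed(seed, {
    if (baseline_sd > 0) {
      signal <- signal + stats::rnorm(length(time), 0, baseline_sd)
    }
    tibble(time = time, signal = signal)
  })
}

#' Simulate a high-resolution fragment spectrum
#'
#' Observed m/z values are the exact ion m/z of each formula under the
#' adduct convention, multiplied by `(1 + eps)` with
#' `eps ~ N(0, ppm_jitter_sd * 1e-6)` — the multiplicative error structure
#' of TOF mass accuracy.
#'
#' @param formulas Character vector of neutral formulas.
#' @param adduct,z,electron_corrected Ion convention, as in [ion_mz()].
#' @param ppm_jitter_sd Mass-jitter SD in ppm (>= 0).
#' @param seed Optional integer seed.
#' @param compound Optional compound label column.
#' @return Tibble sorted by ascending `mz` with columns `mz`,
#'   `formula_true`, `mz_true` (and `compound` if given), ready for
#'   [annotate_peaks()].
#' @export
gen_fragment_spectrum <- function(formulas, adduct = "+H", z = 1L,
                                  electron_corrected = TRUE,
                                  ppm_jitter_sd = 0, seed = NULL,
                                  compound = NULL) {
  if (length(formulas) == 0) {
    return(tibble(mz = numeric(), formula_true = character(),
                  mz_true = numeric()))
  }
  if (!is_number(ppm_jitter_sd) || ppm_jitter_sd < 0) {
    abort_stabindr("`ppm_jitter_sd` must be >= 0.", class = "stabindr_domain_error")
  }
  mz_true <- vapply(
    formulas,
    function(f) ion_mz(f, adduct = adduct, z = z,
                       electron_corrected = electron_corrected),
    numeric(1), USE.NAMES = FALSE
  )
  maybe_with_seed(seed, {
    eps <- stats::rnorm(length(mz_true), 0, ppm_jitter_sd * 1e-6)
    out <- tibble(mz = mz_true * (1 + eps),
                  formula_true = as.character(formulas),
                  mz_true = mz_true) |>
      arrange(.data$mz)
    if (!is.null(compound)) out <- mutate(out, compound = compound, .before = 1)
    out
  })
}
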
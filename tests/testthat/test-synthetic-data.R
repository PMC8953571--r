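test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = 2, seed = 42)
  b <- gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = 2, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a, gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = 2, seed = 43)
  ))
  c1 <- gen_calibration(noise_sd_area = 19976, seed = 7)
  c2 <- gen_calibration(noise_sd_area = 19976, seed = 7)
  expect_identical(c1, c2)
  t1 <- gen_chromatogram(tibble::tibble(tr = 7, sigma = 0.07, tau = 0.02,
                                        height = 1),
                         baseline_sd = 0.01, seed = 3)
  t2 <- gen_chromatogram(tibble::tibble(tr = 7, sigma = 0.07, tau = 0.02,
                                        height = 1),
                         baseline_sd = 0.01, seed = 3)
  expect_identical(t1, t2)
  s1 <- gen_fragment_spectrum("C8H9N", ppm_jitter_sd = 5, seed = 11)
  s2 <- gen_fragment_spectrum("C8H9N", ppm_jitter_sd = 5, seed = 11)
  expect_identical(s1, s2)
})

test_that("generators do not disturb the caller's RNG stream", {
  withr::with_seed(1, {
    x1 <- rnorm(1)
    invisible(gen_time_course(1, 0.1, 20, 0:6, noise_rsd_pct = 2, seed = 99))
    x2 <- rnorm(1)
  })
  withr::with_seed(1, {
    y1 <- rnorm(1)
    y2 <- rnorm(1)
  })
  expect_identical(c(x1, x2), c(y1, y2))
})

test_that("zero-noise generation inverts exactly through each analysis stage", {
  # decay series -> kinetic fit
  tc <- gen_time_course(2, 0.0028, 20, c(0, 1, 3, 6, 8, 12, 16))
  expect_equal(tc$conc, predict_conc(2, 0.0028, 20, tc$time), tolerance = 1e-12)
  expect_equal(suppressWarnings(fit_order(tc, 2))$k, 0.0028, tolerance = 1e-12)
  # detector line -> calibration refit
  cal <- gen_calibration(noise_sd_area = 0)
  fit <- suppressWarnings(fit_calibration(cal))
  expect_equal(c(fit$slope, fit$intercept, fit$r), c(49940, 31468, 1),
               tolerance = 1e-8)
  # Gaussian peak -> suitability metrics
  trc <- gen_chromatogram(tibble::tibble(tr = 7, sigma = 0.0757, tau = 0,
                                         height = 1), sampling_hz = 20)
  pk <- measure_peak(trc, c(6, 8))
  expect_equal(pk$apex_time, 7.0, tolerance = 1e-3)
  expect_equal(asymmetry_factor(pk$a_10, pk$b_10), 1, tolerance = 0.01)
  # exact masses -> all matched at 0 ppm
  sp <- gen_fragment_spectrum(c("C6H4S", "C8H9N"), ppm_jitter_sd = 0)
  ann <- annotate_peaks(dplyr::transmute(sp, mz),
                        tibble::tibble(formula = c("C6H4S", "C8H9N")),
                        tolerance_ppm = 1)
  expect_equal(ann$ppm_error, c(0, 0), tolerance = 1e-9)
})

test_that("seeded noisy runs refit close to truth", {
  tc <- gen_time_course(2, 0.0028, 20, c(0, 1, 3, 6, 8, 12, 16),
                        noise_rsd_pct = 1.5, seed = 42)
  k_hat <- fit_order(tc, 2, c0 = 20)$k
  expect_equal(k_hat, 0.0028, tolerance = 0.10)
  cal <- gen_calibration(noise_sd_area = 19976, seed = 7)
  llod_hat <- fit_calibration(cal)$llod
  expect_equal(llod_hat, 1.32, tolerance = 0.25)
})

test_that("Monte-Carlo mean of noisy end-point matches the noiseless value", {
  # 200 seeds of the 6 h first-order design at 1.5% RSD
  ends <- vapply(1:200, function(s) {
    tail(gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = 1.5,
                         seed = 20000 + s)$conc, 1)
  }, numeric(1))
  expect_equal(mean(ends), 20 * exp(-0.1043 * 6), tolerance = 0.01)
})

test_that("doubling a noise parameter doubles the output SD", {
  sds <- vapply(c(1, 2), function(rsd) {
    ends <- vapply(1:500, function(s) {
      tail(gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = rsd,
                           seed = 30000 + s)$conc, 1)
    }, numeric(1))
    sd(ends)
  }, numeric(1))
  expect_equal(sds[2] / sds[1], 2, tolerance = 0.15)
})

test_that("EMG peaks reduce to Gaussian at tau = 0 and tail for tau > 0", {
  g <- gen_chromatogram(tibble::tibble(tr = 7, sigma = 0.06, tau = 0, height = 2),
                        sampling_hz = 20)
  expect_equal(max(g$signal), 2, tolerance = 1e-6)
  pk <- measure_peak(g, c(6, 8))
  expect_equal(pk$a_10, pk$b_10, tolerance = 1e-3)
  e <- gen_chromatogram(tibble::tibble(tr = 7, sigma = 0.06, tau = 0.03,
                                       height = 2), sampling_hz = 20)
  pke <- measure_peak(e, c(6, 8))
  expect_gt(asymmetry_factor(pke$a_10, pke$b_10), 1)
  # two peaks, two windows
  two <- gen_chromatogram(tibble::tibble(tr = c(4.5, 7), sigma = 0.06,
                                         tau = 0, height = c(1, 0.5)),
                          sampling_hz = 20)
  expect_equal(measure_peak(two, c(4, 5))$apex_time, 4.5, tolerance = 1e-3)
  expect_equal(measure_peak(two, c(6.5, 7.5))$apex_time, 7.0, tolerance = 1e-3)
  expect_warning(
    gen_chromatogram(tibble::tibble(tr = 5, sigma = 0.001, tau = 0, height = 1),
                     sampling_hz = 2),
    "coarse"
  )
})

test_that("ppm jitter behaves like a Gaussian mass error", {
  # 100 seeds at 5 ppm jitter, 15 ppm tolerance: ~3 sigma, >= 99% matched
  formulas <- c("C6H4S", "C8H9N", "C16H17NS", "C10H14N2")
  n_match <- 0L
  n_total <- 0L
  for (s in 1:100) {
    sp <- gen_fragment_spectrum(formulas, ppm_jitter_sd = 5, seed = 40000 + s)
    ann <- annotate_peaks(dplyr::transmute(sp, mz),
                          tibble::tibble(formula = formulas),
                          tolerance_ppm = 15)
    n_match <- n_match + sum(ann$matched)
    n_total <- n_total + nrow(ann)
  }
  expect_gte(n_match / n_total, 0.99)
  expect_identical(nrow(gen_fragment_spectrum(character())), 0L)
})

test_that("generator guards reject invalid noise and designs", {
  expect_error(gen_time_course(1, 0.1, 20, 0:6, noise_rsd_pct = -1),
               class = "stabindr_domain_error")
  expect_error(gen_time_course(1, 0.1, 20, 1:6),
               class = "stabindr_domain_error")
  expect_error(gen_calibration(concs = 10), class = "stabindr_degenerate_design")
  expect_error(gen_chromatogram(tibble::tibble(tr = 12, sigma = 0.1, tau = 0,
                                               height = 1), duration = 10),
               class = "stabindr_domain_error")
})
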
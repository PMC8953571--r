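test_that("noiseless time courses invert exactly for all three orders", {
  designs <- list(
    list(order = 0, k = 1.5, c0 = 20, times = 0:6),
    list(order = 1, k = 0.1043, c0 = 20, times = 0:6),
    list(order = 2, k = 0.0028, c0 = 20, times = c(0, 1, 3, 6, 8, 12, 16))
  )
  for (d in designs) {
    tc <- gen_time_course(d$order, d$k, d$c0, d$times)
    fit <- suppressWarnings(fit_order(tc, d$order))
    expect_equal(fit$k, d$k, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    expect_equal(fit$c0, d$c0, tolerance = 1e-10)
    # and the model screen picks the generating order
    scr <- suppressWarnings(select_model(tc))
    expect_identical(scr$best_order, as.integer(d$order))
  }
})

test_that("constant concentrations yield k = 0 with a zero-variance flag", {
  tc <- tibble::tibble(time = 0:5, conc = 20)
  fit <- suppressWarnings(fit_order(tc, 0))
  expect_identical(fit$k, 0)
  expect_identical(fit$r_squared, 0)
  expect_true("zero_variance" %in% fit$flags)
  expect_true("nondegrading" %in% fit$flags)
  expect_true(is.na(fit$t_half))
})

test_that("fit_order validates its inputs", {
  expect_error(fit_order(tibble::tibble(time = 0:1, conc = c(2, 1)), 1),
               class = "stabindr_domain_error")
  neg <- tibble::tibble(time = 0:3, conc = c(2, 1, 0.5, -0.1))
  expect_error(fit_order(neg, 1), class = "stabindr_domain_error")
  expect_error(fit_order(neg, 2), class = "stabindr_domain_error")
  no_zero <- tibble::tibble(time = 1:4, conc = c(10, 8, 6, 4))
  expect_error(fit_order(no_zero, 0), class = "stabindr_domain_error")
  # ... unless c0 is supplied explicitly
  expect_no_error(suppressWarnings(fit_order(no_zero, 0, c0 = 12)))
})

test_that("half-life and shelf-life reproduce the published values", {
  expect_equal(half_life(1, 0.1043), 6.64, tolerance = 0.001)
  expect_equal(shelf_life(1, 0.1043), 1.01, tolerance = 0.005)
  expect_equal(half_life(2, 0.0028, 20), 17.86, tolerance = 0.001)
  expect_equal(shelf_life(2, 0.0028, 20), 1.98, tolerance = 0.005)
  expect_equal(half_life(2, 0.0018, 20), 27.78, tolerance = 0.001)
  expect_equal(shelf_life(2, 0.0018, 20), 3.09, tolerance = 0.005)
  expect_error(half_life(1, 0), class = "stabindr_domain_error")
  expect_error(half_life(2, 0.1), class = "stabindr_domain_error") # c0 missing
})

test_that("t90 < t1/2 with the exact order-specific ratios", {
  withr::with_seed(606, {
    for (i in 1:20) {
      k <- runif(1, 0.001, 0.5)
      c0 <- runif(1, 5, 50)
      for (ord in 0:2) {
        th <- half_life(ord, k, c0, exact = TRUE)
        t9 <- shelf_life(ord, k, c0, exact = TRUE)
        expect_lt(t9, th)
        if (ord == 1) expect_equal(th / t9, log(2) / log(10 / 9), tolerance = 1e-12)
        if (ord == 2) expect_equal(th / t9, 9, tolerance = 1e-12)
        if (ord == 0) expect_equal(th / t9, 5, tolerance = 1e-12)
      }
    }
  })
})

test_that("half-life scaling laws hold across orders", {
  k <- 0.05
  # first order: independent of c0
  expect_identical(half_life(1, k), half_life(1, k, 40))
  # second order: halves when c0 doubles
  expect_equal(half_life(2, k, 40), half_life(2, k, 20) / 2, tolerance = 1e-12)
  # zero order: doubles when c0 doubles
  expect_equal(half_life(0, k, 40), 2 * half_life(0, k, 20), tolerance = 1e-12)
})

test_that("predicted concentration at t1/2 is C0/2 for every order", {
  k <- c(1.5, 0.1043, 0.0028)
  for (ord in 0:2) {
    c0 <- 20
    # exact constants: identity to machine precision
    t_half <- half_life(ord, k[ord + 1], c0, exact = TRUE)
    expect_equal(predict_conc(ord, k[ord + 1], c0, t_half), c0 / 2,
                 tolerance = 1e-12)
    # compendial 0.693 constant: identity within its rounding error
    t_half_c <- half_life(ord, k[ord + 1], c0)
    expect_equal(predict_conc(ord, k[ord + 1], c0, t_half_c), c0 / 2,
                 tolerance = 1e-3)
  }
  expect_equal(predict_conc(1, 0.1043, 20, 0), 20)
  expect_equal(predict_conc(1, 0.1043, 20, 6), 10.70, tolerance = 1e-3)
  expect_warning(predict_conc(0, 2, 10, 10), "floored")
})

test_that("model selection follows the argmax rule with low-order tie-break", {
  sel <- pick_best_order(c("0" = 0.973, "1" = 0.9914, "2" = 0.988))
  expect_identical(sel$order, 1L)
  expect_false(sel$tie)
  tie <- pick_best_order(c("0" = 0.99, "1" = 0.99, "2" = 0.95))
  expect_identical(tie$order, 0L)
  expect_true(tie$tie)
})

test_that("stochastic recovery of the oxidative first-order design", {
  # 200 seeded replicates at 2% multiplicative noise with triplicate
  # injections per time point (the study design): k nearly unbiased,
  # first order selected in the vast majority of runs
  ks <- numeric(200)
  orders <- integer(200)
  for (s in 1:200) {
    tc <- gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = 2,
                          seed = 70000 + s, replicates = 3)
    scr <- select_model(tc, c0 = 20)
    orders[s] <- scr$best_order
    ks[s] <- glance(scr$fits[["1"]])$k
  }
  bias <- (mean(ks) - 0.1043) / 0.1043
  expect_lt(abs(bias), 0.05)
  expect_gte(mean(orders == 1L), 0.90)
})

test_that("tidy, glance and autoplot methods work on kinetic objects", {
  tc <- gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = 1, seed = 9)
  fit <- fit_order(tc, 1)
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "k"))
  expect_s3_class(glance(fit), "tbl_df")
  scr <- select_model(tc)
  expect_identical(nrow(tidy(scr)), 3L)
  expect_identical(sum(tidy(scr)$selected), 1L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(scr), "ggplot")
})
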
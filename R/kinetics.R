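# Degradation-kinetics engine.
#
# The rate law is fitted by the classical "substitution" route: linearise
# the candidate order (C, ln C or 1/C against time), run ordinary least
# squares, and pick the order whose linearisation gives the highest R^2 on
# the transformed scale. Rate constants feed the half-life and shelf-life
# closed forms:
#   order 0:  C = C0 - k t        t1/2 = C0/(2k)     t90 = 0.1 C0/k
#   order 1:  ln C = ln C0 - k t  t1/2 = 0.693/k     t90 = 0.105/k
#   order 2:  1/C = 1/C0 + k t    t1/2 = 1/(k C0)    t90 = 1/(9 k C0)
# Defaults use the rounded constants 0.693 and 0.105 traditional in
# pharmaceutical stability work; `exact = TRUE` switches to ln(2) and
# ln(10/9).

half_life_consts <- function(exact) {
  if (exact) c(t_half = log(2), t90 = log(10 / 9)) else c(t_half = 0.693, t90 = 0.105)
}

check_order <- function(order) {
  if (!is_number(order) || !order %in% c(0, 1, 2)) {
    abort_stabindr("`order` must be 0, 1 or 2.", class = "stabindr_domain_error")
  }
  as.integer(order)
}

#' Half-life of a degrading drug
#'
#' Time to 50% loss under the given rate law. `c0` (µg/mL) is required for
#' orders 0 and 2; first-order half-life is concentration-independent.
#'
#' @param order Reaction order: 0, 1 or 2.
#' @param k Rate constant (> 0); units µg mL^-1 h^-1, h^-1, or
#'   mL µg^-1 h^-1 for orders 0, 1, 2.
#' @param c0 Initial concentration (µg/mL, > 0 where required).
#' @param exact Use ln(2) instead of the traditional 0.693 (default FALSE).
#' @return Half-life in hours.
#' @examples
#' half_life(1, 0.1043)     # 6.64 h
#' half_life(2, 0.0028, 20) # 17.86 h
#' @export
half_life <- function(order, k, c0 = NULL, exact = FALSE) {
  order <- check_order(order)
  if (!is_number(k) || k <= 0) {
    abort_stabindr("`k` must be > 0.", class = "stabindr_domain_error")
  }
  if (order != 1 && (is.null(c0) || !is_number(c0) || c0 <= 0)) {
    abort_stabindr("`c0` must be > 0 for orders 0 and 2.",
      class = "stabindr_domain_error"
    )
  }
  switch(as.character(order),
    "0" = c0 / (2 * k),
    "1" = half_life_consts(exact)[["t_half"]] / k,
    "2" = 1 / (k * c0)
  )
}

#' Shelf life (t90) of a degrading drug
#'
#' Time to 10% loss (90% remaining potency) under the given rate law.
#'
#' @inheritParams half_life
#' @return Shelf life in hours; always shorter than the half-life.
#' @examples
#' shelf_life(1, 0.1043)     # 1.01 h
#' shelf_life(2, 0.0028, 20) # 1.98 h
#' @export
shelf_life <- function(order, k, c0 = NULL, exact = FALSE) {
  order <- check_order(order)
  if (!is_number(k) || k <= 0) {
    abort_stabindr("`k` must be > 0.", class = "stabindr_domain_error")
  }
  if (order != 1 && (is.null(c0) || !is_number(c0) || c0 <= 0)) {
    abort_stabindr("`c0` must be > 0 for orders 0 and 2.",
      class = "stabindr_domain_error"
    )
  }
  switch(as.character(order),
    "0" = 0.1 * c0 / k,
    "1" = half_life_consts(exact)[["t90"]] / k,
    "2" = 1 / (9 * k * c0)
  )
}

#' Predicted concentration under a rate law
#'
#' Forward model for the three orders; order-0 predictions are floored at
#' zero (with a warning) since concentrations cannot be negative.
#'
#' @inheritParams half_life
#' @param t Time(s) in hours (>= 0), vectorised.
#' @return Concentration(s) in µg/mL.
#' @examples
#' predict_conc(1, 0.1043, 20, 6) # 10.70 ug/mL
#' @export
predict_conc <- function(order, k, c0, t) {
  order <- check_order(order)
  if (!is_number(k) || k <= 0 || !is_number(c0) || c0 <= 0) {
    abort_stabindr("`k` and `c0` must be > 0.", class = "stabindr_domain_error")
  }
  if (any(t < 0)) {
    abort_stabindr("`t` must be >= 0.", class = "stabindr_domain_error")
  }
  out <- switch(as.character(order),
    "0" = c0 - k * t,
    "1" = c0 * exp(-k * t),
    "2" = 1 / (1 / c0 + k * t)
  )
  if (order == 0 && any(out < 0)) {
    rlang::warn("Order-0 prediction floored at 0 for some times.")
    out <- pmax(out, 0)
  }
  out
}

transform_response <- function(conc, order) {
  switch(as.character(order), "0" = conc, "1" = log(conc), "2" = 1 / conc)
}

#' Fit one kinetic order to a time course
#'
#' Linearised ordinary least squares of the transformed concentration
#' (C, ln C, or 1/C) on time. The rate constant is minus the slope for
#' orders 0 and 1 and plus the slope for order 2; R^2 is the squared
#' Pearson correlation of time with the transformed response (the
#' goodness-of-fit the substitution method compares). Half-life and shelf
#' life are evaluated at `c0`, which defaults to the measured concentration
#' at t = 0 — in a forced-degradation design this is the nominal working
#' concentration.
#'
#' @param data Tibble with columns `time` (h, t = 0 present, >= 3 points)
#'   and `conc` (µg/mL; strictly positive for orders 1 and 2).
#' @param order Reaction order: 0, 1 or 2.
#' @param c0 Initial concentration used for t1/2 / t90 (default: `conc` at
#'   `time == 0`).
#' @param exact Passed to [half_life()] / [shelf_life()].
#' @return A `kinetic_fit` object with [tidy()], [glance()] and
#'   [autoplot()] methods. Fields include `k`, `k_se` (fit SE), `r_squared`,
#'   `t_half`, `t90` and `flags` (e.g. `zero_variance`, `nondegrading`).
#' @examples
#' tc <- gen_time_course(1, 0.1043, 20, 0:6)
#' glance(fit_order(tc, 1))
#' @export
fit_order <- function(data, order, c0 = NULL, exact = FALSE) {
  order <- check_order(order)
  data <- as_tibble(data)
  if (!all(c("time", "conc") %in% names(data))) {
    abort_stabindr("Time-course data needs `time` and `conc` columns.",
      class = "stabindr_schema_error"
    )
  }
  data <- arrange(data, .data$time)
  if (nrow(data) < 3) {
    abort_stabindr("At least 3 time points are required.",
      class = "stabindr_domain_error"
    )
  }
  if (any(!is.finite(data$conc))) {
    abort_stabindr("Concentrations must be finite.", class = "stabindr_domain_error")
  }
  if (order >= 1 && any(data$conc <= 0)) {
    abort_stabindr("Orders 1 and 2 require strictly positive concentrations.",
      class = "stabindr_domain_error"
    )
  }
  if (is.null(c0)) {
    at0 <- data$conc[data$time == 0]
    if (length(at0) == 0) {
      abort_stabindr("No t = 0 point; supply `c0` explicitly.",
        class = "stabindr_domain_error"
      )
    }
    c0 <- mean(at0)
  }
  y <- transform_response(data$conc, order)
  fit <- stats::lm(y ~ time, data = tibble(y = y, time = data$time))
  slope <- unname(coef(fit)[["time"]])
  se <- unname(summary(fit)$coefficients["time", "Std. Error"])
  k <- if (order == 2) slope else -slope
  flags <- character()
  if (stats::sd(y) == 0) {
    r2 <- 0
    flags <- c(flags, "zero_variance")
    k <- 0
  } else {
    r2 <- stats::cor(data$time, y)^2
  }
  degrading <- k > 0
  if (!degrading) flags <- c(flags, "nondegrading")
  structure(
    list(
      order = order, k = k, k_se = se,
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      t_half = if (degrading) half_life(order, k, c0, exact) else NA_real_,
      t90 = if (degrading) shelf_life(order, k, c0, exact) else NA_real_,
      c0 = c0, n = nrow(data), flags = flags,
      model = fit, data = data, exact = exact
    ),
    class = "kinetic_fit"
  )
}

order_label <- function(order) {
  c("zero-order", "first-order", "second-order")[order + 1]
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s kinetic fit (n = %d)\n", order_label(x$order), x$n))
  cat(sprintf("  k = %.4g +/- %.2g, R2 = %.4f\n", x$k, x$k_se, x$r_squared))
  cat(sprintf("  t1/2 = %.4g h, t90 = %.4g h (C0 = %g ug/mL)\n",
              x$t_half, x$t90, x$c0))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_order
#' @param x,object A `kinetic_fit`.
#' @param ... Unused.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("intercept", "k"),
    estimate = c(x$intercept, x$k),
    std.error = c(s["(Intercept)", "Std. Error"], x$k_se)
  )
}

#' @rdname fit_order
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(
    order = x$order, k = x$k, k_se = x$k_se, r_squared = x$r_squared,
    t_half = x$t_half, t90 = x$t90, c0 = x$c0, n = x$n,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Pick the best-fitting kinetic order from an R-squared table
#'
#' The argmax rule of the substitution method: the order whose linearised
#' fit has the highest R^2 wins; exact ties go to the lowest order and are
#' flagged.
#'
#' @param r_squared Numeric vector of per-order R^2 values, named by order
#'   (`"0"`, `"1"`, `"2"`) or unnamed in order 0, 1, 2.
#' @return List with `order` (integer), `r_squared` (winning value) and
#'   `tie` (logical).
#' @examples
#' pick_best_order(c("0" = 0.973, "1" = 0.9914, "2" = 0.988)) # order 1
#' @export
pick_best_order <- function(r_squared) {
  if (is.null(names(r_squared))) {
    names(r_squared) <- as.character(seq_along(r_squared) - 1)
  }
  orders <- as.integer(names(r_squared))
  best_r2 <- max(r_squared)
  winners <- orders[r_squared == best_r2]
  list(order = min(winners), r_squared = unname(best_r2),
       tie = length(winners) > 1)
}

#' Fit all three orders and select the best by R-squared
#'
#' Runs [fit_order()] for orders 0, 1 and 2 and applies
#' [pick_best_order()] to the transformed-scale R^2 values.
#'
#' @inheritParams fit_order
#' @return A `kinetic_screen` object: `fits` (list of the three
#'   `kinetic_fit`s), `comparison` (per-order tibble), `best_order`,
#'   `best_fit`, `tie`.
#' @examples
#' tc <- gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = 2, seed = 1)
#' select_model(tc)
#' @export
select_model <- function(data, c0 = NULL, exact = FALSE) {
  fits <- lapply(0:2, function(o) fit_order(data, o, c0 = c0, exact = exact))
  names(fits) <- as.character(0:2)
  comparison <- bind_rows(lapply(fits, glance))
  sel <- pick_best_order(stats::setNames(comparison$r_squared, comparison$order))
  structure(
    list(
      fits = fits, comparison = comparison,
      best_order = sel$order, best_fit = fits[[as.character(sel$order)]],
      tie = sel$tie
    ),
    class = "kinetic_screen"
  )
}

#' @export
print.kinetic_screen <- function(x, ...) {
  cat("Kinetic model screen (substitution method)\n")
  print(as.data.frame(x$comparison[, c("order", "k", "r_squared", "t_half", "t90")]),
        row.names = FALSE, digits = 4)
  cat(sprintf("Selected: %s%s\n", order_label(x$best_order),
              if (x$tie) " (tie broken toward lower order)" else ""))
  invisible(x)
}

#' @rdname select_model
#' @param x,object A `kinetic_screen`.
#' @param ... Unused.
#' @export
tidy.kinetic_screen <- function(x, ...) {
  mutate(x$comparison, selected = .data$order == x$best_order)
}

#' @rdname select_model
#' @export
glance.kinetic_screen <- function(x, ...) {
  mutate(glance(x$best_fit), tie = x$tie)
}
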
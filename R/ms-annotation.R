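# Elemental-composition assignment of high-resolution fragment ions.
#
# decompose_mass() searches CHNOS composition space for formulas whose ion
# m/z falls within a ppm tolerance of a target; annotate_peaks() assigns
# candidate formulas to observed peak lists and reports signed ppm errors,
# reproducing the layout of a QTOF-MS/MS annotation table.

normalise_bounds <- function(bounds) {
  default <- list(C = c(0, 30), H = c(0, 60), N = c(0, 6), O = c(0, 6), S = c(0, 3))
  if (is.null(bounds)) return(default)
  if (is.numeric(bounds) && !is.null(names(bounds))) {
    bounds <- lapply(bounds, function(mx) c(0, mx))
  }
  bad <- setdiff(names(bounds), names(.element_masses))
  if (length(bad) > 0) {
    abort_stabindr(paste0("Unsupported element(s) in bounds: ",
                          paste(bad, collapse = ", ")),
      class = "stabindr_unsupported_element"
    )
  }
  out <- lapply(names(.element_masses), function(e) {
    b <- bounds[[e]] %||% c(0, 0)
    if (length(b) == 1) b <- c(0, b)
    if (any(!is.finite(b)) || b[2] < b[1] || b[1] < 0) {
      abort_stabindr("Element bounds must be finite, non-negative min/max pairs.",
        class = "stabindr_domain_error"
      )
    }
    as.integer(round(b))
  })
  stats::setNames(out, names(.element_masses))
}

counts_to_formula <- function(c_, h, n, o, s) {
  v <- c(C = c_, H = h, N = n, O = o, S = s)
  v <- v[v > 0]
  if (length(v) == 0) return(NA_character_)
  render_formula(chem_formula(v))
}

#' Search elemental compositions matching a target m/z
#'
#' Enumerates all CHNOS formulas within per-element count bounds whose ion
#' m/z (under the given adduct convention) lies within `tolerance_ppm` of
#' `target_mz`. The search is exhaustive within bounds: C/N/O/S counts are
#' enumerated and the admissible H count interval is solved from the mass
#' window, so no candidate inside the window can be missed.
#'
#' Candidates are ranked by |ppm error|, with formulas of plausible RDBE
#' (>= `rdbe_min`) preferred; the RDBE filter can be disabled by setting
#' `rdbe_min = -Inf`.
#'
#' @param target_mz Target m/z (> 0).
#' @param tolerance_ppm Matching half-window in ppm (> 0). Default 15 ppm,
#'   wide enough to cover mass errors seen on a routinely calibrated QTOF.
#' @param bounds Per-element count bounds for the neutral formula: either a
#'   named list of `c(min, max)` pairs or a named vector of maxima
#'   (minima 0). Elements absent from `bounds` are excluded.
#' @param adduct,z,electron_corrected Ion convention, as in [ion_mz()].
#' @param rdbe_min Candidates with neutral RDBE below this are dropped
#'   (default -0.5, permitting even-electron fragment compositions).
#' @return A tibble with columns `formula` (neutral, Hill notation),
#'   `mz_calculated`, `ppm_error`, `rdbe`, sorted by |ppm| then RDBE
#'   plausibility.
#' @examples
#' decompose_mass(163.1230, 5, bounds = c(C = 12, H = 20, N = 3, O = 2, S = 1))
#' @export
decompose_mass <- function(target_mz, tolerance_ppm = 15, bounds = NULL,
                           adduct = c("+H", "-H", "none"), z = 1L,
                           electron_corrected = TRUE, rdbe_min = -0.5) {
  adduct <- match.arg(adduct)
  if (!is_number(target_mz) || target_mz <= 0) {
    abort_stabindr("`target_mz` must be a positive number.",
      class = "stabindr_domain_error"
    )
  }
  if (!is_number(tolerance_ppm) || tolerance_ppm <= 0) {
    abort_stabindr("`tolerance_ppm` must be > 0.", class = "stabindr_domain_error")
  }
  b <- normalise_bounds(bounds)
  shift <- adduct_shift(adduct, electron_corrected)
  # neutral-mass window implied by the ppm window on the ion m/z
  m_lo <- target_mz * (1 - tolerance_ppm * 1e-6) * z - z * shift
  m_hi <- target_mz * (1 + tolerance_ppm * 1e-6) * z - z * shift

  grid <- tidyr::expand_grid(
    c_ = seq.int(b$C[1], b$C[2]),
    n  = seq.int(b$N[1], b$N[2]),
    o  = seq.int(b$O[1], b$O[2]),
    s  = seq.int(b$S[1], b$S[2])
  )
  base <- with(grid, c_ * .element_masses[["C"]] + n * .element_masses[["N"]] +
                 o * .element_masses[["O"]] + s * .element_masses[["S"]])
  mh <- .element_masses[["H"]]
  h_lo <- pmax(ceiling((m_lo - base) / mh - 1e-9), b$H[1])
  h_hi <- pmin(floor((m_hi - base) / mh + 1e-9), b$H[2])
  keep <- which(h_hi >= h_lo)
  if (length(keep) == 0) {
    return(tibble(formula = character(), mz_calculated = numeric(),
                  ppm_error = numeric(), rdbe = numeric()))
  }
  rows <- purrr::map_dfr(keep, function(i) {
    h <- seq.int(h_lo[i], h_hi[i])
    tibble(c_ = grid$c_[i], h = h, n = grid$n[i], o = grid$o[i], s = grid$s[i],
           neutral_mass = base[i] + h * mh)
  })
  rows <- rows |>
    filter(.data$c_ + .data$h + .data$n + .data$o + .data$s > 0) |>
    mutate(
      mz_calculated = (.data$neutral_mass + z * shift) / z,
      ppm_error = ppm_error(target_mz, .data$mz_calculated),
      rdbe = .data$c_ - .data$h / 2 + .data$n / 2 + 1,
      formula = purrr::pmap_chr(
        list(.data$c_, .data$h, .data$n, .data$o, .data$s), counts_to_formula
      )
    ) |>
    filter(abs(.data$ppm_error) <= tolerance_ppm, .data$rdbe >= rdbe_min) |>
    arrange(abs(.data$ppm_error), .data$rdbe < 0, .data$formula) |>
    select("formula", "mz_calculated", "ppm_error", "rdbe")
  rows
}

#' Assign candidate formulas to an observed peak list
#'
#' Each observed m/z is assigned the candidate minimising |ppm error| within
#' `tolerance_ppm`; peaks with no candidate inside tolerance are reported as
#' unmatched with a reason. Ties are broken by smaller distance of RDBE from
#' the nearest integer, then lexicographically by formula.
#'
#' Two calculation modes reflect the two ways a "calculated" m/z can enter
#' an annotation table:
#' \describe{
#'   \item{`computed`}{the default — candidate `formula` values are neutral
#'     compositions and the calculated m/z is derived from the element mass
#'     table under the adduct convention;}
#'   \item{`provided`}{each candidate row carries its own `mz_calculated`
#'     (e.g. values printed in a publication or emitted by vendor software),
#'     and `formula` is taken verbatim as the ion composition label.}
#' }
#'
#' @param peaks Tibble of observed peaks: column `mz` (ascending within a
#'   compound), optional `compound` label, `intensity`, `ion_type`.
#' @param candidates Tibble of candidates: column `formula`, optional
#'   `compound` (matched against the peak list), and `mz_calculated`
#'   (required in provided mode). Duplicate formulas within a compound are
#'   an error.
#' @param tolerance_ppm Matching half-window in ppm (> 0).
#' @param calc_mode `"computed"` or `"provided"`.
#' @param adduct,z,electron_corrected Ion convention for computed mode.
#' @return A tibble (one row per observed peak) with columns `compound`,
#'   `mz_observed`, `formula`, `mz_calculated`, `ppm_error`, `rdbe`,
#'   `matched`, `reason`; molecular-ion rows (if flagged via `ion_type`)
#'   come first within each compound block.
#' @export
annotate_peaks <- function(peaks, candidates,
                           tolerance_ppm = 15,
                           calc_mode = c("computed", "provided"),
                           adduct = c("+H", "-H", "none"), z = 1L,
                           electron_corrected = TRUE) {
  calc_mode <- match.arg(calc_mode)
  adduct <- match.arg(adduct)
  if (!is_number(tolerance_ppm) || tolerance_ppm <= 0) {
    abort_stabindr("`tolerance_ppm` must be > 0.", class = "stabindr_domain_error")
  }
  peaks <- as_tibble(peaks)
  candidates <- as_tibble(candidates)
  if (nrow(peaks) == 0) {
    return(tibble(compound = character(), mz_observed = numeric(),
                  formula = character(), mz_calculated = numeric(),
                  ppm_error = numeric(), rdbe = numeric(),
                  matched = logical(), reason = character()))
  }
  if (!"mz" %in% names(peaks)) {
    abort_stabindr("`peaks` must have an `mz` column.", class = "stabindr_schema_error")
  }
  if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0)) {
    abort_stabindr("Observed m/z must be finite and > 0.",
      class = "stabindr_domain_error"
    )
  }
  if (!"compound" %in% names(peaks)) peaks$compound <- "peak_list"
  if (!"compound" %in% names(candidates)) candidates$compound <- "peak_list"

  if (calc_mode == "provided") {
    if (!"mz_calculated" %in% names(candidates) ||
        any(!is.finite(candidates$mz_calculated))) {
      abort_stabindr(
        "Provided mode requires a finite `mz_calculated` for every candidate.",
        class = "stabindr_schema_error"
      )
    }
  } else {
    candidates$mz_calculated <- vapply(
      candidates$formula,
      function(f) ion_mz(f, adduct = adduct, z = z,
                         electron_corrected = electron_corrected),
      numeric(1), USE.NAMES = FALSE
    )
  }
  dup <- candidates |>
    dplyr::count(.data$compound, .data$formula) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_stabindr(
      paste0("Duplicate candidate formula(s): ",
             paste(unique(dup$formula), collapse = ", ")),
      class = "stabindr_domain_error"
    )
  }
  candidates$rdbe <- rdbe(as.character(candidates$formula))

  assign_one <- function(comp, mz_obs) {
    cand <- candidates[candidates$compound == comp, ]
    if (nrow(cand) > 0) {
      err <- ppm_error(mz_obs, cand$mz_calculated)
      ok <- abs(err) <= tolerance_ppm
    } else {
      ok <- logical(0)
    }
    if (!any(ok)) {
      reason <- if (nrow(cand) == 0) "no candidates for compound" else
        "no candidate within tolerance"
      return(tibble(compound = comp, mz_observed = mz_obs,
                    formula = NA_character_, mz_calculated = NA_real_,
                    ppm_error = NA_real_, rdbe = NA_real_,
                    matched = FALSE, reason = reason))
    }
    cand <- cand[ok, ]
    err <- err[ok]
    pick <- order(abs(err), abs(cand$rdbe - round(cand$rdbe)), cand$formula)[1]
    tibble(compound = comp, mz_observed = mz_obs,
           formula = as.character(cand$formula[pick]),
           mz_calculated = cand$mz_calculated[pick],
           ppm_error = err[pick], rdbe = cand$rdbe[pick],
           matched = TRUE, reason = NA_character_)
  }

  out <- purrr::map2_dfr(peaks$compound, peaks$mz, assign_one)
  if ("ion_type" %in% names(peaks)) out$ion_type <- peaks$ion_type
  if ("condition" %in% names(peaks)) out$condition <- peaks$condition
  # molecular ion first within each compound block, then ascending m/z
  key_mol <- if ("ion_type" %in% names(out)) out$ion_type != "molecular" else
    rep(TRUE, nrow(out))
  out[order(match(out$compound, unique(peaks$compound)), key_mol, out$mz_observed), ] |>
    as_tibble()
}

#' Render a fragment-annotation report
#'
#' Flattens one or more annotation tables (from [annotate_peaks()]) into a
#' single deterministic report: one row per ion with compound, stress
#' condition, formula, observed and calculated m/z, and the ppm error
#' rounded half-up to 2 decimals. Unmatched peaks keep their reason.
#'
#' @param tables A tibble from [annotate_peaks()] or a list of such tibbles.
#' @return A tibble with columns `compound`, `condition`, `formula`,
#'   `mz_observed`, `mz_calculated`, `ppm_error`, `matched`, `reason`.
#' @export
build_annotation_report <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- bind_rows(tables)
  if (nrow(tab) == 0) {
    return(tibble(compound = character(), condition = character(),
                  formula = character(), mz_observed = numeric(),
                  mz_calculated = numeric(), ppm_error = numeric(),
                  matched = logical(), reason = character()))
  }
  if (!"condition" %in% names(tab)) tab$condition <- "none"
  tab |>
    mutate(ppm_error = round_half_up(.data$ppm_error, 2)) |>
    select("compound", "condition", "formula", "mz_observed",
           "mz_calculated", "ppm_error", "matched", "reason")
}
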
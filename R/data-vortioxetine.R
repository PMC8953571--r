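# Published reference data for vortioxetine (VOR), the worked example the
# package ships: the QTOF-MS/MS annotation table of the drug and its seven
# degradation products, and the degradation-kinetics study designs.

#' QTOF-MS/MS annotation table for vortioxetine and its degradation products
#'
#' The published high-resolution annotation of vortioxetine (VOR) and
#' degradation products DP1–DP7: per ion, the observed m/z, the assigned
#' ion composition, the reported calculated m/z and the reported ppm error.
#' The reported calculated masses are carried verbatim (provided-mass mode
#' input); they are not reproducible from standard monoisotopic arithmetic
#' for most compounds, which is exactly why [annotate_peaks()] has a
#' `provided` calculation mode.
#'
#' @return Tibble with columns `compound`, `condition`, `ion_type`
#'   (`molecular`/`fragment`), `mz_observed`, `ion_formula`,
#'   `mz_calculated`, `ppm_printed`.
#' @examples
#' head(vortioxetine_fragments())
#' @export
vortioxetine_fragments <- function() {
  path <- system.file("extdata", "vortioxetine_qtof_fragments.csv",
                      package = "stabindr", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    compound = readr::col_character(),
    condition = readr::col_character(),
    ion_type = readr::col_character(),
    mz_observed = readr::col_double(),
    ion_formula = readr::col_character(),
    mz_calculated = readr::col_double(),
    ppm_printed = readr::col_double()
  ))
}

#' Degradation-kinetics study designs for vortioxetine
#'
#' The three stress conditions under which vortioxetine degrades
#' appreciably, with the published selected order, rate constant (with its
#' reported SD), sampling grid, and nominal working concentration
#' (20 µg/mL). These are the default design parameters of
#' [gen_time_course()] simulations and the inputs from which half-life and
#' shelf-life are reproduced.
#'
#' @return Tibble with columns `condition`, `order`, `k`, `k_sd`, `c0`,
#'   and a list-column `times` (hours).
#' @examples
#' vortioxetine_kinetics()
#' @export
vortioxetine_kinetics <- function() {
  tibble(
    condition = c("oxidative_h2o2_15pct", "uv254_solution", "uv254_solid"),
    order = c(1L, 2L, 2L),
    k = c(0.1043, 0.0028, 0.0018),
    k_sd = c(0.0026, 0.0001, 0.0001),
    c0 = 20,
    times = list(c(0, 1, 2, 3, 4, 5, 6),
                 c(0, 1, 3, 6, 8, 12, 16),
                 c(0, 1, 3, 6, 8, 16))
  )
}
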
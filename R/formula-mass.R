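# Chemical-formula grammar and monoisotopic mass arithmetic.
#
# All m/z bookkeeping in the package goes through this file: a small
# immutable table of monoisotopic atomic masses (CHNOS), a Hill-notation
# formula parser/renderer, neutral and adduct ion m/z, signed ppm error
# and rings-plus-double-bond equivalents (RDBE).

# Monoisotopic masses (Da) of the most abundant isotope, CODATA/NIST values.
.element_masses <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.9720707300
)

#' Physical mass constants (Da)
#'
#' Monoisotopic mass of the proton and rest mass of the electron, used for
#' adduct and charge-state corrections of ion m/z.
#'
#' @format Named numeric vector with elements `proton` and `electron`.
#' @export
mass_constants <- c(proton = 1.00727646, electron = 0.00054858)

#' Monoisotopic element mass table
#'
#' Returns the table of monoisotopic atomic masses backing every calculated
#' m/z in the package. The supported element set is C, H, N, O, S — the
#' compositions that occur in small-molecule drug degradation work with a
#' thioether-containing parent.
#'
#' @return A tibble with columns `element` and `mass_da`.
#' @examples
#' element_mass_table()
#' @export
element_mass_table <- function() {
  tibble(element = names(.element_masses), mass_da = unname(.element_masses))
}

#' Write the element mass table to CSV
#'
#' Dumps the atomic-mass constants to a two-column CSV (`element`, `mass_da`)
#' so the mass basis of any report can be audited.
#'
#' @param path File path to write to.
#' @return The path, invisibly.
#' @export
write_element_masses <- function(path) {
  readr::write_csv(element_mass_table(), path)
  invisible(path)
}

new_chem_formula <- function(counts) {
  structure(counts, class = "chem_formula")
}

#' Construct a chemical formula from element counts
#'
#' @param counts Named integer vector, element symbol -> count (>= 1).
#' @return A `chem_formula` object (named integer vector in Hill order).
#' @examples
#' chem_formula(c(C = 18, H = 22, N = 2, S = 1))
#' @export
chem_formula <- function(counts) {
  if (length(counts) == 0) {
    return(new_chem_formula(stats::setNames(integer(0), character(0))))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    abort_stabindr("`counts` must be a named vector of element counts.",
      class = "stabindr_parse_error"
    )
  }
  bad <- setdiff(names(counts), names(.element_masses))
  if (length(bad) > 0) {
    abort_stabindr(
      paste0("Unsupported element(s): ", paste(bad, collapse = ", "),
             ". Supported: ", paste(names(.element_masses), collapse = ", "), "."),
      class = "stabindr_unsupported_element"
    )
  }
  if (any(counts != round(counts)) || any(counts < 1)) {
    abort_stabindr("Element counts must be positive integers.",
      class = "stabindr_parse_error"
    )
  }
  counts <- tapply(as.integer(counts), names(counts), sum) # merge duplicates
  counts <- stats::setNames(as.integer(counts), names(counts))
  new_chem_formula(counts[hill_order(names(counts))])
}

# Hill convention: C first, H second, then alphabetical; without C,
# everything alphabetical.
hill_order <- function(elements) {
  if ("C" %in% elements) {
    rest <- sort(setdiff(elements, c("C", "H")))
    c("C", intersect("H", elements), rest)
  } else {
    sort(elements)
  }
}

#' Parse a Hill-notation chemical formula
#'
#' Accepts plain ASCII formulas such as `"C18H23N2S"` or `"H2O"`: element
#' symbols from the supported CHNOS set, each optionally followed by a
#' positive integer count (implicit 1). No parentheses, isotopes, or charge
#' signs — charge state lives in the ion convention of [ion_mz()].
#'
#' @param text Non-empty formula string.
#' @return A `chem_formula` object.
#' @examples
#' parse_formula("C18H23N2S")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort_stabindr("`text` must be a single non-empty string.",
      class = "stabindr_parse_error"
    )
  }
  m <- gregexpr("([A-Z][a-z]*)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || length(tokens) == 0) {
    abort_stabindr(paste0("Malformed formula: '", text, "'."),
      class = "stabindr_parse_error"
    )
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  if (any(cnt == "0")) {
    abort_stabindr(paste0("Zero element count in formula: '", text, "'."),
      class = "stabindr_parse_error"
    )
  }
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  chem_formula(stats::setNames(cnt, sym))
}

#' Render a formula in canonical Hill notation
#'
#' @param f A `chem_formula` object.
#' @return A string; `render_formula(parse_formula(x))` is canonical Hill
#'   notation of the same element multiset.
#' @examples
#' render_formula(parse_formula("H22C18SN2"))
#' @export
render_formula <- function(f) {
  f <- as_chem_formula(f)
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

as_chem_formula <- function(f) {
  if (inherits(f, "chem_formula")) return(f)
  if (is.character(f) && length(f) == 1L) return(parse_formula(f))
  abort_stabindr("Expected a chem_formula or a single formula string.",
    class = "stabindr_parse_error"
  )
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", render_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.chem_formula <- function(x, ...) render_formula(x)

#' Monoisotopic mass of a neutral formula
#'
#' Sum of the monoisotopic atomic masses over all atoms. Additive over
#' formula union; an empty formula has mass 0.
#'
#' @param f A `chem_formula`, a formula string, or a character vector of
#'   formula strings (vectorised).
#' @return Numeric mass in Da.
#' @examples
#' monoisotopic_mass("H2O")       # 18.010565
#' monoisotopic_mass("C18H22N2S") # 298.150370 (neutral vortioxetine)
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f) && length(f) > 1L) {
    return(vapply(f, function(x) monoisotopic_mass(x), numeric(1), USE.NAMES = FALSE))
  }
  f <- as_chem_formula(f)
  if (length(f) == 0) return(0)
  sum(.element_masses[names(f)] * unclass(f))
}

adduct_shift <- function(adduct, electron_corrected) {
  # per unit charge, in Da
  switch(adduct,
    "+H"   = if (electron_corrected) mass_constants[["proton"]] else .element_masses[["H"]],
    "-H"   = if (electron_corrected) -mass_constants[["proton"]] else -.element_masses[["H"]],
    "none" = if (electron_corrected) -mass_constants[["electron"]] else 0,
    abort_stabindr("`adduct` must be one of '+H', '-H', 'none'.",
      class = "stabindr_parse_error"
    )
  )
}

#' m/z of an adduct or bare ion
#'
#' Computes the mass-to-charge ratio of a charged species from its neutral
#' formula under a simple adduct convention:
#' \deqn{m/z = (M + z \cdot \delta)/z}
#' where `M` is the neutral monoisotopic mass and `delta` is the per-charge
#' adduct shift. With `electron_corrected = TRUE` (the default, and the
#' physically correct choice for even-electron cations) `+H` adds one proton
#' mass, `-H` subtracts one proton mass, and `none` removes `z` electrons
#' (bare cation by electron loss). With `electron_corrected = FALSE` the
#' electron mass is ignored and `+H`/`-H` add/remove a neutral hydrogen atom.
#'
#' @param formula Neutral formula (`chem_formula`, string, or character
#'   vector — vectorised).
#' @param adduct One of `"+H"`, `"-H"`, `"none"`.
#' @param z Positive integer charge.
#' @param electron_corrected Apply the electron-mass correction (default TRUE).
#' @return Numeric m/z.
#' @examples
#' ion_mz("C18H22N2S", "+H") # 299.157645, protonated vortioxetine
#' @export
ion_mz <- function(formula, adduct = c("+H", "-H", "none"), z = 1L,
                   electron_corrected = TRUE) {
  adduct <- match.arg(adduct)
  if (!is_number(z) || z < 1 || z != round(z)) {
    abort_stabindr("`z` must be a positive integer.", class = "stabindr_domain_error")
  }
  m <- monoisotopic_mass(formula)
  (m + z * adduct_shift(adduct, electron_corrected)) / z
}

#' Signed ppm mass error
#'
#' `(observed - calculated) / calculated * 1e6`, the accuracy currency of
#' high-resolution MS. Vectorised; reports in tabular output are rounded to
#' 2 decimals.
#'
#' @param observed Observed m/z.
#' @param calculated Calculated (theoretical) m/z, must be > 0.
#' @return Signed ppm error.
#' @examples
#' ppm_error(299.1961, 299.1981) # -6.68 ppm
#' @export
ppm_error <- function(observed, calculated) {
  if (any(!is.finite(calculated)) || any(calculated <= 0)) {
    abort_stabindr("`calculated` m/z must be finite and > 0.",
      class = "stabindr_domain_error"
    )
  }
  (observed - calculated) / calculated * 1e6
}

#' Rings-plus-double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1 for CHNOS formulas (O and S are divalent and do
#' not contribute). Half-integer values are meaningful for even-electron ion
#' compositions and are returned as-is.
#'
#' @param f Formula (`chem_formula`, string, or character vector).
#' @return Numeric RDBE (may be half-integer or negative).
#' @examples
#' rdbe("C6H6") # benzene: 4
#' @export
rdbe <- function(f) {
  if (is.character(f) && length(f) > 1L) {
    return(vapply(f, rdbe, numeric(1), USE.NAMES = FALSE))
  }
  f <- as_chem_formula(f)
  cnt <- function(e) if (e %in% names(f)) unclass(f)[[e]] else 0
  cnt("C") - cnt("H") / 2 + cnt("N") / 2 + 1
}
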
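# Independent oracles used by the property tests.

# Element masses restated independently of the package internals.
oracle_masses <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.9720707300)
oracle_proton <- 1.00727646

# Brute-force composition search: quintuple nested loops, scalar mass
# accumulation, no vectorised shortcuts. Returns neutral Hill formulas of
# every candidate whose [M+H]+ (electron-corrected) m/z is within tol ppm.
brute_force_decompose <- function(target_mz, tol_ppm, max_counts) {
  hits <- character()
  for (c_ in 0:max_counts[["C"]]) {
    for (h in 0:max_counts[["H"]]) {
      for (n in 0:max_counts[["N"]]) {
        for (o in 0:max_counts[["O"]]) {
          for (s in 0:max_counts[["S"]]) {
            if (c_ + h + n + o + s == 0) next
            m <- c_ * oracle_masses[["C"]] + h * oracle_masses[["H"]] +
              n * oracle_masses[["N"]] + o * oracle_masses[["O"]] +
              s * oracle_masses[["S"]]
            mz <- m + oracle_proton
            if (abs(mz - target_mz) / target_mz * 1e6 <= tol_ppm) {
              parts <- c(C = c_, H = h, N = n, O = o, S = s)
              parts <- parts[parts > 0]
              hits <- c(hits, paste0(names(parts),
                                     ifelse(parts == 1, "", parts),
                                     collapse = ""))
            }
          }
        }
      }
    }
  }
  sort(hits)
}

# Random CHNOS formula as a named count vector.
random_formula_counts <- function() {
  counts <- c(
    C = sample(0:12, 1), H = sample(0:20, 1), N = sample(0:4, 1),
    O = sample(0:4, 1), S = sample(0:2, 1)
  )
  if (sum(counts) == 0) counts[["C"]] <- 1
  counts[counts > 0]
}

counts_to_string <- function(counts) {
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}
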
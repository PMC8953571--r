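# CSV schemas, run configuration and the report pipeline.
#
# Readers validate the documented schemas (exact header names, "." decimal,
# UTF-8) and report the offending row/column on failure; extra columns are
# accepted with a warning. run_pipeline() ties the analysis stages into a
# deterministic report bundle.

read_schema_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    abort_stabindr(paste0("File not found: ", path),
      class = "stabindr_schema_error"
    )
  }
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )
  if (nrow(raw) == 0) {
    abort_stabindr(paste0("Empty file: ", path), class = "stabindr_schema_error")
  }
  missing <- setdiff(names(required), names(raw))
  if (length(missing) > 0) {
    abort_stabindr(
      paste0("Missing column(s) in ", basename(path), ": ",
             paste(missing, collapse = ", ")),
      class = "stabindr_schema_error"
    )
  }
  extra <- setdiff(names(raw), c(names(required), names(optional)))
  if (length(extra) > 0) {
    rlang::warn(paste0("Ignoring unrecognised column(s) in ", basename(path),
                       ": ", paste(extra, collapse = ", ")))
  }
  convert <- function(tab, spec) {
    for (col in intersect(names(spec), names(tab))) {
      if (spec[[col]] == "numeric") {
        val <- suppressWarnings(as.numeric(tab[[col]]))
        bad <- which(is.na(val) & !is.na(tab[[col]]))
        if (length(bad) > 0) {
          abort_stabindr(
            sprintf("Non-numeric value '%s' in column '%s', row %d of %s.",
                    tab[[col]][bad[1]], col, bad[1], basename(path)),
            class = "stabindr_schema_error"
          )
        }
        tab[[col]] <- val
      }
    }
    tab
  }
  raw |>
    convert(required) |>
    convert(optional) |>
    select(all_of(intersect(c(names(required), names(optional)), names(raw))))
}

#' Read a time-course CSV
#'
#' Schema: `condition` (text), `time_h`, `conc_ug_ml` (numeric).
#'
#' @param path CSV path.
#' @return Tibble with columns `condition`, `time`, `conc`.
#' @export
read_time_course <- function(path) {
  read_schema_csv(path,
    required = c(condition = "character", time_h = "numeric",
                 conc_ug_ml = "numeric")
  ) |>
    dplyr::rename(time = "time_h", conc = "conc_ug_ml")
}

#' Read a calibration CSV
#'
#' Schema: `conc_ug_ml`, `replicate`, `area` (numeric).
#'
#' @param path CSV path.
#' @return Tibble with columns `conc`, `replicate`, `area`.
#' @export
read_calibration <- function(path) {
  read_schema_csv(path,
    required = c(conc_ug_ml = "numeric", replicate = "numeric", area = "numeric")
  ) |>
    dplyr::rename(conc = "conc_ug_ml")
}

#' Read a chromatogram trace CSV
#'
#' Schema: `time_min`, `signal` (numeric).
#'
#' @param path CSV path.
#' @return Tibble with columns `time`, `signal`.
#' @export
read_chromatogram <- function(path) {
  read_schema_csv(path, required = c(time_min = "numeric", signal = "numeric")) |>
    dplyr::rename(time = "time_min")
}

#' Read a fragment peak-list CSV
#'
#' Schema: `compound` (text), `mz` (numeric), optional `intensity`,
#' `ion_type`, `condition`.
#'
#' @param path CSV path.
#' @return Tibble ready for [annotate_peaks()].
#' @export
read_peak_list <- function(path) {
  read_schema_csv(path,
    required = c(compound = "character", mz = "numeric"),
    optional = c(intensity = "numeric", ion_type = "character",
                 condition = "character")
  )
}

#' Read a candidate-formula CSV
#'
#' Schema: `compound` (text), `formula` (text), optional `mz_calculated`
#' (numeric; required downstream in provided mode).
#'
#' @param path CSV path.
#' @return Tibble ready for [annotate_peaks()].
#' @export
read_candidates <- function(path) {
  read_schema_csv(path,
    required = c(compound = "character", formula = "character"),
    optional = c(mz_calculated = "numeric")
  )
}

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values that parse
#' as numbers become numeric; comma-separated values become vectors.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_stabindr(paste0("Config file not found: ", path),
      class = "stabindr_schema_error"
    )
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) < 2)
  if (length(bad) > 0) {
    abort_stabindr(sprintf("Malformed config line %d: '%s'", bad[1], lines[bad[1]]),
      class = "stabindr_schema_error"
    )
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  stats::setNames(lapply(vals, parse_val), keys)
}

pipeline_stage_inputs <- list(
  calibrate = "calibration_csv",
  kinetics = "time_course_csv",
  annotate = c("peaks_csv", "candidates_csv"),
  suitability = "chromatogram_csv"
)

#' Run the analysis pipeline and write a report bundle
#'
#' Orchestrates the stages over CSV inputs and writes one CSV report per
#' stage plus a provenance sidecar and a structured log. Reports are
#' byte-identical across reruns of the same configuration (timestamps go
#' only to the log). All referenced input files are checked before any
#' computation starts.
#'
#' Config keys (list or flat key-value file, see [read_run_config()]):
#' `stages` (subset of `calibrate, kinetics, annotate, suitability`;
#' default all with inputs present), `out_dir`, `calibration_csv`,
#' `time_course_csv`, `peaks_csv`, `candidates_csv`, `chromatogram_csv`,
#' `c0`, `tolerance_ppm` (default 15), `calc_mode`
#' (`computed`/`provided`), `t0_min`, `column_length_m` (default 0.15),
#' `window_min` (two values), `seed`.
#'
#' Report rounding follows printed-table conventions: percentages, ppm and
#' hours to 2 decimals; rate constants and R^2 to 4.
#'
#' @param config Named list or path to a config file.
#' @return Invisibly, a named list of the report tibbles (full precision).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- config$stages %||%
    names(pipeline_stage_inputs)[vapply(pipeline_stage_inputs, function(keys) {
      all(keys %in% names(config))
    }, logical(1))]
  stages <- intersect(names(pipeline_stage_inputs), stages)
  if (length(stages) == 0) {
    abort_stabindr("No runnable stages: no stage inputs in config.",
      class = "stabindr_schema_error"
    )
  }
  # validate every referenced input before computing anything
  for (st in stages) {
    for (key in pipeline_stage_inputs[[st]]) {
      p <- config[[key]]
      if (is.null(p)) {
        abort_stabindr(sprintf("Stage '%s' needs config key '%s'.", st, key),
          class = "stabindr_schema_error"
        )
      }
      if (!file.exists(p)) {
        abort_stabindr(sprintf("Stage '%s': input file not found: %s", st, p),
          class = "stabindr_schema_error"
        )
      }
    }
  }
  log_lines <- c(sprintf("run started %s", format(Sys.time())),
                 sprintf("stages: %s", paste(stages, collapse = ", ")))
  reports <- list()
  meta <- list()
  r2 <- function(x) round_half_up(x, 2)
  r4 <- function(x) round_half_up(x, 4)

  if ("calibrate" %in% stages) {
    cal <- read_calibration(config$calibration_csv)
    fit <- fit_calibration(cal)
    reports$calibration <- glance(fit)
    rendered <- reports$calibration |>
      mutate(across(c("slope", "intercept", "sd_response", "llod", "lloq"), r2),
             across(c("r", "r_squared"), r4))
    readr::write_csv(rendered, file.path(out_dir, "calibration_report.csv"))
    meta$calibration <- "slope/intercept: OLS area~conc; r: Pearson; llod=3.3*SD/S, lloq=10*SD/S, SD=residual SD"
    log_lines <- c(log_lines, sprintf(
      "calibrate: %s (n=%d, sd_mode=%s)", config$calibration_csv, fit$n, fit$sd_mode))
  }
  if ("kinetics" %in% stages) {
    tc <- read_time_course(config$time_course_csv)
    per_cond <- tc |>
      dplyr::group_split(.data$condition)
    rows <- purrr::map_dfr(per_cond, function(d) {
      scr <- select_model(select(d, "time", "conc"), c0 = config$c0)
      mutate(tidy(scr), condition = d$condition[1], tie = scr$tie, .before = 1)
    })
    reports$kinetics <- rows
    rendered <- rows |>
      mutate(across(c("k", "k_se", "r_squared"), r4),
             across(c("t_half", "t90"), r2)) |>
      select("condition", "order", "k", "k_se", "r_squared",
             "t_half", "t90", "selected", "tie")
    readr::write_csv(rendered, file.path(out_dir, "kinetics_report.csv"))
    meta$kinetics <- "linearised OLS per order; R2 on transformed scale; best order = argmax R2 (tie -> lower order); t1/2, t90 from closed forms at C0"
    log_lines <- c(log_lines, sprintf(
      "kinetics: %s (c0=%s)", config$time_course_csv,
      config$c0 %||% "from t=0"))
  }
  if ("annotate" %in% stages) {
    peaks <- read_peak_list(config$peaks_csv)
    cands <- read_candidates(config$candidates_csv)
    mode <- config$calc_mode %||% "computed"
    tol <- config$tolerance_ppm %||% 15
    ann <- annotate_peaks(peaks, cands, tolerance_ppm = tol, calc_mode = mode)
    reports$annotation <- ann
    readr::write_csv(build_annotation_report(ann),
                     file.path(out_dir, "annotation_report.csv"))
    meta$annotation <- sprintf(
      "assignment: argmin |ppm| within %g ppm, calc_mode=%s; ppm=(obs-calc)/calc*1e6, 2 dp", tol, mode)
    log_lines <- c(log_lines, sprintf(
      "annotate: %s + %s (mode=%s, tol=%g ppm, %d/%d matched)",
      config$peaks_csv, config$candidates_csv, mode, tol,
      sum(ann$matched), nrow(ann)))
  }
  if ("suitability" %in% stages) {
    trace <- read_chromatogram(config$chromatogram_csv)
    window <- config$window_min
    pm <- peak_metrics(trace, window = window, t0 = config$t0_min,
                       column_length = config$column_length_m %||% 0.15)
    reports$suitability <- pm
    rendered <- pm |>
      mutate(across(c("t_r", "asymmetry", "tailing", "k_prime"), r2),
             across(c("n_plates", "plates_per_m"), ~ round_half_up(.x, 0)))
    readr::write_csv(rendered, file.path(out_dir, "suitability_report.csv"))
    meta$suitability <- "N = 5.54*(tR/w50)^2 (USP half-height); As = b/a at 10% height; k' = (tR-t0)/t0"
    log_lines <- c(log_lines, sprintf(
      "suitability: %s (L=%g m)", config$chromatogram_csv,
      config$column_length_m %||% 0.15))
  }
  readr::write_csv(
    tibble(report = names(meta), provenance = unlist(meta)),
    file.path(out_dir, "report_metadata.csv")
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(reports)
}
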
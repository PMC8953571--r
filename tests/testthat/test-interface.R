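# fixtures are written programmatically into a temp dir

write_demo_inputs <- function(dir) {
  tc <- dplyr::bind_rows(
    gen_time_course(1, 0.1043, 20, 0:6, noise_rsd_pct = 1, seed = 1,
                    condition = "oxidative"),
    gen_time_course(2, 0.0028, 20, c(0, 1, 3, 6, 8, 12, 16),
                    noise_rsd_pct = 1, seed = 2, condition = "uv254_solution")
  ) |>
    dplyr::transmute(condition, time_h = time, conc_ug_ml = conc)
  readr::write_csv(tc, file.path(dir, "time_course.csv"))

  cal <- gen_calibration(noise_sd_area = 19976, seed = 3) |>
    dplyr::transmute(conc_ug_ml = conc, replicate, area)
  readr::write_csv(cal, file.path(dir, "calibration.csv"))

  fr <- vortioxetine_fragments()
  readr::write_csv(
    dplyr::transmute(fr, compound, mz = mz_observed, ion_type, condition),
    file.path(dir, "peaks.csv")
  )
  readr::write_csv(
    dplyr::transmute(fr, compound, formula = ion_formula, mz_calculated),
    file.path(dir, "candidates.csv")
  )

  trc <- gen_chromatogram(tibble::tibble(tr = 7, sigma = 0.0757, tau = 0.02,
                                         height = 1.2),
                          baseline_sd = 0.002, seed = 4, sampling_hz = 10) |>
    dplyr::transmute(time_min = time, signal)
  readr::write_csv(trc, file.path(dir, "chromatogram.csv"))
  invisible(dir)
}

demo_config <- function(dir, out_dir) {
  list(
    out_dir = out_dir,
    calibration_csv = file.path(dir, "calibration.csv"),
    time_course_csv = file.path(dir, "time_course.csv"),
    peaks_csv = file.path(dir, "peaks.csv"),
    candidates_csv = file.path(dir, "candidates.csv"),
    chromatogram_csv = file.path(dir, "chromatogram.csv"),
    c0 = 20, tolerance_ppm = 15, calc_mode = "provided",
    t0_min = 1.6827, column_length_m = 0.15, window_min = c(6, 8)
  )
}

test_that("schema readers validate headers, types and row positions", {
  dir <- withr::local_tempdir()
  ok <- file.path(dir, "tc.csv")
  writeLines(c("condition,time_h,conc_ug_ml", "ox,0,20", "ox,1,18.2", "ox,2,16.3"), ok)
  tc <- read_time_course(ok)
  expect_identical(nrow(tc), 3L)
  expect_named(tc, c("condition", "time", "conc"))

  missing_col <- file.path(dir, "bad1.csv")
  writeLines(c("condition,conc_ug_ml", "ox,20"), missing_col)
  expect_error(read_time_course(missing_col), "time_h",
               class = "stabindr_schema_error")

  bad_cell <- file.path(dir, "bad2.csv")
  writeLines(c("condition,time_h,conc_ug_ml", "ox,0,20", "ox,one,18"), bad_cell)
  err <- tryCatch(read_time_course(bad_cell), error = identity)
  expect_s3_class(err, "stabindr_schema_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "time_h")

  extra <- file.path(dir, "extra.csv")
  writeLines(c("condition,time_h,conc_ug_ml,operator", "ox,0,20,kw"), extra)
  expect_warning(out <- read_time_course(extra), "unrecognised")
  expect_named(out, c("condition", "time", "conc"))

  empty <- file.path(dir, "empty.csv")
  writeLines("condition,time_h,conc_ug_ml", empty)
  expect_error(read_time_course(empty), class = "stabindr_schema_error")
})

test_that("flat key-value configs parse with numeric coercion", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "run.cfg")
  writeLines(c(
    "# demo config",
    "out_dir = reports",
    "c0 = 20",
    "window_min = 6, 8",
    "stages = kinetics, annotate"
  ), cfg)
  parsed <- read_run_config(cfg)
  expect_identical(parsed$out_dir, "reports")
  expect_identical(parsed$c0, 20)
  expect_identical(parsed$window_min, c(6, 8))
  expect_identical(parsed$stages, c("kinetics", "annotate"))
  bad <- file.path(dir, "bad.cfg")
  writeLines("just a line", bad)
  expect_error(read_run_config(bad), class = "stabindr_schema_error")
})

test_that("the full pipeline writes a deterministic four-report bundle", {
  dir <- withr::local_tempdir()
  write_demo_inputs(dir)
  out1 <- file.path(dir, "out1")
  cfg <- demo_config(dir, out1)
  reports <- suppressWarnings(run_pipeline(cfg))
  expect_setequal(names(reports),
                  c("calibration", "kinetics", "annotation", "suitability"))
  files <- c("calibration_report.csv", "kinetics_report.csv",
             "annotation_report.csv", "suitability_report.csv",
             "report_metadata.csv", "run_log.txt")
  expect_true(all(file.exists(file.path(out1, files))))

  kin <- readr::read_csv(file.path(out1, "kinetics_report.csv"),
                         show_col_types = FALSE)
  expect_identical(nrow(kin), 6L) # 2 conditions x 3 orders
  expect_identical(kin$order[kin$selected & kin$condition == "oxidative"], 1)
  expect_identical(kin$order[kin$selected & kin$condition == "uv254_solution"], 2)

  ann <- readr::read_csv(file.path(out1, "annotation_report.csv"),
                         show_col_types = FALSE)
  expect_identical(nrow(ann), 75L)

  # rerun into a second directory: CSV reports byte-identical
  out2 <- file.path(dir, "out2")
  cfg2 <- demo_config(dir, out2)
  suppressWarnings(run_pipeline(cfg2))
  for (f in setdiff(files, "run_log.txt")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
})

test_that("a single-stage config produces a single report", {
  dir <- withr::local_tempdir()
  write_demo_inputs(dir)
  out <- file.path(dir, "out")
  cfg <- demo_config(dir, out)
  cfg$stages <- "kinetics"
  reports <- run_pipeline(cfg)
  expect_identical(names(reports), "kinetics")
  expect_true(file.exists(file.path(out, "kinetics_report.csv")))
  expect_false(file.exists(file.path(out, "calibration_report.csv")))
})

test_that("a config referencing an absent file fails before computing", {
  dir <- withr::local_tempdir()
  write_demo_inputs(dir)
  out <- file.path(dir, "out")
  cfg <- demo_config(dir, out)
  cfg$time_course_csv <- file.path(dir, "nope.csv")
  expect_error(run_pipeline(cfg), "not found", class = "stabindr_schema_error")
  # nothing was written, including reports for stages with valid inputs
  expect_false(dir.exists(out) && length(list.files(out)) > 0)
})
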
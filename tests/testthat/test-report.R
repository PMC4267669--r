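test_that("control versus itself reports ~100% wild type and no editing", {
  ctrl <- render_trace(random_sequence(650, seed = 61),
                       trace_params(seed = 61))
  guide <- substr(ctrl$bases, 281, 300)
  fit <- decompose_trace(ctrl, ctrl, guide)
  expect_gt(fit$spectrum$percentage[fit$spectrum$indel == 0], 97)
  expect_lt(fit$total_efficiency, 1)
  expect_gt(fit$r_squared, 0.99)
  expect_length(fit$quality, 0L)
})

test_that("an end-to-end synthetic pool matches the generating weights", {
  spec <- data.frame(size = c(0, -3, -1, 1, 5),
                     fraction = c(0.55, 0.1, 0.2, 0.1, 0.05),
                     inserted_bases = c("", "", "", "A", ""))
  sim <- make_experiment(62, spec)
  fit <- decompose_trace(sim$control, sim$sample, sim$guide)
  expect_percentages(fit, spec$size, 100 * spec$fraction, tol = 2)
  expect_lt(abs(fit$total_efficiency - 45), 3)
  # total efficiency is exactly what is not wild type or unexplained
  expect_equal(fit$total_efficiency,
               100 * fit$r_squared -
                 fit$spectrum$percentage[fit$spectrum$indel == 0],
               tolerance = 1e-9)
})

test_that("report files are written, schema-stable and reproducible", {
  sim <- make_experiment(63, data.frame(size = c(0, -1),
                                        fraction = c(0.75, 0.25)))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_trace(sim$control, cpath)
  write_trace(sim$sample, spath)
  fit <- decompose_trace(cpath, spath, sim$guide)
  dir1 <- withr::local_tempdir()
  write_report(fit, dir1)
  expect_setequal(list.files(dir1),
                  c("spectrum.tsv", "profile.tsv", "composition.tsv",
                    "report.json"))
  rep <- jsonlite::read_json(file.path(dir1, "report.json"),
                             simplifyVector = TRUE)
  expect_named(rep, c("tool", "inputs", "parameters", "cut_site", "offset",
                      "window", "r_squared", "total_efficiency", "spectrum",
                      "insertion", "quality_warnings", "fit_warnings"),
               ignore.order = TRUE)
  expect_equal(rep$r_squared, fit$r_squared, tolerance = 1e-12)
  expect_equal(nrow(rep$spectrum), 21L)
  expect_false(is.na(rep$inputs$control$md5))
  # user-facing coordinates are 1-based
  expect_equal(rep$cut_site$position, fit$site$cut_index + 1L)

  spectab <- read.table(file.path(dir1, "spectrum.tsv"), header = TRUE,
                        sep = "\t")
  expect_equal(spectab$indel, -10:10)
  expect_equal(sum(spectab$percentage), 100 * fit$r_squared,
               tolerance = 1e-6)

  # re-running the identical analysis is bit-identical
  fit2 <- decompose_trace(cpath, spath, sim$guide)
  dir2 <- withr::local_tempdir()
  write_report(fit2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir1, f)),
                     label = sprintf("rerun content of %s", f))
  }
})

test_that("an unrelated sample amplicon propagates the offset-alignment error", {
  ctrl <- render_trace(random_sequence(600, seed = 64), trace_params(seed = 64))
  other <- render_trace(random_sequence(600, seed = 65), trace_params(seed = 65))
  guide <- substr(ctrl$bases, 301, 320)
  expect_error(decompose_trace(ctrl, other, guide),
               "does not match control upstream")
})

run_cli <- function(args) {
  script <- system.file("cli", "tracedec", package = "tracedec")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, shQuote(c(script, args)), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(out, "status") %||% 0L, output = out)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the command-line interface honours the exit-code contract", {
  dir <- withr::local_tempdir()
  ctrl_path <- file.path(dir, "control.tsv")
  samp_path <- file.path(dir, "sample.tsv")

  # synth a control and an edited pool, then decompose them
  r <- run_cli(c("synth", "--random", "600", "--seed", "5",
                 "--out", ctrl_path))
  expect_equal(r$status, 0L)
  ctrl <- read_trace(ctrl_path)
  guide <- substr(ctrl$bases, 251, 270)
  cut <- 250 + 17
  r <- run_cli(c("synth", "--random", "600", "--seed", "5",
                 "--indels", sprintf("0@%d,0.7;-1@%d,0.2;+1:G@%d,0.1",
                                     cut, cut, cut),
                 "--out", samp_path))
  expect_equal(r$status, 0L)
  out_dir <- file.path(dir, "out")
  r <- run_cli(c("decompose", "--control", ctrl_path, "--sample", samp_path,
                 "--guide", guide, "--out", out_dir))
  expect_equal(r$status, 0L)
  expect_true(file.exists(file.path(out_dir, "report.json")))
  rep <- jsonlite::read_json(file.path(out_dir, "report.json"),
                             simplifyVector = TRUE)
  expect_lt(abs(rep$total_efficiency - 30), 3)

  # error path: missing file
  r <- run_cli(c("decompose", "--control", "/nonexistent", "--sample",
                 samp_path, "--guide", guide, "--out", out_dir))
  expect_equal(r$status, 1L)

  # quality-warning path: heavy channel crosstalk pushes the pre-break
  # background aberrant signal over 10%
  noisy_ctrl <- file.path(dir, "noisy_control.tsv")
  noisy_samp <- file.path(dir, "noisy_sample.tsv")
  r <- run_cli(c("synth", "--random", "600", "--seed", "6",
                 "--crosstalk", "0.25", "--out", noisy_ctrl))
  expect_equal(r$status, 0L)
  nctrl <- read_trace(noisy_ctrl)
  nguide <- substr(nctrl$bases, 251, 270)
  r <- run_cli(c("synth", "--random", "600", "--seed", "6",
                 "--crosstalk", "0.25", "--out", noisy_samp))
  expect_equal(r$status, 0L)
  r <- run_cli(c("decompose", "--control", noisy_ctrl, "--sample", noisy_samp,
                 "--guide", nguide, "--out", file.path(dir, "out2")))
  expect_equal(r$status, 2L)
})
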
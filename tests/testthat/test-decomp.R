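p0 <- trace_params(noise_cv = 0, crosstalk = 0, decay_rate = 0)

test_that("aberrant_signal is one minus the reference-base fraction", {
  sm <- normalize_peaks(chromatogram("AAA", rbind(
    c(100, 0, 0, 0),
    c(25, 25, 25, 25),
    c(0, 0, 0, 0)
  )))
  ab <- aberrant_signal(sm, "AAN")
  expect_equal(ab[1], 0)
  expect_equal(ab[2], 0.75)
  expect_true(is.na(ab[3]))  # masked row

  # fully frame-shifted pool over a random reference: ~75% aberrant, because
  # one aberrant base in four coincides with the reference by chance
  ref <- random_sequence(4000, seed = 41)
  alt <- random_sequence(4000, seed = 42)
  ab2 <- aberrant_signal(normalize_peaks(render_trace(alt, p0)), ref)
  expect_lt(abs(mean(ab2) - 0.75), 0.03)
})

test_that("the default decomposition window follows the s+5 rule", {
  site <- make_site(200)
  w <- default_window(site, make_offset(0), 700, 700, n = 10)
  expect_equal(c(w$left, w$right), c(215L, 685L))
  w15 <- default_window(site, make_offset(0), 700, 700, n = 15)
  expect_equal(c(w15$left, w15$right), c(220L, 680L))
  # offset shortens the usable sample extent in the control frame
  w_off <- default_window(site, make_offset(30), 700, 700, n = 10)
  expect_equal(w_off$right, 700L - 30L - 15L)
  expect_error(default_window(site, make_offset(0), 240, 240, n = 10),
               "too short")
})

test_that("shifted model columns read the control at the indel-displaced position", {
  ctrl <- render_trace(random_sequence(120, seed = 43), p0)
  sm <- normalize_peaks(ctrl)
  win <- structure(list(left = 30L, right = 90L), class = "decomp_window")
  models <- build_models(sm, win, n = 5)
  expect_equal(dim(models$M), c(4L * 60L, 11L))
  expect_true(all(models$M >= 0 & models$M <= 1))
  pos <- 30:89
  expect_equal(models$M[, models$labels == 0],
               as.vector(sm$fractions[pos + 1L, ]))
  expect_equal(models$M[, models$labels == -1],
               as.vector(sm$fractions[pos + 2L, ]))
  expect_equal(models$M[, models$labels == 3],
               as.vector(sm$fractions[pos - 3L + 1L, ]))
  expect_error(build_models(sm, structure(list(left = 30L, right = 119L),
                                          class = "decomp_window"), n = 5),
               "range error")
})

test_that("a period-3 control makes the -3 column identical to wild type and is flagged", {
  ctrl <- render_trace(strrep("ACG", 60), p0)
  sm <- normalize_peaks(ctrl)
  win <- structure(list(left = 30L, right = 150L), class = "decomp_window")
  models <- build_models(sm, win, n = 5)
  expect_identical(models$M[, models$labels == -3],
                   models$M[, models$labels == 0])
  res <- decompose_signal(sm, models, make_offset(0))
  expect_match(paste(res$warnings, collapse = " "), "singular")
  expect_true(anyNA(res$spectrum$p))
})

test_that("self-decomposition of the control recovers 100% wild type", {
  ctrl <- render_trace(random_sequence(500, seed = 44),
                       trace_params(noise_cv = 0, crosstalk = 0.02, seed = 44))
  sm <- normalize_peaks(ctrl)
  win <- default_window(make_site(200), make_offset(0), 500, 500, 10)
  models <- build_models(sm, win, 10)
  res <- decompose_signal(sm, models, make_offset(0))
  expect_gt(res$r_squared, 0.9999)
  expect_lt(abs(res$spectrum$percentage[res$spectrum$indel == 0] - 100), 0.01)
  expect_lt(res$total_efficiency, 0.01)
})

test_that("noiseless mixtures are recovered essentially exactly", {
  # 70/30 wild type / -1 deletion
  sim <- make_experiment(5, data.frame(size = c(0, -1),
                                       fraction = c(0.7, 0.3)),
                         noise_cv = 0)
  fit <- decompose_trace(sim$control, sim$sample, sim$guide)
  expect_percentages(fit, c(0, -1), c(70, 30), tol = 0.1)

  # five-component spectrum: wt 50, -8 / -3 / +1 / +6 at 12.5 each
  spec <- data.frame(size = c(0, -8, -3, 1, 6),
                     fraction = c(0.5, 0.125, 0.125, 0.125, 0.125))
  sim5 <- make_experiment(6, spec, noise_cv = 0)
  fit5 <- decompose_trace(sim5$control, sim5$sample, sim5$guide)
  expect_percentages(fit5, spec$size, 100 * spec$fraction, tol = 0.5)
  others <- !fit5$spectrum$indel %in% spec$size
  expect_true(all(fit5$spectrum$percentage[others] < 0.1))
  expect_true(all(fit5$spectrum$p[fit5$spectrum$indel %in% spec$size] < 1e-6))
})

test_that("NNLS agrees with an exhaustive grid-search oracle on tiny instances", {
  set.seed(55)
  # two columns, free grid over [0,1]^2
  for (i in 1:3) {
    M <- matrix(runif(24), 12L, 2L)
    w_true <- c(0.62, 0.17)
    y <- as.vector(M %*% w_true) + rnorm(12, sd = 0.01)
    got <- pracma::lsqnonneg(M, y)$x
    oracle <- nnls_grid_oracle(M, y)
    expect_true(all(abs(got - oracle) < 2e-3))
  }
  # three columns, exact convex mixture, simplex-face grid
  ctrl <- render_trace(random_sequence(40, seed = 56), p0)
  sm <- normalize_peaks(ctrl)
  win <- structure(list(left = 10L, right = 22L), class = "decomp_window")
  models <- build_models(sm, win, n = 1)
  w_true <- c(0.25, 0.6, 0.15)
  y <- as.vector(models$M %*% w_true)
  got <- pracma::lsqnonneg(models$M, y)$x
  oracle <- nnls_grid_oracle(models$M, y)
  expect_true(all(abs(got - oracle) < 2e-3))
})

test_that("percentages always sum to 100 * R-squared and stay non-negative", {
  for (seed in 1:5) {
    sim <- make_experiment(seed, data.frame(size = c(0, -2, 4),
                                            fraction = c(0.6, 0.25, 0.15)))
    fit <- decompose_trace(sim$control, sim$sample, sim$guide)
    expect_equal(sum(fit$spectrum$percentage), 100 * fit$r_squared,
                 tolerance = 1e-9)
    expect_true(all(fit$spectrum$percentage >= 0))
    expect_true(all(fit$spectrum$coefficient >= 0))
    expect_true(all(fit$spectrum$p >= 0 & fit$spectrum$p <= 1, na.rm = TRUE))
  }
})

test_that("the spectrum is stable under moderate window shifts", {
  sim <- make_experiment(8, data.frame(size = c(0, -1, 2),
                                       fraction = c(0.55, 0.3, 0.15)))
  fit <- decompose_trace(sim$control, sim$sample, sim$guide)
  # keep the right edge inside both reads; shift the left edge +-10
  for (shift in c(-10L, 10L)) {
    alt <- decompose_trace(sim$control, sim$sample, sim$guide,
                           window = c(fit$window$left + shift,
                                      fit$window$right - 12L))
    expect_true(all(abs(alt$spectrum$percentage - fit$spectrum$percentage) < 2))
  }
})

test_that("quality checks flag poor background, poor fit and misplaced signal", {
  # clean self-decomposition: no warnings
  sim <- make_experiment(9, data.frame(size = 0, fraction = 1))
  fit <- decompose_trace(sim$control, sim$sample, sim$guide)
  expect_length(fit$quality, 0L)

  stub <- function(r2, eff) {
    structure(list(r_squared = r2, total_efficiency = eff),
              class = "decomp_result")
  }
  profile <- data.frame(pos = 0:199,
                        control = rep(0.02, 200),
                        sample = c(rep(0.02, 100), rep(0.6, 100)))
  expect_length(quality_check(profile, stub(0.99, 40), 100), 0L)
  expect_match(quality_check(profile, stub(0.85, 40), 100), "R-squared",
               all = FALSE)
  # 15% baseline aberrance in the control
  noisy <- profile
  noisy$control <- rep(0.15, 200)
  expect_match(quality_check(noisy, stub(0.99, 40), 100), "background",
               all = FALSE)
  # editing reported but no rise at the cut: misalignment
  flat <- data.frame(pos = 0:199, control = rep(0.02, 200),
                     sample = rep(0.03, 200))
  expect_match(quality_check(flat, stub(0.95, 30), 100), "misalign",
               all = FALSE)
})
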
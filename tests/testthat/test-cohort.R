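test_that("uniform sampling is in-bounds, unbiased and reproducible", {
  sp <- load_parameter_table("3L")
  n <- 5000
  X <- sample_inputs(sp, n, seed = 3)
  expect_identical(dim(X), c(5000L, 36L))
  expect_true(all(sweep(X, 2, sp$entries$lower, ">=") &
                    sweep(X, 2, sp$entries$upper, "<=")))
  # column means within 3 standard errors of the range midpoints
  mid <- (sp$entries$lower + sp$entries$upper) / 2
  rng <- sp$entries$upper - sp$entries$lower
  expect_true(all(abs(colMeans(X) - mid) <= 3 * rng / sqrt(12 * n)))
  expect_identical(X, sample_inputs(sp, n, seed = 3))
  expect_false(identical(X[1, ], sample_inputs(sp, n, seed = 4)[1, ]))
  expect_error(sample_inputs(sp, 0, seed = 1), "at least 1")
})

test_that("waveform QC separates sub- and super-cutoff content", {
  fs <- 1000
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  clean <- 100 * 133.322 + 40 * 133.322 * sin(2 * pi * 2 * t)
  qc <- qc_config()
  res <- qc_waveform(clean, qc)
  expect_lt(res$rms, 0.1)          # 2 Hz passes the 100 Hz low-pass intact
  expect_true(res$pass)
  dirty <- clean + 10 * sin(2 * pi * 150 * t)
  res2 <- qc_waveform(dirty, qc)
  # independent oracle: a second-order Butterworth at 1.5x the cut-off only
  # partially attenuates; the zero-phase (double-pass) amplitude gain with
  # bilinear prewarping is 1/(1 + (tan(pi f/fs)/tan(pi fc/fs))^4), so the
  # removed component has RMS A/sqrt(2) * (1 - gain)
  gain <- 1 / (1 + (tan(pi * 150 / fs) / tan(pi * 100 / fs))^4)
  expect_equal(res2$rms, 10 / sqrt(2) * (1 - gain), tolerance = 0.02)
  expect_gt(res2$rms, 4)
  expect_false(res2$pass)
  # far above the cut-off the contaminant is removed almost completely
  res3 <- qc_waveform(clean + 10 * sin(2 * pi * 400 * t), qc)
  expect_equal(res3$rms, 10 / sqrt(2), tolerance = 0.02)
  expect_error(qc_waveform(clean[1:4], qc), "too short")
  expect_error(qc_config(fc = 600), "Nyquist")
})

test_that("physiological filters apply the printed bounds", {
  stub <- make_stub_engine()
  g <- build_geometry("2L")
  ok <- stub(NULL, g, NULL)
  expect_true(apply_physiological_filters(ok)$accept)

  low_dia <- make_stub_engine(dia = 49)(NULL, g, NULL)
  f <- apply_physiological_filters(low_dia)
  expect_false(f$accept)
  expect_identical(f$reasons, "diastolic_low")

  # boundary: LM flow exactly 900 is inclusive
  lm900 <- make_stub_engine(lm_flow = 900)(NULL, g, NULL)
  expect_true(apply_physiological_filters(lm900)$accept)

  co7 <- make_stub_engine(co = 7)(NULL, g, NULL)
  f3 <- apply_physiological_filters(co7)
  expect_false(f3$accept)
  expect_identical(f3$reasons, "cardiac_output")

  failed <- structure(list(status = "solver_failure"),
                      class = "patient_simulation")
  expect_error(apply_physiological_filters(failed), "upstream")
})

test_that("cycle normalization preserves values and means", {
  expect_equal(normalize_cycle(rep(7, 123), period = 0.8), rep(7, 1000))
  x <- sin(2 * pi * seq(0, 1 - 1e-3, by = 1e-3))
  expect_equal(normalize_cycle(x, period = 1), x, tolerance = 1e-10)
  y <- 5 + sin(2 * pi * seq(0, 1 - 1 / 773, length.out = 773))
  expect_equal(mean(normalize_cycle(y, period = 0.9)), mean(y),
               tolerance = 1e-3)
  expect_error(normalize_cycle(x, period = 0), "positive")
})

test_that("the generator logs provenance exhaustively", {
  sp <- load_parameter_table("2L")
  fail_at <- c(3, 7, 11, 20, 21, 30, 33, 40, 41, 50)
  stub <- make_stub_engine(fail_index = fail_at)
  ch <- generate_cohort(sp, 50, seed = 5, simulate_fn = stub)
  expect_equal(nrow(ch$inputs), 40L)
  expect_setequal(ch$rejections$index, fail_at)
  expect_true(all(ch$rejections$reason == "solver_failure"))
  # accepted + rejected == requested
  expect_identical(nrow(ch$inputs) + nrow(ch$rejections), ch$n_requested)
})

test_that("generation is deterministic and filters are idempotent", {
  ch <- filtered_cohort_2l()
  sp <- ch$space
  ch_again <- generate_cohort(sp, 30, seed = 101)
  ch_small <- generate_cohort(sp, 30, seed = 101)
  expect_identical(ch_again$inputs, ch_small$inputs)
  expect_identical(ch_again$outputs, ch_small$outputs)
  # idempotence: every accepted patient passes the bounds read off outputs
  o <- ch$outputs
  expect_true(all(o$diastolic_mmHg > 50 & o$systolic_mmHg < 150 &
                    o$lm_flow >= 300 & o$lm_flow <= 900 &
                    o$cardiac_output >= 3.5 & o$cardiac_output <= 6))
  # provenance: requested = accepted + per-reason rejections
  expect_identical(nrow(ch$inputs) + nrow(ch$rejections), ch$n_requested)
  expect_true(all(ch$rejections$reason %in%
                    c("solver_failure", "oscillation", "diastolic_low",
                      "systolic_high", "lm_flow", "cardiac_output")))
})

test_that("filters-off keeps every usable run", {
  pre <- prefilter_cohort_2l()
  expect_false(pre$filters_on)
  expect_true(all(pre$rejections$reason %in% c("solver_failure", "oscillation")))
  # the pre-filter population includes out-of-bounds physiology
  o <- pre$outputs
  in_bounds <- o$diastolic_mmHg > 50 & o$systolic_mmHg < 150 &
    o$lm_flow >= 300 & o$lm_flow <= 900 &
    o$cardiac_output >= 3.5 & o$cardiac_output <= 6
  expect_gt(sum(!in_bounds), 0)
})

test_that("acceptance filtering induces input correlations", {
  ch <- filtered_cohort_2l()
  sp <- ch$space
  watch <- c("P_mean", "compliance_scale", "sigma_a0", "f_hyperemia", "q_tot")
  pre_model <- fit_gaussian_copula(sample_inputs(sp, 4000, seed = 700), sp)
  post_model <- fit_gaussian_copula(ch$inputs, sp)
  pre_R <- pre_model$R[watch, watch]
  post_R <- post_model$R[watch, watch]
  off <- upper.tri(pre_R)
  expect_true(all(abs(pre_R[off]) < 0.05))
  expect_gt(max(abs(post_R[off])), 0.05)
})
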
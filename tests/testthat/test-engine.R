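mid_params <- function(patient_type = "3L") {
  midpoint_vector(load_parameter_table(patient_type))
}

# named numeric copy that tolerates out-of-range edits (engine diagnostics)
raw_params <- function(pv) {
  v <- as.numeric(pv)
  names(v) <- names(pv)
  v
}

test_that("stenosis pressure drop matches its closed forms", {
  # no flow, no drop
  expect_identical(stenosis_pressure_drop(0, 50, 10, 0.15, 4.5e-3, 1050), 0)
  # zero severity: pure Poiseuille of the host lumen, no turbulent loss
  q <- 2
  r_m <- 0.15e-2
  expected <- 8 * 4.5e-3 * 0.01 / (pi * r_m^4) * 1e-6 * q
  expect_equal(stenosis_pressure_drop(q, 0, 10, 0.15, 4.5e-3, 1050), expected,
               tolerance = 1e-12)
  # independently evaluated two-term formula at 50% severity
  sev <- 50; L <- 10; r0 <- 0.15; eta <- 4.5e-3; rho <- 1050; kt <- 1.52
  rs <- r0 * 1e-2 * (1 - sev / 100)
  Rv <- 8 * eta * (L * 1e-3) / (pi * rs^4) * 1e-6
  A0 <- pi * (r0 * 1e-2)^2
  As <- pi * rs^2
  Kt <- kt * rho / (2 * A0^2) * (A0 / As - 1)^2 * 1e-12
  expect_equal(stenosis_pressure_drop(q, sev, L, r0, eta, rho),
               Rv * q + Kt * q^2, tolerance = 1e-12)
  # monotone in severity at fixed flow
  sev_grid <- seq(0, 90, by = 5)
  drops <- stenosis_pressure_drop(rep(q, length(sev_grid)), sev_grid,
                                  10, 0.15, 4.5e-3, 1050)
  expect_true(all(diff(drops) > 0))
  expect_error(stenosis_pressure_drop(1, 100, 10, 0.15, 4.5e-3, 1050),
               "severity")
})

test_that("compute_ffr is the ratio of time-averaged pressures", {
  x <- 100 + sin(seq(0, 6 * pi, length.out = 3000))
  expect_equal(compute_ffr(x, x), 1.0)
  pd <- rep(60 * 133.322, 3000)
  pa <- rep(80 * 133.322, 3000)
  expect_equal(compute_ffr(pd, pa), 0.75)
  expect_error(compute_ffr(pd, -pa), "positive")
  expect_error(compute_ffr(pd[1:10], pa), "equal length")
  # <= 0.8 marks a haemodynamically significant lesion
  expect_true(compute_ffr(pd, pa) <= 0.8)
})

test_that("hyperaemia divides every microvascular resistance, nothing else", {
  micro <- microcirculation_state(6000, c(0.26, 0.33, 0.33, 0.08),
                                  c(2e-4, 5e-4, 6e-4), pim_frac = 0.75)
  same <- apply_hyperaemia(micro, 1)
  expect_equal(same, micro)
  h <- apply_hyperaemia(micro, 4)
  for (nm in c("R_art", "R_myo1", "R_myo2", "R_ven")) {
    expect_equal(h[[nm]], micro[[nm]] / 4)
  }
  for (nm in c("C_art", "C_myo", "C_ven", "pim_frac")) {
    expect_equal(h[[nm]], micro[[nm]])
  }
  expect_error(apply_hyperaemia(micro, 0.5), ">= 1")
  # in a series epicardial+microvascular network the flow gain stays below f
  R_epi <- 200; R_mic <- 2000; dp <- 12000
  for (f in c(2, 3, 5)) {
    gain <- (dp / (R_epi + R_mic / f)) / (dp / (R_epi + R_mic))
    expect_lt(gain, f)
  }
})

test_that("microcirculation fractions renormalize with a venous floor", {
  m <- microcirculation_state(1000, c(0.2, 0.3, 0.3, 0), c(1, 1, 1) * 1e-4,
                              0.5, rven_floor = 0.02)
  total <- m$R_art + m$R_myo1 + m$R_myo2 + m$R_ven
  expect_equal(total, 1000, tolerance = 1e-9)
  expect_gte(m$R_ven, 0.02 / 1.02 * 1000 - 1e-9)
})

test_that("mid-range simulation honours the mean-pressure contract", {
  sim <- cached("sim_mid_3l", simulate_patient(mid_params(), build_geometry("3L")))
  expect_identical(sim$status, "ok")
  target <- 100 * 133.322
  expect_lt(abs(sim$meta$mean_pao - target) / target, 0.01)
  expect_length(sim$aortic_pressure, 3000L)   # 1000 points per analyzed cycle
  expect_true(all(is.finite(sim$aortic_pressure)))
  # periodic steady state: last two cycles agree within 1% RMS
  c2 <- sim$aortic_pressure[1001:2000]
  c3 <- sim$aortic_pressure[2001:3000]
  expect_lt(sqrt(mean((c3 - c2)^2)) / mean(c3), 0.01)
})

test_that("healthy vessels give FFR near one; severity and hyperaemia depress it", {
  g <- build_geometry("3L")
  base <- raw_params(mid_params())
  v0 <- base
  v0[c("sev_LAD", "sev_LCx", "sev_RCA")] <- 0
  sim0 <- simulate_patient(v0, g)
  expect_identical(sim0$status, "ok")
  expect_true(all(sim0$ffr >= 0.95))
  # FFR monotone non-increasing in severity
  ffr_lad <- sapply(c(30, 50, 70), function(s) {
    v <- base; v["sev_LAD"] <- s
    simulate_patient(v, g)$ffr[["LAD"]]
  })
  expect_true(all(diff(ffr_lad) < 0))
  # and non-increasing in the hyperaemia factor
  ffr_f <- sapply(c(2, 3.5, 5), function(f) {
    v <- base; v["f_hyperemia"] <- f
    simulate_patient(v, g)$ffr[["LAD"]]
  })
  expect_true(all(diff(ffr_f) < 0))
})

test_that("every input parameter is live", {
  sp <- load_parameter_table("3L")
  g <- build_geometry("3L")
  base <- raw_params(midpoint_vector(sp))
  ref <- simulate_patient(base, g)
  summary_of <- function(sim) {
    c(sim$ffr, co = sim$cardiac_output, lm = sim$lm_flow,
      sys = max(sim$aortic_pressure), dia = min(sim$aortic_pressure))
  }
  ref_s <- summary_of(ref)
  for (j in seq_len(sp$dimension)) {
    v <- base
    v[j] <- v[j] + 0.1 * (sp$entries$upper[j] - sp$entries$lower[j])
    sim <- simulate_patient(v, g)
    expect_identical(sim$status, "ok")
    expect_gt(max(abs(summary_of(sim) - ref_s)), 0,
              label = paste("output response to", sp$entries$name[j]))
  }
})

test_that("simulation is deterministic and respects patient-type pairing", {
  g <- build_geometry("2L")
  pv <- midpoint_vector(load_parameter_table("2L"))
  s1 <- simulate_patient(pv, g)
  s2 <- simulate_patient(pv, g)
  expect_identical(s1$ffr, s2$ffr)
  expect_identical(s1$aortic_pressure, s2$aortic_pressure)
  expect_error(simulate_patient(pv, build_geometry("3L")), "patient types")
  expect_named(s1$ffr, c("LAD", "RCA"))
})
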
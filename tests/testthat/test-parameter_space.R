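test_that("parameter spaces have the exact printed dimensions", {
  sp2 <- load_parameter_table("2L")
  sp3 <- load_parameter_table("3L")
  expect_s3_class(sp2, "parameter_space")
  expect_identical(sp2$dimension, 34L)
  expect_identical(sp3$dimension, 36L)
  # 29 scalars + 2 per lesion + 1 shared position
  n_lesion2 <- sum(grepl("^(sev|len)_", sp2$entries$name))
  n_lesion3 <- sum(grepl("^(sev|len)_", sp3$entries$name))
  expect_identical(n_lesion2, 4L)
  expect_identical(n_lesion3, 6L)
  expect_identical(sp2$dimension - n_lesion2 - 1L, 29L)
  expect_identical(sp3$dimension - n_lesion3 - 1L, 29L)
  expect_error(load_parameter_table("4L"), "unknown patient type")
})

test_that("parameter table carries the printed ranges and units", {
  sp <- load_parameter_table("3L")
  tab <- sp$entries
  expect_false(anyDuplicated(tab$name) > 0)
  expect_true(all(tab$lower < tab$upper))
  row <- function(nm) tab[tab$name == nm, ]
  expect_equal(unlist(row("len_LAD")[c("lower", "upper")]),
               c(lower = 3, upper = 37))
  expect_equal(unlist(row("len_LCx")[c("lower", "upper")]),
               c(lower = 3, upper = 17))
  expect_equal(unlist(row("len_RCA")[c("lower", "upper")]),
               c(lower = 3, upper = 17))
  for (v in c("LAD", "LCx", "RCA")) {
    expect_equal(unlist(row(paste0("sev_", v))[c("lower", "upper")]),
                 c(lower = 30, upper = 70))
  }
  expect_equal(row("P_mean")$unit, "mmHg")
  # the two myocardial fractions are separate entries sharing one range
  expect_equal(row("R_myo1_frac")[c("lower", "upper")],
               row("R_myo2_frac")[c("lower", "upper")],
               ignore_attr = TRUE)
})

test_that("parameter vectors are validated against their space", {
  sp <- load_parameter_table("2L")
  pv <- midpoint_vector(sp)
  expect_length(pv, 34L)
  expect_identical(names(pv), sp$entries$name)
  bad <- as.numeric(pv)
  bad[1] <- sp$entries$upper[1] + 1
  expect_error(parameter_vector(sp, bad), "out of bounds")
  expect_error(parameter_vector(sp, bad[-1]), "length")
})

test_that("Murray's law daughter radius matches the cube-root closure", {
  expect_equal(murray_daughter_radius(0.2, 0.1), (0.008 - 0.001)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(murray_daughter_radius(0.2, 0.1), 0.19129, tolerance = 1e-4)
  # side radius -> 0 leaves the mother radius unchanged
  expect_equal(murray_daughter_radius(0.15, 1e-9), 0.15, tolerance = 1e-9)
  expect_error(murray_daughter_radius(0.1, 0.1), "degenerate")
  expect_error(murray_daughter_radius(0.1, 0.2), "degenerate")
})

test_that("coronary geometry satisfies its structural invariants", {
  for (pt in c("2L", "3L")) {
    g <- build_geometry(pt)
    seg <- g$segments
    main <- seg[!seg$side, ]
    expect_equal(sum(main$length_cm[main$vessel == "LM"]), 2)
    expect_equal(sum(main$length_cm[main$vessel == "LAD"]), 10)
    expect_equal(sum(main$length_cm[main$vessel == "RCA"]), 10)
    expect_equal(sum(main$length_cm[main$vessel == "LCx"]), 8)
    expect_true(all(seg$radius_cm[seg$side] == 0.1))
    expect_equal(seg$wall_cm, 0.1 * seg$radius_cm, tolerance = 1e-12)
    # radii non-increasing distally along each main line
    for (v in c("LAD", "LCx", "RCA")) {
      r <- main$radius_cm[main$vessel == v]
      expect_true(all(diff(r) <= 1e-12))
    }
  }
})

test_that("Murray closure holds at every bifurcation to 1e-12 relative", {
  g <- build_geometry("3L")
  seg <- g$segments
  main <- seg[!seg$side, ]
  # LM split into LAD and LCx
  r_lm <- main$radius_cm[main$vessel == "LM"][1]
  r_lad <- main$radius_cm[main$vessel == "LAD"][1]
  r_lcx <- main$radius_cm[main$vessel == "LCx"][1]
  expect_equal(r_lm^3, r_lad^3 + r_lcx^3, tolerance = 1e-12)
  # every within-vessel taper balances against the 0.1 cm side branch
  for (v in c("LAD", "LCx", "RCA")) {
    r <- main$radius_cm[main$vessel == v]
    for (i in seq_len(length(r) - 1)) {
      expect_equal(r[i]^3, r[i + 1]^3 + g$side_radius^3, tolerance = 1e-12)
    }
  }
})

test_that("lesion slots follow the patient type", {
  expect_setequal(build_geometry("2L")$lesion_slots$segment, c("C1", "C7"))
  expect_setequal(build_geometry("3L")$lesion_slots$segment,
                  c("C1", "C7", "C11"))
  g <- build_geometry("3L")
  expect_equal(g$lesion_slots$vessel[g$lesion_slots$segment == "C11"], "LCx")
  # geometry is independent of any sampled parameters: two builds identical
  expect_identical(build_geometry("3L"), build_geometry("3L"))
})
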
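test_that("linear-Gaussian closed forms are recovered within 1e-3", {
  for (rho in c(0, 0.5, -0.5)) {
    b <- make_benchmark("linear_gaussian", rho = rho)
    r <- full_analysis(b$f, b$model, accuracy = 4)
    for (col in c("S_TC", "S_TU", "S_U", "S_C", "S_IU")) {
      expect_equal(r$indices[[col]], b$analytic[[col]], tolerance = 1e-3,
                   label = sprintf("%s at rho=%g", col, rho))
    }
    expect_equal(r$mean, b$mean, tolerance = 1e-6)
    expect_equal(r$variance, b$variance, tolerance = 1e-3)
  }
  # asymmetric coefficients
  b2 <- make_benchmark("linear_gaussian", rho = 0.3, a = c(2, 1))
  r2 <- full_analysis(b2$f, b2$model, accuracy = 4)
  expect_equal(r2$indices$S_TC, b2$analytic$S_TC, tolerance = 1e-3)
  expect_equal(r2$indices$S_TU, b2$analytic$S_TU, tolerance = 1e-3)
})

test_that("a five-dimensional correlated linear model matches closed forms", {
  d <- 5
  rho <- 0.5
  R <- diag(d)
  R[1, 2] <- R[2, 1] <- rho
  marg <- rep(list(list(type = "normal", mean = 0, sd = 1)), d)
  names(marg) <- paste0("x", 1:d)
  model <- correlation_model(R, marg)
  a <- c(1, 1, 2, 0.5, 0)
  f <- function(x) as.numeric(x %*% a)
  V <- sum(a^2) + 2 * rho * a[1] * a[2]
  r <- full_analysis(f, model, accuracy = 4)
  stc_exact <- c((a[1] + rho * a[2])^2, (a[2] + rho * a[1])^2,
                 a[3]^2, a[4]^2, 0) / V
  stu_exact <- c(a[1]^2 * (1 - rho^2), a[2]^2 * (1 - rho^2),
                 a[3]^2, a[4]^2, 0) / V
  expect_equal(r$indices$S_TC, stc_exact, tolerance = 1e-3)
  expect_equal(r$indices$S_TU, stu_exact, tolerance = 1e-3)
  expect_equal(r$indices$S_U, stu_exact, tolerance = 1e-3)
  # output independent of x5 has all indices zero
  expect_lt(max(abs(as.numeric(r$indices[5, -1]))), 1e-9)
})

test_that("independent Ishigami reduces to the classical Sobol indices", {
  b <- make_benchmark("ishigami_independent")
  # accuracy 7 is the converged level for this non-polynomial integrand;
  # see the convergence test below for the level-4 behaviour
  r <- full_analysis(b$f, b$model, accuracy = 7)
  expect_equal(r$variance, 13.8445, tolerance = 1e-3)
  expect_equal(r$indices$S_TC, b$analytic$S_TC, tolerance = 1e-2)
  expect_equal(r$indices$S_TU, b$analytic$S_TU, tolerance = 1e-2)
  expect_equal(r$indices$S_TC[1], 0.3139, tolerance = 1e-2)
  expect_equal(r$indices$S_TU[3], 0.2437, tolerance = 1e-2)
  # under independence S^C vanishes and S^U equals S^TC
  expect_lt(max(abs(r$indices$S_C)), 1e-6)
  expect_equal(r$indices$S_U, r$indices$S_TC, tolerance = 1e-6)
})

test_that("decomposition identities hold exactly by construction", {
  b <- make_benchmark("linear_gaussian", rho = 0.4)
  r <- full_analysis(b$f, b$model, accuracy = 3)
  expect_identical(r$indices$S_C, r$indices$S_TC - r$indices$S_U)
  expect_identical(r$indices$S_IU, r$indices$S_TU - r$indices$S_U)
  ba <- make_benchmark("additive_uniform")
  ra <- full_analysis(ba$f, ba$model, accuracy = 3)
  expect_lt(max(abs(ra$indices$S_IU)), 1e-10)
  expect_lt(max(abs(ra$indices$S_C)), 1e-10)
  expect_equal(ra$indices$S_U, ba$analytic$S_U, tolerance = 1e-10)
})

test_that("single-index entry points agree with the full analysis", {
  b <- make_benchmark("linear_gaussian", rho = 0.5)
  v <- estimate_moments(b$f, b$model, 4)$variance
  expect_equal(total_correlated_index(b$f, b$model, 1, 4, variance = v),
               0.75, tolerance = 1e-6)
  expect_equal(total_uncorrelated_index(b$f, b$model, 1, 4, variance = v),
               0.25, tolerance = 1e-6)
  expect_equal(uncorrelated_main_index(b$f, b$model, 1, 4, variance = v),
               0.25, tolerance = 1e-6)
})

test_that("index estimates agree with a double-loop Monte-Carlo oracle", {
  # correlated tri-variate model with a nonlinear response
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.5
  marg <- rep(list(list(type = "uniform", lower = 0, upper = 1)), 3)
  names(marg) <- c("a", "b", "c")
  model <- correlation_model(R, marg)
  f <- function(x) x[, 1]^2 + x[, 1] * x[, 2] + 0.5 * x[, 3]
  r <- full_analysis(f, model, accuracy = 6)

  # S^TC_1 oracle: V(E(Y|X1)) by conditional sampling on a fine stratification
  set.seed(61)
  n_out <- 1000L; n_in <- 1000L
  u1 <- (seq_len(n_out) - 0.5) / n_out
  cm <- vapply(u1, function(u) {
    U <- cbind(rep(u, n_in), matrix(runif(2 * n_in), ncol = 2))
    mean(f(inverse_rosenblatt(U, model, ordering = c(1, 2, 3))))
  }, numeric(1))
  y_all <- f(sample_copula(model, 2e5, seed = 62))
  v_mc <- var(y_all)
  stc1_mc <- var(cm) / v_mc
  se <- 3 * stc1_mc * sqrt(2 / n_out)   # generous 3-sigma band
  expect_equal(r$indices$S_TC[1], stc1_mc, tolerance = max(se, 0.02))
  expect_equal(r$variance, v_mc, tolerance = 0.01 * v_mc * 3)
})

test_that("benchmark convergence improves from accuracy 2 to 4", {
  b <- make_benchmark("ishigami_independent")
  idx <- lapply(2:4, function(k) {
    full_analysis(b$f, b$model, accuracy = k)$indices
  })
  d23 <- max(abs(idx[[2]]$S_TC - idx[[1]]$S_TC),
             abs(idx[[2]]$S_TU - idx[[1]]$S_TU))
  d34 <- max(abs(idx[[3]]$S_TC - idx[[2]]$S_TC),
             abs(idx[[3]]$S_TU - idx[[2]]$S_TU))
  expect_lt(d34, d23)
})

test_that("key-driver ranking respects its threshold", {
  b <- make_benchmark("additive_uniform")
  r <- full_analysis(b$f, b$model, accuracy = 3)
  top <- rank_key_drivers(r, threshold = 0.05)
  expect_identical(top$input[1], "x3")
  expect_true(all(diff(top$max_index) <= 0))
  expect_identical(nrow(rank_key_drivers(r, threshold = 0)), 3L)
  expect_identical(nrow(rank_key_drivers(r, threshold = 2)), 0L)
})

test_that("the bar-chart report draws the key drivers", {
  b <- make_benchmark("additive_uniform")
  r <- full_analysis(b$f, b$model, accuracy = 3)
  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path)
  mids <- plot(r, threshold = 0.05)
  grDevices::dev.off()
  expect_identical(ncol(mids), 3L)   # three qualifying inputs
  expect_true(file.exists(png_path))
  expect_warning(plot(r, threshold = 2), "nothing to plot")
  unlink(png_path)
})

test_that("benchmark factory validates its argument", {
  expect_error(make_benchmark("unknown_thing"), "arg")
  b <- make_benchmark("linear_gaussian", rho = 0.5)
  expect_identical(names(b$model$marginals), c("x1", "x2"))
})
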
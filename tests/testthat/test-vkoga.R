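test_that("Matern k2 kernel matches its printed formula", {
  expect_equal(matern_k2_kernel(1, 0), 3)
  # eps * r = 1: exp(-1) * (3 + 3 + 1) = 7/e
  expect_equal(matern_k2_kernel(2, 0.5), 7 / exp(1), tolerance = 1e-12)
  r <- seq(0, 10, by = 0.05)
  expect_true(all(diff(matern_k2_kernel(0.7, r)) < 0))
  expect_error(matern_k2_kernel(-1, 1), "positive")
  expect_error(matern_k2_kernel(1, -0.5), "non-negative")
})

test_that("f-greedy picks the largest residual first and drives it down", {
  set.seed(51)
  X <- matrix(runif(200 * 3), ncol = 3)
  y <- sin(2 * pi * X[, 1]) + X[, 2]^2
  m <- train_vkoga(X, y, eps = 2, max_centers = 60,
                   scaling = list(lower = rep(0, 3), upper = rep(1, 3)))
  # first center is the argmax of |y| (surrogate starts at zero)
  expect_equal(as.numeric(m$centers[1, ]), as.numeric(X[which.max(abs(y)), ]))
  expect_equal(m$history[1], max(abs(y)))
  # the max residual decays strongly overall; per-step monotonicity is not
  # guaranteed for f-greedy (only the selected point is zeroed), so assert
  # a monotone envelope: the running minimum over quarters decreases
  h <- m$history
  q <- split(h, cut(seq_along(h), 4, labels = FALSE))
  expect_true(all(diff(vapply(q, min, numeric(1))) < 0))
  expect_lt(tail(h, 1), 0.05 * h[1])
})

test_that("functions in the kernel span are recovered exactly", {
  # training on exactly the m centers of a kernel-span function must
  # reproduce it globally (uniqueness of kernel interpolation)
  set.seed(52)
  d <- 4
  Xc <- matrix(runif(15 * d), ncol = d)
  alpha_true <- rnorm(15)
  kf <- function(A, B) matern_k2_kernel(1.5, corovpc:::cross_dist(A, B))
  y <- as.numeric(kf(Xc, Xc) %*% alpha_true)
  m <- train_vkoga(Xc, y, eps = 1.5, max_centers = 20, tolerance = 1e-10,
                   scaling = list(lower = rep(0, d), upper = rep(1, d)))
  expect_lte(nrow(m$centers), 15L)
  Xnew <- matrix(runif(300 * d), ncol = d)
  expect_lt(max(abs(predict(m, Xnew) - kf(Xnew, Xc) %*% alpha_true)), 1e-7)
})

test_that("prediction interpolates the training values at the centers", {
  set.seed(53)
  X <- matrix(runif(120 * 2), ncol = 2)
  y <- exp(-X[, 1]) * cos(3 * X[, 2])
  m <- train_vkoga(X, y, eps = 1, max_centers = 120, tolerance = 1e-9,
                   scaling = list(lower = c(0, 0), upper = c(1, 1)))
  span <- m$scaling$upper - m$scaling$lower
  Xc_orig <- sweep(sweep(m$centers, 2, span, "*"), 2, m$scaling$lower, "+")
  expect_lt(max(abs(predict(m, Xc_orig) -
                      y[match(round(m$centers[, 1], 10),
                              round(X[, 1], 10))])), 1e-6)
  # batch and single-point evaluation agree (up to BLAS summation order)
  single <- vapply(1:5, function(i) predict(m, X[i, ]), numeric(1))
  expect_equal(single, predict(m, X[1:5, ]), tolerance = 1e-10)
  # zero coefficients give the zero surrogate
  m0 <- m
  m0$coefficients <- rep(0, length(m$coefficients))
  expect_equal(predict(m0, X[1:7, ]), rep(0, 7))
  expect_error(predict(m, X[, 1, drop = FALSE]), "columns")
})

test_that("duplicate rows are dropped with a warning", {
  X <- matrix(runif(40), ncol = 2)
  X <- rbind(X, X[1:3, ])
  y <- X[, 1] + X[, 2]
  expect_warning(
    m <- train_vkoga(X, y, eps = 1, max_centers = 10,
                     scaling = list(lower = c(0, 0), upper = c(1, 1))),
    "duplicate")
  expect_error(train_vkoga(X[0, , drop = FALSE], numeric(0)), "non-empty")
})

test_that("error metrics match hand calculations", {
  expect_equal(rmse_nrmse(c(1, 2, 3), c(1, 2, 3)), list(rmse = 0, nrmse = 0))
  expect_equal(rmse_nrmse(c(2, 3), c(1, 2))$rmse, 1)
  d <- c(0.01, -0.02, 0.02)
  expect_equal(rmse_nrmse(0.5 + d, rep(0.5, 3))$rmse, sqrt(0.0009 / 3),
               tolerance = 1e-12)
  expect_equal(rmse_nrmse(0.5 + d, rep(0.5, 3))$rmse, 0.017321,
               tolerance = 1e-4)
  expect_error(rmse_nrmse(c(1, -1), c(1, -1))$nrmse, "zero")
})

test_that("Bland-Altman limits of agreement are mean +/- 1.96 sd", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ba0[1:3]), c(mean_diff = 0, upper_loa = 0, lower_loa = 0))
  ba1 <- bland_altman(c(1.05, 2.05), c(1, 2))
  expect_equal(ba1$mean_diff, 0.05)
  expect_equal(ba1$upper_loa, 0.05, tolerance = 1e-12)
  set.seed(54)
  dd <- rnorm(500, sd = 0.3)
  ba2 <- bland_altman(dd, rep(0, 500))
  expect_equal(ba2$upper_loa - ba2$mean_diff, 1.96 * sd(dd), tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "at least two")
})

test_that("surrogate JSON round trip preserves predictions exactly", {
  set.seed(55)
  X <- matrix(runif(150 * 3), ncol = 3)
  y <- X[, 1] * X[, 2] + sin(X[, 3])
  m <- train_vkoga(X, y, eps = 1, max_centers = 50,
                   scaling = list(lower = rep(0, 3), upper = rep(1, 3)))
  path <- tempfile(fileext = ".json")
  save_surrogate(m, path)
  m2 <- load_surrogate(path)
  probe <- matrix(runif(60), ncol = 3)
  expect_identical(predict(m, probe), predict(m2, probe))
  # tampered schema is rejected
  txt <- sub("corovpc_surrogate_v1", "other_schema", readLines(path))
  writeLines(txt, path)
  expect_error(load_surrogate(path), "schema")
})
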
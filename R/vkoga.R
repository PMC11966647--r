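# Kernel greedy (VKOGA) surrogate of per-lesion FFR: Matern k2 kernel,
# f-greedy center selection with Newton-basis updates, and validation
# metrics (RMSE / nRMSE, Bland-Altman limits of agreement).

#' Matern k2 radial basis function
#'
#' `K(eps, r) = exp(-eps r) (3 + 3 eps r + (eps r)^2)`, a twice
#' mean-square-differentiable Matern kernel; `eps` is the shape parameter
#' and `r` the (non-negative) radial distance.
#'
#' @param eps shape parameter, positive.
#' @param r distances, non-negative (vector or matrix).
#' @return kernel values, same shape as `r`.
#' @export
matern_k2_kernel <- function(eps, r) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  if (any(r < 0)) stop("distances must be non-negative")
  er <- eps * r
  exp(-er) * (3 + 3 * er + er^2)
}

#' Gaussian radial basis function (comparison kernel)
#' @param eps shape parameter, positive.
#' @param r distances, non-negative.
#' @return kernel values.
#' @export
gaussian_kernel <- function(eps, r) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  if (any(r < 0)) stop("distances must be non-negative")
  exp(-(eps * r)^2)
}

kernel_fun <- function(kernel_id) {
  switch(kernel_id,
         matern_k2 = matern_k2_kernel,
         gaussian = gaussian_kernel,
         stop("unknown kernel: ", kernel_id))
}

# pairwise Euclidean distances between rows of A (m x d) and B (n x d)
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Train a kernel greedy (VKOGA) surrogate
#'
#' f-greedy kernel interpolation: starting from the zero surrogate, the
#' training point with the largest absolute residual is added as a center at
#' each step, using numerically stable Newton-basis updates; training stops
#' at `max_centers` centers or when the maximum residual drops to
#' `tolerance`. Inputs are min-max scaled to the unit cube before distance
#' computation (scaling is stored in the model). When `eps` is `NULL` the
#' shape parameter is selected on a held-out split of the training data over
#' a log-spaced grid.
#'
#' @param X training inputs (n x d matrix).
#' @param y training outputs (length n).
#' @param kernel `"matern_k2"` (default) or `"gaussian"`.
#' @param max_centers maximum number of greedy centers.
#' @param tolerance residual stopping tolerance.
#' @param eps shape parameter; `NULL` for grid-search selection.
#' @param eps_grid candidate shape parameters for the grid search.
#' @param holdout_frac fraction of the training data held out for the grid
#'   search.
#' @param scaling optional list with `lower`/`upper` vectors fixing the
#'   unit-cube scaling (defaults to the column ranges of `X`).
#' @param seed seed for the grid-search split.
#' @return object of class `kernel_surrogate` with fields `kernel`, `eps`,
#'   `centers` (scaled), `coefficients`, `scaling`, `history` (per-iteration
#'   maximum residual) and `meta`.
#' @export
train_vkoga <- function(X, y, kernel = "matern_k2", max_centers = 500L,
                        tolerance = 1e-5, eps = NULL,
                        eps_grid = 10^seq(-1, 1, length.out = 5),
                        holdout_frac = 0.2, scaling = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0 || length(y) != n) stop("X and y must be non-empty and conforming")
  if (is.null(scaling)) {
    scaling <- list(lower = apply(X, 2, min), upper = apply(X, 2, max))
  }
  span <- scaling$upper - scaling$lower
  span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, scaling$lower, "-"), 2, span, "/")

  dup <- duplicated(Xs)
  if (any(dup)) {
    warning(sum(dup), " duplicate training rows dropped")
    Xs <- Xs[!dup, , drop = FALSE]
    y <- y[!dup]
    n <- nrow(Xs)
  }

  if (is.null(eps)) {
    set.seed(as.integer(seed))
    n_hold <- max(1L, round(holdout_frac * n))
    hold <- sample.int(n, n_hold)
    best <- Inf
    eps_sel <- eps_grid[1]
    kf <- kernel_fun(kernel)
    Xtr <- Xs[-hold, , drop = FALSE]
    for (e in eps_grid) {
      fit <- vkoga_greedy(Xtr, y[-hold], kernel, e,
                          min(max_centers, 200L), tolerance)
      K <- kf(e, cross_dist(Xs[hold, , drop = FALSE],
                            Xtr[fit$idx, , drop = FALSE]))
      pred <- as.numeric(K %*% fit$alpha)
      err <- sqrt(mean((pred - y[hold])^2))
      if (err < best) {
        best <- err
        eps_sel <- e
      }
    }
    eps <- eps_sel
  }

  fit <- vkoga_greedy(Xs, y, kernel, eps, max_centers, tolerance)
  structure(list(
    kernel = kernel, eps = eps,
    centers = Xs[fit$idx, , drop = FALSE],
    coefficients = fit$alpha,
    scaling = scaling,
    history = fit$history,
    meta = list(n_train = n, max_centers = max_centers,
                tolerance = tolerance, seed = seed)),
    class = "kernel_surrogate")
}

# core f-greedy Newton-basis loop on pre-scaled inputs
vkoga_greedy <- function(Xs, y, kernel, eps, max_centers, tolerance) {
  kf <- kernel_fun(kernel)
  n <- nrow(Xs)
  m <- min(max_centers, n)
  k0 <- kf(eps, 0)
  V <- matrix(0, n, m)          # Newton basis values on training set
  p2 <- rep(k0, n)              # squared power function
  r <- y                        # residual
  idx <- integer(0)
  cN <- numeric(0)              # Newton coefficients
  history <- numeric(0)
  for (j in seq_len(m)) {
    i_new <- which.max(abs(r))
    history[j] <- abs(r[i_new])
    if (abs(r[i_new]) <= tolerance) break
    if (p2[i_new] <= 1e-13 * k0) break   # numerically dependent center
    pj <- sqrt(p2[i_new])
    kcol <- kf(eps, cross_dist(Xs, Xs[i_new, , drop = FALSE]))[, 1]
    vj <- if (length(idx) > 0) {
      (kcol - V[, seq_along(idx), drop = FALSE] %*% V[i_new, seq_along(idx)]) / pj
    } else {
      kcol / pj
    }
    vj <- as.numeric(vj)
    cj <- r[i_new] / pj
    idx <- c(idx, i_new)
    cN <- c(cN, cj)
    V[, length(idx)] <- vj
    r <- r - cj * vj
    p2 <- pmax(p2 - vj^2, 0)
  }
  nc <- length(idx)
  # convert Newton coefficients to kernel-expansion coefficients:
  # L (lower triangular) holds the Newton basis evaluated at the centers
  L <- V[idx, seq_len(nc), drop = FALSE]
  alpha <- backsolve(t(L), cN)
  list(idx = idx, alpha = alpha, history = history[seq_len(nc)])
}

#' Predict with a kernel surrogate
#'
#' Evaluates the kernel expansion `S(x) = sum_j alpha_j K(x, x_j)` with the
#' stored unit-cube scaling.
#'
#' @param object a `kernel_surrogate`.
#' @param newdata matrix (m x d) or vector (length d) of inputs in the
#'   original units.
#' @param ... unused.
#' @return numeric predictions of length m.
#' @export
predict.kernel_surrogate <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$centers)) {
    stop("newdata has ", ncol(newdata), " columns; surrogate expects ",
         ncol(object$centers))
  }
  span <- object$scaling$upper - object$scaling$lower
  span[span == 0] <- 1
  Xs <- sweep(sweep(newdata, 2, object$scaling$lower, "-"), 2, span, "/")
  kf <- kernel_fun(object$kernel)
  K <- kf(object$eps, cross_dist(Xs, object$centers))
  as.numeric(K %*% object$coefficients)
}

#' @export
print.kernel_surrogate <- function(x, ...) {
  cat(sprintf("<kernel_surrogate> %s kernel, eps = %.4g, %d centers (n_train = %d)\n",
              x$kernel, x$eps, nrow(x$centers), x$meta$n_train))
  invisible(x)
}

#' Root mean square error and normalized RMSE
#'
#' `rmse = sqrt(mean((pred - ref)^2))`; `nrmse = rmse / mean(ref)`.
#'
#' @param predictions,references numeric vectors of equal length.
#' @return list with `rmse` and `nrmse`.
#' @export
rmse_nrmse <- function(predictions, references) {
  if (length(predictions) != length(references) || length(references) == 0) {
    stop("predictions and references must be non-empty and of equal length")
  }
  rmse <- sqrt(mean((predictions - references)^2))
  mref <- mean(references)
  if (mref == 0) stop("nRMSE undefined: reference mean is zero")
  list(rmse = rmse, nrmse = rmse / mref)
}

#' Bland-Altman agreement statistics
#'
#' Mean difference and 95% limits of agreement
#' (`mean +/- 1.96 sd` of the differences).
#'
#' @param predictions,references numeric vectors of equal length, `n >= 2`.
#' @return list with `mean_diff`, `upper_loa`, `lower_loa`, `sd_diff`.
#' @export
bland_altman <- function(predictions, references) {
  if (length(predictions) != length(references) || length(references) < 2) {
    stop("need at least two paired values")
  }
  d <- predictions - references
  m <- mean(d)
  s <- sd(d)
  list(mean_diff = m, upper_loa = m + 1.96 * s, lower_loa = m - 1.96 * s,
       sd_diff = s)
}

#' Deterministic train/test split
#'
#' Splits indices with at least `n_train` training rows (all remaining rows
#' become the test set), reproducibly for a seed.
#'
#' @param n total number of rows.
#' @param n_train minimum training rows (default 2500).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
train_test_split <- function(n, n_train = 2500L, seed = 1L) {
  if (n <= n_train) stop("need more than n_train rows to split")
  set.seed(as.integer(seed))
  tr <- sort(sample.int(n, n_train))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Save a kernel surrogate to JSON
#' @param model a `kernel_surrogate`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "kernel_surrogate"))
  obj <- list(schema = "corovpc_surrogate_v1",
              kernel = model$kernel, eps = model$eps,
              centers = model$centers, coefficients = model$coefficients,
              scaling = model$scaling, history = model$history,
              meta = model$meta)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a kernel surrogate from JSON
#' @param path file written by [save_surrogate()].
#' @return a `kernel_surrogate`.
#' @export
load_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "corovpc_surrogate_v1")) {
    stop("schema mismatch: not a corovpc surrogate file")
  }
  structure(list(kernel = obj$kernel, eps = obj$eps,
                 centers = as.matrix(obj$centers),
                 coefficients = as.numeric(obj$coefficients),
                 scaling = list(lower = as.numeric(obj$scaling$lower),
                                upper = as.numeric(obj$scaling$upper)),
                 history = as.numeric(obj$history),
                 meta = obj$meta),
            class = "kernel_surrogate")
}
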
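# Gaussian-copula dependence model over the cohort inputs: rank-based
# correlation recovery and the (inverse) Rosenblatt transform consumed by
# the correlated sensitivity analysis.

#' Construct a correlation model
#'
#' A Gaussian copula over named inputs: a correlation matrix in the latent
#' normal space plus per-input marginal distributions. Marginals are
#' `uniform(lower, upper)` (the cohort default) or `normal(mean, sd)` (used
#' by the analytic benchmarks).
#'
#' @param R correlation matrix (symmetric, unit diagonal, PSD up to a small
#'   tolerance, repaired by eigenvalue clipping when the violation is below
#'   `psd_tol`).
#' @param marginals list of per-input specs, each
#'   `list(type = "uniform", lower=, upper=)` or
#'   `list(type = "normal", mean=, sd=)`. Named, in the input ordering.
#' @param psd_tol largest admissible PSD violation (most negative eigenvalue)
#'   that is silently repaired; larger violations error.
#' @return object of class `correlation_model` with elements `R`,
#'   `marginals`, `names`, `d`.
#' @export
correlation_model <- function(R, marginals, psd_tol = 1e-6) {
  R <- as.matrix(R)
  d <- nrow(R)
  stopifnot(ncol(R) == d, length(marginals) == d)
  if (max(abs(R - t(R))) > 1e-10) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stop("R must have a unit diagonal")
  if (max(abs(R)) > 1 + 1e-10) stop("|R_ij| must not exceed 1")
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam_min <- min(ev$values)
  if (lam_min < -psd_tol) {
    stop(sprintf("R is not positive semi-definite (min eigenvalue %.3g)", lam_min))
  }
  if (lam_min < 0) {
    # nearest-PSD repair by eigenvalue clipping + diagonal renormalization
    lam <- pmax(ev$values, 0)
    R <- ev$vectors %*% (lam * t(ev$vectors))
    s <- 1 / sqrt(diag(R))
    R <- R * (s %o% s)
    R <- (R + t(R)) / 2
  }
  nms <- names(marginals)
  if (is.null(nms)) nms <- paste0("x", seq_len(d))
  dimnames(R) <- list(nms, nms)
  structure(list(R = R, marginals = marginals, names = nms, d = d),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  off <- x$R[upper.tri(x$R)]
  cat(sprintf("<correlation_model> d = %d, max |rho| = %.3f\n",
              x$d, if (length(off)) max(abs(off)) else 0))
  invisible(x)
}

#' Uniform marginals of a parameter space
#' @param space a `parameter_space`.
#' @return named list of uniform marginal specs.
#' @export
space_marginals <- function(space) {
  validate_parameter_space(space)
  m <- lapply(seq_len(space$dimension), function(i) {
    list(type = "uniform", lower = space$entries$lower[i],
         upper = space$entries$upper[i])
  })
  names(m) <- space$entries$name
  m
}

marginal_quantile <- function(marg, u) {
  switch(marg$type,
         uniform = marg$lower + u * (marg$upper - marg$lower),
         normal = qnorm(u, mean = marg$mean, sd = marg$sd),
         stop("unknown marginal type: ", marg$type))
}

#' Fit a Gaussian copula to input data
#'
#' Rank-based normal-scores estimator: each column is transformed to (0,1)
#' with the empirical CDF (the (rank - 0.5)/n convention), mapped through the
#' standard normal quantile, and the Pearson correlation of the scores gives
#' the copula correlation matrix. Marginals default to the sampling-range
#' uniforms when a `parameter_space` is supplied.
#'
#' @param inputs n x d numeric matrix (accepted cohort inputs).
#' @param space optional `parameter_space` supplying uniform marginals and
#'   column names; otherwise empirical uniforms over the observed range.
#' @return a `correlation_model`.
#' @export
fit_gaussian_copula <- function(inputs, space = NULL) {
  inputs <- as.matrix(inputs)
  n <- nrow(inputs)
  d <- ncol(inputs)
  if (n < 3) stop("need at least 3 rows to estimate correlations")
  const <- which(apply(inputs, 2, function(x) diff(range(x)) == 0))
  if (length(const) > 0) {
    nms <- colnames(inputs)
    lab <- if (is.null(nms)) const else nms[const]
    stop("constant column(s): ", paste(lab, collapse = ", "))
  }
  z <- apply(inputs, 2, function(x) qnorm((rank(x) - 0.5) / n))
  R <- cor(z)
  if (is.null(space)) {
    marginals <- lapply(seq_len(d), function(j) {
      list(type = "uniform", lower = min(inputs[, j]), upper = max(inputs[, j]))
    })
    names(marginals) <- colnames(inputs)
  } else {
    validate_parameter_space(space)
    stopifnot(d == space$dimension)
    marginals <- space_marginals(space)
  }
  correlation_model(R, marginals)
}

#' Inverse Rosenblatt transform
#'
#' Maps points of the unit hypercube to the input space under the Gaussian
#' copula: standard-normal quantiles of `u` are correlated through the
#' Cholesky factor of the (permuted) correlation matrix and pushed through
#' the marginal quantile functions. The `ordering` determines the
#' conditioning sequence: the first listed input is driven directly by the
#' first cube coordinate, each later input is conditioned on its
#' predecessors. The joint distribution of the output is the same for every
#' ordering.
#'
#' @param u numeric matrix (m x d) or vector (length d) of cube points in
#'   \[0, 1\].
#' @param model a `correlation_model`.
#' @param ordering integer permutation of `1:d` (default identity).
#' @return m x d matrix of input values, columns in the model's input order.
#' @export
inverse_rosenblatt <- function(u, model, ordering = seq_len(model$d)) {
  stopifnot(inherits(model, "correlation_model"))
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  d <- model$d
  stopifnot(ncol(u) == d, length(ordering) == d,
            all(sort(ordering) == seq_len(d)))
  if (any(u < 0 | u > 1)) stop("u must lie in the unit hypercube")
  Rp <- model$R[ordering, ordering, drop = FALSE]
  L <- t(chol(Rp + diag(1e-12, d)))
  z <- qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15))
  zc <- z %*% t(L)                       # correlated scores, permuted order
  x <- matrix(NA_real_, nrow(u), d)
  uu <- pnorm(zc)
  for (k in seq_len(d)) {
    j <- ordering[k]
    x[, j] <- marginal_quantile(model$marginals[[j]], uu[, k])
  }
  colnames(x) <- model$names
  x
}

#' Sample from a correlation model
#'
#' Monte-Carlo draws through the inverse Rosenblatt transform.
#'
#' @param model a `correlation_model`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return n x d matrix of samples.
#' @export
sample_copula <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- matrix(runif(n * model$d), nrow = n)
  inverse_rosenblatt(u, model)
}

#' Notable correlation pairs
#'
#' Lists input pairs whose copula correlation reaches the threshold, sorted
#' by decreasing absolute correlation.
#'
#' @param model a `correlation_model`.
#' @param threshold minimum `|rho|` (default 0.1, the weak-correlation
#'   boundary).
#' @return data frame with columns `input_a`, `input_b`, `rho`.
#' @export
report_notable_pairs <- function(model, threshold = 0.1) {
  stopifnot(inherits(model, "correlation_model"))
  d <- model$d
  idx <- which(upper.tri(model$R), arr.ind = TRUE)
  rho <- model$R[idx]
  keep <- abs(rho) >= threshold
  out <- data.frame(input_a = model$names[idx[keep, 1]],
                    input_b = model$names[idx[keep, 2]],
                    rho = rho[keep], stringsAsFactors = FALSE)
  out[order(-abs(out$rho)), , drop = FALSE]
}
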
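# Smolyak sparse-grid quadrature on the unit cube, built from nested 1D
# rules by the combination technique (difference rules). The paper-style
# accuracy level k maps to the level budget L = k - 1 over multi-indices
# {l : sum(l) <= L}, with nested 1D sizes 1, 3, 5, 9, 17, ... (2^l + 1).

# 1D rule sizes per level
rule_size <- function(level) ifelse(level == 0L, 1L, 2L^level + 1L)

# Clenshaw-Curtis nodes on [0, 1] (endpoints included for m >= 2)
cc_nodes <- function(m) {
  if (m == 1L) return(0.5)
  (1 - cos(pi * (0:(m - 1)) / (m - 1))) / 2
}

# Clenshaw-Curtis weights on [0, 1]: solve for exactness on the Chebyshev
# basis T_k(2x - 1); the moment of T_k over [0, 1] is 1/(1 - k^2) for even
# k and 0 for odd k. Small m only, and the Chebyshev Vandermonde at CC
# nodes is well conditioned.
cc_weights <- function(m) {
  if (m == 1L) return(1)
  x <- 2 * cc_nodes(m) - 1
  V <- sapply(0:(m - 1), function(k) cos(k * acos(pmin(pmax(x, -1), 1))))
  mom <- ifelse(0:(m - 1) %% 2 == 0, 1 / (1 - (0:(m - 1))^2), 0)
  as.numeric(solve(t(V), mom))
}

# Gauss-Hermite (probabilists') rule expressed on the unit cube: nodes are
# pnorm(z) so that mapping back through qnorm recovers the Gaussian nodes;
# integrates polynomials in z = qnorm(u) exactly to degree 2m - 1 against
# the standard normal weight. Used for unbounded (normal) marginals where
# Clenshaw-Curtis in u is singular.
gh_rule <- function(m) {
  if (m == 1L) return(list(nodes = 0.5, weights = 1))
  k <- sqrt(seq_len(m - 1))
  J <- matrix(0, m, m)
  J[cbind(1:(m - 1), 2:m)] <- k
  J[cbind(2:m, 1:(m - 1))] <- k
  ev <- eigen(J, symmetric = TRUE)
  z <- rev(ev$values)
  w <- rev(ev$vectors[1, ]^2)
  list(nodes = pnorm(z), weights = w)
}

rule_1d <- function(level, type = c("cc", "gh")) {
  type <- match.arg(type)
  m <- rule_size(level)
  if (type == "cc") list(nodes = cc_nodes(m), weights = cc_weights(m))
  else gh_rule(m)
}

# difference rule Delta_l = Q_l - Q_{l-1} on the union of their nodes
delta_rule <- function(level, type) {
  ql <- rule_1d(level, type)
  if (level == 0L) return(ql)
  qm <- rule_1d(level - 1L, type)
  nodes <- ql$nodes
  weights <- ql$weights
  for (i in seq_along(qm$nodes)) {
    j <- which(abs(nodes - qm$nodes[i]) < 1e-12)
    if (length(j) == 1L) {
      weights[j] <- weights[j] - qm$weights[i]
    } else {
      nodes <- c(nodes, qm$nodes[i])
      weights <- c(weights, -qm$weights[i])
    }
  }
  list(nodes = nodes, weights = weights)
}

# multi-indices l in N_0^d with sum(l) <= L, as a list of (dims, levels)
# pairs over the non-zero components only (at most L of them)
sparse_multi_indices <- function(d, L) {
  out <- list(list(dims = integer(0), levels = integer(0)))
  if (L < 1L) return(out)
  # compositions: choose k active dims and positive levels summing <= L
  for (k in 1:min(L, d)) {
    combos <- utils::combn(d, k)
    parts <- positive_compositions(L, k)
    for (ci in seq_len(ncol(combos))) {
      for (pi in seq_len(nrow(parts))) {
        out[[length(out) + 1L]] <- list(dims = combos[, ci],
                                        levels = parts[pi, ])
      }
    }
  }
  out
}

# all vectors of k positive integers with sum <= total
positive_compositions <- function(total, k) {
  if (k == 1L) return(matrix(seq_len(total), ncol = 1))
  acc <- list()
  rec <- function(prefix, remaining, slots) {
    if (slots == 0L) {
      acc[[length(acc) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(remaining - slots + 1L)) {
      rec(c(prefix, v), remaining - v, slots - 1L)
    }
  }
  rec(integer(0), total, k)
  do.call(rbind, acc)
}

#' Number of Smolyak sparse-grid nodes (combination formula)
#'
#' Counts the distinct nodes of the nested sparse grid at the given accuracy
#' without building it: the generating-function coefficient sum of
#' `(1 + 2x + 2x^2 + 4x^3 + 8x^4 + ...)^d` truncated at the level budget
#' `L = accuracy - 1`, where the coefficient of `x^l` is the number of new
#' nodes the 1D rule adds at level `l`.
#'
#' @param d dimension, `>= 1`.
#' @param accuracy accuracy level `k >= 1` (budget `L = k - 1`).
#' @return integer node count.
#' @export
count_smolyak_nodes <- function(d, accuracy) {
  if (d < 1 || accuracy < 1) stop("d and accuracy must be positive")
  L <- accuracy - 1L
  new_nodes <- c(1, vapply(seq_len(max(L, 1)), function(l) {
    rule_size(l) - rule_size(l - 1L)
  }, numeric(1)))
  # polynomial (coefficients of x^0..x^L) raised to the d-th power, truncated
  poly <- c(1, new_nodes[-1][seq_len(L)])
  acc <- c(1, rep(0, L))
  for (i in seq_len(d)) {
    nxt <- rep(0, L + 1L)
    for (a in 0:L) {
      if (acc[a + 1L] == 0) next
      for (b in 0:(L - a)) nxt[a + b + 1L] <- nxt[a + b + 1L] + acc[a + 1L] * poly[b + 1L]
    }
    acc <- nxt
  }
  as.integer(round(sum(acc)))
}

#' Build a Smolyak sparse grid on the unit cube
#'
#' Assembles the nodes and combination-technique weights of the sparse grid
#' with level budget `L = accuracy - 1` over the multi-index set
#' `{l : sum(l) <= L}`, using nested Clenshaw-Curtis rules (sizes 1, 3, 5,
#' 9, ...) for `"cc"` dimensions and Gauss-Hermite-in-u rules for `"gh"`
#' dimensions (unbounded normal marginals).
#'
#' @param d dimension.
#' @param accuracy accuracy level `k >= 1`.
#' @param rules character vector of per-dimension rule types (`"cc"` or
#'   `"gh"`), recycled to length `d`.
#' @return object of class `sparse_grid`: list with `nodes` (n x d matrix in
#'   `[0,1]^d`), `weights` (summing to 1), `d`, `accuracy`, `rules`.
#' @export
build_smolyak_grid <- function(d, accuracy, rules = "cc") {
  if (d < 1 || accuracy < 1) stop("d and accuracy must be positive")
  d <- as.integer(d)
  L <- as.integer(accuracy) - 1L
  rules <- rep(rules, length.out = d)

  # per-type registry of node values; id 1 is the base node (0.5)
  registry <- list(cc = 0.5, gh = 0.5)
  node_ids <- function(type, values) {
    reg <- registry[[type]]
    ids <- integer(length(values))
    for (i in seq_along(values)) {
      j <- which(abs(reg - values[i]) < 1e-12)
      if (length(j) == 0L) {
        reg <- c(reg, values[i])
        j <- length(reg)
      }
      ids[i] <- j[1]
    }
    registry[[type]] <<- reg
    ids
  }

  wmap <- new.env(parent = emptyenv(), hash = TRUE)
  cmap <- new.env(parent = emptyenv(), hash = TRUE)

  for (mi in sparse_multi_indices(d, L)) {
    dims <- mi$dims
    k <- length(dims)
    if (k == 0L) {
      prev <- wmap[["k"]]
      wmap[["k"]] <- (if (is.null(prev)) 0 else prev) + 1
      if (is.null(cmap[["k"]])) cmap[["k"]] <- list(dims = integer(0), ids = integer(0))
      next
    }
    deltas <- lapply(seq_len(k), function(j) {
      dl <- delta_rule(mi$levels[j], rules[dims[j]])
      dl$ids <- node_ids(rules[dims[j]], dl$nodes)
      dl
    })
    sizes <- vapply(deltas, function(x) length(x$nodes), integer(1))
    combo <- as.matrix(expand.grid(lapply(sizes, seq_len)))
    wj <- vapply(seq_len(k), function(j) deltas[[j]]$weights[combo[, j]],
                 numeric(nrow(combo)))
    idj <- vapply(seq_len(k), function(j) deltas[[j]]$ids[combo[, j]],
                  integer(nrow(combo)))
    if (nrow(combo) == 1L) {
      wj <- matrix(wj, nrow = 1)
      idj <- matrix(idj, nrow = 1)
    }
    wrow <- apply(wj, 1, prod)
    for (r in seq_len(nrow(combo))) {
      keep <- idj[r, ] != 1L          # base node 0.5 omitted from the key
      dd <- dims[keep]; ii <- idj[r, keep]
      key <- paste0("k", paste(dd, ii, sep = ":", collapse = ","))
      prev <- wmap[[key]]
      wmap[[key]] <- (if (is.null(prev)) 0 else prev) + wrow[r]
      if (is.null(cmap[[key]])) cmap[[key]] <- list(dims = dd, ids = ii)
    }
  }

  keys <- ls(wmap, all.names = TRUE)
  n <- length(keys)
  nodes <- matrix(0.5, n, d)
  weights <- numeric(n)
  for (i in seq_len(n)) {
    key <- keys[i]
    weights[i] <- wmap[[key]]
    cc <- cmap[[key]]
    if (length(cc$dims) > 0) {
      vals <- vapply(seq_along(cc$dims), function(j) {
        registry[[rules[cc$dims[j]]]][cc$ids[j]]
      }, numeric(1))
      nodes[i, cc$dims] <- vals
    }
  }
  structure(list(nodes = nodes, weights = weights, d = d,
                 accuracy = as.integer(accuracy), rules = rules),
            class = "sparse_grid")
}

#' @export
print.sparse_grid <- function(x, ...) {
  cat(sprintf("<sparse_grid> d = %d, accuracy = %d, %d nodes\n",
              x$d, x$accuracy, nrow(x$nodes)))
  invisible(x)
}

#' Integrate a function over the unit cube on a sparse grid
#'
#' Weighted combination-technique sum. `f` is called once with the full node
#' matrix (n x d) and must return n values.
#'
#' @param f function of a node matrix.
#' @param grid a `sparse_grid`.
#' @return the quadrature value.
#' @export
sparse_integrate <- function(f, grid) {
  stopifnot(inherits(grid, "sparse_grid"))
  y <- f(grid$nodes)
  if (length(y) != nrow(grid$nodes)) {
    stop("f must return one value per node")
  }
  if (any(!is.finite(y))) {
    bad <- which(!is.finite(y))[1]
    stop("non-finite integrand value at node ",
         paste(signif(grid$nodes[bad, ], 4), collapse = ", "))
  }
  sum(grid$weights * y)
}
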
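# Cohort-level verification statistics: two-sample Kolmogorov-Smirnov
# tests, per-vessel FFR summaries, and cohort-to-reference comparisons.

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum over the pooled support of the absolute
#' difference of the two empirical CDFs. The p-value uses the asymptotic
#' Kolmogorov distribution with the standard small-sample correction
#' `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) D` at the effective size
#' `ne = na nb / (na + nb)`.
#'
#' @param a,b numeric samples, non-empty.
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  pooled <- sort(unique(c(a, b)))
  Fa <- ecdf(a)(pooled)
  Fb <- ecdf(b)(pooled)
  D <- max(abs(Fa - Fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  p <- kolmogorov_q(lambda)
  list(statistic = D, p_value = p)
}

# complementary Kolmogorov distribution Q(lambda) = 2 sum (-1)^{k-1} e^{-2k^2 lambda^2}
kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, q))
}

#' Cohort summary statistics
#'
#' Per-vessel and pooled mean, variance and standard deviation of the
#' accepted per-lesion FFR values, plus the acceptance bookkeeping. The
#' variance uses the population convention (divide by n).
#'
#' @param cohort a `cohort` with a non-empty accepted set.
#' @return object of class `cohort_summary`: list with `table` (data frame:
#'   `output`, `mean`, `variance`, `sd`, `n`; one row per lesion vessel plus
#'   a pooled row), `rejection_counts`, `n_requested`, `n_accepted`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort$outputs) == 0) stop("cohort has no accepted patients")
  lesions <- cohort$space$lesions
  pvar <- function(x) mean((x - mean(x))^2)
  rows <- lapply(lesions, function(v) {
    x <- cohort$outputs[[paste0("ffr_", v)]]
    data.frame(output = paste0("FFR ", v), mean = mean(x), variance = pvar(x),
               sd = sqrt(pvar(x)), n = length(x), stringsAsFactors = FALSE)
  })
  pooled <- unlist(cohort$outputs[paste0("ffr_", lesions)], use.names = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    output = "FFR pooled", mean = mean(pooled), variance = pvar(pooled),
    sd = sqrt(pvar(pooled)), n = length(pooled), stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  rejc <- table(cohort$rejections$reason)
  structure(list(table = tab,
                 rejection_counts = as.list(rejc),
                 n_requested = cohort$n_requested,
                 n_accepted = nrow(cohort$inputs),
                 patient_type = cohort$patient_type),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> patient-%s: %d accepted / %d requested\n",
              x$patient_type, x$n_accepted, x$n_requested))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare cohort FFR values with a reference table
#'
#' Per-vessel and combined two-sample KS comparison of per-lesion FFR
#' distributions, e.g. a generated cohort against an external clinical
#' table.
#'
#' @param cohort_ffr data frame with columns `vessel` and `ffr`.
#' @param reference_ffr data frame with columns `vessel` and `ffr`.
#' @return data frame with rows per common vessel plus `combined`, columns
#'   `vessel`, `ks_statistic`, `p_value`, `n_cohort`, `n_reference`.
#' @export
compare_cohorts <- function(cohort_ffr, reference_ffr) {
  need <- c("vessel", "ffr")
  if (!all(need %in% names(cohort_ffr)) || !all(need %in% names(reference_ffr))) {
    stop("both tables need columns `vessel` and `ffr`")
  }
  va <- unique(cohort_ffr$vessel)
  vb <- unique(reference_ffr$vessel)
  unmatched <- c(setdiff(va, vb), setdiff(vb, va))
  if (length(unmatched) > 0) {
    stop("vessel labels not present in both tables: ",
         paste(unique(unmatched), collapse = ", "))
  }
  vessels <- sort(va)
  rows <- lapply(vessels, function(v) {
    a <- cohort_ffr$ffr[cohort_ffr$vessel == v]
    b <- reference_ffr$ffr[reference_ffr$vessel == v]
    ks <- ks_two_sample(a, b)
    data.frame(vessel = v, ks_statistic = ks$statistic, p_value = ks$p_value,
               n_cohort = length(a), n_reference = length(b),
               stringsAsFactors = FALSE)
  })
  ks <- ks_two_sample(cohort_ffr$ffr, reference_ffr$ffr)
  rows[[length(rows) + 1L]] <- data.frame(
    vessel = "combined", ks_statistic = ks$statistic, p_value = ks$p_value,
    n_cohort = nrow(cohort_ffr), n_reference = nrow(reference_ffr),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
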
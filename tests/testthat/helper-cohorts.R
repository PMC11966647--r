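# Shared, lazily generated cohorts for the heavier tests. Seeds and sizes
# are fixed up front; results are cached per test run so that several test
# files can reuse the same cohorts without regenerating them.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- force(expr)
  .cohort_cache[[key]]
}

# filtered 2L cohort, n = 2000 (acceptance criterion 3 scale)
filtered_cohort_2l <- function() {
  cached("filt2l", {
    generate_cohort(load_parameter_table("2L"), 2000, seed = 101)
  })
}

# filtered 3L cohort, n = 1000
filtered_cohort_3l <- function() {
  cached("filt3l", {
    generate_cohort(load_parameter_table("3L"), 1000, seed = 102)
  })
}

# pre-filter 2L cohort large enough for a 2500-sample training set
prefilter_cohort_2l <- function() {
  cached("pre2l", {
    generate_cohort(load_parameter_table("2L"), 3600, seed = 103,
                    filters_on = FALSE)
  })
}

# surrogates for the pre-filter 2L cohort (one per lesion), with their
# held-out nRMSE
surrogates_2l <- function() {
  cached("sur2l", {
    pre <- prefilter_cohort_2l()
    space <- pre$space
    split <- train_test_split(nrow(pre$inputs), 2500, seed = 104)
    out <- list()
    for (v in space$lesions) {
      y <- pre$outputs[[paste0("ffr_", v)]]
      m <- train_vkoga(pre$inputs[split$train, ], y[split$train],
                       max_centers = 1000, eps = 0.2,
                       scaling = list(lower = space$entries$lower,
                                      upper = space$entries$upper))
      pr <- predict(m, pre$inputs[split$test, ])
      out[[v]] <- list(model = m,
                       metrics = rmse_nrmse(pr, y[split$test]),
                       bland_altman = bland_altman(pr, y[split$test]))
    }
    out
  })
}

# a small deterministic stub engine for generator plumbing tests: fails on
# a fixed set of indices and produces constant physiological outputs
make_stub_engine <- function(fail_index = integer(0), lm_flow = 500,
                             co = 5, sys = 120, dia = 70) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  function(params, geometry, config) {
    counter$i <- counter$i + 1L
    if (counter$i %in% fail_index) {
      return(structure(list(status = "solver_failure", meta = list()),
                       class = "patient_simulation"))
    }
    n <- 3000L
    tt <- seq_len(n) / 1000
    pao <- ((sys + dia) / 2 + (sys - dia) / 2 * sin(2 * pi * tt)) * 133.322
    lesions <- geometry$lesion_slots$vessel
    ffr <- stats::setNames(rep(0.8, length(lesions)), lesions)
    structure(list(status = "ok", time = seq_len(n) / 1000,
                   aortic_pressure = pao,
                   lv_pressure = pao,
                   distal_pressure = matrix(0.8 * pao, n,
                                            length(lesions),
                                            dimnames = list(NULL, lesions)),
                   branch_flow = matrix(100, n, 3), ffr = ffr,
                   ffr_flagged = ffr <= 0 | ffr > 1,
                   cardiac_output = co, lm_flow = lm_flow,
                   meta = list(scale = 1, converged = TRUE, cycles_run = 23,
                               mean_pao = mean(pao))),
              class = "patient_simulation")
  }
}
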
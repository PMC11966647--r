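# Pipeline orchestration and artifact serialization: one reproducible run
# from cohort generation through copula fitting, surrogate training and
# correlated sensitivity analysis, with a manifest tying the stages
# together. Artifacts are plain text (CSV + JSON).

#' Pipeline configuration
#'
#' @param patient_type `"2L"` or `"3L"`.
#' @param n number of sampled input sets.
#' @param seed sampling seed; the train/test split uses `seed + 1`.
#' @param out_dir output directory (created if missing).
#' @param accuracy Smolyak accuracy level of the sensitivity stage.
#' @param n_train minimum surrogate training-set size.
#' @param max_centers greedy center budget of each surrogate.
#' @param engine an `engine_config`.
#' @param qc a `qc_config`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(patient_type, n, seed, out_dir,
                            accuracy = 2, n_train = 2500L,
                            max_centers = 400L,
                            engine = engine_config(), qc = qc_config()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate -> fit-copula -> train-surrogates (one per lesion) ->
#' sensitivity analysis -> summary report, writing each artifact and a JSON
#' manifest into the output directory. The surrogates are trained on the
#' pre-filter (QC-passing) population; the copula and the summary use the
#' physiologically filtered cohort.
#'
#' @param config a `pipeline_config`.
#' @return the manifest (named list of artifact paths and stage metadata),
#'   invisibly; the manifest is also written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- load_parameter_table(config$patient_type)
  manifest <- list(patient_type = config$patient_type, n = config$n,
                   seed = config$seed, accuracy = config$accuracy,
                   artifacts = list())

  stage <- function(name, expr) {
    t0 <- Sys.time()
    value <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$artifacts[[name]] <<- c(manifest$artifacts[[name]],
                                     list(seconds = round(as.numeric(Sys.time() - t0), 2)))
    value
  }

  # 1. cohorts: one pre-filter run (training population) and its filtered view
  pre <- stage("generate", {
    generate_cohort(space, config$n, config$seed, engine = config$engine,
                    qc = config$qc, filters_on = FALSE)
  })
  filt <- refilter_cohort(pre)
  cohort_path <- file.path(config$out_dir, "cohort")
  save_cohort(filt, cohort_path)
  manifest$artifacts$generate$path <- paste0(cohort_path, c(".csv", ".json"))

  # 2. copula on the accepted (filtered) inputs
  model <- stage("fit_copula", fit_gaussian_copula(filt$inputs, space))
  copula_path <- file.path(config$out_dir, "copula.csv")
  save_correlation_matrix(model, copula_path)
  manifest$artifacts$fit_copula$path <- copula_path

  # 3. surrogates per lesion on the pre-filter population
  lesions <- space$lesions
  surrogates <- list()
  metrics <- list()
  for (v in lesions) {
    fit <- stage(paste0("surrogate_", v), {
      y <- pre$outputs[[paste0("ffr_", v)]]
      n_ok <- length(y)
      if (n_ok <= config$n_train) {
        stop("not enough usable runs (", n_ok, ") for a ", config$n_train,
             "-sample training set")
      }
      split <- train_test_split(n_ok, config$n_train, seed = config$seed + 1L)
      m <- train_vkoga(pre$inputs[split$train, , drop = FALSE], y[split$train],
                       max_centers = config$max_centers,
                       scaling = list(lower = space$entries$lower,
                                      upper = space$entries$upper),
                       seed = config$seed + 1L)
      pr <- predict(m, pre$inputs[split$test, , drop = FALSE])
      list(model = m,
           metrics = c(rmse_nrmse(pr, y[split$test]),
                       bland_altman(pr, y[split$test])))
    })
    sp <- file.path(config$out_dir, paste0("surrogate_", v, ".json"))
    save_surrogate(fit$model, sp)
    manifest$artifacts[[paste0("surrogate_", v)]]$path <- sp
    manifest$artifacts[[paste0("surrogate_", v)]]$metrics <- fit$metrics
    surrogates[[v]] <- fit$model
    metrics[[v]] <- fit$metrics
  }

  # 4. correlated sensitivity analysis per lesion FFR; the variance is
  # normalized with a Monte-Carlo estimate over the copula, which stays
  # robust at low accuracy levels in this dimension
  for (v in lesions) {
    res <- stage(paste0("sa_", v), {
      v_mc <- var(predict(surrogates[[v]],
                          sample_copula(model, 1e4, seed = config$seed + 2L)))
      full_analysis(surrogates[[v]], model, accuracy = config$accuracy,
                    output_name = paste0("FFR_", v), variance = v_mc)
    })
    rp <- file.path(config$out_dir, paste0("sa_", v))
    save_sensitivity_result(res, rp)
    manifest$artifacts[[paste0("sa_", v)]]$path <- paste0(rp, c(".csv", ".json"))
  }

  # 5. cohort summary report
  summ <- stage("report", cohort_summary(filt))
  report_path <- file.path(config$out_dir, "summary.csv")
  write.csv(summ$table, report_path, row.names = FALSE)
  manifest$artifacts$report$path <- report_path

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = I(17), auto_unbox = TRUE)
  invisible(manifest)
}

# apply the physiological filters post hoc to a filters-off cohort, using
# the recorded scalar outputs (same bounds as apply_physiological_filters)
refilter_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  o <- cohort$all_outputs
  ok_sim <- !is.na(o$cardiac_output)
  acc <- ok_sim &
    o$diastolic_mmHg > 50 & o$systolic_mmHg < 150 &
    o$lm_flow >= 300 & o$lm_flow <= 900 &
    o$cardiac_output >= 3.5 & o$cardiac_output <= 6
  acc[is.na(acc)] <- FALSE
  reasons <- vapply(seq_len(nrow(o)), function(i) {
    if (!ok_sim[i]) {
      idx <- which(cohort$rejections$index == i)
      return(if (length(idx) > 0) cohort$rejections$reason[idx[1]] else "solver_failure")
    }
    r <- character(0)
    if (!(o$diastolic_mmHg[i] > 50)) r <- c(r, "diastolic_low")
    if (!(o$systolic_mmHg[i] < 150)) r <- c(r, "systolic_high")
    if (o$lm_flow[i] < 300 || o$lm_flow[i] > 900) r <- c(r, "lm_flow")
    if (o$cardiac_output[i] < 3.5 || o$cardiac_output[i] > 6) r <- c(r, "cardiac_output")
    if (length(r) == 0) "" else r[1]
  }, character(1))
  out <- cohort
  out$inputs <- cohort$all_inputs[acc, , drop = FALSE]
  out$outputs <- cohort$all_outputs[acc, , drop = FALSE]
  rownames(out$outputs) <- NULL
  out$accepted_index <- which(acc)
  out$rejections <- data.frame(index = which(!acc), reason = reasons[!acc],
                               all_reasons = reasons[!acc],
                               stringsAsFactors = FALSE)
  out$filters_on <- TRUE
  out
}

#' Save a cohort as CSV + JSON
#'
#' Writes `<path>.csv` (accepted inputs and scalar outputs side by side) and
#' `<path>.json` (metadata: seed, config snapshot, rejection log).
#'
#' @param cohort a `cohort`.
#' @param path base path without extension.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  tab <- cbind(as.data.frame(cohort$inputs), cohort$outputs)
  write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(schema = "corovpc_cohort_v1",
               patient_type = cohort$patient_type,
               seed = cohort$seed, n_requested = cohort$n_requested,
               filters_on = cohort$filters_on,
               n_inputs = ncol(cohort$inputs),
               input_names = colnames(cohort$inputs),
               accepted_index = cohort$accepted_index,
               rejections = cohort$rejections,
               config = cohort$config)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Load a cohort saved by [save_cohort()]
#'
#' Restores the accepted inputs/outputs and provenance (the full pre-filter
#' sample matrix is not persisted).
#'
#' @param path base path without extension.
#' @return a `cohort` (without `all_inputs`/`all_outputs`).
#' @export
load_cohort <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, "corovpc_cohort_v1")) {
    stop("schema mismatch: not a corovpc cohort file")
  }
  tab <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  d <- meta$n_inputs
  inputs <- as.matrix(tab[, seq_len(d), drop = FALSE])
  outputs <- tab[, -seq_len(d), drop = FALSE]
  space <- load_parameter_table(meta$patient_type)
  structure(list(inputs = inputs, outputs = outputs,
                 rejections = as.data.frame(meta$rejections),
                 accepted_index = meta$accepted_index,
                 space = space, patient_type = meta$patient_type,
                 seed = meta$seed, n_requested = meta$n_requested,
                 filters_on = meta$filters_on, config = meta$config,
                 waveforms = NULL),
            class = "cohort")
}

#' Save a correlation matrix as CSV
#'
#' Writes the copula correlation matrix with input names as header row and
#' first column; marginals are appended as a JSON sidecar
#' (`<path>.marginals.json`).
#'
#' @param model a `correlation_model`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
save_correlation_matrix <- function(model, path) {
  stopifnot(inherits(model, "correlation_model"))
  tab <- data.frame(input = model$names, model$R, check.names = FALSE)
  colnames(tab) <- c("input", model$names)
  write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(list(schema = "corovpc_copula_v1",
                            marginals = model$marginals),
                       paste0(path, ".marginals.json"),
                       digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a correlation model saved by [save_correlation_matrix()]
#' @param path CSV file path.
#' @return a `correlation_model`.
#' @export
load_correlation_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  R <- as.matrix(tab[, -1, drop = FALSE])
  rownames(R) <- tab$input
  meta <- jsonlite::read_json(paste0(path, ".marginals.json"),
                              simplifyVector = FALSE)
  if (!identical(meta$schema, "corovpc_copula_v1")) {
    stop("schema mismatch: not a corovpc copula file")
  }
  correlation_model(R, meta$marginals)
}

#' Save a sensitivity result (CSV indices + JSON metadata)
#' @param result a `sensitivity_result`.
#' @param path base path without extension.
#' @return `path`, invisibly.
#' @export
save_sensitivity_result <- function(result, path) {
  stopifnot(inherits(result, "sensitivity_result"))
  write.csv(result$indices, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(schema = "corovpc_sa_v1", mean = result$mean,
                            variance = result$variance,
                            accuracy = result$accuracy,
                            n_nodes_moments = result$n_nodes_moments,
                            output_name = result$output_name),
                       paste0(path, ".json"), digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a sensitivity result saved by [save_sensitivity_result()]
#' @param path base path without extension.
#' @return a `sensitivity_result`.
#' @export
load_sensitivity_result <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, "corovpc_sa_v1")) {
    stop("schema mismatch: not a corovpc sensitivity file")
  }
  structure(list(indices = utils::read.csv(paste0(path, ".csv")),
                 mean = meta$mean, variance = meta$variance,
                 accuracy = meta$accuracy,
                 n_nodes_moments = meta$n_nodes_moments,
                 output_name = meta$output_name),
            class = "sensitivity_result")
}

#' Command-line entry point
#'
#' Minimal subcommand interface: `corovpc_cli(c("run-all", "--patient-type",
#' "3L", "--n", "500", "--seed", "42", "--out", "runs/demo"))`. Subcommands:
#' `run-all` (the full pipeline) and `generate` (cohort only, with
#' `--no-filters` to keep the pre-filter population).
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return the stage result, invisibly.
#' @export
corovpc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    stop("usage: corovpc_cli(c(\"run-all|generate\", \"--patient-type\", ...))")
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0) {
      if (is.null(default)) stop("missing required option ", flag)
      default
    } else {
      args[i[1] + 1L]
    }
  }
  if (!(cmd %in% c("run-all", "generate"))) {
    stop("unknown subcommand: ", cmd)
  }
  patient_type <- opt("--patient-type")
  n <- as.integer(opt("--n", "500"))
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out")
  if (cmd == "run-all") {
    cfg <- pipeline_config(patient_type, n, seed, out,
                           accuracy = as.integer(opt("--accuracy", "2")))
    return(invisible(run_pipeline(cfg)))
  }
  space <- load_parameter_table(patient_type)
  ch <- generate_cohort(space, n, seed,
                        filters_on = !("--no-filters" %in% args))
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  save_cohort(ch, out)
  invisible(ch)
}
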
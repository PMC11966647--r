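# Virtual cohort generator: uniform input sampling, simulation, waveform QC,
# physiological acceptance filtering and cohort assembly with provenance.

#' Quality-control configuration for waveform screening
#'
#' A second-order low-pass Butterworth filter (zero-phase, forward-backward)
#' separates high-frequency oscillation content from the physiological
#' signal; waveforms whose removed content has an RMS above the threshold are
#' rejected as numerically contaminated.
#'
#' @param order filter order (2).
#' @param fs sampling frequency (Hz).
#' @param fc cut-off frequency (Hz), below the Nyquist frequency.
#' @param rms_threshold rejection threshold on the RMS of the removed
#'   high-frequency content (Pa); rejection is strict (`rms > threshold`).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(order = 2L, fs = 1000, fc = 100, rms_threshold = 4) {
  if (fc >= fs / 2) stop("cut-off must be below the Nyquist frequency")
  if (rms_threshold <= 0) stop("rms_threshold must be positive")
  if (order != 2L) stop("only the second-order filter is supported")
  structure(list(order = 2L, fs = fs, fc = fc, rms_threshold = rms_threshold),
            class = "qc_config")
}

# second-order low-pass Butterworth coefficients via the bilinear transform
butter2_lowpass <- function(fc, fs) {
  K <- tan(pi * fc / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  b <- c(K^2, 2 * K^2, K^2) * norm
  a <- c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm)
  list(b = b, a = a)
}

# direct-form-II transposed IIR filter
iir_filter <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  z1 <- 0; z2 <- 0
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] - a[2] * y[i] + z2
    z2 <- b[3] * x[i] - a[3] * y[i]
  }
  y
}

# zero-phase forward-backward application with reflective edge padding
filtfilt2 <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 30L)
  # odd (point-symmetric) extension, as used by standard filtfilt routines
  head_ext <- 2 * x[1] - x[(pad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(head_ext, x, tail_ext)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Waveform quality control
#'
#' Low-pass filters the pressure signal with a zero-phase second-order
#' Butterworth filter and computes the RMS of the removed high-frequency
#' residual. Signals whose residual RMS exceeds the threshold are flagged as
#' contaminated by numerical oscillations.
#'
#' @param pressure pressure series (Pa) sampled at `qc$fs`.
#' @param qc a [qc_config()].
#' @return list with `rms` (Pa) and `pass` (logical; `rms` strictly above the
#'   threshold fails).
#' @export
qc_waveform <- function(pressure, qc = qc_config()) {
  if (length(pressure) < 3L * qc$order + 1L) {
    stop("series too short for quality control")
  }
  co <- butter2_lowpass(qc$fc, qc$fs)
  filtered <- filtfilt2(co$b, co$a, pressure)
  rms <- sqrt(mean((pressure - filtered)^2))
  list(rms = rms, pass = rms <= qc$rms_threshold)
}

#' Physiological acceptance filters
#'
#' Applies the four population filters to a completed simulation: diastolic
#' aortic pressure strictly above 50 mmHg, systolic strictly below 150 mmHg,
#' cycle-mean left-main flow within \[300, 900\] ml/min and cardiac output
#' within \[3.5, 6\] l/min (flow and output bounds inclusive).
#'
#' @param sim a `patient_simulation` with `status == "ok"`.
#' @return list with `accept` (logical) and `reasons` (character vector among
#'   `diastolic_low`, `systolic_high`, `lm_flow`, `cardiac_output`; empty when
#'   accepted).
#' @export
apply_physiological_filters <- function(sim) {
  stopifnot(inherits(sim, "patient_simulation"))
  if (sim$status != "ok") {
    stop("cannot filter a failed simulation; screen solver failures upstream")
  }
  dia <- min(sim$aortic_pressure) / MMHG_PA
  sys <- max(sim$aortic_pressure) / MMHG_PA
  reasons <- character(0)
  if (!(dia > 50)) reasons <- c(reasons, "diastolic_low")
  if (!(sys < 150)) reasons <- c(reasons, "systolic_high")
  if (sim$lm_flow < 300 || sim$lm_flow > 900) reasons <- c(reasons, "lm_flow")
  if (sim$cardiac_output < 3.5 || sim$cardiac_output > 6) {
    reasons <- c(reasons, "cardiac_output")
  }
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Uniform input sampling
#'
#' Draws `n` independent input vectors, each coordinate uniform within its
#' printed range. Reproducible for a given seed.
#'
#' @param space a `parameter_space`.
#' @param n number of samples, positive.
#' @param seed integer seed.
#' @return `n x d` matrix with column names from the space.
#' @export
sample_inputs <- function(space, n, seed) {
  validate_parameter_space(space)
  if (!is.numeric(n) || n < 1) stop("n must be at least 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  d <- space$dimension
  lo <- space$entries$lower
  hi <- space$entries$upper
  m <- matrix(runif(n * d), nrow = n, ncol = d)
  m <- sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
  colnames(m) <- space$entries$name
  m
}

#' Resample a periodic series to 1000 points per cycle
#'
#' Linearly resamples one cardiac cycle onto a uniform grid of `n_out` points
#' spanning the cycle, endpoints aligned to the cycle boundaries.
#'
#' @param series values sampled uniformly over one period (first sample at
#'   cycle start; the implied next sample after the last closes the cycle).
#' @param period cycle duration (s), positive.
#' @param n_out output samples per cycle (default 1000).
#' @return numeric vector of length `n_out`.
#' @export
normalize_cycle <- function(series, period, n_out = 1000L) {
  if (period <= 0) stop("period must be positive")
  n <- length(series)
  if (n < 2) stop("series must span at least one sampled period")
  t_in <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  t_out <- seq(0, period * (1 - 1 / n_out), length.out = n_out)
  stats::approx(x = c(t_in, period), y = c(series, series[1]),
                xout = t_out, method = "linear")$y
}

#' Generate a virtual patient cohort
#'
#' Runs the full generator chain: uniform sampling, simulation, waveform
#' quality control on the aortic pressure, and (optionally) the physiological
#' acceptance filters. Every rejection is logged with its sample index and
#' all violated criteria; the first violated criterion in the fixed order
#' solver -> oscillation -> diastolic_low -> systolic_high -> lm_flow ->
#' cardiac_output is recorded as the primary reason.
#'
#' @param space a `parameter_space`.
#' @param n number of input sets to draw.
#' @param seed integer seed for the sampling.
#' @param engine an `engine_config`.
#' @param qc a `qc_config`.
#' @param filters_on apply the physiological filters (`TRUE`) or keep every
#'   QC-passing run (`FALSE`, the surrogate-training population).
#' @param geometry optional `coronary_geometry` (built from the space's
#'   patient type when omitted).
#' @param simulate_fn simulation backend, defaulting to [simulate_patient()];
#'   injectable for testing.
#' @param keep_waveforms keep per-patient waveform series in the cohort
#'   (memory-heavy; default `FALSE` retains scalar outputs only).
#' @return object of class `cohort`: list with `inputs` (accepted input
#'   matrix), `outputs` (data frame: per-lesion FFR columns `ffr_<vessel>`,
#'   `cardiac_output`, `lm_flow`, `systolic_mmHg`, `diastolic_mmHg`,
#'   `qc_rms`), `rejections` (data frame: `index`, `reason`, `all_reasons`),
#'   `accepted_index`, `space`, `seed`, `n_requested`, `filters_on`,
#'   `config` snapshot, and optionally `waveforms`.
#' @export
generate_cohort <- function(space, n, seed, engine = engine_config(),
                            qc = qc_config(), filters_on = TRUE,
                            geometry = NULL,
                            simulate_fn = simulate_patient,
                            keep_waveforms = FALSE) {
  validate_parameter_space(space)
  if (is.null(geometry)) geometry <- build_geometry(space$patient_type)
  inputs <- sample_inputs(space, n, seed)

  lesions <- space$lesions
  out_cols <- c(paste0("ffr_", lesions), "cardiac_output", "lm_flow",
                "systolic_mmHg", "diastolic_mmHg", "qc_rms")
  outputs <- matrix(NA_real_, nrow = n, ncol = length(out_cols),
                    dimnames = list(NULL, out_cols))
  reason1 <- character(n)
  reason_all <- character(n)
  accept <- logical(n)
  waveforms <- if (keep_waveforms) vector("list", n) else NULL

  for (i in seq_len(n)) {
    sim <- simulate_fn(inputs[i, ], geometry, engine)
    if (sim$status != "ok") {
      reason1[i] <- "solver_failure"
      reason_all[i] <- "solver_failure"
      next
    }
    qcres <- qc_waveform(sim$aortic_pressure, qc)
    outputs[i, "qc_rms"] <- qcres$rms
    if (!qcres$pass) {
      reason1[i] <- "oscillation"
      reason_all[i] <- "oscillation"
      next
    }
    outputs[i, paste0("ffr_", lesions)] <- sim$ffr[lesions]
    outputs[i, "cardiac_output"] <- sim$cardiac_output
    outputs[i, "lm_flow"] <- sim$lm_flow
    outputs[i, "systolic_mmHg"] <- max(sim$aortic_pressure) / MMHG_PA
    outputs[i, "diastolic_mmHg"] <- min(sim$aortic_pressure) / MMHG_PA
    if (keep_waveforms) waveforms[[i]] <- sim

    if (filters_on) {
      fl <- apply_physiological_filters(sim)
      if (!fl$accept) {
        reason1[i] <- fl$reasons[1]
        reason_all[i] <- paste(fl$reasons, collapse = ";")
        next
      }
    }
    accept[i] <- TRUE
  }

  rejections <- data.frame(
    index = which(!accept),
    reason = reason1[!accept],
    all_reasons = reason_all[!accept],
    stringsAsFactors = FALSE)

  structure(list(
    inputs = inputs[accept, , drop = FALSE],
    outputs = as.data.frame(outputs[accept, , drop = FALSE]),
    all_inputs = inputs,
    all_outputs = as.data.frame(outputs),
    rejections = rejections,
    accepted_index = which(accept),
    space = space,
    patient_type = space$patient_type,
    seed = as.integer(seed),
    n_requested = as.integer(n),
    filters_on = filters_on,
    config = list(engine = unclass(engine), qc = unclass(qc)),
    waveforms = waveforms),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> patient-%s: %d accepted / %d requested (filters %s), seed %d\n",
    x$patient_type, nrow(x$inputs), x$n_requested,
    if (x$filters_on) "on" else "off", x$seed))
  if (nrow(x$rejections) > 0) {
    tab <- table(x$rejections$reason)
    cat("  rejections:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Per-lesion FFR table of a cohort
#'
#' Long-format table of accepted per-lesion FFR values, suitable for
#' cohort-to-reference comparisons.
#'
#' @param cohort a `cohort`.
#' @return data frame with columns `vessel` and `ffr`.
#' @export
cohort_ffr_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  lesions <- cohort$space$lesions
  do.call(rbind, lapply(lesions, function(v) {
    data.frame(vessel = v, ffr = cohort$outputs[[paste0("ffr_", v)]],
               stringsAsFactors = FALSE)
  }))
}
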
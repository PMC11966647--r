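# Reduced-order pulsatile coronary circulation engine: maps a parameter
# vector to pressure/flow waveforms, per-lesion FFR, cardiac output and
# left-main flow. All internal computation is in SI-like units
# (Pa, ml, s; resistances Pa s ml^-1, compliances ml Pa^-1).

#' Engine configuration
#'
#' Collects the numerical and mapping constants of the reduced-order engine.
#' Defaults are fixed, versioned choices; see the methods vignette for the
#' rationale behind each value.
#'
#' @param steps_per_cycle integration steps (and output samples) per cardiac
#'   cycle; each cycle is distributed over this many points.
#' @param n_record number of analyzed cycles returned (default 3, the FFR
#'   averaging window).
#' @param min_adapt,max_adapt minimum/maximum number of burn-in cycles during
#'   which contractility is rescaled towards the target mean aortic pressure.
#' @param conv_tol relative tolerance on the cycle-mean aortic pressure during
#'   adaptation (the post-hoc acceptance bound is `mean_tol`).
#' @param mean_tol maximum relative deviation of the recorded cycle-mean
#'   aortic pressure from its target before the run is declared a solver
#'   failure.
#' @param damping exponent of the multiplicative controller update.
#' @param k_t turbulent loss coefficient of the stenosis element.
#' @param flow_split resting coronary flow split over `c(LAD, LCx, RCA)`.
#' @param R_ref reference systemic resistance (Pa s ml^-1) multiplied by the
#'   `resistance_scale` input.
#' @param C_ref reference systemic compliance numerator; the systemic
#'   compliance is `compliance_scale * C_ref / (E * (1 - mu^2))` ml/Pa with
#'   the Young modulus `E` in Pa.
#' @param z_frac characteristic (proximal) fraction of the systemic
#'   resistance; the remainder is peripheral.
#' @param c_ao_frac fraction of the systemic compliance lumped at the aortic
#'   root node.
#' @param emax_coeff peak-elastance coefficient: `Emax0 = emax_coeff *
#'   sigma_a0 * volume_fraction/100` (Pa/ml).
#' @param emin_coeff passive-elastance coefficient: `Emin = emin_coeff *
#'   (sigma_f0 * c_f + sigma_r0 * c_r)` (Pa/ml).
#' @param v_wall ventricular wall volume (ml); the unloaded cavity volume is
#'   `volume_fraction/100 * v_wall`.
#' @param R_mit,R_av mitral and aortic valve resistances (Pa s ml^-1).
#' @param rven_floor minimum venous share of the branch microvascular
#'   resistance (guards against a zero venous resistance).
#' @return list of class `engine_config`.
#' @export
engine_config <- function(steps_per_cycle = 1000L, n_record = 3L,
                          min_adapt = 25L, max_adapt = 25L,
                          conv_tol = 0.005, mean_tol = 0.01, damping = 0.8,
                          k_t = 1.52,
                          flow_split = c(LAD = 0.5, LCx = 0.3, RCA = 0.2),
                          R_ref = 162, C_ref = 7500, z_frac = 0.035,
                          c_ao_frac = 0.08,
                          emax_coeff = 6.5e-3, emin_coeff = 1.5e-4,
                          v_wall = 200, R_mit = 2, R_av = 4,
                          rven_floor = 0.02) {
  structure(as.list(environment()), class = "engine_config")
}

# ---- stenosis element -------------------------------------------------------

#' Viscous and turbulent stenosis coefficients
#'
#' Internal helper returning the linear (viscous) resistance in
#' Pa s ml^-1 and the quadratic loss coefficient in Pa (ml/s)^-2 of a
#' stenosis, in terms of the flow through the host segment. The severity is a
#' diameter reduction: the throat radius is `host_radius * (1 - severity/100)`.
#' The viscous part is the Poiseuille resistance of the throat; the turbulent
#' part follows the Young--Tsai expansion-loss convention
#' `K_t = k_t * rho / (2 A0^2) * (A0/As - 1)^2` referenced to the
#' unobstructed area `A0`.
#' @keywords internal
stenosis_coefficients <- function(severity, length_mm, host_radius_cm,
                                  eta, rho, k_t = 1.52) {
  if (any(severity < 0) || any(severity >= 100)) {
    stop("severity must be in [0, 100)")
  }
  if (any(length_mm <= 0)) stop("stenosis length must be positive")
  r0 <- host_radius_cm * 1e-2                     # m
  rs <- r0 * (1 - severity / 100)
  L <- length_mm * 1e-3                           # m
  R_v <- 8 * eta * L / (pi * rs^4) * 1e-6         # Pa s ml^-1
  A0 <- pi * r0^2
  As <- pi * rs^2
  K_t <- k_t * rho / (2 * A0^2) * (A0 / As - 1)^2 * 1e-12  # Pa (ml/s)^-2
  list(R_v = R_v, K_t = K_t)
}

#' Pressure drop over a stenotic lesion
#'
#' Two-term lumped stenosis model `dP = R_v q + K_t q |q|`: a Poiseuille
#' (viscous) resistance of the narrowed lumen plus a turbulent expansion
#' loss. Severity is percent diameter reduction.
#'
#' @param q flow through the lesion (ml/s); may be a vector.
#' @param severity percent diameter reduction, in \[0, 100).
#' @param length stenosis length (mm), positive.
#' @param host_radius unobstructed host vessel radius (cm).
#' @param eta dynamic viscosity (Pa s).
#' @param rho blood density (kg m^-3).
#' @param k_t turbulent loss constant (default 1.52).
#' @return pressure drop (Pa), same length as `q`.
#' @export
stenosis_pressure_drop <- function(q, severity, length, host_radius,
                                   eta, rho, k_t = 1.52) {
  co <- stenosis_coefficients(severity, length, host_radius, eta, rho, k_t)
  co$R_v * q + co$K_t * q * abs(q)
}

# ---- FFR and hyperaemia -----------------------------------------------------

#' Fractional flow reserve from pressure series
#'
#' Ratio of the time-averaged distal to aortic pressure over `n_beats`
#' consecutive cardiac cycles (the series are assumed to cover exactly an
#' integer number of cycles at hyperaemia; the averaging window uses the last
#' `n_beats` cycles).
#'
#' @param distal_pressure distal (post-stenotic) pressure series (Pa).
#' @param aortic_pressure aortic pressure series (Pa), same length.
#' @param n_beats number of cycles spanned by the averaging window.
#' @return dimensionless FFR value.
#' @export
compute_ffr <- function(distal_pressure, aortic_pressure, n_beats = 3) {
  if (length(distal_pressure) != length(aortic_pressure)) {
    stop("pressure series must have equal length")
  }
  n <- length(aortic_pressure)
  if (n < n_beats) stop("series shorter than the averaging window")
  pa <- mean(aortic_pressure)
  if (!is.finite(pa) || pa <= 0) stop("mean aortic pressure must be positive")
  mean(distal_pressure) / pa
}

#' Microcirculation state of one coronary branch
#'
#' Resting microvascular resistances and compliances of a branch. The total
#' branch resistance is sized from the resting perfusion pressure and flow;
#' the four resistance fractions are renormalized to sum to one (with a small
#' floor on the venous share).
#'
#' @param R_total total resting branch resistance (Pa s ml^-1).
#' @param fractions numeric length 4: arterial, myocardial-1, myocardial-2 and
#'   venous resistance fractions (renormalized internally).
#' @param compliances numeric length 3: arterial, myocardial and venous
#'   compliances (ml/Pa).
#' @param pim_frac intramyocardial pressure fraction of LV pressure.
#' @param rven_floor minimum venous fraction after renormalization.
#' @return list of class `microcirculation_state` with elements `R_art`,
#'   `R_myo1`, `R_myo2`, `R_ven`, `C_art`, `C_myo`, `C_ven`, `pim_frac`.
#' @export
microcirculation_state <- function(R_total, fractions, compliances,
                                   pim_frac, rven_floor = 0.02) {
  stopifnot(R_total > 0, length(fractions) == 4, length(compliances) == 3,
            all(fractions >= 0), all(compliances > 0))
  fr <- fractions
  fr[4] <- max(fr[4], rven_floor)
  fr <- fr / sum(fr)
  structure(list(
    R_art = fr[1] * R_total, R_myo1 = fr[2] * R_total,
    R_myo2 = fr[3] * R_total, R_ven = fr[4] * R_total,
    C_art = compliances[1], C_myo = compliances[2], C_ven = compliances[3],
    pim_frac = pim_frac), class = "microcirculation_state")
}

#' Apply hyperaemia to a microcirculation state
#'
#' Divides every microvascular resistance by the hyperaemia factor `f`
#' (uniform maximal vasodilation); compliances are unchanged.
#'
#' @param micro a `microcirculation_state`.
#' @param f hyperaemia factor, `>= 1`.
#' @return the vasodilated `microcirculation_state`.
#' @export
apply_hyperaemia <- function(micro, f) {
  stopifnot(inherits(micro, "microcirculation_state"))
  if (!is.numeric(f) || length(f) != 1 || f < 1) {
    stop("hyperaemia factor f must be >= 1")
  }
  for (nm in c("R_art", "R_myo1", "R_myo2", "R_ven")) {
    micro[[nm]] <- micro[[nm]] / f
  }
  micro
}

# ---- epicardial network assembly -------------------------------------------

#' Poiseuille resistance of a cylindrical segment
#' @param length_cm,radius_cm segment dimensions (cm).
#' @param eta dynamic viscosity (Pa s).
#' @return resistance in Pa s ml^-1.
#' @keywords internal
poiseuille_resistance <- function(length_cm, radius_cm, eta) {
  8 * eta * (length_cm * 1e-2) / (pi * (radius_cm * 1e-2)^4) * 1e-6
}

# Epicardial path description of one branch: flow-fraction-weighted linear
# resistances split at the FFR measurement point (just distal to the lesion),
# plus the stenosis coefficients expressed in branch-inlet flow terms.
branch_epicardial <- function(geometry, vessel, params, cfg) {
  seg <- geometry$segments
  main <- seg[seg$vessel == vessel & !seg$side, , drop = FALSE]
  eta <- params[["eta"]]
  R_seg <- poiseuille_resistance(main$length_cm, main$radius_cm, eta) *
    main$flow_frac

  # left branches share the LM pressure drop; in branch-inlet flow terms the
  # LM resistance is divided by the branch share of left coronary flow
  R_lm <- 0
  if (vessel %in% c("LAD", "LCx")) {
    lm <- seg[seg$id == "C5", , drop = FALSE]
    share <- geometry$flow_split[[vessel]] /
      (geometry$flow_split[["LAD"]] + geometry$flow_split[["LCx"]])
    R_lm <- poiseuille_resistance(lm$length_cm, lm$radius_cm, eta) / share
  }

  slot <- geometry$lesion_slots[geometry$lesion_slots$vessel == vessel, ,
                                drop = FALSE]
  if (nrow(slot) == 0) {
    return(list(R_pre = R_lm + sum(R_seg), R_post = 0, R_sv = 0, K_t = 0,
                has_lesion = FALSE))
  }

  host_i <- match(slot$segment, main$id)
  host <- main[host_i, ]
  sev <- params[[paste0("sev_", vessel)]]
  len_mm <- params[[paste0("len_", vessel)]]
  pos <- params[["sten_position"]]

  L_host <- host$length_cm
  L_les <- min(len_mm / 10, L_host)              # cm, safety clamp
  start <- pos * (L_host - L_les)                # lesion start within host
  phi <- host$flow_frac

  co <- stenosis_coefficients(sev, len_mm, host$radius_cm,
                              eta, params[["rho"]], cfg$k_t)
  R_host_unit <- poiseuille_resistance(1, host$radius_cm, eta)  # per cm

  upstream <- if (host_i > 1) sum(R_seg[seq_len(host_i - 1)]) else 0
  downstream <- if (host_i < nrow(main)) sum(R_seg[(host_i + 1):nrow(main)]) else 0

  list(
    R_pre = R_lm + upstream + start * R_host_unit * phi,
    R_sv = co$R_v * phi,
    K_t = co$K_t * phi^2,
    R_post = (L_host - start - L_les) * R_host_unit * phi + downstream,
    has_lesion = TRUE)
}

# ---- parameter mapping ------------------------------------------------------

# unit-interval position of a value within the printed sampling range;
# used for the documented monotone affine timing maps
unit_in <- function(x, lo, hi) (x - lo) / (hi - lo)

#' Map a parameter vector to the lumped-network constants
#' @keywords internal
build_engine_inputs <- function(params, geometry, cfg) {
  p <- as.list(params)
  Pmean <- p$P_mean * MMHG_PA
  Pvo <- p$P_vo
  HF <- p$HF / 60                                # Hz
  qtot <- p$q_tot / 60                           # ml/s

  E_pa <- p$E * 1e6
  C_sys <- p$compliance_scale * cfg$C_ref / (E_pa * (1 - p$mu^2))
  R_sys <- p$resistance_scale * cfg$R_ref

  frac_sys <- 0.30 +
    0.08 * unit_in(p$l_s0, 1.9e-6, 2.2e-6) +
    0.04 * unit_in(p$v_0, 9.6e-6, 1e-5) -
    0.04 * unit_in(p$c_a, 1e6, 2e6) -
    0.03 * unit_in(p$sigma_a0, 9e4, 2.5e5)
  kappa <- 1 + unit_in(p$c_a, 1e6, 2e6)

  vessels <- c("LAD", "LCx", "RCA")
  Rlin <- Kt <- Rm1 <- Rm2 <- Rven <- Cart <- Cmyo <- Cven <- numeric(3)
  meas <- vector("list", 3)
  names(meas) <- vessels
  for (b in seq_along(vessels)) {
    v <- vessels[b]
    epi <- branch_epicardial(geometry, v, params, cfg)
    q_rest <- geometry$flow_split[[v]] * qtot
    R_tot <- (Pmean - Pvo) / q_rest
    micro <- microcirculation_state(
      R_tot,
      fractions = c(p$R_art_frac, p$R_myo1_frac, p$R_myo2_frac, p$R_ven_frac),
      compliances = c(p$C_art, p$C_myo, p$C_ven) * 1e-3,   # mm^3/Pa -> ml/Pa
      pim_frac = p$P_im_frac, rven_floor = cfg$rven_floor)
    micro <- apply_hyperaemia(micro, p$f_hyperemia)
    Rlin[b] <- epi$R_pre + epi$R_sv + epi$R_post + micro$R_art
    Kt[b] <- epi$K_t
    Rm1[b] <- micro$R_myo1; Rm2[b] <- micro$R_myo2; Rven[b] <- micro$R_ven
    Cart[b] <- micro$C_art; Cmyo[b] <- micro$C_myo; Cven[b] <- micro$C_ven
    meas[[b]] <- list(R_meas = epi$R_pre + epi$R_sv, K_t = epi$K_t,
                      has_lesion = epi$has_lesion)
  }

  list(
    T = 1 / HF, steps_per_cycle = cfg$steps_per_cycle,
    min_adapt = cfg$min_adapt, max_adapt = cfg$max_adapt,
    n_record = cfg$n_record, conv_tol = cfg$conv_tol, damping = cfg$damping,
    Emax0 = cfg$emax_coeff * p$sigma_a0 * (p$volume_fraction / 100),
    Emin = cfg$emin_coeff * (p$sigma_f0 * p$c_f + p$sigma_r0 * p$c_r),
    V0 = (p$volume_fraction / 100) * cfg$v_wall,
    frac_sys = frac_sys, kappa = kappa,
    R_mit = cfg$R_mit, R_av = cfg$R_av, Ppv = p$P_pul_ven,
    Z = cfg$z_frac * R_sys, Rp = (1 - cfg$z_frac) * R_sys,
    C_ao = cfg$c_ao_frac * C_sys, C_wk = (1 - cfg$c_ao_frac) * C_sys,
    Pvo = Pvo, Ptarget = Pmean, pim_frac = p$P_im_frac,
    Rlin = Rlin, Kt = Kt, Rm1 = Rm1, Rm2 = Rm2, Rven = Rven,
    Cart = Cart, Cmyo = Cmyo, Cven = Cven,
    meas = meas)
}

# ---- simulation -------------------------------------------------------------

#' Simulate one virtual patient
#'
#' Integrates the lumped coronary circulation over adaptive burn-in cycles
#' (during which contractility is rescaled until the cycle-mean aortic
#' pressure matches the `P_mean` input within tolerance) followed by analyzed
#' cycles recorded at `steps_per_cycle` samples per cycle. Hyperaemia is
#' applied to all microvascular resistances throughout, so FFR, left-main
#' flow and the physiological filters all refer to the hyperaemic state.
#'
#' @param params a `parameter_vector` (or named numeric in the space order).
#' @param geometry a `coronary_geometry` for the same patient type.
#' @param config an `engine_config`.
#' @return object of class `patient_simulation`: list with `status`
#'   (`"ok"` or `"solver_failure"`) and, when ok, `time` (s),
#'   `aortic_pressure` and `lv_pressure` (Pa series, `n_record * 1000`
#'   samples), `distal_pressure` (matrix, one column per lesion vessel, Pa),
#'   `branch_flow` (matrix, columns LAD/LCx/RCA, ml/min), `ffr` (named per
#'   lesion vessel), `ffr_flagged` (per lesion: outside (0, 1]), `cardiac_output`
#'   (l/min), `lm_flow` (cycle-mean, ml/min), and `meta` (controller scale,
#'   achieved mean pressure, cycles run).
#' @export
simulate_patient <- function(params, geometry, config = engine_config()) {
  stopifnot(inherits(geometry, "coronary_geometry"))
  if (inherits(params, "parameter_vector")) {
    sp <- attr(params, "space")
    if (!is.null(sp) && sp$patient_type != geometry$patient_type) {
      stop("parameter vector and geometry patient types differ")
    }
  }
  inp <- build_engine_inputs(params, geometry, config)
  res <- .engine_run(inp[setdiff(names(inp), "meas")])

  failed <- res$status != 0 ||
    !is.finite(res$mean_pao) ||
    abs(res$mean_pao - inp$Ptarget) / inp$Ptarget > config$mean_tol
  if (failed) {
    return(structure(list(status = "solver_failure",
                          meta = list(scale = res$scale,
                                      converged = isTRUE(res$converged),
                                      cycles_run = res$cycles_run,
                                      mean_pao = res$mean_pao)),
                     class = "patient_simulation"))
  }

  vessels <- c("LAD", "LCx", "RCA")
  lesioned <- vapply(inp$meas, function(m) m$has_lesion, logical(1))
  q <- res$q_branch                              # ml/s, branch inlet flow
  pd <- matrix(NA_real_, nrow = length(res$p_ao), ncol = sum(lesioned))
  colnames(pd) <- vessels[lesioned]
  j <- 0
  for (b in which(lesioned)) {
    j <- j + 1
    m <- inp$meas[[b]]
    pd[, j] <- res$p_ao - m$R_meas * q[, b] - m$K_t * q[, b] * abs(q[, b])
  }
  ffr <- vapply(seq_len(ncol(pd)), function(jj) {
    compute_ffr(pd[, jj], res$p_ao, n_beats = config$n_record)
  }, numeric(1))
  names(ffr) <- colnames(pd)

  lm_flow <- mean(q[, 1] + q[, 2]) * 60          # LAD + LCx, ml/min
  co <- mean(res$q_av) * 60 / 1000               # l/min

  structure(list(
    status = "ok",
    time = res$time,
    aortic_pressure = res$p_ao,
    lv_pressure = res$p_lv,
    distal_pressure = pd,
    branch_flow = q * 60,
    ffr = ffr,
    ffr_flagged = ffr <= 0 | ffr > 1 + 1e-9,
    cardiac_output = co,
    lm_flow = lm_flow,
    meta = list(scale = res$scale, converged = isTRUE(res$converged),
                cycles_run = res$cycles_run, mean_pao = res$mean_pao,
                steps_per_cycle = config$steps_per_cycle,
                n_record = config$n_record)),
    class = "patient_simulation")
}

#' @export
print.patient_simulation <- function(x, ...) {
  cat("<patient_simulation> status:", x$status)
  if (x$status == "ok") {
    cat(sprintf("; FFR: %s; CO %.2f l/min; LM %.0f ml/min",
                paste(sprintf("%s=%.3f", names(x$ffr), x$ffr), collapse = " "),
                x$cardiac_output, x$lm_flow))
  }
  cat("\n")
  invisible(x)
}
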
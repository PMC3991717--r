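#' Contrast-agent injection rate
#'
#' The injection is a step function: a constant amount-rate `dose/duration`
#' over the injection window and zero elsewhere, so its integral over all
#' time equals the administered dose.
#'
#' @param t time(s), s; must be >= 0.
#' @param protocol an [injection_protocol()].
#' @return Amount rate(s), mmol/s (vectorised over `t`).
#' @export
injection_rate <- function(t, protocol) {
  stopifnot(inherits(protocol, "injection_protocol"))
  if (any(t < 0)) stop("time must be >= 0")
  on <- t >= protocol$start_time & t < protocol$start_time + protocol$duration
  ifelse(on, total_dose(protocol) / protocol$duration, 0)
}

#' Amount flux along one directed edge
#'
#' Evaluates the kinetic law of a single directed flux at a given state.
#' A linear law returns `k * C_source * V_ref`; a Michaelis-Menten law
#' returns `v_max * C_source / (K_m + C_source) * V_ref`. The plasma-to-EES
#' diffusion flux is driven by the free concentration
#' `C_p - C_alb = (1 - albumin_bound_fraction) * C_p`. `V_ref` is the
#' source or destination volume according to the edge's `vref` convention.
#'
#' @param edge edge name (see [model_spec()]).
#' @param state named concentrations, mmol/L; must contain `C_p`, `C_e`,
#'   `C_h` as needed and be non-negative.
#' @param params a [kinetic_parameters()] object.
#' @param phys a [physiology()] object.
#' @param spec a [model_spec()]; the edge must be present in it.
#' @return Amount flux, mmol/s (always >= 0).
#' @export
flux_amount <- function(edge, state, params, phys, spec) {
  if (!edge %in% .EDGES)
    stop("unknown edge '", edge, "'; valid edges: ",
         paste(.EDGES, collapse = ", "))
  cfg <- spec$flux_config[[edge]]
  if (!cfg$present)
    stop("edge ", edge, " is absent from variant ", spec$name)
  conc_of <- c(plasma = "C_p", ees = "C_e", hepatocyte = "C_h", splenic = "C_s")
  src <- .EDGE_SRC[[edge]]
  cs <- state[[conc_of[[src]]]]
  if (is.null(cs)) stop("state must contain ", conc_of[[src]])
  if (any(cs < 0)) stop("concentrations must be >= 0")
  if (edge == "plasma_to_ees")
    cs <- cs * (1 - phys$albumin_bound_fraction)
  comp <- if (cfg$vref == "source") src else .EDGE_DST[[edge]]
  vref <- switch(comp, plasma = phys$V_plasma, ees = phys$V_ees,
                 hepatocyte = hepatocyte_volume(phys))
  rate <- c(plasma_to_ees = params$k_diff, ees_to_plasma = params$k_diff,
            plasma_to_hepatocyte = params$k_ph,
            hepatocyte_to_plasma = params$k_hp,
            hepatocyte_to_bile = params$k_hb,
            plasma_to_urine = params$k_kid)
  if (cfg$law == "linear") {
    rate[[edge]] * cs * vref
  } else {
    mm <- params$mm[[edge]]
    if (is.null(mm)) stop("no Michaelis-Menten constants for edge ", edge)
    mm$v_max * cs / (mm$K_m + cs) * vref
  }
}

#' Simulate the compartmental model
#'
#' Integrates the whole-body ODE system from all-zero initial state with an
#' adaptive Dormand-Prince (RK45) scheme, splitting the integration at the
#' injection step edges. Internally the solver tracks compartment amounts,
#' so total mass (compartments + sinks) equals the cumulative injected
#' amount up to solver tolerance at every output time.
#'
#' @param spec a [model_spec()].
#' @param params a [kinetic_parameters()] object.
#' @param phys a [physiology()] object.
#' @param protocol an [injection_protocol()].
#' @param times sorted non-negative output times, s.
#' @param rtol,atol solver relative/absolute tolerances.
#' @return A `trajectory`: a data.frame with columns `time`, concentrations
#'   `C_p`, `C_e`, `C_h`, `C_s` (mmol/L) and cumulative sink amounts `A_b`,
#'   `A_u` (mmol); attributes carry the dose and volumes.
#' @export
simulate_model <- function(spec, params, phys, protocol, times,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "model_spec"), inherits(params, "kinetic_parameters"),
            inherits(phys, "physiology"), inherits(protocol, "injection_protocol"))
  if (length(times) == 0) stop("times must be non-empty")
  if (any(times < 0) || is.unsorted(times))
    stop("times must be sorted and non-negative")
  Vh <- hepatocyte_volume(phys)
  em <- .edge_matrix(spec, params, phys)
  dose <- total_dose(protocol)
  rate <- if (dose > 0) dose / protocol$duration else 0
  am <- .simulate_amounts(as.numeric(times), phys$V_plasma, phys$V_ees, Vh,
                          phys$albumin_bound_fraction, em,
                          protocol$start_time,
                          protocol$start_time + protocol$duration, rate,
                          rtol, atol, 1e7)
  traj <- data.frame(time = as.numeric(times),
                     C_p = am[, 1] / phys$V_plasma,
                     C_e = am[, 2] / phys$V_ees,
                     C_h = am[, 3] / Vh,
                     C_s = am[, 4],
                     A_b = am[, 5],
                     A_u = am[, 6])
  structure(traj, dose = dose, V_plasma = phys$V_plasma, V_ees = phys$V_ees,
            V_hepatocyte = Vh, variant = spec$name,
            class = c("trajectory", "data.frame"))
}

#' Biliary and renal elimination fractions
#'
#' @param traj a trajectory from [simulate_model()].
#' @param dose administered dose, mmol; defaults to the trajectory's dose.
#' @return Named vector `c(bile_pct, urine_pct)`: percent of dose in each
#'   sink at the final trajectory time.
#' @export
elimination_fractions <- function(traj, dose = attr(traj, "dose")) {
  if (is.null(dose) || dose <= 0) stop("dose must be > 0")
  n <- nrow(traj)
  c(bile_pct = 100 * traj$A_b[n] / dose,
    urine_pct = 100 * traj$A_u[n] / dose)
}

#' Dose-normalised plasma content
#'
#' The percent of the administered dose residing in the plasma pool at time
#' `t`: `100 * C_p(t) * V_plasma / dose`. The published physiological-realism
#' ("ad hoc") constraint requires this to exceed 1% at t = 3 h.
#'
#' @param traj a trajectory from [simulate_model()].
#' @param dose administered dose, mmol.
#' @param t time, s; must lie within the trajectory's span (linear
#'   interpolation between output points).
#' @return Percent of dose.
#' @export
plasma_dose_fraction <- function(traj, dose = attr(traj, "dose"),
                                 t = max(traj$time)) {
  if (is.null(dose) || dose <= 0) stop("dose must be > 0")
  if (t < min(traj$time) || t > max(traj$time))
    stop("t = ", t, " outside the trajectory span [", min(traj$time), ", ",
         max(traj$time), "]")
  Vp <- attr(traj, "V_plasma")
  cp <- if (t %in% traj$time) traj$C_p[match(t, traj$time)] else
    approx(traj$time, traj$C_p, xout = t)$y
  100 * cp * Vp / dose
}
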
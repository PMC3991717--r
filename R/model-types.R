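#' Kinetic rate parameters of the contrast-agent model
#'
#' Bundles the five fitted quantities of the whole-body gadoxetate model --
#' the signal scaling `xi` and the first-order rate constants for
#' hepatocyte-to-bile excretion (`k_hb`), plasma/EES diffusion (`k_diff`),
#' hepatocyte uptake (`k_ph`) and hepatocyte-to-plasma backflux (`k_hp`) --
#' together with the fixed (never fitted) renal elimination rate `k_kid` and
#' optional Michaelis-Menten constants for model variants that saturate a
#' flux.
#'
#' @param xi dimensionless scaling between modelled relaxivity change and the
#'   measured ROI signal; must be > 0.
#' @param k_hb,k_diff,k_ph,k_hp first-order rate constants, 1/s; must be
#'   >= 0.
#' @param k_kid renal elimination rate constant, 1/s. The default is the
#'   glomerular-filtration clearance of 118 mL/min divided by the plasma
#'   volume of [physiology()].
#' @param mm optional named list of Michaelis-Menten constants, one entry per
#'   saturating edge (`plasma_to_hepatocyte`, `hepatocyte_to_plasma`,
#'   `hepatocyte_to_bile`), each a list with elements `v_max`
#'   (mmol L^-1 s^-1, >= 0) and `K_m` (mmol L^-1, > 0).
#' @return An object of class `kinetic_parameters`.
#' @seealso [reference_parameters()] for the published optimal estimates.
#' @export
kinetic_parameters <- function(xi = 1, k_hb = 0, k_diff = 0, k_ph = 0,
                               k_hp = 0, k_kid = renal_rate(), mm = list()) {
  rates <- c(k_hb = k_hb, k_diff = k_diff, k_ph = k_ph, k_hp = k_hp,
             k_kid = k_kid)
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi) || xi <= 0)
    stop("xi must be a single positive number")
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  if (length(mm)) {
    bad <- setdiff(names(mm), c("plasma_to_hepatocyte", "hepatocyte_to_plasma",
                                "hepatocyte_to_bile"))
    if (length(bad))
      stop("unknown Michaelis-Menten edge(s): ", paste(bad, collapse = ", "))
    for (nm in names(mm)) {
      m <- mm[[nm]]
      if (!is.list(m) || is.null(m$v_max) || is.null(m$K_m))
        stop("mm$", nm, " must be a list with v_max and K_m")
      if (m$v_max < 0) stop("v_max must be >= 0 for edge ", nm)
      if (m$K_m <= 0) stop("K_m must be > 0 for edge ", nm)
    }
  }
  structure(list(xi = xi, k_hb = k_hb, k_diff = k_diff, k_ph = k_ph,
                 k_hp = k_hp, k_kid = k_kid, mm = mm),
            class = "kinetic_parameters")
}

#' Renal elimination rate constant from clearance
#'
#' Glomerular filtration clears gadoxetate from plasma at an apparent
#' clearance of about 118 mL/min; dividing by the plasma volume gives the
#' first-order rate constant used by the model.
#'
#' @param clearance_mL_min renal plasma clearance, mL/min.
#' @param V_plasma plasma volume, L.
#' @return Rate constant, 1/s.
#' @export
renal_rate <- function(clearance_mL_min = 118, V_plasma = 1.94) {
  if (clearance_mL_min < 0 || V_plasma <= 0)
    stop("clearance must be >= 0 and V_plasma > 0")
  (clearance_mL_min / 1000 / 60) / V_plasma
}

#' Published optimal parameter estimates for the reference model
#'
#' The best-fit values of the five estimated parameters of the minimal
#' all-linear model (variant M0) for healthy human subjects:
#' `xi = 1.604`, `k_hb = 3.852e-4`, `k_diff = 1.731e-3`, `k_ph = 4.776e-3`,
#' `k_hp = 2.857e-4` (rates in 1/s), with the fixed renal rate from
#' [renal_rate()].
#'
#' @return A [kinetic_parameters()] object.
#' @export
reference_parameters <- function() {
  kinetic_parameters(xi = 1.604, k_hb = 3.852e-4, k_diff = 1.731e-3,
                     k_ph = 4.776e-3, k_hp = 2.857e-4)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (1/s unless noted):\n")
  cat(sprintf("  xi     = %.4g (dimensionless)\n", x$xi))
  for (nm in c("k_hb", "k_diff", "k_ph", "k_hp", "k_kid"))
    cat(sprintf("  %-6s = %.4g\n", nm, x[[nm]]))
  if (length(x$mm))
    for (nm in names(x$mm))
      cat(sprintf("  MM %s: v_max = %.4g mmol/L/s, K_m = %.4g mmol/L\n",
                  nm, x$mm[[nm]]$v_max, x$mm[[nm]]$K_m))
  invisible(x)
}

#' Standard-human physiology for the whole-body model
#'
#' Compartment volumes, blood composition, ROI composition fractions and
#' in-situ relaxivities for a "standard human". The plasma volume of 1.94 L
#' follows from an assumed hematocrit of 0.43. The EES volume is an
#' *effective* whole-body extracellular-extravascular distribution volume and
#' the hepatocyte volume is `V_liver * hepatocyte_fraction`; both were fixed
#' by calibrating the shipped flux-reference convention against the published
#' 3-h biliary/renal elimination windows (see the package vignette).
#'
#' @param V_plasma,V_ees,V_liver compartment volumes, L.
#' @param hepatocyte_fraction volume fraction of the liver made up of
#'   hepatocyte intracellular space.
#' @param hematocrit erythrocyte volume fraction of whole blood, in `[0, 1)`.
#' @param albumin_bound_fraction fraction of plasma agent bound to serum
#'   albumin (bound agent contributes to the plasma concentration and signal
#'   but not to transcapillary diffusion), in `[0, 1)`.
#' @param roi_fractions named list (`liver`, `spleen`, `vein`) of named
#'   compartment-fraction vectors gamma.
#' @param relaxivities named vector of in-situ r1 relaxivities at 1.5 T and
#'   310 K, L mmol^-1 s^-1.
#' @return An object of class `physiology`.
#' @export
physiology <- function(V_plasma = 1.94,
                       V_ees = 21.0,
                       V_liver = 1.7,
                       hepatocyte_fraction = 0.68,
                       hematocrit = 0.43,
                       albumin_bound_fraction = 0.10,
                       roi_fractions = list(
                         liver = c(plasma = 0.12, ees = 0.20, hepatocyte = 0.68),
                         spleen = c(plasma = 0.35, ees = 0.20),
                         vein = c(plasma = 1.0)),
                       relaxivities = c(plasma = 7.3, ees = 6.9,
                                        hepatocyte = 10.7, splenic = 0)) {
  vols <- c(V_plasma = V_plasma, V_ees = V_ees, V_liver = V_liver)
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("all volumes must be finite and > 0")
  if (hepatocyte_fraction <= 0 || hepatocyte_fraction > 1)
    stop("hepatocyte_fraction must be in (0, 1]")
  if (hematocrit < 0 || hematocrit >= 1)
    stop("hematocrit must be in [0, 1)")
  if (albumin_bound_fraction < 0 || albumin_bound_fraction >= 1)
    stop("albumin_bound_fraction must be in [0, 1)")
  if (!all(c("liver", "spleen", "vein") %in% names(roi_fractions)))
    stop("roi_fractions must contain liver, spleen and vein")
  for (roi in names(roi_fractions)) {
    g <- roi_fractions[[roi]]
    if (any(g < 0) || any(g > 1))
      stop("ROI fractions must lie in [0, 1] (ROI ", roi, ")")
    if (!all(names(g) %in% .COMPARTMENTS))
      stop("unknown compartment in roi_fractions$", roi)
  }
  gv <- roi_fractions$vein
  if (!identical(names(gv), "plasma") || gv[["plasma"]] != 1)
    stop("the vein ROI must consist of plasma only (gamma_plasma = 1)")
  if (!all(.COMPARTMENTS %in% names(relaxivities)))
    stop("relaxivities must name all compartments")
  structure(list(V_plasma = V_plasma, V_ees = V_ees, V_liver = V_liver,
                 hepatocyte_fraction = hepatocyte_fraction,
                 hematocrit = hematocrit,
                 albumin_bound_fraction = albumin_bound_fraction,
                 roi_fractions = roi_fractions,
                 relaxivities = relaxivities),
            class = "physiology")
}

#' Hepatocyte compartment volume
#'
#' @param phys a [physiology()] object.
#' @return `V_liver * hepatocyte_fraction`, L.
#' @export
hepatocyte_volume <- function(phys) phys$V_liver * phys$hepatocyte_fraction

#' @export
print.physiology <- function(x, ...) {
  cat("Standard-human physiology:\n")
  cat(sprintf("  V_plasma = %.3g L, V_ees = %.3g L, V_liver = %.3g L\n",
              x$V_plasma, x$V_ees, x$V_liver))
  cat(sprintf("  hepatocyte volume = %.3g L (fraction %.2f)\n",
              hepatocyte_volume(x), x$hepatocyte_fraction))
  cat(sprintf("  hematocrit = %.2f, albumin-bound fraction = %.2f\n",
              x$hematocrit, x$albumin_bound_fraction))
  invisible(x)
}

#' Contrast-agent injection protocol
#'
#' The agent enters plasma as a step input: a constant amount-rate
#' `dose / duration` over `[start_time, start_time + duration)`. The clinical
#' estimation protocol is a 0.025 mmol/kg bolus over 7 s into a 73 kg
#' subject; the high-dose validation protocol infuses 0.2--0.5 mmol/kg over
#' 10 min into 83 kg subjects.
#'
#' @param dose_per_kg dose, mmol per kg body weight; >= 0.
#' @param body_weight subject body weight, kg.
#' @param duration injection duration, s; > 0.
#' @param mode `"bolus"` or `"infusion"` (label only; the input shape is the
#'   step function in both cases).
#' @param start_time injection start, s.
#' @return An object of class `injection_protocol`.
#' @export
injection_protocol <- function(dose_per_kg = 0.025, body_weight = 73,
                               duration = 7, mode = c("bolus", "infusion"),
                               start_time = 0) {
  mode <- match.arg(mode)
  if (dose_per_kg < 0) stop("dose_per_kg must be >= 0")
  if (body_weight <= 0) stop("body_weight must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (start_time < 0) stop("start_time must be >= 0")
  structure(list(dose_per_kg = dose_per_kg, body_weight = body_weight,
                 duration = duration, mode = mode, start_time = start_time),
            class = "injection_protocol")
}

#' Total injected dose
#'
#' @param protocol an [injection_protocol()].
#' @return `dose_per_kg * body_weight`, mmol.
#' @export
total_dose <- function(protocol) protocol$dose_per_kg * protocol$body_weight

#' @export
print.injection_protocol <- function(x, ...) {
  cat(sprintf("%s of %.3g mmol/kg x %.3g kg = %.4g mmol over %.3g s (start %g s)\n",
              x$mode, x$dose_per_kg, x$body_weight, total_dose(x),
              x$duration, x$start_time))
  invisible(x)
}
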
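#' Model structure specification
#'
#' A `model_spec` names which directed fluxes exist, the kinetic law of each
#' (`"linear"` mass action or `"michaelis_menten"`), and the reference volume
#' (`"source"` or `"destination"` compartment) that converts the
#' concentration rate law into an amount flux in mmol/s. The two sinks
#' (hepatocyte-to-bile, plasma-to-urine) are strictly irreversible and the
#' splenic intracellular space exchanges no agent in any variant.
#'
#' The shipped default reference-volume convention was fixed by calibration
#' against the published 3-h elimination windows (see the vignette): the
#' bidirectional plasma/EES diffusion edge is referenced to the EES volume in
#' both directions, hepatocyte uptake to the hepatocyte volume, hepatocyte
#' backflux to the plasma volume, and both sinks to their source volume. Mass
#' is conserved under any convention because the same amount flux leaves the
#' source and enters the destination.
#'
#' @param name variant label.
#' @param flux_config named list over the directed edges `plasma_to_ees`,
#'   `ees_to_plasma`, `plasma_to_hepatocyte`, `hepatocyte_to_plasma`,
#'   `hepatocyte_to_bile`, `plasma_to_urine`; each element is a list with
#'   `present` (logical), `law` (`"linear"` or `"michaelis_menten"`) and
#'   `vref` (`"source"` or `"destination"`).
#' @return An object of class `model_spec`.
#' @seealso [build_variant()] for the registry of published variants M0-M9.
#' @export
model_spec <- function(name, flux_config) {
  if (!all(.EDGES %in% names(flux_config)))
    stop("flux_config must configure all edges: ",
         paste(setdiff(.EDGES, names(flux_config)), collapse = ", "))
  bad <- setdiff(names(flux_config), .EDGES)
  if (length(bad)) stop("unknown edge(s): ", paste(bad, collapse = ", "))
  for (e in .EDGES) {
    cfg <- flux_config[[e]]
    if (!is.list(cfg) || !all(c("present", "law", "vref") %in% names(cfg)))
      stop("edge ", e, " must be a list(present, law, vref)")
    if (!cfg$law %in% c("linear", "michaelis_menten"))
      stop("edge ", e, ": law must be linear or michaelis_menten")
    if (!cfg$vref %in% c("source", "destination"))
      stop("edge ", e, ": vref must be source or destination")
    if (.EDGE_DST[[e]] %in% .SINKS && cfg$vref == "destination")
      stop("edge ", e, ": sinks have no volume; vref must be source")
  }
  if (!flux_config$plasma_to_urine$present)
    stop("renal elimination (plasma_to_urine) is present in every variant")
  structure(list(name = name, flux_config = flux_config[.EDGES]),
            class = "model_spec")
}

.default_vref <- c(plasma_to_ees = "destination",   # V_ees
                   ees_to_plasma = "source",        # V_ees
                   plasma_to_hepatocyte = "destination",  # V_h
                   hepatocyte_to_plasma = "destination",  # V_plasma
                   hepatocyte_to_bile = "source",   # V_h
                   plasma_to_urine = "source")      # V_plasma

.edge_cfg <- function(present = TRUE, law = "linear", vref) {
  list(present = present, law = law, vref = vref)
}

.variant_registry <- function() {
  base <- lapply(.EDGES, function(e) .edge_cfg(vref = .default_vref[[e]]))
  names(base) <- .EDGES
  mm_bile <- function(cfg) { cfg$hepatocyte_to_bile$law <- "michaelis_menten"; cfg }
  mm_uptake <- function(cfg) {
    cfg$plasma_to_hepatocyte$law <- "michaelis_menten"
    if (cfg$hepatocyte_to_plasma$present)
      cfg$hepatocyte_to_plasma$law <- "michaelis_menten"
    cfg
  }
  drop <- function(cfg, edges) { for (e in edges) cfg[[e]]$present <- FALSE; cfg }
  list(
    M0 = base,
    M1 = mm_bile(base),
    M2 = drop(base, "hepatocyte_to_plasma"),
    M3 = mm_bile(base),
    M4 = mm_bile(drop(base, "hepatocyte_to_plasma")),
    M5 = drop(base, c("plasma_to_hepatocyte", "hepatocyte_to_plasma")),
    M6 = drop(base, "hepatocyte_to_bile"),
    M7 = mm_bile(drop(base, c("plasma_to_ees", "ees_to_plasma"))),
    M8 = mm_uptake(mm_bile(base)),
    M9 = mm_uptake(mm_bile(drop(base, "hepatocyte_to_plasma")))
  )
}

#' Build a named model variant
#'
#' Returns the flux configuration of one of the registered model structures.
#' `M0` is the proposed minimal model: all four edges present with linear
#' laws and reversible hepatocyte exchange. The rejected alternatives differ
#' by saturating the biliary flux (M1/M3/M4/M7/M8/M9), saturating hepatocyte
#' exchange (M8/M9), making uptake irreversible (M2/M4/M9), or removing the
#' uptake (M5), biliary (M6) or diffusion (M7) edge.
#'
#' @param name one of `"M0"` ... `"M9"`.
#' @return A [model_spec()].
#' @export
build_variant <- function(name) {
  reg <- .variant_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg))
    stop("unknown variant '", name, "'; valid names: ",
         paste(names(reg), collapse = ", "))
  model_spec(name, reg[[name]])
}

#' Names of the parameters fitted under a model structure
#'
#' `xi` is always fitted. Each present linear edge other than renal
#' elimination contributes its rate constant; each Michaelis-Menten edge
#' contributes `v_max_<edge>` and `K_m_<edge>`. The renal rate `k_kid` is
#' fixed, never fitted.
#'
#' @param spec a [model_spec()].
#' @return Character vector of parameter names.
#' @export
fitted_parameter_names <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  nms <- "xi"
  fc <- spec$flux_config
  if (fc$plasma_to_ees$present) nms <- c(nms, "k_diff")
  rate_name <- c(plasma_to_hepatocyte = "k_ph", hepatocyte_to_plasma = "k_hp",
                 hepatocyte_to_bile = "k_hb")
  for (e in names(rate_name)) {
    if (!fc[[e]]$present) next
    if (fc[[e]]$law == "linear") nms <- c(nms, rate_name[[e]])
    else nms <- c(nms, paste0("v_max_", e), paste0("K_m_", e))
  }
  nms
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model variant", x$name, "\n")
  for (e in .EDGES) {
    cfg <- x$flux_config[[e]]
    cat(sprintf("  %-22s %s%s\n", e,
                if (cfg$present) cfg$law else "(absent)",
                if (cfg$present) paste0(", vref=", cfg$vref) else ""))
  }
  cat("  fitted:", paste(fitted_parameter_names(x), collapse = ", "), "\n")
  invisible(x)
}

# numeric 6 x 5 edge matrix for the C++ core:
# columns present, law, k-or-vmax, km, vref (L)
.edge_matrix <- function(spec, params, phys, allow_missing_mm = FALSE) {
  Vh <- hepatocyte_volume(phys)
  vol <- c(plasma = phys$V_plasma, ees = phys$V_ees, hepatocyte = Vh)
  rate <- c(plasma_to_ees = params$k_diff, ees_to_plasma = params$k_diff,
            plasma_to_hepatocyte = params$k_ph,
            hepatocyte_to_plasma = params$k_hp,
            hepatocyte_to_bile = params$k_hb, plasma_to_urine = params$k_kid)
  m <- matrix(0, nrow = 6, ncol = 5, dimnames = list(.EDGES, NULL))
  for (i in seq_along(.EDGES)) {
    e <- .EDGES[i]
    cfg <- spec$flux_config[[e]]
    comp <- if (cfg$vref == "source") .EDGE_SRC[[e]] else .EDGE_DST[[e]]
    m[i, 1] <- as.numeric(cfg$present)
    m[i, 5] <- vol[[comp]]
    if (cfg$law == "linear") {
      m[i, 2] <- 0; m[i, 3] <- rate[[e]]; m[i, 4] <- 1
    } else {
      mm <- params$mm[[e]]
      if (cfg$present && is.null(mm) && !allow_missing_mm)
        stop("variant ", spec$name, " needs Michaelis-Menten constants for ",
             e, " (params$mm$", e, ")")
      m[i, 2] <- 1
      m[i, 3] <- if (is.null(mm)) 0 else mm$v_max
      m[i, 4] <- if (is.null(mm)) 1 else mm$K_m
    }
  }
  m
}
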
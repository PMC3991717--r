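#' Profile-likelihood confidence interval for one parameter
#'
#' Walks the parameter multiplicatively up and down from the fitted optimum,
#' re-optimising all other parameters at each grid point, until the
#' re-optimised cost can no longer be kept below the absolute chi-square
#' acceptance threshold. The confidence bound is the last grid value whose
#' re-optimised cost passes; a walk that reaches the span limit without
#' crossing the threshold marks the interval as not finite in that
#' direction.
#'
#' Following the published analysis, the physiological-realism constraint
#' can be folded into the profiled cost as an extra squared residual,
#' `((min_pct - plasma_pct)/sigma_pct)^2`, active only when the plasma
#' content falls below `min_pct` at 3 h; this is a softened version of the
#' strict filter and correspondingly widens the parameter uncertainty.
#'
#' @param spec a [model_spec()].
#' @param data the fitted dataset.
#' @param param_name one of the variant's fitted parameter names.
#' @param fit_result the `fit_result` holding the unconstrained optimum.
#' @param phys,protocol model context.
#' @param threshold absolute acceptance threshold (default: the fit's).
#' @param step_factor multiplicative grid step (> 1).
#' @param span span limit as a multiple of the optimum, per direction.
#' @param reopt_maxit Nelder-Mead iteration cap per re-optimisation.
#' @param include_constraint fold the plasma constraint into the cost?
#' @param constraint list with `t` (s), `min_pct`, `sigma_pct` (percentage
#'   points).
#' @param bounds bounds for the re-optimised parameters.
#' @return An object of class `profile_likelihood_result`: grid, profiled
#'   costs, `lower`, `upper`, `finite` (both bounds found inside the span).
#' @export
profile_likelihood <- function(spec, data, param_name, fit_result,
                               phys = physiology(),
                               protocol = attr(data, "protocol"),
                               threshold = fit_result$threshold,
                               step_factor = 1.05, span = 1000,
                               reopt_maxit = 150,
                               include_constraint = TRUE,
                               constraint = list(t = 10800, min_pct = 1,
                                                 sigma_pct = 0.25),
                               bounds = default_bounds(spec,
                                 with_scale = any(data$label == "plasma_sample"))) {
  nms <- colnames(bounds)
  if (!param_name %in% nms)
    stop("unknown parameter '", param_name, "'; fitted parameters: ",
         paste(nms, collapse = ", "))
  if (step_factor <= 1) stop("step_factor must be > 1")
  if (is.null(fit_result$optimal_vector))
    stop("fit_result carries no optimum; fit the model first")
  obj <- .make_objective(spec, data, phys, protocol,
                         constraint = if (include_constraint) constraint)
  other <- setdiff(nms, param_name)
  lo <- log10(bounds["lower", other]); hi <- log10(bounds["upper", other])
  profiled_cost <- function(pval, start_l) {
    if (length(other) == 0L)
      return(list(cost = obj(setNames(pval, param_name)), par = numeric(0)))
    fn <- function(l) {
      l <- pmin(pmax(l, lo), hi)
      par <- setNames(c(10^l, pval), c(other, param_name))
      obj(par)
    }
    op <- optim(start_l, fn, method = "Nelder-Mead",
                control = list(maxit = reopt_maxit, reltol = 1e-10))
    list(cost = op$value, par = pmin(pmax(op$par, lo), hi))
  }
  opt_v <- fit_result$optimal_vector
  p0 <- opt_v[[param_name]]
  start0 <- log10(pmin(pmax(opt_v[other], 10^lo), 10^hi))
  base <- profiled_cost(p0, start0)
  grid <- p0; costs <- base$cost
  walk <- function(direction) {
    pv <- p0; start_l <- base$par; k <- 0
    last_ok <- if (base$cost <= threshold) p0 else NA_real_
    finite <- FALSE
    while (TRUE) {
      k <- k + 1
      pv <- p0 * step_factor^(direction * k)
      if (pv > p0 * span || pv < p0 / span) break
      res <- profiled_cost(pv, start_l)
      grid <<- c(grid, pv); costs <<- c(costs, res$cost)
      if (res$cost <= threshold) {
        last_ok <- pv
        start_l <- res$par
      } else {
        finite <- TRUE
        break
      }
    }
    list(bound = last_ok, finite = finite)
  }
  up <- walk(+1)
  dn <- walk(-1)
  ord <- order(grid)
  structure(list(parameter = param_name, grid = grid[ord],
                 costs = costs[ord],
                 optimum = p0, optimal_cost = base$cost,
                 lower = dn$bound, upper = up$bound,
                 finite = up$finite && dn$finite,
                 threshold = threshold,
                 include_constraint = include_constraint),
            class = "profile_likelihood_result")
}

#' @export
print.profile_likelihood_result <- function(x, ...) {
  cat(sprintf("Profile likelihood for %s: optimum %.4g, interval [%.4g, %.4g] (%s)\n",
              x$parameter, x$optimum, x$lower, x$upper,
              if (x$finite) "finite" else "NOT finite within span"))
  invisible(x)
}

#' Profile likelihood over all fitted parameters
#'
#' @param spec,data,fit_result,... passed to [profile_likelihood()].
#' @return A list of `profile_likelihood_result` plus a `summary`
#'   data.frame (parameter, optimum, lower, upper, finite).
#' @export
profile_all <- function(spec, data, fit_result, ...) {
  nms <- names(fit_result$optimal_vector)
  res <- lapply(nms, function(nm)
    profile_likelihood(spec, data, nm, fit_result, ...))
  names(res) <- nms
  summary <- data.frame(
    parameter = nms,
    optimum = vapply(res, function(r) r$optimum, numeric(1)),
    lower = vapply(res, function(r) r$lower, numeric(1)),
    upper = vapply(res, function(r) r$upper, numeric(1)),
    finite = vapply(res, function(r) r$finite, logical(1)))
  rownames(summary) <- NULL
  list(profiles = res, summary = summary,
       n_finite = sum(summary$finite))
}

# thin an ensemble to at most cap members by cost-stratified selection
.thin_ensemble <- function(ens, cap = 500) {
  if (nrow(ens) <= cap) return(ens)
  ord <- order(ens$cost)
  idx <- ord[unique(round(seq(1, length(ord), length.out = cap)))]
  ens[idx, , drop = FALSE]
}

#' Core-prediction envelope over an acceptable ensemble
#'
#' Simulates every (optionally thinned) member of the statistically
#' acceptable ensemble and returns the pointwise minimum and maximum of the
#' requested model quantity: the translation of parameter uncertainty into
#' prediction uncertainty.
#'
#' @param ensemble data.frame of acceptable parameter vectors (one row per
#'   member, columns the fitted parameters, a `cost` column allowed), e.g.
#'   `fit_result$ensemble`.
#' @param quantity one of `"liver"`, `"spleen"`, `"vein"` (ROI signals),
#'   `"plasma_fraction"` (percent of dose in plasma), `"bile_pct"`,
#'   `"urine_pct"` (cumulative elimination percent).
#' @param spec,phys,protocol model context.
#' @param times output times, s.
#' @param cap maximum number of members simulated (cost-stratified
#'   thinning). Subset/superset band nesting is guaranteed only when `cap`
#'   covers both ensembles, since thinning may select different members.
#' @return A `prediction_band`: data.frame (`time`, `lower`, `upper`) with
#'   attributes `quantity` and `n_members`.
#' @export
core_prediction_band <- function(ensemble, quantity, spec,
                                 phys = physiology(),
                                 protocol = injection_protocol(),
                                 times = seq(0, 2400, by = 60), cap = 500) {
  qs <- c("liver", "spleen", "vein", "plasma_fraction", "bile_pct",
          "urine_pct")
  if (!quantity %in% qs)
    stop("unknown quantity '", quantity, "'; valid: ",
         paste(qs, collapse = ", "))
  if (is.null(ensemble) || nrow(ensemble) == 0)
    stop("ensemble is empty; run fit_model() (and check rejection) first")
  ens <- .thin_ensemble(ensemble, cap)
  nms <- setdiff(names(ens), "cost")
  dose <- total_dose(protocol)
  vals <- matrix(NA_real_, nrow = length(times), ncol = nrow(ens))
  for (i in seq_len(nrow(ens))) {
    par <- setNames(as.numeric(ens[i, nms]), nms)
    p <- .params_from_vector(par, spec, k_kid = renal_rate())
    traj <- simulate_model(spec, p, phys, protocol, times)
    vals[, i] <- switch(quantity,
      liver = ,
      spleen = ,
      vein = roi_signal(traj, quantity, signal_design(phys, p$xi)),
      plasma_fraction = 100 * traj$C_p * phys$V_plasma / dose,
      bile_pct = 100 * traj$A_b / dose,
      urine_pct = 100 * traj$A_u / dose)
  }
  structure(data.frame(time = times,
                       lower = apply(vals, 1, min),
                       upper = apply(vals, 1, max)),
            quantity = quantity, n_members = nrow(ens),
            class = c("prediction_band", "data.frame"))
}

#' Liver-signal sensitivity to the literature volume parameters
#'
#' Re-simulates the liver signal with each volume parameter individually
#' perturbed by `-rel_change` and `+rel_change` (all kinetic parameters
#' fixed at their supplied values) and ranks the volumes by the maximal
#' absolute deviation of the liver signal from nominal.
#'
#' @param spec,optimal_params,phys,protocol model context.
#' @param rel_change relative perturbation; must be > -1, default 0.20.
#' @param times output times, s.
#' @return A list: `curves` (per volume, data.frame `time`, `minus`,
#'   `nominal`, `plus`) and `ranking` (data.frame sorted by decreasing
#'   `max_abs_dev`).
#' @export
volume_sensitivity <- function(spec, optimal_params, phys = physiology(),
                               protocol = injection_protocol(),
                               rel_change = 0.20,
                               times = seq(0, 2400, by = 60)) {
  if (rel_change <= -1) stop("rel_change must be > -1")
  vols <- c("V_plasma", "V_ees", "V_liver", "hepatocyte_fraction")
  liver_signal <- function(ph) {
    traj <- simulate_model(spec, optimal_params, ph, protocol, times)
    roi_signal(traj, "liver", signal_design(ph, optimal_params$xi))
  }
  nominal <- liver_signal(phys)
  perturb <- function(vname, fac) {
    ph <- phys
    ph[[vname]] <- ph[[vname]] * fac
    if (vname == "hepatocyte_fraction" && ph[[vname]] > 1)
      ph[[vname]] <- 1
    liver_signal(ph)
  }
  curves <- lapply(vols, function(v) {
    data.frame(time = times,
               minus = perturb(v, 1 - rel_change),
               nominal = nominal,
               plus = perturb(v, 1 + rel_change))
  })
  names(curves) <- vols
  ranking <- data.frame(
    volume = vols,
    max_abs_dev = vapply(vols, function(v) {
      cv <- curves[[v]]
      max(abs(cv$minus - cv$nominal), abs(cv$plus - cv$nominal))
    }, numeric(1)))
  ranking <- ranking[order(-ranking$max_abs_dev), ]
  rownames(ranking) <- NULL
  list(curves = curves, ranking = ranking, rel_change = rel_change)
}

#' Simulated gradual loss of liver function
#'
#' Scales the hepatocyte uptake rate `k_ph` by each factor in
#' `uptake_scalings` (all other parameters fixed at the optimum) and
#' reports the predicted liver signal and the biliary/renal elimination
#' shares (each route as a percent of the total eliminated amount).
#'
#' @param spec,optimal_params,phys,protocol model context.
#' @param uptake_scalings factors in (0, 1]; 1 reproduces the nominal model.
#' @param times liver-signal output times, s.
#' @param t_end horizon for the elimination shares, s.
#' @return A list: `signals` (data.frame `time` x one column per scaling)
#'   and `elimination` (data.frame `scaling`, `bile_pct`, `urine_pct`,
#'   `bile_share_pct`, `urine_share_pct`).
#' @export
simulate_function_loss <- function(spec, optimal_params, phys = physiology(),
                                   protocol = injection_protocol(),
                                   uptake_scalings = c(1, 0.75, 0.5, 0.25,
                                                       0.1, 0.01),
                                   times = seq(0, 2400, by = 60),
                                   t_end = 10800) {
  if (any(uptake_scalings <= 0) || any(uptake_scalings > 1))
    stop("uptake scalings must lie in (0, 1]")
  sigs <- data.frame(time = times)
  elim <- data.frame(scaling = uptake_scalings, bile_pct = NA_real_,
                     urine_pct = NA_real_, bile_share_pct = NA_real_,
                     urine_share_pct = NA_real_)
  if (uptake_scalings[1] != 1 && !1 %in% uptake_scalings)
    warning("scaling 1 (nominal) not included")
  for (i in seq_along(uptake_scalings)) {
    s <- uptake_scalings[i]
    p <- optimal_params
    p$k_ph <- optimal_params$k_ph * s
    traj <- simulate_model(spec, p, phys, protocol, times)
    sigs[[sprintf("s_%g", s)]] <-
      roi_signal(traj, "liver", signal_design(phys, p$xi))
    tr2 <- simulate_model(spec, p, phys, protocol, c(0, t_end))
    ef <- elimination_fractions(tr2, total_dose(protocol))
    tot <- sum(ef)
    elim$bile_pct[i] <- ef[["bile_pct"]]
    elim$urine_pct[i] <- ef[["urine_pct"]]
    elim$bile_share_pct[i] <- if (tot > 0) 100 * ef[["bile_pct"]] / tot else NA
    elim$urine_share_pct[i] <- if (tot > 0) 100 * ef[["urine_pct"]] / tot else NA
  }
  list(signals = sigs, elimination = elim)
}
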
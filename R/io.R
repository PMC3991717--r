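#' Write a time-series dataset as a delimited table
#'
#' Tab-separated UTF-8 with a header row; generator provenance (design,
#' variant, seed) is embedded as `#`-prefixed comment lines.
#'
#' @param ds a `timeseries_dataset`.
#' @param path output file.
#' @export
write_timeseries <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(design = attr(ds, "design"), variant = attr(ds, "variant"),
               seed = attr(ds, "seed"), scale = attr(ds, "scale"))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           null = "null")), con)
  writeLines("# columns: time_s value sigma label in_cost [dose_group]", con)
  write.table(as.data.frame(ds), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a time-series dataset written by [write_timeseries()]
#'
#' @param path input file.
#' @return A `timeseries_dataset`.
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  meta <- list()
  first <- lines[startsWith(lines, "# {")]
  if (length(first))
    meta <- jsonlite::fromJSON(sub("^# ", "", first[1]))
  body <- lines[!startsWith(lines, "#")]
  ds <- read.delim(text = paste(body, collapse = "\n"),
                   stringsAsFactors = FALSE)
  need <- c("time", "value", "sigma", "label", "in_cost")
  miss <- setdiff(need, names(ds))
  if (length(miss))
    stop("malformed dataset ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (col in c("time", "value", "sigma"))
    ds[[col]] <- suppressWarnings(as.numeric(ds[[col]]))
  bad <- which(!is.finite(ds$time) | !is.finite(ds$value) |
                 !is.finite(ds$sigma))
  if (length(bad))
    stop("malformed dataset ", path, ": non-numeric record at data line ",
         bad[1])
  structure(ds, design = meta$design, variant = meta$variant,
            seed = meta$seed, scale = meta$scale,
            protocol = injection_protocol(),
            class = c("timeseries_dataset", "data.frame"))
}

#' Write a simulated trajectory as a delimited table
#'
#' @param traj a trajectory from [simulate_model()].
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# variant=", attr(traj, "variant"),
                    " dose_mmol=", format(attr(traj, "dose"))), con)
  writeLines("# units: time s; C_* mmol/L; A_* mmol", con)
  write.table(as.data.frame(traj), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' @param result a `fit_result`.
#' @param path output file.
#' @export
write_fit_result <- function(result, path) {
  out <- list(variant = result$spec$name,
              optimal_vector = as.list(result$optimal_vector),
              optimal_cost = result$optimal_cost,
              threshold = result$threshold,
              rejected = result$rejected,
              seed = result$seed,
              diagnostics = result$diagnostics,
              constraint = result$constraint,
              ensemble = result$ensemble)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a fit result written by [write_fit_result()]
#'
#' @param path input file.
#' @return A `fit_result` (the model spec is rebuilt from the variant name).
#' @export
read_fit_result <- function(path) {
  x <- jsonlite::fromJSON(path)
  spec <- build_variant(x$variant)
  ens <- as.data.frame(x$ensemble)
  ov <- unlist(x$optimal_vector)
  structure(list(
    optimal_params = if (length(ov) && !isTRUE(x$rejected))
      .params_from_vector(ov, spec, k_kid = renal_rate()),
    optimal_vector = ov,
    optimal_cost = x$optimal_cost,
    ensemble = ens,
    threshold = x$threshold,
    rejected = isTRUE(x$rejected),
    seed = x$seed,
    spec = spec,
    constraint = x$constraint,
    diagnostics = x$diagnostics), class = "fit_result")
}

#' Read a run configuration (JSON)
#'
#' Validates keys against the known configuration schema and applies
#' defaults; unknown keys are an error so typos never silently change runs.
#'
#' @param path JSON file, or `NULL` for the all-defaults configuration.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    variant = "M0",
    seed = 1L,
    alpha = 0.05,
    n_identifiable = 4,
    restarts = 5,
    evals_per_restart = 10000,
    proposal_width = 0.3,
    step_factor = 1.05,
    span = 1000,
    reopt_maxit = 150,
    include_constraint = TRUE,
    constraint_t = 10800,
    constraint_min_pct = 1,
    constraint_sigma_pct = 0.25,
    horizon = 10800,
    times = seq(0, 2400, by = 60),
    dose_per_kg = 0.025,
    body_weight = 73,
    duration = 7,
    mode = "bolus",
    physiology = list())
  if (is.null(path)) return(defaults)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (length(cfg$physiology)) {
    bad <- setdiff(names(cfg$physiology), names(formals(physiology)))
    if (length(bad))
      stop("unknown physiology key(s): ", paste(bad, collapse = ", "))
  }
  modifyList(defaults, cfg)
}

.config_physiology <- function(cfg) do.call(physiology, cfg$physiology)

.config_protocol <- function(cfg) {
  injection_protocol(dose_per_kg = cfg$dose_per_kg,
                     body_weight = cfg$body_weight,
                     duration = cfg$duration, mode = cfg$mode)
}
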
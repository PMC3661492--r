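# End-to-end pipeline: each stage reads its upstream artifacts from the
# output directory, writes CSV/JSON products plus a manifest (inputs,
# config hash), and is a no-op when re-run with an unchanged configuration.

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

write_manifest <- function(outdir, stage, config, inputs, outputs) {
  man <- list(stage = stage, config_hash = config_hash(config),
              inputs = inputs, outputs = outputs,
              package_version = as.character(utils::packageVersion("hurdlecatch")))
  jsonlite::write_json(man, file.path(outdir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

manifest_current <- function(outdir, stage, config) {
  path <- file.path(outdir, paste0(stage, "_manifest.json"))
  if (!file.exists(path)) return(FALSE)
  man <- jsonlite::read_json(path)
  identical(man$config_hash, unname(config_hash(config))) &&
    all(file.exists(file.path(outdir, unlist(man$outputs))))
}

require_upstream <- function(outdir, stage, producer) {
  path <- file.path(outdir, paste0(stage, "_manifest.json"))
  if (!file.exists(path)) {
    stopf("missing upstream artifact '%s'; run %s() first", stage, producer)
  }
}

#' Simulate a fishery to disk
#'
#' Generates effort, simulates captures, applies observer coverage, and
#' writes the observable effort table, an observer table of the observed
#' tows, and the hidden truth.
#'
#' @param outdir output directory (created if needed).
#' @param config a [scenario_config()].
#' @param seed simulation seed.
#' @return `outdir`, invisibly.
#' @export
run_simulate <- function(outdir, config = scenario_config(), seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- c(unclass(config), seed = seed)
  if (manifest_current(outdir, "simulate", cfg)) return(invisible(outdir))
  tows <- generate_effort(config, seed)
  tows <- simulate_captures(tows, config, seed + 1)
  truth <- attr(tows, "truth")
  split <- apply_observer_coverage(tows, config$coverage, seed + 2)
  write_effort_table(split$observable, file.path(outdir, "effort.csv"))
  obs <- split$observable[split$observable$observed, , drop = FALSE]
  ob_tab <- tibble::tibble(vessel_id = obs$vessel_id,
                           start_time = format_local_time(obs$start_time),
                           end_time = format_local_time(obs$end_time),
                           start_lat = obs$start_lat, start_lon = obs$start_lon,
                           target_species = obs$target_species,
                           captures = obs$captures)
  write.csv(ob_tab, file.path(outdir, "observer.csv"), row.names = FALSE)
  write_effort_table(split$truth, file.path(outdir, "truth.csv"))
  jsonlite::write_json(truth[c("alpha", "beta", "lambda", "total_captures")],
                       file.path(outdir, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, "simulate", cfg, character(),
                 c("effort.csv", "observer.csv", "truth.csv",
                   "truth_params.json"))
  invisible(outdir)
}

#' Prepare the modelling dataset
#'
#' Reads effort (and optionally observer) tables, links observer records,
#' restricts to the large-vessel mackerel fleet inside the study area, and
#' derives the covariate table.
#'
#' @param outdir pipeline directory.
#' @param effort_path,observer_path input tables; default the simulate
#'   outputs in `outdir`. `observer_path = NULL` skips linking (effort
#'   already carries `observed`/`captures`).
#' @param link whether to link the observer table onto the effort records.
#' @return `outdir`, invisibly; writes `covariates.csv` and a load report.
#' @export
run_prepare <- function(outdir,
                        effort_path = file.path(outdir, "effort.csv"),
                        observer_path = file.path(outdir, "observer.csv"),
                        link = FALSE) {
  cfg <- list(effort_path = effort_path, observer_path = observer_path,
              link = link)
  if (manifest_current(outdir, "prepare", cfg)) return(invisible(outdir))
  if (!file.exists(effort_path)) {
    stopf("missing effort table '%s'; run run_simulate() or point at your data",
          effort_path)
  }
  tows <- read_effort_table(effort_path)
  report <- list(load = attr(tows, "load_report"))
  if (link && !is.null(observer_path) && file.exists(observer_path)) {
    obs <- read_observer_table(observer_path)
    linked <- link_observer_records(tows, obs)
    tows <- linked$tows
    report$linking <- list(n_matched = linked$n_matched,
                           n_unmatched = nrow(linked$unmatched))
  }
  tows <- tows[in_study_area(tows), , drop = FALSE]
  tows <- filter_large_vessel_mackerel_fleet(tows)
  cov <- derive_covariates(tows)
  report$excluded_gear <- attr(cov, "excluded")$n
  cov_out <- cov
  cov_out$depth_factor <- as.character(cov_out$depth_factor)
  cov_out$subarea <- as.character(cov_out$subarea)
  cov_out$light <- as.character(cov_out$light)
  cov_out$month <- as.character(cov_out$month)
  cov_out$season <- as.character(cov_out$season)
  write.csv(cov_out, file.path(outdir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(outdir, "prepare_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_manifest(outdir, "prepare", cfg, basename(effort_path),
                 c("covariates.csv", "prepare_report.json"))
  invisible(outdir)
}

read_covariates_artifact <- function(outdir) {
  cov <- tibble::as_tibble(read.csv(file.path(outdir, "covariates.csv"),
                                    stringsAsFactors = FALSE))
  cov$depth_factor <- factor(cov$depth_factor, c("shallow", "deep"))
  cov$subarea <- factor(cov$subarea, c("north", "south"))
  cov$light <- factor(cov$light, c("dark", "light", "black"))
  cov$month <- factor(cov$month, month.abb)
  cov$season <- factor(cov$season, c("JFM", "AMJ", "JAS", "OND"))
  cov$captures <- suppressWarnings(as.integer(cov$captures))
  cov
}

#' Stepwise covariate selection stage
#'
#' @param outdir pipeline directory (needs the prepare stage).
#' @param candidates candidate [covariate_spec()]s.
#' @param stop_frac deviance stopping fraction.
#' @return `outdir`, invisibly; writes `selection_trace.csv` and
#'   `selected_covariates.json`.
#' @export
run_select <- function(outdir, candidates = default_covariate_specs(),
                       stop_frac = 0.01) {
  require_upstream(outdir, "prepare", "run_prepare")
  cfg <- list(candidates = names(candidates), stop_frac = stop_frac)
  if (manifest_current(outdir, "select", cfg)) return(invisible(outdir))
  cov <- read_covariates_artifact(outdir)
  cov_obs <- cov[cov$observed, , drop = FALSE]
  # drop candidates whose source columns are unavailable
  ok <- vapply(candidates, function(s) {
    col <- cov_obs[[s$source]]
    !is.null(col) && !anyNA(col)
  }, TRUE)
  y <- as.numeric(!is.na(cov_obs$captures) & cov_obs$captures > 0)
  sel <- step_select(cov_obs, y, candidates[ok], stop_frac)
  write.csv(sel$trace, file.path(outdir, "selection_trace.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(selected = sel$selected),
                       file.path(outdir, "selected_covariates.json"),
                       auto_unbox = TRUE)
  write_manifest(outdir, "select", cfg, "covariates.csv",
                 c("selection_trace.csv", "selected_covariates.json"))
  invisible(outdir)
}

#' Fit the hurdle model stage
#'
#' @param outdir pipeline directory (needs the prepare stage; uses the
#'   select stage's covariates when present, else the final-model four).
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @return `outdir`, invisibly; writes `posterior.csv` (one row per kept
#'   draw, columns named) and `diagnostics.json`.
#' @export
run_fit <- function(outdir, priors = prior_spec(), config = mcmc_config()) {
  require_upstream(outdir, "prepare", "run_prepare")
  cfg <- c(unclass(priors), unclass(config))
  if (manifest_current(outdir, "fit", cfg)) return(invisible(outdir))
  cov <- read_covariates_artifact(outdir)
  sel_path <- file.path(outdir, "selected_covariates.json")
  specs <- if (file.exists(sel_path)) {
    nm <- unlist(jsonlite::read_json(sel_path)$selected)
    if (length(nm)) default_covariate_specs()[nm] else final_model_specs()
  } else {
    final_model_specs()
  }
  dm <- build_design_matrix(cov, specs)
  post <- sample_posterior(dm, priors, config)
  draws <- posterior_draws(post)
  chain <- rep(seq_along(post$chains), vapply(post$chains, nrow, 0L))
  write.csv(cbind(chain = chain, as.data.frame(draws)),
            file.path(outdir, "posterior.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(rhat = as.list(post$rhat), ess = as.list(post$ess),
         n_chains = config$n_chains, draws_per_chain = draws_per_chain(config),
         specs = names(specs)),
    file.path(outdir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, "fit", cfg, "covariates.csv",
                 c("posterior.csv", "diagnostics.json"))
  invisible(outdir)
}

read_posterior_artifact <- function(outdir) {
  df <- read.csv(file.path(outdir, "posterior.csv"), check.names = FALSE)
  chains <- lapply(split(df[, -1, drop = FALSE], df$chain), as.matrix)
  diag <- jsonlite::read_json(file.path(outdir, "diagnostics.json"))
  nm <- colnames(chains[[1]])
  yl <- sub("^alpha_", "", grep("^alpha_", nm, value = TRUE))
  structure(list(chains = unname(chains), param_names = nm,
                 n_beta = sum(grepl("^beta_", nm)), year_levels = yl,
                 rhat = unlist(diag$rhat), ess = unlist(diag$ess),
                 priors = prior_spec(), config = NULL),
            class = "hurdle_posterior")
}

#' Estimation stage: totals, rates, coefficient table, PPC
#'
#' @param outdir pipeline directory (needs prepare and fit stages).
#' @param seed prediction-simulation seed.
#' @return `outdir`, invisibly; writes `annual_summary.csv`,
#'   `coefficients.csv`, `group_estimates.csv`, `ppc_event_size.csv`.
#' @export
run_estimate <- function(outdir, seed = 1) {
  require_upstream(outdir, "prepare", "run_prepare")
  require_upstream(outdir, "fit", "run_fit")
  cfg <- list(seed = seed)
  if (manifest_current(outdir, "estimate", cfg)) return(invisible(outdir))
  cov <- read_covariates_artifact(outdir)
  post <- read_posterior_artifact(outdir)
  diag <- jsonlite::read_json(file.path(outdir, "diagnostics.json"))
  specs <- default_covariate_specs()[unlist(diag$specs)]
  dm <- build_design_matrix(cov, specs)
  est_v <- predict_group_totals(post, dm, "year_vessel", seed)
  est_y <- collapse_to_years(est_v)
  annual <- annual_summary_table(cov, est_y)
  factor_cols <- colnames(dm$X)[grepl("^(light|subarea|depth_factor|month|season)_",
                                      colnames(dm$X))]
  coefs <- coefficient_table(post, exponentiate_factors = factor_cols)
  n_obs_ev <- cov$captures[cov$observed & !is.na(cov$captures) & cov$captures > 0]
  ppc <- if (length(n_obs_ev)) ppc_event_size(post, n_obs_ev, seed) else NULL
  write.csv(annual, file.path(outdir, "annual_summary.csv"), row.names = FALSE)
  write.csv(coefs, file.path(outdir, "coefficients.csv"), row.names = FALSE)
  write.csv(as.data.frame(est_v), file.path(outdir, "group_estimates.csv"),
            row.names = FALSE)
  if (!is.null(ppc)) {
    write.csv(ppc, file.path(outdir, "ppc_event_size.csv"), row.names = FALSE)
  }
  write_manifest(outdir, "estimate", cfg, c("covariates.csv", "posterior.csv"),
                 c("annual_summary.csv", "coefficients.csv",
                   "group_estimates.csv"))
  invisible(outdir)
}

#' Combine all artifacts into one run report
#'
#' @param outdir pipeline directory (needs the estimate stage).
#' @return path of the JSON report, invisibly; also writes a markdown
#'   summary.
#' @export
run_report <- function(outdir) {
  require_upstream(outdir, "estimate", "run_estimate")
  annual <- read.csv(file.path(outdir, "annual_summary.csv"))
  coefs <- read.csv(file.path(outdir, "coefficients.csv"))
  diag <- jsonlite::read_json(file.path(outdir, "diagnostics.json"))
  rep <- list(annual_summary = annual, coefficients = coefs,
              diagnostics = diag,
              total_estimated_captures = sum(annual$est_captures))
  path <- file.path(outdir, "report.json")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  md <- c("# Bycatch estimation run",
          "",
          sprintf("Total estimated captures: %d", sum(annual$est_captures)),
          "",
          "## Annual summary", "",
          paste(capture.output(print(annual)), collapse = "\n"),
          "",
          "## Coefficients", "",
          paste(capture.output(print(coefs)), collapse = "\n"))
  writeLines(md, file.path(outdir, "report.md"))
  write_manifest(outdir, "report", list(), "annual_summary.csv",
                 c("report.json", "report.md"))
  invisible(path)
}
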
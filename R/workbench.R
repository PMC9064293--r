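# Configuration and end-to-end pipeline orchestration:
# synthetic -> extract -> fit -> report; trace -> pushback; tracks -> rates.

#' Default run configuration
#'
#' All tunable constants of the pipeline in one place. `delta_rho` has no
#' default for real data — the tissue density must be supplied — but the
#' synthetic demo pipeline fills in its generator value.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    delta_rho = NULL,               # kg/m^3; must be supplied for ADSA stages
    g = 9.80665,                    # m/s^2
    pixel_scale = 7.5e-6,           # m/px for rendered synthetic images
    seed = 1L,
    synthetic = list(gamma = 0.22e-3, delta_rho = 40, R0 = 7.5e-4,
                     n_points = 200, radial_noise_sd = 0.01),
    qc = list(c_min = 0.6, d_max = 0.15),
    fit = list(bo_min = 0.05, fit_tilt = FALSE),
    pushback = list(k = 3, sustain = 600, smooth_window = 5,
                    relax_read_time = 180),
    force = list(sigma_em = 0.22e-3, L_i = 1.2e-3),
    output_dir = NULL),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; the config round-trips losslessly through YAML.
#'
#' @param file YAML path, or `NULL` for pure defaults.
#' @param overrides named list applied on top (e.g. parsed CLI flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(file = NULL, overrides = list()) {
  cfg <- unclass(default_run_config())
  if (!is.null(file))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(file), keep.null = TRUE)
  if (length(overrides))
    cfg <- utils::modifyList(cfg, overrides, keep.null = TRUE)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param file path.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the measurement pipeline on synthetic inputs
#'
#' Executes the selected stages in dependency order on generated data:
#' \describe{
#'   \item{adsa}{synthetic drop contour -> QC -> ADSA tension fit -> summary
#'     row (requires `delta_rho`, from `config$delta_rho` or the synthetic
#'     generator block).}
#'   \item{imaging}{rendered drop image -> contour extraction -> ADSA fit.}
#'   \item{pushback}{synthetic force trace -> relaxation/plateau/onset
#'     decomposition.}
#'   \item{morpho}{synthetic track table -> regional widths -> rates and
#'     changepoint.}
#'   \item{force}{worked example F = sigma_em * L_i.}
#' }
#' Every report carries provenance (config hash, seed, package version), and
#' reruns with identical config and seed produce identical outputs. Summary
#' CSVs are written when `config$output_dir` is set.
#'
#' @param config a `run_config`.
#' @param stages character subset of
#'   `c("adsa", "imaging", "pushback", "morpho", "force")`.
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("adsa", "pushback", "morpho", "force")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("adsa", "imaging", "pushback", "morpho", "force"),
                      several.ok = TRUE)
  seed <- config$seed %||% 1L
  rep <- list(provenance = list(
    config_hash = config_hash(config), seed = seed,
    package_version = as.character(utils::packageVersion("tensiomorph"))))
  syn <- config$synthetic
  if (any(c("adsa", "imaging") %in% stages)) {
    drho <- config$delta_rho %||% syn$delta_rho
    if (is.null(drho))
      stop("missing parameter 'delta_rho': required for ADSA stages",
           call. = FALSE)
  }
  if ("adsa" %in% stages) {
    cont <- synth_drop_contour(syn$gamma, syn$delta_rho, syn$R0,
                               n_points = syn$n_points,
                               radial_noise_sd = syn$radial_noise_sd,
                               seed = seed)
    fit <- fit_adsa(cont, delta_rho = drho, g = config$g,
                    bo_min = config$fit$bo_min,
                    fit_tilt = isTRUE(config$fit$fit_tilt))
    rep$adsa <- list(fit = fit, summary = fit_report(fit),
                     truth_gamma = attr(cont, "truth")$gamma)
  }
  if ("imaging" %in% stages) {
    img <- synth_drop_image(syn$gamma, syn$delta_rho, syn$R0,
                            pixel_scale = config$pixel_scale,
                            blur_sd = 2, seed = seed)
    cont <- extract_contour(img, qc_thresholds = config$qc)
    if (!attr(cont, "qc")$accepted)
      stop("imaging stage: extracted contour rejected by QC", call. = FALSE)
    fit <- fit_adsa(cont, delta_rho = drho, g = config$g,
                    bo_min = config$fit$bo_min)
    rep$imaging <- list(fit = fit, summary = fit_report(fit),
                        truth_gamma = attr(img, "truth")$gamma)
  }
  if ("pushback" %in% stages) {
    tr <- synth_pushback_trace(seed = seed)
    pb <- do.call(analyze_pushback,
                  c(list(tr), config$pushback[c("k", "sustain", "smooth_window",
                                                "relax_read_time")]))
    rep$pushback <- list(fit = pb, truth_onset = attr(tr, "truth")$onset_time)
  }
  if ("morpho" %in% stages) {
    tracks <- synth_track_table(seed = seed)
    rs <- region_widths(tracks)
    rep$morpho <- list(rates = estimate_rate(rs),
                       changepoint = detect_rate_change(rs, region = "NIMZ"))
  }
  if ("force" %in% stages) {
    rep$force <- predict_force(config$force$sigma_em, config$force$L_i)
  }
  rep <- structure(rep, class = "run_report")
  if (!is.null(config$output_dir)) write_run_report(rep, config$output_dir)
  rep
}

#' @rdname run_pipeline
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$adsa))
    utils::write.csv(report$adsa$summary, file.path(dir, "adsa_summary.csv"),
                     row.names = FALSE)
  if (!is.null(report$imaging))
    utils::write.csv(report$imaging$summary, file.path(dir, "imaging_summary.csv"),
                     row.names = FALSE)
  if (!is.null(report$pushback)) {
    pb <- report$pushback$fit
    utils::write.csv(data.frame(plateau_force_N = pb$plateau_force,
                                onset_time_s = pb$onset_time,
                                delta_F_30min_N = pb$delta_F_30min,
                                noise_sd_N = pb$noise_sd),
                     file.path(dir, "pushback_summary.csv"), row.names = FALSE)
  }
  if (!is.null(report$morpho))
    utils::write.csv(report$morpho$rates, file.path(dir, "convergence_rates.csv"),
                     row.names = FALSE)
  if (!is.null(report$force))
    utils::write.csv(data.frame(sigma_em_N_per_m = report$force$sigma_em,
                                L_i_m = report$force$L_i,
                                force_uN = report$force$force_uN),
                     file.path(dir, "force_prediction.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("tensiomorph pipeline run\n")
  cat(sprintf("  config %s, seed %d, version %s\n",
              substr(x$provenance$config_hash, 1, 8), x$provenance$seed,
              x$provenance$package_version))
  if (!is.null(x$adsa)) {
    cat(sprintf("  [adsa]     gamma_hat = %.4g mN/m (truth %.4g)\n",
                1e3 * x$adsa$fit$gamma, 1e3 * x$adsa$truth_gamma))
  }
  if (!is.null(x$imaging)) {
    cat(sprintf("  [imaging]  gamma_hat = %.4g mN/m (truth %.4g)\n",
                1e3 * x$imaging$fit$gamma, 1e3 * x$imaging$truth_gamma))
  }
  if (!is.null(x$pushback)) {
    cat(sprintf("  [pushback] onset = %.0f s (truth %.0f)\n",
                x$pushback$fit$onset_time, x$pushback$truth_onset))
  }
  if (!is.null(x$morpho)) {
    r <- x$morpho$rates
    cat(sprintf("  [morpho]   rates: %s\n",
                paste(sprintf("%s %.1f%%/hr", r$region, r$rate), collapse = ", ")))
    if (x$morpho$changepoint$has_changepoint)
      cat(sprintf("             NIMZ breakpoint at %.2f hr\n",
                  x$morpho$changepoint$changepoint))
  }
  if (!is.null(x$force))
    cat(sprintf("  [force]    F = %.2f uN\n", x$force$force_uN))
  invisible(x)
}
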
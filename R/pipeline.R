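#' Run the two-condition analysis pipeline from a config
#'
#' Executes the staged workflow of the study — assemble the community,
#' apply conditions, optionally fit exchange capacities at the first
#' condition, simulate both conditions, run flux fold-change analytics,
#' and run sensitivity scans — writing every stage's outputs (TSV/JSON)
#' plus a run manifest into the output directory.
#'
#' Config schema (YAML file or R list):
#' \preformatted{
#' model: toy                  # "toy" or a path to community SBML
#' x0: 1
#' seed: 1
#' outdir: results/run
#' stages: [assemble, condition, fit, simulate, analytics, scan]
#' conditions: {fit: L-OLR, verify: H-OLR}
#' fit:
#'   axes: {SOB.ac.lower: [-2.5, -1.5, -0.75],
#'          MET.ac.upper: [-14, -11.55, -9]}
#'   observed: synthetic       # or a TSV path (guild, abundance)
#'   noise_sd: 0.05
#' scan: {modes: [olr, hplus], n_points: 9}
#' }
#'
#' @param config path to a YAML config or an equivalent named list.
#' @return invisibly, a list with the run \code{manifest} and the stage
#'   results; stage failures raise errors after the manifest (marked
#'   failed) is written.
#' @export
run_pipeline <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  defaults <- list(model = "toy", x0 = 1, seed = 1L, outdir = "results/run",
                   stages = c("assemble", "condition", "simulate",
                              "analytics"),
                   conditions = list(fit = "L-OLR", verify = "H-OLR"),
                   fit = list(observed = "synthetic", noise_sd = 0.05),
                   scan = list(modes = "olr", n_points = 9))
  config <- utils::modifyList(defaults, config)
  known <- c("assemble", "condition", "fit", "simulate", "analytics",
             "scan")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  results <- list()
  manifest <- list(
    command = "run_pipeline",
    config_hash = digest::digest(config),
    config_file = cfg_path,
    input_digests = if (!is.null(cfg_path) && file.exists(config$model))
      stats::setNames(list(digest::digest(file = config$model)),
                      config$model) else NULL,
    solver = "guildcom dense two-phase simplex",
    package_version = as.character(utils::packageVersion("guildcom")),
    seed = config$seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = "running")
  write_manifest <- function() {
    manifest$outputs <- outputs
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit({
    if (identical(manifest$status, "running")) {
      manifest$status <- "failed"
      write_manifest()
    }
  })
  emit <- function(name, writer) {
    path <- file.path(config$outdir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }

  # assemble
  model <- if (identical(config$model, "toy"))
    make_toy_community(toy_community_spec(x0 = config$x0,
                                          seed = config$seed))
  else read_community_sbml(config$model)
  if ("assemble" %in% config$stages) {
    results$validation <- validate_community(model)
    emit("validation.json",
         function(p) write_validation_json(results$validation, p))
    emit("exchange_sets.tsv", function(p) write_exchange_tsv(model, p))
  }

  cond_fit <- condition_preset(config$conditions$fit)
  cond_verify <- condition_preset(config$conditions$verify)
  m_fit <- apply_condition(model, cond_fit)
  if ("condition" %in% config$stages) {
    emit("condition_fit.tsv", function(p) write_condition_tsv(cond_fit, p))
    emit("condition_verify.tsv",
         function(p) write_condition_tsv(cond_verify, p))
  }

  if ("fit" %in% config$stages) {
    axes <- config$fit$axes
    if (is.null(axes)) stop("fit stage requires fit$axes in the config")
    observed <- if (identical(config$fit$observed, "synthetic"))
      make_synthetic_observation(m_fit, noise_sd = config$fit$noise_sd,
                                 seed = config$seed)
    else utils::read.delim(config$fit$observed)
    results$fit <- fit_exchange_capacities(m_fit, observed, axes)
    emit("fit.json", function(p) write_fit_json(results$fit, p))
    if (!is.null(results$fit$best)) {
      model <- apply_capacities(model, results$fit$best)
      m_fit <- apply_condition(model, cond_fit)
    }
  }

  if (any(c("simulate", "analytics") %in% config$stages)) {
    settings <- solver_settings(flux_resolution = "parsimonious")
    results$solution_fit <- maximize_growth(m_fit, settings)
    results$solution_verify <- maximize_growth(
      apply_condition(model, cond_verify), settings)
    emit("solution_fit.json",
         function(p) write_solution(results$solution_fit, p))
    emit("solution_verify.json",
         function(p) write_solution(results$solution_verify, p))
  }

  if ("analytics" %in% config$stages) {
    results$ffc <- flux_comparison(results$solution_fit,
                                   results$solution_verify)
    emit("ffc.tsv", function(p) write_ffc_tsv(results$ffc, p))
  }

  if ("scan" %in% config$stages) {
    if ("olr" %in% config$scan$modes) {
      results$olr <- olr_sweep(model, cond_fit,
                               n_points = config$scan$n_points)
      emit("scan_olr.tsv", function(p) write_scan_tsv(results$olr, p))
    }
    if ("capacity2d" %in% config$scan$modes) {
      results$capacity2d <- capacity_scan_2d(
        model, cond_fit, n_capacity = 2,
        loading_points = config$scan$n_points)
      emit("scan_capacity2d.json",
           function(p) write_scan_tsv(results$capacity2d, p))
    }
    if ("hplus" %in% config$scan$modes) {
      results$hplus <- h_plus_sweep(model, cond_verify,
                                    n_points = config$scan$n_points)
      emit("scan_hplus.tsv", function(p) write_scan_tsv(results$hplus, p))
    }
  }

  manifest$status <- "ok"
  write_manifest()
  on.exit()
  invisible(list(manifest = manifest, results = results))
}
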
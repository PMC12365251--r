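# Pipeline orchestration: scenario config, simulate -> quantify -> report.

#' Default pipeline configuration
#'
#' Nested list describing a complete virtual study: the dosing scenario, the
#' three instrument blocks and the analysis block. Serialize with
#' [write_pipeline_config()]; every stage echoes its censoring and threshold
#' choices into the report header so outputs are self-describing.
#'
#' @return Named list, schema-validated by [validate_pipeline_config()].
#' @export
default_pipeline_config <- function() {
  list(
    scenario = list(
      np_mass_mg = 3.3817, pd_mass_ug = 9.976, schedule_h = 0,
      dose_type = "applied",
      rates = as.list(default_transit_rates()),
      uptake_fraction = 0.01,
      times_h = seq(0, 24, by = 2)),
    xfi = list(grid = c(2, 2), background_rate = 5, dwell_s = 1,
               flux_ph_s = 1e10),
    icpms = list(slope = 2e4, intercept = 50, blank_sd = 10, drift = 0.05,
                 dilution_factor = 13 / 3, digest_volume_ml = 3),
    imc = list(width = 16, height = 16, ions_per_particle = 1, noise_max = 1,
               n_particle_sites = 5),
    analysis = list(noise_ceiling = 1.0, lod_k = 3, loq_k = 10),
    seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Checks the block structure and rejects unknown keys at the top and block
#' level before any stage runs.
#'
#' @param config Configuration list.
#' @return The config, invisibly; errors describe the offending key.
#' @export
validate_pipeline_config <- function(config) {
  allowed <- list(
    top = c("scenario", "xfi", "icpms", "imc", "analysis", "seed"),
    scenario = c("np_mass_mg", "pd_mass_ug", "schedule_h", "dose_type",
                 "rates", "uptake_fraction", "times_h"),
    xfi = c("grid", "background_rate", "dwell_s", "flux_ph_s"),
    icpms = c("slope", "intercept", "blank_sd", "drift", "dilution_factor",
              "digest_volume_ml"),
    imc = c("width", "height", "ions_per_particle", "noise_max",
            "n_particle_sites"),
    analysis = c("noise_ceiling", "lod_k", "loq_k"))
  reject <- function(keys, where, ok) {
    unknown <- setdiff(keys, ok)
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  reject(names(config), "top level", allowed$top)
  for (blk in intersect(names(config), names(allowed)))
    reject(names(config[[blk]]), blk, allowed[[blk]])
  for (blk in c("scenario", "xfi", "icpms", "imc", "analysis", "seed"))
    if (is.null(config[[blk]])) stop("config block missing: ", blk)
  invisible(config)
}

#' Write / read a pipeline configuration file
#'
#' YAML with a `format` key carrying the dialect version; readers refuse
#' unknown versions.
#'
#' @param config Configuration list.
#' @param path File path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` the validated config list.
#' @export
write_pipeline_config <- function(config, path) {
  validate_pipeline_config(config)
  yaml::write_yaml(c(list(format = "pdnptrace-config v1"), config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$format, "pdnptrace-config v1"))
    stop("unknown config format/version in ", path)
  cfg$format <- NULL
  validate_pipeline_config(cfg)
  cfg
}

#' Run the full simulate-quantify-report pipeline
#'
#' Executes scenario simulation, the three virtual instruments with their
#' quantification stages, and the mass-balance report, writing every table
#' under `out_dir`. Deterministic given the seed: re-running with the same
#' config reproduces bit-identical tables.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or the
#'   path of a YAML config file.
#' @param out_dir Output directory (created).
#' @param seed Optional override of `config$seed`.
#' @return Object of class `run_manifest`: `config_hash`, `package_version`,
#'   `seed`, `files` (per-stage output list), `summary` (headline numbers),
#'   `timestamp`.
#' @export
#' @examples
#' \donttest{
#' man <- run_pipeline(default_pipeline_config(), tempfile("run"))
#' man$summary
#' }
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "pdnptrace_run", seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  # --- scenario ------------------------------------------------------------
  sc <- config$scenario
  study <- stage("simulate", {
    reg <- dose_regimen(sc$np_mass_mg, sc$pd_mass_ug,
                        schedule_h = unlist(sc$schedule_h),
                        dose_type = sc$dose_type)
    simulate_biodistribution(reg, rates = unlist(sc$rates),
                             uptake_fraction = sc$uptake_fraction,
                             times_h = unlist(sc$times_h), seed = seed)
  })
  files$truth <- file.path(out_dir, "ground_truth.tsv")
  write_truth_table(study, files$truth)
  final <- study$masses[nrow(study$masses), ]
  dose <- study$regimen$daily_pd_mass_ug

  # --- XFI stage: image the final fecal pool -------------------------------
  xq <- config$xfi
  xfi_total <- stage("xfi", {
    grid <- unlist(xq$grid)
    truth_map <- matrix(final$feces / prod(grid), grid[1], grid[2])
    scan <- generate_xfi_scan(truth_map,
                              beam = xfi_beam(flux_ph_s = xq$flux_ph_s),
                              background_rate = xq$background_rate,
                              dwell_s = xq$dwell_s,
                              seed = derive_seed(seed, "pipeline-xfi"))
    calib <- calibrate_flux(xfi_scan_references(scan), scan$beam$area_mm2)
    map <- build_mass_map(scan, calib)
    files$xfi_map <- file.path(out_dir, "xfi_mass_map.tsv")
    write_mass_map(map, files$xfi_map)
    map$total_ug
  })

  # --- ICP-MS stage: digest the compartments -------------------------------
  iq <- config$icpms
  icpms_out <- stage("icpms", {
    organs <- c("stomach", "small_intestine", "cecum", "colon", "systemic")
    mass_ng <- unlist(final[organs]) * 1000
    concs <- mass_ng / (iq$dilution_factor * iq$digest_volume_ml)
    batch <- generate_icpms_batch(unname(concs), slope = iq$slope,
                                  intercept = iq$intercept,
                                  blank_sd = iq$blank_sd, drift = iq$drift,
                                  dilution_factor = iq$dilution_factor,
                                  digest_volume_ml = iq$digest_volume_ml,
                                  seed = derive_seed(seed, "pipeline-icpms"))
    files$icpms_batch <- file.path(out_dir, "icpms_batch.tsv")
    write_icpms_batch(batch, files$icpms_batch)
    res <- quantify_batch(batch, lod_k = config$analysis$lod_k,
                          loq_k = config$analysis$loq_k)
    res$organ <- organs
    files$icpms_results <- file.path(out_dir, "icpms_results.tsv")
    con <- file(files$icpms_results, "w")
    writeLines(c("# format: pdnptrace-icpms-results v1",
                 sprintf("# censoring: bdl->0, between->LOD; lod_k=%g loq_k=%g",
                         config$analysis$lod_k, config$analysis$loq_k)), con)
    utils::write.table(res, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    res
  })

  # --- IMC stage: one ROI seeded from the systemic burden ------------------
  mq <- config$imc
  imc_out <- stage("imc", {
    rs <- derive_seed(seed, "pipeline-imc")
    set.seed(rs)
    n_sites <- mq$n_particle_sites
    pp <- data.frame(x = sample.int(mq$width, n_sites) - 1L,
                     y = sample.int(mq$height, n_sites) - 1L,
                     n_particles = 1L + stats::rpois(n_sites, 1))
    roi <- generate_imc_roi(mq$width, mq$height, pp,
                            ions_per_particle = mq$ions_per_particle,
                            noise_max = mq$noise_max, seed = rs,
                            roi_id = "pipeline_roi", tissue = "liver")
    files$imc_roi <- file.path(out_dir, "imc_roi.txt")
    write_imc_txt(roi, files$imc_roi)
    summ <- threshold_pixels(roi, "Pd108", config$analysis$noise_ceiling)
    files$imc_positives <- file.path(out_dir, "imc_positives.tsv")
    con <- file(files$imc_positives, "w")
    writeLines(c("# format: pdnptrace-imc-positives v1",
                 sprintf("# noise_ceiling: %g dual counts",
                         config$analysis$noise_ceiling)), con)
    utils::write.table(summ$positives, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    close(con)
    summ
  })

  # --- mass-balance report -------------------------------------------------
  report <- stage("biodist", {
    excreted <- data.frame(mouse = "m1", time_h = study$masses$time_h,
                           pd_mass_ug = c(0, diff(study$masses$feces)),
                           method = "truth")
    cum <- cumulative_excretion(excreted, dose)
    organ_pct <- percent_of_dose(
      censored_contribution(icpms_out$mass_ng, icpms_out$status) / 1000, dose)
    rec <- data.frame(organ = icpms_out$organ,
                      pct_of_dose = as.numeric(organ_pct),
                      status = icpms_out$status)
    files$report <- file.path(out_dir, "recovery_report.tsv")
    con <- file(files$report, "w")
    writeLines(c("# format: pdnptrace-recovery v1",
                 sprintf("# dose_ug: %g (%s dose)", dose,
                         study$regimen$dose_type),
                 sprintf("# censoring: bdl->0, between->LOD"),
                 sprintf("# xfi_feces_total_ug: %.6g", xfi_total),
                 sprintf("# imc_positive_pixels: %d",
                         nrow(imc_out$positives))), con)
    utils::write.table(rec, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    list(recovery = rec, cumulative = cum)
  })

  cfg_file <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_file)
  files$config <- cfg_file
  structure(list(
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("pdnptrace")),
    seed = seed, files = files,
    summary = list(
      dose_ug = dose,
      excreted_pct = report$cumulative$cum_pct[nrow(report$cumulative)],
      organ_recovery_pct = sum(report$recovery$pct_of_dose),
      xfi_feces_total_ug = xfi_total,
      imc_positive_pixels = nrow(imc_out$positives)),
    timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("pdnptrace run (seed %d, config %s)\n", x$seed,
              substr(x$config_hash, 1, 8)))
  cat(sprintf("  dose %.4g ug; excreted %.1f %%; organ recovery %.2f %%; XFI feces %.4g ug; %d IMC positives\n",
              x$summary$dose_ug, x$summary$excreted_pct,
              x$summary$organ_recovery_pct, x$summary$xfi_feces_total_ug,
              x$summary$imc_positive_pixels))
  cat("  outputs:", length(x$files), "file(s)\n")
  invisible(x)
}
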
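write_manifest <- function(dir, seed, config_path, timings, warnings, files) {
  manifest <- list(
    package = "fontanmix",
    version = as.character(utils::packageVersion("fontanmix")),
    seed = seed,
    config_hash = if (!is.null(config_path)) unname(tools::md5sum(config_path)) else NULL,
    timings_s = timings,
    warnings = if (length(warnings)) warnings else list(),
    files = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full single-patient pipeline
#'
#' Builds the velocity field for one virtual patient, runs the mixing
#' analysis and all three HFD quantification methods, and writes the results
#' to `out_dir` as CSV files (`crossings.csv`, `mixing_by_phase.csv`,
#' `mixing_summary.csv`, `hfd.csv`) plus a `manifest.json` listing every
#' output file with its checksum, the seed, per-stage runtimes and collected
#' warnings. All randomness derives from `seed` through per-stage substreams,
#' so identical seed and configuration give byte-identical outputs.
#'
#' @param config a [flow_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param n_hv_mixing HV particles per release event in the mixing stage
#'   (default 7500, the study-scale count).
#' @param n_hfd particles per HFD seeding strategy (default 7500).
#' @param substeps RK4 substeps per time step.
#' @param mixing_cycles release/analysis horizon of the mixing stage.
#' @return Invisibly, a list with `mixing` (a `fontan_mixing`), `hfd`
#'   (three-method tibble), `x_split` and `manifest` path.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L, n_hv_mixing = 7500,
                         n_hfd = 7500, substeps = 10, mixing_cycles = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character()
  wh <- function(w) { warnings <<- c(warnings, conditionMessage(w))
                      invokeRestart("muffleWarning") }
  timings <- list()
  tic <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    r <- withCallingHandlers(force(code), warning = wh)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  config_path <- file.path(out_dir, "config.json")
  write_config(config, config_path)
  field <- tic("field", make_duct_field(config))
  x_split <- tic("split", solve_split_threshold(field, config$s))
  mixing <- tic("mixing", run_mixing(field, config, n_hv = n_hv_mixing,
                                     cycles = mixing_cycles,
                                     substeps = substeps, seed = seed + 1L))
  hfd <- tic("hfd", run_three_methods(field, config, n_total = n_hfd,
                                      x_split = x_split, substeps = substeps,
                                      seed = seed + 100L))

  files <- file.path(out_dir, c("config.json", "crossings.csv",
                                "mixing_by_phase.csv", "mixing_summary.csv",
                                "hfd.csv"))
  readr::write_csv(attr(mixing, "crossings"), files[2])
  readr::write_csv(mixing$phase, files[3])
  readr::write_csv(mixing$summary, files[4])
  readr::write_csv(hfd, files[5])
  manifest <- write_manifest(out_dir, seed, config_path, timings,
                             warnings, files)
  invisible(list(mixing = mixing, hfd = hfd, x_split = x_split,
                 manifest = manifest))
}

#' Run the cohort pipeline
#'
#' Samples a cohort of virtual patients (see [generate_cohort()]), quantifies
#' HFD by the three seeding strategies for each, and compares the methods
#' with the full agreement machinery (paired t, Bland-Altman, ICC, mean
#' absolute difference). Writes `hfd_cohort.csv`, `stats.csv` (one row per
#' method pair) and `manifest.json` to `out_dir`.
#'
#' @param n_patients cohort size.
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @param n_hfd particles per HFD seeding strategy and patient.
#' @param substeps RK4 substeps per time step.
#' @param eps_max upper bound of the cohort stirring-amplitude draw.
#' @param ... further arguments to [generate_cohort()].
#' @return Invisibly, a list with `hfd` (per-patient tibble), `agreement`
#'   (an `hfd_agreement`) and `manifest` path.
#' @export
run_cohort <- function(n_patients, out_dir, seed = 1L, n_hfd = 7500,
                       substeps = 10, eps_max = 0.5, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character()
  wh <- function(w) { warnings <<- c(warnings, conditionMessage(w))
                      invokeRestart("muffleWarning") }
  t0 <- proc.time()[["elapsed"]]
  cohort <- generate_cohort(n_patients, seed = seed, eps_max = eps_max, ...)
  hfd <- withCallingHandlers(
    purrr::imap_dfr(cohort, function(cfg, i) {
      field <- make_duct_field(cfg)
      mutate(run_three_methods(field, cfg, n_total = n_hfd,
                               substeps = substeps, seed = cfg$seed),
             patient = i, .before = 1)
    }),
    warning = wh)
  agreement <- withCallingHandlers(
    hfd_agreement(hfd, patient, method, hfd), warning = wh)
  timings <- list(cohort = round(proc.time()[["elapsed"]] - t0, 3))

  files <- file.path(out_dir, c("hfd_cohort.csv", "stats.csv"))
  readr::write_csv(hfd, files[1])
  readr::write_csv(tidy(agreement), files[2])
  manifest <- write_manifest(out_dir, seed, NULL, timings, warnings, files)
  invisible(list(hfd = hfd, agreement = agreement, manifest = manifest))
}
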
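#' Configuration for an end-to-end synthetic study run
#'
#' Collects every tunable of the pipeline in one object: the phantom and
#' cohort specifications, the lung blood fraction, the lower-lobe
#' exclusion flag, the cavity-segmentation threshold, the t-test method,
#' the output directory and the root seed. All randomness flows from the
#' root seed through fixed per-stage offsets, so a run is fully
#' reproducible and partial re-runs of a stage see the same stream.
#'
#' @param out_dir output directory for tables and the manifest.
#' @param seed root RNG seed (integer).
#' @param phantom a [phantom_spec()], or `NULL` for the default phantom.
#' @param phantom_dir optional directory written by [write_phantom()]; when
#'   given, the imaging subject is read from disk instead of generated, and
#'   missing or malformed files fail with the stage and subject named.
#' @param cohort a [cohort_spec()], or `NULL` for [default_cohort_spec()].
#' @param blood_fraction lung blood volume fraction used in SUV_T.
#' @param exclude_lower drop lower-lobe regions from the lung averages.
#' @param threshold_fraction RV cavity segmentation threshold.
#' @param test_method `"welch"` or `"pooled"` group comparisons.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, phantom = NULL, cohort = NULL,
                       phantom_dir = NULL,
                       blood_fraction = 0.16, exclude_lower = FALSE,
                       threshold_fraction = 0.5,
                       test_method = c("welch", "pooled")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 phantom = phantom, cohort = cohort,
                 phantom_dir = phantom_dir,
                 blood_fraction = blood_fraction,
                 exclude_lower = exclude_lower,
                 threshold_fraction = threshold_fraction,
                 test_method = match.arg(test_method)),
            class = "run_config")
}

stage_try <- function(stage, subject, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s, subject %s] %s", stage, subject,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Quantify one phantom (or phantom-format) subject
#'
#' Runs the full imaging quantification on one subject's data: SUV
#' conversion, 24-region lung partition and summary, blood-pool reference,
#' ED/ES extraction, RV cavity segmentation and volumetry, wall maximum
#' SUVs and the RV/LV ratio.
#'
#' @param series a [gated_pet_series()].
#' @param ct CT HU [voxel_grid()].
#' @param rois named list of masks as produced by the phantom truth
#'   (`lung`, `la`, `aorta`, `rv_wall`, `lv_wall`, `septum`, `ra_wall`).
#' @param seed_voxel 0-based RV cavity seed `c(x, y, z)`.
#' @param blood_fraction,exclude_lower,threshold_fraction see
#'   [run_config()].
#' @return list with `lung` ([lung_summary()]), `cardiac`
#'   ([cardiac_measures()] result) and `suv_b`.
#' @export
quantify_subject <- function(series, ct, rois, seed_voxel,
                             blood_fraction = 0.16, exclude_lower = FALSE,
                             threshold_fraction = 0.5) {
  suv_static <- to_suv(average_frames(series), series$injected_dose,
                       series$body_weight)
  regions <- partition_lung_regions(rois$lung)
  meas <- region_measures(suv_static, ct, regions)
  suv_b <- blood_pool_suv(suv_static, rois$la, rois$aorta)
  lung <- lung_summary(meas, suv_b, blood_fraction = blood_fraction,
                       exclude_lower = exclude_lower)
  cardiac <- cardiac_measures(series, rois, seed_ed = seed_voxel,
                              seed_es = seed_voxel,
                              threshold_fraction = threshold_fraction)
  list(lung = lung, cardiac = cardiac, suv_b = suv_b)
}

#' Ungated (static-equivalent) image of a gated series
#'
#' Voxelwise mean of the eight frames: the calibration-preserving analogue
#' of the static reconstruction, used for uptake (SUV) measurements.
#'
#' @param series a [gated_pet_series()].
#' @return activity [voxel_grid()].
#' @export
average_frames <- function(series) {
  stopifnot(inherits(series, "gated_pet_series"))
  acc <- series$frames[[1]]$values
  for (k in 2:8) acc <- acc + series$frames[[k]]$values
  grid_like(series$frames[[1]], acc / 8)
}

#' Run the full synthetic study
#'
#' End-to-end driver: builds the digital thorax phantom and quantifies it
#' against its own ground truth, generates the subject cohort, derives the
#' echo quantities, and emits the group-comparison and correlation tables.
#' Writes `subjects.csv`, `tables/comparisons.csv`,
#' `tables/correlations.csv`, `phantom_quant.json` and `manifest.json`
#' (seed, configuration hash, package version, stage record counts,
#' aggregated warnings) under `config$out_dir`. Deterministic: the same
#' config and seed produce byte-identical tables.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `phantom_quant`, `subjects`, `tables`,
#'   `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$out_dir, "tables"), showWarnings = FALSE)
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, w)

  ## stage 1: phantom generation (or load) + imaging quantification
  if (!is.null(config$phantom_dir)) {
    subject_id <- basename(config$phantom_dir)
    phantom <- stage_try("imaging_load", subject_id,
                         read_phantom(config$phantom_dir))
  } else {
    subject_id <- "phantom_01"
    pspec <- config$phantom %||% phantom_spec(seed = config$seed)
    phantom <- stage_try("phantom", subject_id, make_thorax(pspec))
  }
  quant <- withCallingHandlers(
    stage_try("imaging_quant", subject_id,
              quantify_subject(phantom$series, phantom$ct, phantom$truth$rois,
                               phantom$truth$rv_seed_voxel,
                               blood_fraction = config$blood_fraction,
                               exclude_lower = config$exclude_lower,
                               threshold_fraction = config$threshold_fraction)),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!quant$cardiac$contourable) note(paste0(subject_id, ": non-contourable RV"))

  phantom_quant <- list(
    lung = list(avg_suv_m = quant$lung$avg_suv_m,
                avg_suv_l = quant$lung$avg_suv_l,
                avg_suv_t = quant$lung$avg_suv_t,
                suv_b = quant$suv_b,
                n_regions = length(quant$lung$included_regions)),
    cardiac = list(edv = quant$cardiac$edv, esv = quant$cardiac$esv,
                   ef = quant$cardiac$ef, sv = quant$cardiac$sv,
                   rv_lv_ratio = quant$cardiac$rv_lv_ratio,
                   contourable = quant$cardiac$contourable),
    truth = list(edv = phantom$truth$true_edv, esv = phantom$truth$true_esv,
                 ef = phantom$truth$true_ef,
                 lung_suv_m = phantom$truth$lung_suv_m,
                 tissue_suv = phantom$truth$uptake$lung_tissue,
                 rv_lv_ratio = phantom$truth$uptake$rv_wall /
                   phantom$truth$uptake$lv_wall)
  )

  ## stage 2: cohort generation (seed offset keeps streams independent)
  cspec <- config$cohort %||% default_cohort_spec(seed = config$seed + 1000L)
  subjects <- stage_try("cohort", "all", make_cohort(cspec))

  ## stage 3: echo derivation
  subjects <- withCallingHandlers(
    stage_try("echo", "all", derive_echo(subjects)),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  ## stage 4: statistics
  tables <- stage_try("stats", "all",
                      build_tables(subjects, method = config$test_method))

  ## outputs
  subj_path <- file.path(config$out_dir, "subjects.csv")
  utils::write.csv(subjects, subj_path, row.names = FALSE)
  utils::write.csv(tables$comparisons,
                   file.path(config$out_dir, "tables", "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$correlations,
                   file.path(config$out_dir, "tables", "correlations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(phantom_quant,
                       file.path(config$out_dir, "phantom_quant.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_file <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package = "petph",
    version = as.character(utils::packageVersion("petph")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    n_subjects = nrow(subjects),
    n_groups = length(unique(subjects$group)),
    group_sizes = as.list(table(subjects$group)),
    n_comparisons = nrow(tables$comparisons),
    n_correlations = nrow(tables$correlations),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(phantom_quant = phantom_quant, subjects = subjects,
                 tables = tables, manifest = manifest))
}
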
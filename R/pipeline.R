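# End-to-end orchestration: inputs -> FD/FA feature blocks -> behavioral
# statistics -> PLSC -> combined JSON report. A single JSON (or YAML) config
# names every path and option; all stochastic stages take their seed from the
# config, so a rerun with the same config is reproducible (and the report is
# written without timestamps, so deterministic stages are byte-identical).

REPORT_SCHEMA_VERSION <- "1.0"

#' Load and validate a pipeline run configuration
#'
#' @param config Path to a JSON (or `.yaml`/`.yml`) file, or an equivalent
#'   named list. Required fields: `seed` and `paths` (with `masks_dir`,
#'   `atlas`, `fa_map`, `labels`, `behavior_csv`, `cop_dir`, `out_dir`).
#'   Optional: `fd` (features, schedule, offset_policy), `plsc` (n_perm,
#'   n_boot, bsr_threshold), `stats` (alpha).
#' @return A validated `run_config` list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_fm("config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_fm("yaml package not available; use a JSON config")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop_fm("config must set a seed")
  p <- config$paths
  need <- c("masks_dir", "atlas", "fa_map", "labels", "behavior_csv",
            "cop_dir", "out_dir")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0)
    stop_fm("config paths missing: %s", paste(miss, collapse = ", "))
  for (key in setdiff(need, "out_dir"))
    if (!file.exists(p[[key]]))
      stop_fm("config path '%s' does not exist: %s", key, p[[key]])
  defaults <- list(
    fd = list(features = c("general", "surface", "skeleton"),
              schedule = "dyadic", offset_policy = "corner"),
    plsc = list(n_perm = 1000, n_boot = 500, bsr_threshold = 2),
    stats = list(alpha = 0.05))
  for (sec in names(defaults)) {
    got <- if (is.null(config[[sec]])) list() else config[[sec]]
    defaults[[sec]][names(got)] <- got
    config[[sec]] <- defaults[[sec]]
  }
  config$seed <- as.integer(config$seed)
  class(config) <- "run_config"
  config
}

read_mask_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(files) == 0) stop_fm("no NIfTI masks found in %s", dir)
  masks <- lapply(files, function(f) {
    v <- read_nifti(f)
    binary_mask(v$data > 0, v$pixdim)
  })
  names(masks) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  masks
}

stage_log <- function(stage, t0) {
  message(sprintf("[fractamorph] stage %-9s done in %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: fractal-dimension features of every mask in
#' `masks_dir`; ROI-mean FA from the atlas and FA map; the COP displacement
#' statistic from the perturbation trials; between-group behavioral
#' statistics; PLSC of the imaging block against the behavioral block from
#' the cohort CSV. Per-stage TSV/JSON artifacts and a combined
#' `report.json` are written under `out_dir`.
#'
#' @param config A [run_config()] (or path / list accepted by it).
#' @return The report, invisibly (a named list, schema-versioned).
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  out <- cfg$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(schema_version = REPORT_SCHEMA_VERSION, seed = cfg$seed)

  t0 <- as.numeric(Sys.time())
  masks <- read_mask_dir(cfg$paths$masks_dir)
  fd_tab <- roi_fd_features(masks, features = cfg$fd$features,
                            schedule = cfg$fd$schedule,
                            offset_policy = cfg$fd$offset_policy)
  write.table(fd_tab, file.path(out, "fd.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  report$fd <- fd_tab
  stage_log("fd", t0)

  t0 <- as.numeric(Sys.time())
  vol <- read_labeled_volume(cfg$paths$atlas, cfg$paths$fa_map,
                             cfg$paths$labels)
  fa_tab <- mean_fa_by_roi(vol$map, vol$atlas)
  write.table(fa_tab, file.path(out, "fa.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  report$fa <- fa_tab
  stage_log("fa", t0)

  t0 <- as.numeric(Sys.time())
  trial_files <- sort(list.files(cfg$paths$cop_dir, pattern = "\\.csv$",
                                 full.names = TRUE))
  if (length(trial_files) == 0)
    stop_fm("stage cop: no trial CSVs in %s", cfg$paths$cop_dir)
  trials <- lapply(trial_files, read_cop_csv)
  report$cop <- list(displacement_cm = cop_displacement(trials),
                     n_trials = length(trials))
  stage_log("cop", t0)

  t0 <- as.numeric(Sys.time())
  cohort <- read_cohort_csv(cfg$paths$behavior_csv)
  beh_tab <- compare_groups(cohort)
  beh_tab$significant <- beh_tab$p <= cfg$stats$alpha
  write.table(beh_tab, file.path(out, "behavior.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  report$behavior <- beh_tab
  stage_log("behavior", t0)

  t0 <- as.numeric(Sys.time())
  model <- plsc(cohort$X, cohort$Y, n_perm = cfg$plsc$n_perm,
                n_boot = cfg$plsc$n_boot,
                bsr_threshold = cfg$plsc$bsr_threshold, seed = cfg$seed)
  plsc_doc <- list(singular_values = model$singular_values,
                   cov_explained = model$cov_explained,
                   perm_p = model$perm_p,
                   saliences_img = model$V, saliences_beh = model$U,
                   bsr_img = model$bsr_img, bsr_beh = model$bsr_beh,
                   stable_img = model$stable_img,
                   stable_beh = model$stable_beh,
                   loadings_img = model$loadings_img,
                   loadings_beh = model$loadings_beh,
                   bsr_threshold = cfg$plsc$bsr_threshold)
  jsonlite::write_json(plsc_doc, file.path(out, "plsc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(data.frame(subject_id = cohort$subject_ids,
                         group = as.character(cohort$group),
                         score_img = model$scores_img[, 1],
                         score_beh = model$scores_beh[, 1]),
              file.path(out, "scores.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  report$plsc <- plsc_doc
  stage_log("plsc", t0)

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Validate a pipeline report against the result schema
#'
#' @param report A report list (as returned by [run_pipeline()]) or a path
#'   to a `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report,
                                                          simplifyVector = TRUE)
  if (!identical(as.character(report$schema_version), REPORT_SCHEMA_VERSION))
    stop_fm("unknown report schema version: %s", report$schema_version)
  need <- c("schema_version", "seed", "fd", "fa", "cop", "behavior", "plsc")
  miss <- setdiff(need, names(report))
  if (length(miss) > 0)
    stop_fm("report is missing section(s): %s", paste(miss, collapse = ", "))
  for (col in c("roi", "feature", "fd")) if (is.null(report$fd[[col]]))
    stop_fm("report$fd lacks column '%s'", col)
  for (col in c("roi", "mean_fa")) if (is.null(report$fa[[col]]))
    stop_fm("report$fa lacks column '%s'", col)
  if (is.null(report$cop$displacement_cm))
    stop_fm("report$cop lacks displacement_cm")
  for (col in c("measure", "t", "p", "d")) if (is.null(report$behavior[[col]]))
    stop_fm("report$behavior lacks column '%s'", col)
  pl <- report$plsc
  for (fld in c("singular_values", "cov_explained", "perm_p", "saliences_img",
                "saliences_beh", "stable_img", "stable_beh"))
    if (is.null(pl[[fld]])) stop_fm("report$plsc lacks '%s'", fld)
  if (abs(sum(pl$cov_explained) - 1) > 1e-8)
    stop_fm("plsc cov_explained does not sum to 1")
  invisible(TRUE)
}

#' Populate a demo input directory with synthetic fixtures
#'
#' Writes everything [run_pipeline()] needs: phantom masks, a labeled atlas
#' with a matching FA map, an 18-subject cohort CSV (8 HC / 10 TBI, 34
#' imaging features) and five COP perturbation trials, plus a ready-to-run
#' `config.json`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every synthetic generator.
#' @param n_perm,n_boot Resampling sizes written into the demo config.
#' @return Path to the generated config file, invisibly.
#' @export
make_demo <- function(dir, seed = 1, n_perm = 1000, n_boot = 500) {
  for (sub in c("masks", "cop_trials", "out"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)

  masks <- list(
    sponge = make_phantom(phantom_spec("menger_sponge", 2)),
    cube   = make_phantom(phantom_spec("solid_cube", 12)),
    rod    = make_phantom(phantom_spec("rod", 20)))
  for (nm in names(masks))
    write_nifti(masks[[nm]]$occupancy, file.path(dir, "masks",
                                                 paste0(nm, ".nii.gz")))

  vol <- make_labeled_volume(
    shape = c(24, 24, 24),
    roi_boxes = list(list(lo = c(2, 2, 2), hi = c(8, 8, 8)),
                     list(lo = c(12, 2, 2), hi = c(20, 8, 8)),
                     list(lo = c(2, 12, 2), hi = c(8, 20, 8)),
                     list(lo = c(12, 12, 12), hi = c(20, 20, 20))),
    roi_values = c(0.55, 0.48, 0.62, 0.40),
    roi_names = c("cst_l", "cst_r", "cc_body", "mcp"))
  write_labeled_volume(vol, file.path(dir, "atlas.nii.gz"),
                       file.path(dir, "fa.nii.gz"),
                       file.path(dir, "labels.json"))

  cohort <- make_cohort(cohort_spec(effect = 2, noise_sd = 1,
                                    group_shift = c(-1.5, 1, 0, -0.5, 1.5),
                                    seed = sub_seed(seed, "demo_cohort")))
  write_cohort_csv(cohort, file.path(dir, "cohort.csv"))

  for (k in 1:5) {
    tr <- make_cop_trace(cop_trace_spec(seed = sub_seed(seed, paste0("trial", k))))
    write_cop_csv(tr, file.path(dir, "cop_trials", sprintf("trial%02d.csv", k)))
  }

  cfg <- list(seed = as.integer(seed),
              paths = list(masks_dir = file.path(dir, "masks"),
                           atlas = file.path(dir, "atlas.nii.gz"),
                           fa_map = file.path(dir, "fa.nii.gz"),
                           labels = file.path(dir, "labels.json"),
                           behavior_csv = file.path(dir, "cohort.csv"),
                           cop_dir = file.path(dir, "cop_trials"),
                           out_dir = file.path(dir, "out")),
              plsc = list(n_perm = n_perm, n_boot = n_boot, bsr_threshold = 2))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg_path)
}
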
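# End-to-end orchestration: simulate -> preprocess -> fit -> extract ->
# reliability, with a structured config, a run manifest, and worked-example
# validation of printed summary tables.

#' Build a full run configuration
#'
#' Collects every tunable of the pipeline with its default.  Any field can
#' be overridden; the config (and its hash) is stamped into the run
#' manifest so outputs are traceable.
#'
#' @param phantom a [phantom_spec()].
#' @param cohort a [cohort_spec()].
#' @param scheme a [diffusion_scheme()].
#' @param preprocess list: `half_width`, `band_width`, `max_shift`,
#'   `center`.
#' @param tensor list: `mask_threshold`, `epsilon`, `rd_convention`,
#'   `target_spacing`.
#' @param roi list: `radial_fraction`, `roi_params`.
#' @param stats list: `icc_form`, `cv_aggregate`, `p_adjust`.
#' @param seed integer master seed (propagated into phantom and cohort).
#' @param write_images write NIfTI stacks and maps to disk.
#' @return A list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), cohort = cohort_spec(),
                       scheme = diffusion_scheme(),
                       preprocess = list(half_width = 16L, band_width = 3L,
                                         max_shift = 5L, center = "auto"),
                       tensor = list(mask_threshold = 0.1, epsilon = 0,
                                     rd_convention = "standard",
                                     target_spacing = 0.2),
                       roi = list(radial_fraction = 0.6, roi_params = NULL),
                       stats = list(icc_form = "agreement",
                                    cv_aggregate = "mean",
                                    p_adjust = "bonferroni"),
                       seed = 1L, write_images = FALSE) {
  phantom$seed <- seed
  cohort$seed <- seed
  cfg <- list(phantom = phantom, cohort = cohort, scheme = scheme,
              preprocess = preprocess, tensor = tensor, roi = roi,
              stats = stats, seed = seed, write_images = write_images)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a run configuration
#' @param config a `run_config`.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(lapply(rapply(unclass(config), unclass, how = "replace"),
                          identity), f)
  unname(tools::md5sum(f))
}

#' Process one DWI stack to tract metrics
#'
#' The per-session chain: crop to the intra-spinal space, motion-correct
#' against the mean-b0 midsagittal profile, average repetitions, fit the
#' tensor and compute FA/MD/AD/RD maps, interpolate to the target grid,
#' and run the ROI stage.
#'
#' @param stack a [dwi_stack()].
#' @param config a [run_config()].
#' @return List with `stack` (averaged), `shifts`, `maps` (interpolated),
#'   `roi` (the [roi_stage()] output).
#' @export
process_stack <- function(stack, config = run_config()) {
  pp <- config$preprocess
  cropped <- crop_to_canal(stack, center = pp$center %||% "auto",
                           half_width = pp$half_width %||% 16L)
  mc <- correct_stack(cropped, band_width = pp$band_width %||% 3L,
                      max_shift = pp$max_shift %||% 5L)
  avg <- average_repetitions(mc$stack)
  tp <- config$tensor
  maps <- compute_maps(avg, config$scheme,
                       mask_threshold = tp$mask_threshold %||% 0.1,
                       epsilon = tp$epsilon %||% 0,
                       rd_convention = tp$rd_convention %||% "standard")
  imaps <- interpolate_maps(maps, tp$target_spacing %||% 0.2)
  roi_args <- list(maps = imaps,
                   radial_fraction = config$roi$radial_fraction %||% 0.6)
  if (!is.null(config$roi$roi_params)) roi_args$roi_params <- config$roi$roi_params
  roi <- do.call(roi_stage, roi_args)
  list(stack = avg, shifts = mc$shifts, maps = imaps, roi = roi)
}

#' Run the full simulation-to-reliability pipeline
#'
#' Simulates the cohort, processes every participant x scanner x session
#' stack through preprocessing, tensor fitting and ROI extraction, writes
#' the tidy metrics CSV and the reliability report (CSV + full-precision
#' JSON), and returns a manifest.  Deterministic under the config seed.
#' With a single session per scanner the reliability stage is skipped
#' with a warning.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return A list of class `run_manifest`: per-stage outputs, config hash,
#'   wall-clock seconds, warnings, and the in-memory `tidy` and `report`
#'   tables.
#' @export
run_full <- function(config = run_config(), out_dir = tempfile("sdti_run_")) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  files <- character()
  stage_times <- c()
  tick <- function(stage, t) stage_times <<- c(stage_times,
                                               stats::setNames(as.numeric(t), stage))

  ts <- Sys.time()
  sim <- simulate_cohort(config$cohort, config$phantom, config$scheme,
                         images = TRUE)
  tick("simulate", Sys.time() - ts)
  truth_f <- file.path(out_dir, "truth.csv")
  utils::write.csv(sim$truth, truth_f, row.names = FALSE)
  files <- c(files, truth_f)

  ts <- Sys.time()
  tidy <- list()
  for (key in names(sim$stacks)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    st <- sim$stacks[[key]]$stack
    if (isTRUE(config$write_images)) {
      pfx <- file.path(out_dir, gsub("\\.", "_", key))
      files <- c(files, write_dwi_stack(st, pfx, config$scheme))
    }
    res <- process_stack(st, config)
    pm <- res$roi$metrics$per_region
    tidy[[key]] <- data.frame(participant = parts[1], scanner = parts[2],
                              session = as.integer(sub("s", "", parts[3])),
                              region = pm$region, metric = pm$metric,
                              value = pm$value)
    if (isTRUE(config$write_images)) {
      mp_dir <- file.path(out_dir, "maps")
      files <- c(files, write_metric_maps(res$maps, mp_dir,
                                          gsub("\\.", "_", key)))
    }
  }
  tidy <- do.call(rbind, tidy)
  rownames(tidy) <- NULL
  tick("process", Sys.time() - ts)
  tidy_f <- file.path(out_dir, "tract_metrics.csv")
  write_tidy_metrics(tidy, tidy_f)
  files <- c(files, tidy_f)

  report <- NULL
  if (config$cohort$sessions_per_scanner >= 2) {
    ts <- Sys.time()
    report <- build_reliability_table(tidy,
                                      icc_form = config$stats$icc_form %||% "agreement",
                                      cv_aggregate = config$stats$cv_aggregate %||% "mean",
                                      p_adjust = config$stats$p_adjust %||% "bonferroni")
    tick("reliability", Sys.time() - ts)
    rep_f <- file.path(out_dir, "reliability_report.csv")
    utils::write.csv(round_reliability_table(report), rep_f, row.names = FALSE)
    json_f <- file.path(out_dir, "reliability_report.json")
    jsonlite::write_json(report, json_f, digits = NA, pretty = TRUE)
    files <- c(files, rep_f, json_f)
  } else {
    note("sessions_per_scanner < 2: reliability stage skipped")
    warnf("reliability stage skipped: fewer than 2 sessions per scanner")
  }

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   files = data.frame(path = files,
                                      md5 = unname(tools::md5sum(files))),
                   stage_seconds = as.list(stage_times),
                   wall_clock_seconds = as.numeric(Sys.time() - t0),
                   warnings = warnings_log,
                   tidy = tidy, report = report, out_dir = out_dir)
  class(manifest) <- "run_manifest"
  man_f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest[c("config_hash", "seed", "stage_seconds",
                                  "wall_clock_seconds", "warnings")],
                       man_f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Recompute derivable cells of printed summary tables
#'
#' Treats a table of printed summary values (means, SDs, n, mean
#' differences) as input and recomputes every derivable cell: limits of
#' agreement from (D, SD of differences), the t-based 95% CI from
#' (mean, SD, n), and the pooled mean from the two session means.  Each
#' recomputed cell is compared with its printed counterpart at 3-decimal
#' report rounding.
#'
#' @param reference data frame (or CSV path) with columns `table`,
#'   `metric`, `region`, `n`, and printed cells `test_mean`, `test_sd`,
#'   `test_ci_lo`, `test_ci_hi`, `retest_mean`, `retest_sd`, `pooled_mean`,
#'   `D`, `D_sd`, `loa_lower`, `loa_upper` (missing cells may be `NA`).
#' @param tol absolute tolerance on the 3-decimal comparison (default
#'   0.0015, i.e. one rounding step).
#' @return Data frame with one row per reference row and cell:
#'   `cell`, `printed`, `recomputed`, `match`.
#' @export
validate_tables <- function(reference, tol = 0.0015) {
  if (is.character(reference)) reference <- utils::read.csv(reference)
  if (nrow(reference) == 0)
    return(data.frame(table = character(), metric = character(),
                      region = character(), cell = character(),
                      printed = numeric(), recomputed = numeric(),
                      match = logical()))
  out <- list()
  add <- function(row, cell, printed, recomputed) {
    if (is.na(printed) || is.na(recomputed)) return()
    out[[length(out) + 1]] <<- data.frame(
      table = row$table, metric = row$metric, region = row$region,
      cell = cell, printed = printed,
      recomputed = round_half_away(recomputed, 3),
      match = abs(round_half_away(recomputed, 3) - printed) <= tol)
  }
  for (i in seq_len(nrow(reference))) {
    r <- reference[i, ]
    if (!is.na(r$D) && !is.na(r$D_sd)) {
      add(r, "loa_lower", r$loa_lower, r$D - 1.96 * r$D_sd)
      add(r, "loa_upper", r$loa_upper, r$D + 1.96 * r$D_sd)
    }
    if (!is.na(r$test_mean) && !is.na(r$test_sd) && !is.na(r$n)) {
      ci <- mean_ci(r$test_mean, sd = r$test_sd, n = r$n)
      add(r, "test_ci_lo", r$test_ci_lo, ci$ci[1])
      add(r, "test_ci_hi", r$test_ci_hi, ci$ci[2])
    }
    if (!is.na(r$test_mean) && !is.na(r$retest_mean))
      add(r, "pooled_mean", r$pooled_mean, (r$test_mean + r$retest_mean) / 2)
  }
  do.call(rbind, out)
}

#' Printed summary rows shipped with the package
#'
#' Loads the transcription of the published per-scanner and inter-scanner
#' summary tables (means, SDs, CIs, Bland-Altman cells, CVs, ICCs for
#' n = 16 participants) used as worked-example inputs by
#' [validate_tables()].
#'
#' @return Data frame, one row per table x metric x region.
#' @export
printed_summary_rows <- function() {
  utils::read.csv(system.file("extdata", "printed_summary_rows.csv",
                              package = "spinaldti"))
}
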
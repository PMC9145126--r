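#' In-silico study configuration
#'
#' Describes a full simulated exposure study: an exposure grid sampled every
#' 30 minutes over 5 hours, control and exposed groups of phantom eyes,
#' repeated acquisitions per time point, and the phantom, toxicity-course
#' and band definitions used throughout.
#'
#' @param exposure_grid_min strictly increasing exposure times in minutes,
#'   starting at 0 (the pre-exposure baseline); default `seq(0, 270, 30)`.
#' @param n_eyes_per_group eyes per group (default 3).
#' @param n_repeats repeated acquisitions per eye and time point (default 5).
#' @param phantom a [phantom_config()].
#' @param course a [toxicity_course()] applied to the exposed group.
#' @param bands a [band_spec()].
#' @param seed master seed for the whole study.
#' @return an object of class `study_config`.
#' @export
study_config <- function(exposure_grid_min = seq(0, 270, by = 30),
                         n_eyes_per_group = 3L, n_repeats = 5L,
                         phantom = make_default_cornea(),
                         course = toxicity_course(),
                         bands = band_spec(), seed = 1L) {
  if (!is.numeric(exposure_grid_min) || length(exposure_grid_min) < 1 ||
      exposure_grid_min[1] != 0 || anyNA(exposure_grid_min) ||
      any(diff(exposure_grid_min) <= 0))
    config_error("exposure grid must be strictly increasing and start at 0 (baseline)")
  check_scalar(n_eyes_per_group, "n_eyes_per_group", 1)
  check_scalar(n_repeats, "n_repeats", 1)
  check_scalar(seed, "seed", 0)
  if (!inherits(phantom, "phantom_config")) config_error("'phantom' must be a phantom_config")
  if (!inherits(course, "toxicity_course")) config_error("'course' must be a toxicity_course")
  if (!inherits(bands, "band_spec")) config_error("'bands' must be a band_spec")
  phantom$n_repeats <- as.integer(n_repeats)
  structure(
    list(exposure_grid_min = as.numeric(exposure_grid_min),
         n_eyes_per_group = as.integer(n_eyes_per_group),
         n_repeats = as.integer(n_repeats), phantom = phantom,
         course = course, bands = bands, seed = as.integer(seed)),
    class = "study_config")
}

# Metrics of one simulated acquisition. Hue and motility are measured on the
# normalized band-integral image / raw series; histogram matching is applied
# only for rendered output (see the methods vignette).
acquisition_metrics <- function(sim, bands, sample_id, group, exposure_min) {
  series <- sim$series
  masks <- sim$masks
  img <- process_series(series, bands, histmatch = FALSE)
  axial <- series$axial_um_per_px
  rows <- list()
  if (!is.null(masks$total_epithelium)) {
    pk <- find_hue_peaks(hue_histogram(img, masks$total_epithelium), n_peaks = 2)
    rows$total <- data.frame(
      sample_id = sample_id, group = group, exposure_min = exposure_min,
      roi = "total_epithelium",
      motility = motility_coefficient(series, masks$total_epithelium),
      peak_hue_deg = pk$hue_deg[1],
      second_peak_hue_deg = if (nrow(pk) > 1) pk$hue_deg[2] else NA_real_,
      thickness_um = thickness_from_mask(masks$total_epithelium, axial))
  }
  if (!is.null(masks$basal_epithelium)) {
    pk <- find_hue_peaks(hue_histogram(img, masks$basal_epithelium), n_peaks = 1)
    rows$basal <- data.frame(
      sample_id = sample_id, group = group, exposure_min = exposure_min,
      roi = "basal_epithelium",
      motility = motility_coefficient(series, masks$basal_epithelium),
      peak_hue_deg = pk$hue_deg[1], second_peak_hue_deg = NA_real_,
      thickness_um = thickness_from_mask(masks$basal_epithelium, axial))
  }
  if (!is.null(masks$stroma)) {
    rows$stroma <- data.frame(
      sample_id = sample_id, group = group, exposure_min = exposure_min,
      roi = "stroma", motility = NA_real_, peak_hue_deg = NA_real_,
      second_peak_hue_deg = NA_real_,
      thickness_um = thickness_from_mask(masks$stroma, axial))
  }
  do.call(rbind, unname(rows))
}

#' Run the full simulated exposure time course
#'
#' For every (group, eye, exposure time, repeat) a fresh speckle realization
#' is simulated, processed into a dynamic-contrast image, and measured:
#' motility (total and basal epithelium), hue peaks (one for the basal ROI,
#' two for the total epithelium), and thickness (epithelium and stroma).
#' Control eyes use baseline (exposure 0) dynamics at all times, each time
#' point being an independent realization, emulating repeated imaging
#' sessions. Writes `metrics_repeats.csv` (one row per repeat and ROI),
#' `metrics_by_eye.csv` (mean across repeats) and one averaged
#' histogram-matched RGB PNG per (group, eye, time point). Fully
#' reproducible from `config$seed`.
#'
#' @param config a [study_config()].
#' @param output_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param progress print stage timings to stderr.
#' @return invisibly, a list with `repeats` and `by_eye` data.frames.
#' @export
run_timecourse <- function(config, output_dir = NULL, progress = FALSE) {
  if (!inherits(config, "study_config")) config_error("'config' must be a study_config")
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  all_rows <- list()
  for (group in c("control", "BAK")) {
    for (eye in seq_len(config$n_eyes_per_group)) {
      sample_id <- sprintf("%s_eye%02d", group, eye)
      for (ti in seq_along(config$exposure_grid_min)) {
        t_min <- config$exposure_grid_min[ti]
        t0 <- Sys.time()
        cfg <- config$phantom
        # one seed stream per (group, eye, time point); repeats branch below
        cfg$seed <- derive_seed(config$seed,
                                if (group == "BAK") 1 else 2, eye, ti)
        imgs <- vector("list", config$n_repeats)
        for (rep_i in seq_len(config$n_repeats)) {
          sim <- tryCatch(
            simulate_series(cfg,
                            exposure_min = if (group == "BAK") t_min else 0,
                            course = config$course,
                            repeat_index = rep_i - 1L),
            error = function(e) stop_dmoct(sprintf(
              "simulation failed at (%s, eye %d, %g min, repeat %d): %s",
              group, eye, t_min, rep_i, conditionMessage(e)), "dmoct_stage_error"))
          all_rows[[length(all_rows) + 1L]] <-
            acquisition_metrics(sim, config$bands, sample_id, group, t_min)
          if (!is.null(output_dir))
            imgs[[rep_i]] <- process_series(sim$series, config$bands,
                                            histmatch = TRUE)
        }
        if (!is.null(output_dir)) {
          avg <- average_repeats(imgs)
          write_rgb(avg, file.path(output_dir, sprintf(
            "%s_t%03d_avg.png", sample_id, as.integer(t_min))))
        }
        if (progress)
          message(sprintf("[dmoct] %s eye %d t=%g min: %.2f s", group, eye,
                          t_min, as.numeric(Sys.time() - t0, units = "secs")))
      }
    }
  }
  repeats <- do.call(rbind, all_rows)
  rownames(repeats) <- NULL
  by_eye <- aggregate_metrics(repeats,
                              by = c("sample_id", "group", "exposure_min", "roi"))
  if (!is.null(output_dir)) {
    write_metrics(repeats, file.path(output_dir, "metrics_repeats.csv"))
    write_metrics(by_eye, file.path(output_dir, "metrics_by_eye.csv"))
  }
  invisible(list(repeats = repeats, by_eye = by_eye))
}

metric_cols <- c("motility", "peak_hue_deg", "second_peak_hue_deg", "thickness_um")

aggregate_metrics <- function(table, by, fun = function(x) mean(x, na.rm = TRUE)) {
  key <- interaction(table[by], drop = TRUE, lex.order = TRUE)
  out <- table[!duplicated(key), by, drop = FALSE]
  idx <- split(seq_len(nrow(table)), key)[as.character(unique(key))]
  for (cn in metric_cols) {
    out[[cn]] <- vapply(idx, function(i) {
      v <- table[[cn]][i]
      if (all(is.na(v))) NA_real_ else fun(v[!is.na(v)])
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Group-level summary of a metrics table
#'
#' Per (group, exposure time, ROI): mean and sample SD of each metric across
#' eyes/repeats. No inferential statistics are computed; the table is
#' intended for downstream plotting or testing.
#'
#' @param table a metrics data.frame with the [write_metrics()] schema.
#' @return data.frame with `group`, `exposure_min`, `roi` and, per metric,
#'   `<metric>_mean` and `<metric>_sd` (`NA` SD for single records).
#' @export
summarize_groups <- function(table) {
  if (!is.data.frame(table) || !nrow(table))
    validation_error("'table' must be a non-empty data.frame")
  missing_cols <- setdiff(METRICS_COLUMNS, names(table))
  if (length(missing_cols))
    validation_error(sprintf("table is missing column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  by <- c("group", "exposure_min", "roi")
  means <- aggregate_metrics(table, by)
  sds <- aggregate_metrics(table, by,
                           fun = function(x) if (length(x) < 2) NA_real_ else stats::sd(x))
  out <- means[by]
  for (cn in metric_cols) {
    out[[paste0(cn, "_mean")]] <- means[[cn]]
    out[[paste0(cn, "_sd")]] <- sds[[cn]]
  }
  out
}
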
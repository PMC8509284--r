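## Study orchestration: cohort configuration and the end-to-end simulation.

#' Study configuration
#'
#' Defines the simulated cohorts (group, timepoint, size), the acquisition
#' protocol, the fitting and histogram options, and optional speed/ROI
#' settings. The default reproduces the study design: 22 healthy controls,
#' 7 isogenic and 5 allogenic grafts per timepoint, imaged at weeks 3 and 6.
#'
#' @param cohorts A data frame with columns `group`, `timepoint`, `n`.
#' @param shape Phantom grid dimensions.
#' @param geometry Phantom geometry, see [kidney_geometry()].
#' @param protocol Acquisition protocol, see [default_protocol()].
#' @param fit Fit options, see [fit_options()].
#' @param histogram List of arguments passed to [histogram_metrics()].
#' @param roi_voxels If not `NULL`, fit T1/T2 only inside compact per-
#'   compartment sub-ROIs of this size (emulating manual ROI placement and
#'   reducing compute); ADC is always fitted over the full image for the
#'   whole-kidney histogram.
#' @return A `study_config` object.
#' @export
study_config <- function(cohorts = default_cohorts(),
                         shape = c(128, 128),
                         geometry = kidney_geometry(),
                         protocol = default_protocol(),
                         fit = fit_options(),
                         histogram = list(),
                         roi_voxels = NULL) {
  cohorts <- as_tibble(cohorts)
  stopifnot(all(c("group", "timepoint", "n") %in% names(cohorts)))
  if (any(cohorts$n < 1)) abort("Every cohort must have n >= 1.")
  ## validate that every referenced parameter set exists
  purrr::pwalk(cohorts, function(group, timepoint, n) {
    tissue_parameters(group, timepoint)
  })
  structure(list(cohorts = cohorts, shape = shape, geometry = geometry,
                 protocol = protocol, fit = fit, histogram = histogram,
                 roi_voxels = roi_voxels),
            class = "study_config")
}

#' @rdname study_config
#' @export
default_cohorts <- function() {
  tibble(group = c("control", "isogenic", "allogenic", "isogenic",
                   "allogenic"),
         timepoint = c("none", "w3", "w3", "w6", "w6"),
         n = c(22L, 7L, 5L, 7L, 5L))
}

#' Read a study configuration from a YAML file
#'
#' The file may define `cohorts` (list of group/timepoint/n records),
#' `shape`, and overrides for `protocol`, `fit` and `histogram` options.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cohorts)) {
    cohorts <- dplyr::bind_rows(lapply(y$cohorts, as_tibble))
    ## YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
    names(cohorts)[names(cohorts) == "FALSE"] <- "n"
    args$cohorts <- cohorts
  }
  if (!is.null(y$shape)) args$shape <- as.integer(y$shape)
  if (!is.null(y$protocol)) {
    args$protocol <- do.call(default_protocol, y$protocol)
  }
  if (!is.null(y$fit)) args$fit <- do.call(fit_options, y$fit)
  if (!is.null(y$histogram)) args$histogram <- y$histogram
  if (!is.null(y$roi_voxels)) args$roi_voxels <- as.integer(y$roi_voxels)
  do.call(study_config, args)
}

## Stable per-subject seeding: independent of cohort ordering, so adding a
## cohort never perturbs existing subjects. Kept well below 2^31.
cohort_code <- function(group, timepoint) {
  key <- paste(group, timepoint, sep = ".")
  codes <- c(control.none = 1L, isogenic.w3 = 2L, isogenic.w6 = 3L,
             allogenic.w3 = 4L, allogenic.w6 = 5L)
  if (key %in% names(codes)) return(codes[[key]])
  6L + (sum(utf8ToInt(key)) %% 50L)
}

#' @rdname study_config
#' @param master_seed Study master seed.
#' @param group,timepoint,index Cohort identity and subject index.
#' @export
subject_seed <- function(master_seed, group, timepoint, index) {
  as.integer((master_seed %% 20000L) * 100000L +
               cohort_code(group, timepoint) * 10000L + index)
}

#' Run the simulated study end to end
#'
#' For every subject: phantom generation, forward synthesis of the three
#' acquisitions, voxel-wise T1/T2/ADC fitting, compartmental region means
#' with CMD, and whole-kidney ADC histogram metrics. Group-level comparisons
#' (ANOVA + Tukey across control/isogenic/allogenic per timepoint for the
#' region means; unpaired t-tests between grafts for the histogram metrics)
#' are computed on the per-subject results.
#'
#' @param config A `study_config`.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param outdir If not `NULL`, CSV results and a JSON manifest are written
#'   there.
#' @param save_maps Also write per-subject NIfTI parameter maps (requires
#'   `outdir`).
#' @return A `study_result` list: `region_stats`, `cmd_stats`,
#'   `histogram_stats`, `comparisons`, `config`, `manifest`.
#' @export
run_study <- function(config = study_config(), seed = 1, outdir = NULL,
                      save_maps = FALSE) {
  stopifnot(inherits(config, "study_config"))
  labels <- make_label_map(config$shape, config$geometry)
  region_rows <- list()
  hist_rows <- list()
  for (ci in seq_len(nrow(config$cohorts))) {
    co <- config$cohorts[ci, ]
    params <- tissue_parameters(co$group, co$timepoint)
    for (i in seq_len(co$n)) {
      sseed <- subject_seed(seed, co$group, co$timepoint, i)
      sid <- sprintf("%s_%s_%02d", co$group, co$timepoint, i)
      res <- analyze_subject(params, config, labels, sseed)
      for (m in res$maps_used) {
        region_rows[[length(region_rows) + 1L]] <-
          region_means(res[[m]], labels, sid, co$group, co$timepoint)
      }
      hist_rows[[length(hist_rows) + 1L]] <-
        dplyr::mutate(res$histogram, subject_id = sid, group = co$group,
                      timepoint = co$timepoint, .before = 1)
      if (save_maps && !is.null(outdir)) {
        for (m in res$maps_used) {
          write_param_map(res[[m]],
                          file.path(outdir, paste0(sid, "_", res[[m]]$kind)))
        }
      }
    }
  }
  region_stats <- cohort_table(region_rows)
  cmd_stats <- cmd_table(region_stats)
  histogram_stats <- dplyr::bind_rows(hist_rows)
  comparisons <- study_comparisons(region_stats, cmd_stats, histogram_stats)
  manifest <- list(
    package = "renomap",
    version = as.character(utils::packageVersion("renomap")),
    seed = seed,
    config_hash = rlang::hash(config),
    n_subjects = sum(config$cohorts$n)
  )
  out <- structure(list(region_stats = region_stats, cmd_stats = cmd_stats,
                        histogram_stats = histogram_stats,
                        comparisons = comparisons, config = config,
                        manifest = manifest),
                   class = "study_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(region_stats, file.path(outdir, "region_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(cmd_stats, file.path(outdir, "cmd_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(histogram_stats,
                     file.path(outdir, "histogram_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(outdir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

## One subject: phantom -> synthesis -> three fits -> histogram.
analyze_subject <- function(params, config, labels, sseed) {
  phantom <- make_phantom(params, config$shape, seed = sseed,
                          geometry = config$geometry)
  series <- synthesize_subject(phantom, config$protocol, seed = sseed)
  fmask <- if (!is.null(config$roi_voxels)) {
    subsample_roi(labels, config$roi_voxels, seed = sseed)
  } else NULL
  t1_map <- fit_t1_ir(series$ir, fit_mask = fmask, options = config$fit)
  t2_map <- fit_t2(series$me, fit_mask = fmask, options = config$fit)
  adc_map <- fit_adc(series$dwi, options = config$fit)
  hist <- do.call(map_histogram,
                  c(list(adc_map, labels), config$histogram))
  list(t1 = t1_map, t2 = t2_map, adc = adc_map, histogram = hist,
       maps_used = c("t1", "t2", "adc"))
}

## Group comparisons mirroring the study's reporting: per timepoint, region
## means across the three arms; histogram heterogeneity between the grafts.
study_comparisons <- function(region_stats, cmd_stats, histogram_stats) {
  out <- list()
  tps <- setdiff(unique(region_stats$timepoint), "none")
  region_sets <- list(T1_ms = c("cortex", "osom", "isom"),
                      T2_ms = c("cortex", "osom", "isom"),
                      ADC_e3mm2s = c("cortex", "om"))
  for (tp in tps) {
    sub_tp <- function(df) {
      dplyr::filter(df, .data$timepoint %in% c(tp, "none"))
    }
    for (mk in names(region_sets)) {
      for (reg in region_sets[[mk]]) {
        d <- sub_tp(region_stats) |>
          dplyr::filter(.data$map_kind == mk, .data$region == reg)
        if (dplyr::n_distinct(d$group) < 2) next
        cmp <- compare_groups(d, "mean", "group")
        out[[length(out) + 1L]] <- tidy(cmp) |>
          dplyr::mutate(map_kind = mk, region = reg, timepoint = tp,
                        metric = paste(mk, reg, sep = "."), .before = 1)
      }
      d <- sub_tp(cmd_stats) |> dplyr::filter(.data$map_kind == mk)
      if (dplyr::n_distinct(d$group) >= 2) {
        cmp <- compare_groups(d, "cmd", "group")
        out[[length(out) + 1L]] <- tidy(cmp) |>
          dplyr::mutate(map_kind = mk, region = "cmd", timepoint = tp,
                        metric = paste(mk, "cmd", sep = "."), .before = 1)
      }
    }
    grafts <- histogram_stats |>
      dplyr::filter(.data$timepoint == tp,
                    .data$group %in% c("isogenic", "allogenic"))
    if (dplyr::n_distinct(grafts$group) == 2) {
      for (met in c("mean", "sd", "kurtosis", "skewness", "entropy", "iqr")) {
        cmp <- compare_groups(grafts, met, "group")
        out[[length(out) + 1L]] <- tidy(cmp) |>
          dplyr::mutate(map_kind = "ADC_e3mm2s", region = "whole_kidney",
                        timepoint = tp,
                        metric = paste("hist", met, sep = "."), .before = 1)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d subjects, %d region rows, seed hash %s\n",
              x$manifest$n_subjects, nrow(x$region_stats),
              substr(x$manifest$config_hash, 1, 8)))
  invisible(x)
}

#' Summarize a study result
#'
#' @param x A `study_result`.
#' @param ... Unused.
#' @return A tibble of group-level means +/- SEM per map kind and region.
#' @method glance study_result
#' @export
glance.study_result <- function(x, ...) {
  x$region_stats |>
    dplyr::group_by(.data$group, .data$timepoint, .data$map_kind,
                    .data$region) |>
    dplyr::summarise(n = dplyr::n(),
                     sem = sd(.data$mean) / sqrt(dplyr::n()),
                     mean = mean(.data$mean, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::relocate("mean", .before = "sem")
}
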
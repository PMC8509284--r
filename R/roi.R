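## Compartmental region statistics and cortico-medullary difference.

roi_regions <- c("cortex", "osom", "isom", "om", "whole_kidney")

#' Per-region means of a parameter map
#'
#' Arithmetic mean of the fitted values over the unmasked voxels of each
#' anatomical region (cortex, OSOM, ISOM, the composite OM and the whole
#' kidney). A region left empty after masking yields `NA` (never 0) with a
#' warning.
#'
#' @param map A `param_map`.
#' @param labels A `label_map` of the same shape.
#' @param subject_id,group,timepoint Identifiers carried into the output.
#' @return A tibble with one row per region: `subject_id`, `group`,
#'   `timepoint`, `map_kind`, `region`, `mean`, `n_voxels`.
#' @export
region_means <- function(map, labels, subject_id = NA_character_,
                         group = NA_character_, timepoint = NA_character_) {
  stopifnot(inherits(map, "param_map"))
  if (!identical(dim(map$values), dim(labels))) {
    abort("Parameter map and label map shapes differ.")
  }
  rows <- purrr::map(roi_regions, function(reg) {
    sel <- region_mask(labels, reg) & map$mask
    n <- sum(sel)
    if (n == 0) {
      warn(sprintf("Region '%s' has no valid voxels; mean set to NA.", reg))
    }
    tibble(subject_id = as.character(subject_id), group = group,
           timepoint = timepoint, map_kind = map$kind, region = reg,
           mean = if (n > 0) mean(map$values[sel]) else NA_real_,
           n_voxels = n)
  })
  dplyr::bind_rows(rows)
}

#' Cortico-medullary difference per subject
#'
#' CMD is the per-subject difference between the ISOM and cortex region means
#' (exactly `mean_isom - mean_cortex`); it is `NA` if either region mean is
#' missing. Computed per subject and map kind, then typically averaged across
#' a group.
#'
#' @param region_stats A tibble as returned by [region_means()] /
#'   [cohort_table()].
#' @return A tibble with one row per subject x map kind: identifiers plus
#'   `cmd`.
#' @export
cmd_table <- function(region_stats) {
  region_stats |>
    dplyr::filter(.data$region %in% c("cortex", "isom")) |>
    dplyr::select("subject_id", "group", "timepoint", "map_kind",
                  "region", "mean") |>
    tidyr::pivot_wider(names_from = "region", values_from = "mean") |>
    dplyr::mutate(cmd = .data$isom - .data$cortex) |>
    dplyr::select("subject_id", "group", "timepoint", "map_kind", "cmd")
}

#' Bind per-subject region statistics into a cohort table
#'
#' @param stats A list of tibbles from [region_means()] (or a single tibble).
#' @return One long tibble, deterministically ordered by subject, map kind
#'   and region.
#' @export
cohort_table <- function(stats) {
  if (is.data.frame(stats)) stats <- list(stats)
  out <- dplyr::bind_rows(stats)
  if (nrow(out) == 0) {
    return(tibble(subject_id = character(), group = character(),
                  timepoint = character(), map_kind = character(),
                  region = character(), mean = double(),
                  n_voxels = integer()))
  }
  out |>
    dplyr::mutate(region = factor(.data$region, levels = roi_regions)) |>
    dplyr::arrange(.data$subject_id, .data$map_kind, .data$region) |>
    dplyr::mutate(region = as.character(.data$region))
}

#' Sample a compact sub-ROI in each compartment
#'
#' Emulates manual ROI placement: within each of cortex, OSOM and ISOM a
#' random in-region center voxel is drawn and the `n_per_region` nearest
#' in-region voxels around it form the ROI. Useful both to mimic reader
#' variability and to restrict expensive voxel-wise fits.
#'
#' @param labels A `label_map`.
#' @param n_per_region Target voxels per compartment ROI.
#' @param seed Integer seed.
#' @return A logical matrix marking the selected voxels.
#' @export
subsample_roi <- function(labels, n_per_region = 150, seed = 1) {
  lab <- unclass(labels)
  sel <- matrix(FALSE, nrow(lab), ncol(lab))
  withr::with_seed(seed, {
    for (code in 1:3) {
      idx <- which(lab == code, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      ctr <- idx[sample.int(nrow(idx), 1), ]
      d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
      keep <- idx[order(d2)[seq_len(min(n_per_region, nrow(idx)))], ,
                  drop = FALSE]
      sel[keep] <- TRUE
    }
  })
  sel
}
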
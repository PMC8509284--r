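## NIfTI + JSON-sidecar input/output.

nifti_with_pixdim <- function(arr, voxel_mm, slice_mm = 2) {
  dims <- dim(arr) %||% length(arr)
  pix <- switch(as.character(length(dims)),
                "2" = c(voxel_mm[1], voxel_mm[2]),
                "4" = c(voxel_mm[1], voxel_mm[2], slice_mm, 1),
                rep(1, length(dims)))
  RNifti::asNifti(arr, list(pixdim = c(0, pix,
                                       rep(0, 7 - length(pix)))[1:8]))
}

write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write and read a phantom as NIfTI plus JSON sidecar
#'
#' Writes `<prefix>_label.nii.gz` (integer label map),
#' `<prefix>_truth_{t1,t2,adc}.nii.gz` (float truth grids) and
#' `<prefix>.json` (tissue parameters, heterogeneity settings, seed, voxel
#' size).
#'
#' @param phantom A `kidney_phantom`.
#' @param prefix Output path prefix.
#' @return `write_phantom()` returns the prefix invisibly; `read_phantom()`
#'   returns a `kidney_phantom`.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "kidney_phantom"))
  vx <- phantom$voxel_size_mm
  RNifti::writeNifti(nifti_with_pixdim(unclass(phantom$label_map), vx),
                     paste0(prefix, "_label.nii.gz"), datatype = "int16")
  for (f in c("t1", "t2", "adc")) {
    RNifti::writeNifti(nifti_with_pixdim(phantom[[paste0("truth_", f)]], vx),
                       paste0(prefix, "_truth_", f, ".nii.gz"),
                       datatype = "float")
  }
  p <- phantom$params
  write_sidecar(list(
    group = p$group, timepoint = p$timepoint,
    compartments = as.list(setNames(
      purrr::pmap(p$values[-1], function(t1_ms, t2_ms, adc)
        list(t1_ms = t1_ms, t2_ms = t2_ms, adc = adc)),
      p$values$compartment)),
    heterogeneity = p$heterogeneity,
    seed = phantom$seed,
    voxel_size_mm = vx,
    geometry = attr(phantom$label_map, "geometry")
  ), paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  lab_arr <- as.array(RNifti::readNifti(paste0(prefix, "_label.nii.gz")))
  geometry <- meta$geometry
  labels <- structure(matrix(as.integer(lab_arr), nrow(lab_arr)),
                      voxel_size_mm = meta$voxel_size_mm,
                      geometry = geometry,
                      class = c("label_map", "matrix", "array"))
  comp <- meta$compartments
  params <- structure(list(
    group = meta$group, timepoint = meta$timepoint,
    values = tibble(compartment = names(comp),
                    t1_ms = unname(purrr::map_dbl(comp, "t1_ms")),
                    t2_ms = unname(purrr::map_dbl(comp, "t2_ms")),
                    adc = unname(purrr::map_dbl(comp, "adc"))),
    heterogeneity = meta$heterogeneity), class = "tissue_params")
  grids <- lapply(c(t1 = "t1", t2 = "t2", adc = "adc"), function(f) {
    a <- as.array(RNifti::readNifti(paste0(prefix, "_truth_", f, ".nii.gz")))
    matrix(as.numeric(a), nrow(a))
  })
  structure(list(label_map = labels, truth_t1 = grids$t1,
                 truth_t2 = grids$t2, truth_adc = grids$adc,
                 voxel_size_mm = meta$voxel_size_mm, params = params,
                 seed = meta$seed),
            class = "kidney_phantom")
}

#' Write and read an acquisition series as 4D NIfTI plus JSON sidecar
#'
#' The sidecar uses BIDS-flavoured field names where natural
#' (`InversionTime`, `EchoTime`, `BValue`, `RepetitionTime`, all in the
#' package's native units).
#'
#' @param series An `acq_series`.
#' @param prefix Output path prefix.
#' @param voxel_mm In-plane voxel size recorded in the NIfTI header.
#' @return `write_series()` returns the prefix invisibly; `read_series()`
#'   returns an `acq_series`.
#' @export
write_series <- function(series, prefix, voxel_mm = c(35 / 128, 35 / 128)) {
  stopifnot(inherits(series, "acq_series"))
  RNifti::writeNifti(nifti_with_pixdim(series$data, voxel_mm),
                     paste0(prefix, ".nii.gz"), datatype = "float")
  axis_field <- switch(series$kind, IR_T1 = "InversionTime",
                       ME_T2 = "EchoTime", DWI = "BValue")
  meta <- list(Kind = series$kind, RepetitionTime = series$tr_ms,
               S0Scale = series$s0_scale, SNR = series$snr,
               Seed = series$seed)
  meta[[axis_field]] <- series$param_axis
  write_sidecar(meta, paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_series
#' @export
read_series <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  arr <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  axis <- meta$InversionTime %||% meta$EchoTime %||% meta$BValue
  acq_series(meta$Kind, array(as.numeric(arr), dim = dim(arr)), axis,
             tr_ms = meta$RepetitionTime %||% NA_real_,
             s0_scale = meta$S0Scale, snr = meta$SNR,
             seed = meta$Seed %||% NA_integer_)
}

#' Write and read a parameter map as NIfTI plus JSON sidecar
#'
#' Writes `<prefix>.nii.gz` (values, float), `<prefix>_quality.nii.gz` (R^2),
#' `<prefix>_mask.nii.gz` and `<prefix>.json`.
#'
#' @param map A `param_map`.
#' @param prefix Output path prefix.
#' @param voxel_mm In-plane voxel size recorded in the NIfTI header.
#' @return `write_param_map()` returns the prefix invisibly;
#'   `read_param_map()` returns a `param_map`.
#' @export
write_param_map <- function(map, prefix, voxel_mm = c(35 / 128, 35 / 128)) {
  stopifnot(inherits(map, "param_map"))
  vals <- map$values
  vals[is.na(vals)] <- 0
  qual <- map$quality
  qual[!is.finite(qual)] <- 0
  RNifti::writeNifti(nifti_with_pixdim(vals, voxel_mm),
                     paste0(prefix, ".nii.gz"), datatype = "float")
  RNifti::writeNifti(nifti_with_pixdim(qual, voxel_mm),
                     paste0(prefix, "_quality.nii.gz"), datatype = "float")
  RNifti::writeNifti(nifti_with_pixdim(map$mask + 0L, voxel_mm),
                     paste0(prefix, "_mask.nii.gz"), datatype = "int16")
  meta <- map$meta
  meta$options <- NULL
  write_sidecar(c(list(Kind = map$kind), meta), paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_param_map
#' @export
read_param_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(suffix) {
    a <- as.array(RNifti::readNifti(paste0(prefix, suffix, ".nii.gz")))
    matrix(as.numeric(a), nrow(a))
  }
  vals <- rd("")
  mask <- rd("_mask") > 0
  vals[!mask & vals == 0] <- NA_real_
  param_map(meta$Kind, vals, mask, rd("_quality"),
            meta = meta[setdiff(names(meta), "Kind")])
}
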
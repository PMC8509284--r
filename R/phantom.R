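## Digital kidney phantom: layered label map + ground-truth parameter fields.

#' Compartment codes used by the phantom label map
#'
#' Voxels are coded 0 = background, 1 = cortex, 2 = outer stripe of the outer
#' medulla (OSOM), 3 = inner stripe of the outer medulla (ISOM). Composite
#' regions are derived from these: the outer medulla (OM) is OSOM union ISOM,
#' the whole kidney is cortex union OM.
#'
#' @return A named integer vector of compartment codes.
#' @export
compartment_codes <- function() {
  c(background = 0L, cortex = 1L, osom = 2L, isom = 3L)
}

#' Default phantom geometry
#'
#' Concentric elliptical bands standing in for the coronal cross-section of a
#' mouse kidney: the cortex is the outermost tissue band, the ISOM the
#' innermost. Radii are fractions of the outer ellipse's normalized elliptical
#' radius, semi-axes are fractions of the grid dimensions.
#'
#' @param semi_axes_frac Semi-axes of the outer ellipse as fractions of the
#'   grid dimensions (long axis along x).
#' @param r_osom,r_isom Outer normalized radii of the OSOM and ISOM bands;
#'   the cortex occupies `(r_osom, 1]`, the OSOM `(r_isom, r_osom]`, the ISOM
#'   `[0, r_isom]`.
#' @return A list with the geometry parameters.
#' @export
kidney_geometry <- function(semi_axes_frac = c(0.44, 0.27),
                            r_osom = 0.75, r_isom = 0.55) {
  list(semi_axes_frac = semi_axes_frac, r_osom = r_osom, r_isom = r_isom)
}

#' Build a layered kidney label map
#'
#' @param shape Grid dimensions, at least 64 x 64.
#' @param geometry Geometry list, see [kidney_geometry()].
#' @param fov_mm In-plane field of view in mm (square); sets the voxel size.
#' @return An integer matrix of compartment codes (class `label_map`) with
#'   attributes `voxel_size_mm` and `geometry`.
#' @export
make_label_map <- function(shape = c(128, 128), geometry = kidney_geometry(),
                           fov_mm = 35) {
  if (length(shape) != 2 || any(shape < 64)) {
    abort("`shape` must be two integers, each >= 64.")
  }
  g <- geometry
  band_widths <- c(cortex = 1 - g$r_osom,
                   osom = g$r_osom - g$r_isom,
                   isom = g$r_isom)
  if (any(band_widths <= 0)) {
    abort(paste0("Degenerate geometry: all band widths must be positive ",
                 "(require 0 < r_isom < r_osom < 1)."))
  }
  nx <- shape[1]; ny <- shape[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  a <- g$semi_axes_frac[1] * nx
  b <- g$semi_axes_frac[2] * ny
  x <- (seq_len(nx) - cx) / a
  y <- (seq_len(ny) - cy) / b
  rho <- sqrt(outer(x^2, y^2, `+`))
  lab <- matrix(0L, nx, ny)
  lab[rho <= 1] <- 1L
  lab[rho <= g$r_osom] <- 2L
  lab[rho <= g$r_isom] <- 3L
  structure(lab,
            voxel_size_mm = c(fov_mm / nx, fov_mm / ny),
            geometry = g,
            class = c("label_map", "matrix", "array"))
}

#' Logical mask of a named region on a label map
#'
#' @param labels A `label_map`.
#' @param region One of `"cortex"`, `"osom"`, `"isom"`, `"om"`,
#'   `"whole_kidney"`, `"background"`.
#' @return A logical matrix.
#' @export
region_mask <- function(labels, region) {
  codes <- switch(region,
    cortex = 1L, osom = 2L, isom = 3L,
    om = c(2L, 3L), whole_kidney = c(1L, 2L, 3L), background = 0L,
    abort(sprintf("Unknown region '%s'.", region))
  )
  matrix(unclass(labels) %in% codes, nrow(labels), ncol(labels))
}

#' Group-level tissue parameter sets
#'
#' Per-compartment T1/T2/ADC ground truth for the three study arms of a mouse
#' kidney-transplant experiment: untouched healthy controls, isogenic grafts
#' (ischemic injury, no rejection) and allogenic grafts (chronic rejection),
#' the grafts at 3 or 6 weeks after transplantation. Allogenic grafts carry a
#' spatially patchy ADC heterogeneity model whose two-class mixture is
#' calibrated so the whole-kidney ADC dispersion matches the reported allograft
#' histogram SD and IQR (see [calibrate_mixture()]).
#'
#' ADC is expressed in 1e-3 mm^2/s throughout the package.
#'
#' @param group `"control"`, `"isogenic"` or `"allogenic"`.
#' @param timepoint `"w3"`, `"w6"` or (for controls) `"none"`.
#' @return A `tissue_params` object: a list with `group`, `timepoint`, a
#'   tibble `values` (compartment, t1_ms, t2_ms, adc) and a `heterogeneity`
#'   list (`enabled`, `adc_delta`, `within_patch_sd`, `patch_scale_vox`).
#' @export
tissue_parameters <- function(group = c("control", "isogenic", "allogenic"),
                              timepoint = c("none", "w3", "w6")) {
  group <- match.arg(group)
  timepoint <- match.arg(timepoint)
  if (group == "control") timepoint <- "none"
  if (group != "control" && timepoint == "none") {
    abort("Graft groups need a timepoint ('w3' or 'w6').")
  }
  key <- paste(group, timepoint, sep = ".")
  ## cortex / OSOM / ISOM rows; ADC carries one outer-medullary value for both
  ## OM stripes (the stripes are not separable on ADC maps).
  vals <- switch(key,
    control.none  = list(t1 = c(1304, 1283, 1808), t2 = c(44, 42, 54),
                         adc = c(1.61, 1.72, 1.72)),
    isogenic.w3   = list(t1 = c(1457, 1466, 1904), t2 = c(48, 48, 58),
                         adc = c(1.29, 1.43, 1.43)),
    isogenic.w6   = list(t1 = c(1393, 1399, 1859), t2 = c(45, 44, 55),
                         adc = c(1.40, 1.56, 1.56)),
    allogenic.w3  = list(t1 = c(1965, 2134, 2282), t2 = c(48, 57, 54),
                         adc = c(1.47, 1.47, 1.47)),
    allogenic.w6  = list(t1 = c(1899, 2036, 2031), t2 = c(44, 51, 50),
                         adc = c(1.44, 1.27, 1.27))
  )
  het <- list(enabled = FALSE, adc_delta = 0, within_patch_sd = 0,
              patch_scale_vox = 6)
  if (group == "allogenic") {
    target <- if (timepoint == "w3") c(sd = 0.33, iqr = 0.45)
              else c(sd = 0.32, iqr = 0.43)
    cal <- calibrate_mixture(target[["sd"]], target[["iqr"]])
    het <- list(enabled = TRUE, adc_delta = cal[["adc_delta"]],
                within_patch_sd = cal[["within_patch_sd"]],
                patch_scale_vox = 6)
  }
  out <- list(
    group = group, timepoint = timepoint,
    values = tibble(compartment = c("cortex", "osom", "isom"),
                    t1_ms = vals$t1, t2_ms = vals$t2, adc = vals$adc),
    heterogeneity = het
  )
  class(out) <- "tissue_params"
  validate_tissue_params(out)
  out
}

validate_tissue_params <- function(p) {
  v <- p$values
  if (any(v$t1_ms <= 0) || any(v$t2_ms <= 0) || any(v$adc <= 0)) {
    abort("All tissue parameter values must be strictly positive.")
  }
  if (any(v$t1_ms <= v$t2_ms)) {
    abort("t1_ms must exceed t2_ms in every compartment.")
  }
  if (isTRUE(p$heterogeneity$enabled) && p$group != "allogenic") {
    abort("Patchy heterogeneity is modelled for allogenic grafts only.")
  }
  invisible(p)
}

#' Population SD and IQR of a balanced two-class Gaussian mixture
#'
#' For voxel values drawn as a 50/50 mixture of N(mu - delta, sigma^2) and
#' N(mu + delta, sigma^2): the population SD is `sqrt(delta^2 + sigma^2)`
#' and the IQR follows from numerically inverting the mixture CDF.
#'
#' @param delta Half-offset between the two class means.
#' @param sigma Within-class standard deviation.
#' @return `mixture_sd()`/`mixture_iqr()` return a single number.
#' @export
mixture_sd <- function(delta, sigma) sqrt(delta^2 + sigma^2)

#' @rdname mixture_sd
#' @export
mixture_iqr <- function(delta, sigma) {
  if (sigma <= 0) return(2 * abs(delta))
  q <- function(p) {
    uniroot(function(x) {
      0.5 * stats::pnorm((x + delta) / sigma) +
        0.5 * stats::pnorm((x - delta) / sigma) - p
    }, c(-abs(delta) - 9 * sigma, abs(delta) + 9 * sigma), tol = 1e-12)$root
  }
  q(0.75) - q(0.25)
}

#' Calibrate the heterogeneity mixture offset from a target SD
#'
#' Inverts the balanced-mixture closed form: given a target whole-kidney ADC
#' SD and the within-class SD, the class half-offset is
#' `delta = sqrt(target_sd^2 - within_sd^2)`.
#'
#' @param target_sd Target population SD (1e-3 mm^2/s).
#' @param within_sd Within-class SD (1e-3 mm^2/s), must not exceed `target_sd`.
#' @return The class half-offset `delta` (1e-3 mm^2/s).
#' @export
calibrate_heterogeneity <- function(target_sd, within_sd) {
  if (within_sd > target_sd) abort("within_sd must not exceed target_sd.")
  sqrt(target_sd^2 - within_sd^2)
}

#' Jointly calibrate the mixture to a target SD and IQR
#'
#' The balanced two-class mixture has one shape degree of freedom once its SD
#' is fixed: the split between class separation and within-class spread. The
#' reported IQR/SD ratio pins it down (a pure Gaussian has IQR = 1.349 SD; a
#' hard two-point mixture has IQR = 2 SD). If the target IQR is at or below
#' the Gaussian ratio the mixture degenerates to `delta = 0` (pure Gaussian
#' texture).
#'
#' @param target_sd,target_iqr Target population SD and IQR (1e-3 mm^2/s).
#' @return Named numeric vector with `adc_delta` and `within_patch_sd`.
#' @export
calibrate_mixture <- function(target_sd, target_iqr) {
  stopifnot(target_sd > 0, target_iqr > 0)
  gauss_iqr <- 2 * stats::qnorm(0.75) * target_sd
  if (target_iqr <= gauss_iqr) {
    return(c(adc_delta = 0, within_patch_sd = target_sd))
  }
  if (target_iqr >= 2 * target_sd) {
    return(c(adc_delta = target_sd, within_patch_sd = 0))
  }
  f <- function(d) mixture_iqr(d, sqrt(target_sd^2 - d^2)) - target_iqr
  d <- uniroot(f, c(1e-4 * target_sd, (1 - 1e-7) * target_sd), tol = 1e-10)$root
  c(adc_delta = d, within_patch_sd = sqrt(target_sd^2 - d^2))
}

## Separable Gaussian smoothing by dense kernel matrices; rows renormalized so
## edge voxels keep zero mean under white-noise input.
gaussian_smooth <- function(m, sd_vox) {
  if (sd_vox <= 0) return(m)
  smooth_mat <- function(n) {
    k <- outer(seq_len(n), seq_len(n), function(i, j) {
      stats::dnorm(i - j, sd = sd_vox)
    })
    k / rowSums(k)
  }
  smooth_mat(nrow(m)) %*% m %*% t(smooth_mat(ncol(m)))
}

#' Generate a patchy two-class ADC heterogeneity field
#'
#' Tissue voxels are assigned to one of two patch classes by thresholding a
#' smoothed Gaussian random field at zero (equal expected class weights); the
#' class means are the compartment base value plus/minus `adc_delta`, with
#' additional within-class Gaussian variation. Values are clipped below at
#' 0.1e-3 mm^2/s. Background voxels are 0.
#'
#' @param labels A `label_map`.
#' @param adc_base Named per-compartment base ADC (`cortex`, `osom`, `isom`),
#'   1e-3 mm^2/s.
#' @param settings Heterogeneity settings list (`enabled`, `adc_delta`,
#'   `within_patch_sd`, `patch_scale_vox`).
#' @param seed Integer seed; the field is reproducible given the seed.
#' @return A numeric matrix of truth ADC values.
#' @export
make_heterogeneity_field <- function(labels, adc_base, settings, seed) {
  if (!isTRUE(settings$enabled)) {
    abort("make_heterogeneity_field() requires settings$enabled = TRUE.")
  }
  if (settings$adc_delta < 0) abort("adc_delta must be non-negative.")
  if (settings$within_patch_sd < 0) abort("within_patch_sd must be non-negative.")
  lab <- unclass(labels)
  tissue <- lab > 0L
  base <- matrix(0, nrow(lab), ncol(lab))
  for (comp in c("cortex", "osom", "isom")) {
    base[lab == compartment_codes()[[comp]]] <- adc_base[[comp]]
  }
  withr::with_seed(seed, {
    field <- gaussian_smooth(matrix(rnorm(length(lab)), nrow(lab)),
                             settings$patch_scale_vox)
    cls <- ifelse(field > 0, 1, -1)
    noise <- matrix(rnorm(length(lab), sd = settings$within_patch_sd), nrow(lab))
    out <- base + cls * settings$adc_delta + noise
  })
  out <- pmax(out, 0.1)
  out[!tissue] <- 0
  out
}

#' Build a digital kidney phantom
#'
#' Combines the layered label map with per-compartment ground-truth T1/T2/ADC
#' fields. Control and isogenic phantoms are piecewise constant; allogenic
#' phantoms get the patchy ADC heterogeneity field.
#'
#' @param params A `tissue_params` object, see [tissue_parameters()].
#' @param shape Grid dimensions.
#' @param seed Integer seed (drives the heterogeneity field only).
#' @param geometry Geometry list, see [kidney_geometry()].
#' @return A `kidney_phantom` object: list with `label_map`, `truth_t1`,
#'   `truth_t2`, `truth_adc`, `voxel_size_mm`, `params`, `seed`.
#' @export
make_phantom <- function(params, shape = c(128, 128), seed = 1,
                         geometry = kidney_geometry()) {
  validate_tissue_params(params)
  labels <- make_label_map(shape, geometry)
  lab <- unclass(labels)
  fill <- function(col) {
    m <- matrix(0, nrow(lab), ncol(lab))
    for (i in 1:3) {
      m[lab == i] <- params$values[[col]][i]
    }
    m
  }
  truth_t1 <- fill("t1_ms")
  truth_t2 <- fill("t2_ms")
  if (isTRUE(params$heterogeneity$enabled)) {
    adc_base <- setNames(as.list(params$values$adc), params$values$compartment)
    truth_adc <- make_heterogeneity_field(labels, adc_base,
                                          params$heterogeneity, seed)
  } else {
    truth_adc <- fill("adc")
  }
  structure(
    list(label_map = labels, truth_t1 = truth_t1, truth_t2 = truth_t2,
         truth_adc = truth_adc,
         voxel_size_mm = attr(labels, "voxel_size_mm"),
         params = params, seed = as.integer(seed)),
    class = "kidney_phantom"
  )
}

#' @export
print.kidney_phantom <- function(x, ...) {
  cat(sprintf("<kidney_phantom> %s/%s, %d x %d, seed %d\n",
              x$params$group, x$params$timepoint,
              nrow(x$label_map), ncol(x$label_map), x$seed))
  n <- table(factor(unclass(x$label_map), levels = 0:3,
                    labels = names(compartment_codes())))
  print(n)
  invisible(x)
}
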
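## Voxel-wise parameter estimation: T1 (magnitude IR), T2 and ADC.

#' Fitting options
#'
#' @param r2_floor Minimum coefficient of determination for a voxel to enter
#'   the validity mask.
#' @param t1_bounds,t2_bounds,adc_bounds Plausibility bounds (ms, ms,
#'   1e-3 mm^2/s); voxels outside are masked out.
#' @param t1_search T1 search interval for the variable-projection fit (ms).
#' @param grid_n Number of log-spaced T1 grid points in the coarse search.
#' @param refine_iter Golden-section iterations in the per-voxel refinement.
#' @param min_signal_frac Voxels whose maximum signal falls below this
#'   fraction of the robust image maximum are not fitted (background).
#' @param refine `"none"` (weighted log-linear only) or `"nls"` (nonlinear
#'   least-squares refinement of the T2/ADC exponential fit).
#' @return A named list of options.
#' @export
fit_options <- function(r2_floor = 0.9,
                        t1_bounds = c(200, 5000),
                        t2_bounds = c(5, 500),
                        adc_bounds = c(0.05, 4),
                        t1_search = c(100, 10000),
                        grid_n = 40,
                        refine_iter = 70,
                        min_signal_frac = 0.2,
                        refine = c("none", "nls")) {
  list(r2_floor = r2_floor, t1_bounds = t1_bounds, t2_bounds = t2_bounds,
       adc_bounds = adc_bounds, t1_search = t1_search, grid_n = grid_n,
       refine_iter = refine_iter, min_signal_frac = min_signal_frac,
       refine = match.arg(refine))
}

#' Construct a parameter map
#'
#' @param kind `"T1_ms"`, `"T2_ms"` or `"ADC_e3mm2s"`.
#' @param values Numeric matrix of fitted values (NA where not fitted).
#' @param mask Logical matrix: fit attempted, converged and plausible.
#' @param quality Numeric matrix of per-voxel R^2.
#' @param meta Provenance list.
#' @return A `param_map` object.
#' @export
param_map <- function(kind, values, mask, quality, meta = list()) {
  kind <- match.arg(kind, c("T1_ms", "T2_ms", "ADC_e3mm2s"))
  stopifnot(identical(dim(values), dim(mask)),
            identical(dim(values), dim(quality)))
  structure(list(kind = kind, values = values, mask = mask,
                 quality = quality, meta = meta),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<param_map> %s: %d x %d, %d valid voxels, median %.3g\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$mask),
              if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}

## Reshape a series into a (n_meas x n_voxel) matrix for selected voxels.
series_voxels <- function(series, fit_mask, min_signal_frac) {
  d <- dim(series$data)
  n <- d[4]
  flat <- matrix(series$data, d[1] * d[2] * d[3], n)
  vmax <- flat[, 1]
  for (k in 2:n) vmax <- pmax(vmax, flat[, k])
  if (is.null(fit_mask)) {
    thr <- min_signal_frac * quantile(vmax, 0.99, names = FALSE)
    sel <- vmax > thr
  } else {
    stopifnot(identical(dim(fit_mask), d[1:2]))
    sel <- as.vector(fit_mask) & vmax > 0
  }
  list(Y = t(flat[sel, , drop = FALSE]), idx = which(sel), dims = d[1:2])
}

## Per-voxel linear LS of signed data on [1, exp(-ti/T1)] for a vector of
## per-voxel T1 values; returns RSS and coefficients (variable projection).
t1_proj <- function(S, ti, t1v, Sy, Syy, n) {
  X <- exp(-outer(ti, 1 / t1v))
  Sx <- .colSums(X, n, length(t1v))
  Sxx <- .colSums(X * X, n, length(t1v))
  Sxy <- .colSums(S * X, n, length(t1v))
  den <- n * Sxx - Sx^2
  b1 <- (n * Sxy - Sx * Sy) / den
  b0 <- (Sy - b1 * Sx) / n
  list(rss = pmax(Syy - b0 * Sy - b1 * Sxy, 0), b0 = b0, b1 = b1)
}

#' Fit a voxel-wise T1 map from a magnitude inversion-recovery series
#'
#' Per voxel, nonlinear least squares of the three-parameter magnitude model
#' `|a - b * exp(-ti/T1)|`. Polarity of the pre-null measurements is restored
#' by exhaustive search over candidate null positions: for every candidate the
#' sign-restored data are fitted and the candidate with the smallest residual
#' wins. For fixed T1 the model is linear in (a, b), so the fit reduces to a
#' one-dimensional search over T1 (coarse log-spaced grid followed by
#' golden-section refinement), which is deterministic and needs no starting
#' values. The reported T1 is the exponential rate constant itself (single-shot
#' readout, no Look-Locker correction).
#'
#' @param series An `acq_series` of kind `"IR_T1"` with at least 4 TIs.
#' @param fit_mask Optional logical matrix restricting which voxels are
#'   fitted (e.g. a compact ROI); by default all voxels above the background
#'   signal threshold are fitted.
#' @param options See [fit_options()].
#' @return A `param_map` of kind `"T1_ms"`.
#' @export
fit_t1_ir <- function(series, fit_mask = NULL, options = fit_options()) {
  stopifnot(inherits(series, "acq_series"))
  if (series$kind != "IR_T1") abort("fit_t1_ir() needs an IR_T1 series.")
  ti <- series$param_axis
  n <- length(ti)
  if (n < 4) abort("At least 4 inversion times are required.")
  sv <- series_voxels(series, fit_mask, options$min_signal_frac)
  Y <- sv$Y
  V <- ncol(Y)
  vals <- matrix(NA_real_, sv$dims[1], sv$dims[2])
  msk <- matrix(FALSE, sv$dims[1], sv$dims[2])
  qual <- matrix(NA_real_, sv$dims[1], sv$dims[2])
  if (V > 0) {
    Syy <- .colSums(Y * Y, n, V)
    grid <- exp(seq(log(options$t1_search[1]), log(options$t1_search[2]),
                    length.out = options$grid_n))
    best_rss <- rep(Inf, V)
    best_j <- integer(V)
    best_g <- integer(V)
    for (j in 0:(n - 1)) {
      S <- Y
      if (j > 0) S[seq_len(j), ] <- -S[seq_len(j), , drop = FALSE]
      Sy <- .colSums(S, n, V)
      for (g in seq_along(grid)) {
        x <- exp(-ti / grid[g])
        Sx <- sum(x); Sxx <- sum(x * x)
        Sxy <- as.vector(crossprod(x, S))
        b1 <- (n * Sxy - Sx * Sy) / (n * Sxx - Sx^2)
        b0 <- (Sy - b1 * Sx) / n
        rss <- Syy - b0 * Sy - b1 * Sxy
        upd <- rss < best_rss
        if (any(upd)) {
          best_rss[upd] <- rss[upd]
          best_j[upd] <- j
          best_g[upd] <- g
        }
      }
    }
    ## sign-restore each voxel at its winning candidate, then refine T1
    rowidx <- matrix(seq_len(n), n, V)
    S <- Y * ifelse(rowidx <= rep(best_j, each = n), -1, 1)
    Sy <- .colSums(S, n, V)
    lo <- grid[pmax(best_g - 1L, 1L)]
    hi <- grid[pmin(best_g + 1L, length(grid))]
    phi <- (sqrt(5) - 1) / 2
    for (it in seq_len(options$refine_iter)) {
      m1 <- hi - phi * (hi - lo)
      m2 <- lo + phi * (hi - lo)
      f1 <- t1_proj(S, ti, m1, Sy, Syy, n)$rss
      f2 <- t1_proj(S, ti, m2, Sy, Syy, n)$rss
      left <- f1 < f2
      hi <- ifelse(left, m2, hi)
      lo <- ifelse(left, lo, m1)
    }
    t1 <- (lo + hi) / 2
    fin <- t1_proj(S, ti, t1, Sy, Syy, n)
    tss <- Syy - Sy^2 / n
    r2 <- 1 - fin$rss / tss
    a <- fin$b0
    bcoef <- -fin$b1
    ok <- is.finite(t1) & is.finite(r2) &
      t1 > options$t1_bounds[1] & t1 < options$t1_bounds[2] &
      a > 0 & bcoef > 0 & r2 >= options$r2_floor
    ok <- !is.na(ok) & ok
    vals[sv$idx] <- t1
    qual[sv$idx] <- r2
    msk[sv$idx] <- ok
  }
  param_map("T1_ms", vals, msk, qual,
            meta = list(model = "magnitude_ir_varpro", ti_ms = ti,
                        tr_ms = series$tr_ms, snr = series$snr,
                        series_seed = series$seed, options = options))
}

## Weighted log-linear exponential fit: ln y = intercept + slope * x with
## weights y^2 (non-positive samples excluded); R^2 on the linear scale.
wlls_exp <- function(Y, x) {
  n <- nrow(Y); V <- ncol(Y)
  pos <- Y > 0
  W <- (Y * Y) * pos
  L <- log(ifelse(pos, Y, 1))
  Sw <- .colSums(W, n, V)
  Swx <- .colSums(W * x, n, V)
  Swxx <- .colSums(W * x * x, n, V)
  Swy <- .colSums(W * L, n, V)
  Swxy <- .colSums(W * x * L, n, V)
  den <- Sw * Swxx - Swx^2
  slope <- (Sw * Swxy - Swx * Swy) / den
  intercept <- (Swy - slope * Swx) / Sw
  Yhat <- exp(matrix(intercept, n, V, byrow = TRUE) + outer(x, slope))
  rss <- .colSums((Y - Yhat)^2, n, V)
  Sy <- .colSums(Y, n, V)
  tss <- .colSums(Y * Y, n, V) - Sy^2 / n
  list(slope = slope, intercept = intercept, r2 = 1 - rss / tss,
       usable = .colSums(pos, n, V))
}

## Golden-section NLS refinement of y = m0 * exp(-x * rate) on the linear
## scale, amplitude profiled out in closed form.
nls_exp_refine <- function(Y, x, rate0, iter = 60) {
  n <- nrow(Y); V <- ncol(Y)
  rss_at <- function(r) {
    U <- exp(-outer(x, r))
    m0 <- .colSums(U * Y, n, V) / .colSums(U * U, n, V)
    .colSums((Y - U * matrix(m0, n, V, byrow = TRUE))^2, n, V)
  }
  lo <- rate0 / 3
  hi <- rate0 * 3
  phi <- (sqrt(5) - 1) / 2
  for (it in seq_len(iter)) {
    m1 <- hi - phi * (hi - lo)
    m2 <- lo + phi * (hi - lo)
    left <- rss_at(m1) < rss_at(m2)
    hi <- ifelse(left, m2, hi)
    lo <- ifelse(left, lo, m1)
  }
  (lo + hi) / 2
}

#' Fit a voxel-wise T2 map from a multi-echo series
#'
#' Two-parameter mono-exponential fit `m0 * exp(-te/T2)`. The primary
#' estimator is weighted log-linear least squares with squared-signal weights
#' (exact on noiseless data, deterministic, no starting values); an optional
#' nonlinear refinement on the linear scale is available via
#' `fit_options(refine = "nls")`. Non-positive signals are excluded from the
#' log fit; voxels with fewer than 3 usable echoes are masked out. Values are
#' clipped at the upper T2 bound and such voxels are masked.
#'
#' @inheritParams fit_t1_ir
#' @param series An `acq_series` of kind `"ME_T2"` with at least 3 echoes.
#' @return A `param_map` of kind `"T2_ms"`.
#' @export
fit_t2 <- function(series, fit_mask = NULL, options = fit_options()) {
  stopifnot(inherits(series, "acq_series"))
  if (series$kind != "ME_T2") abort("fit_t2() needs an ME_T2 series.")
  te <- series$param_axis
  if (length(te) < 3) abort("At least 3 echo times are required.")
  fit_exp_map(series, te, "T2_ms", options, fit_mask,
              value_fun = function(slope) 1 / pmax(-slope, 1e-12),
              bounds = options$t2_bounds, min_usable = 3)
}

#' Fit a voxel-wise ADC map from a diffusion-weighted series
#'
#' Mono-exponential fit `s0 * exp(-b * ADC)` over all b-values by weighted
#' log-linear least squares (optional nonlinear refinement as for [fit_t2()]).
#' ADC is reported in 1e-3 mm^2/s. The series must include b = 0. Voxels whose
#' ADC falls outside the plausibility bounds (including a minimum-ADC QC
#' bound) keep their fitted value but are masked out.
#'
#' @inheritParams fit_t1_ir
#' @param series An `acq_series` of kind `"DWI"` including b = 0.
#' @return A `param_map` of kind `"ADC_e3mm2s"`.
#' @export
fit_adc <- function(series, fit_mask = NULL, options = fit_options()) {
  stopifnot(inherits(series, "acq_series"))
  if (series$kind != "DWI") abort("fit_adc() needs a DWI series.")
  b <- series$param_axis
  if (length(b) < 2 || b[1] != 0) {
    abort("DWI series must have at least 2 b-values including b = 0.")
  }
  fit_exp_map(series, b, "ADC_e3mm2s", options, fit_mask,
              value_fun = function(slope) -slope * 1000,
              bounds = options$adc_bounds, min_usable = 2)
}

fit_exp_map <- function(series, x, kind, options, fit_mask, value_fun,
                        bounds, min_usable) {
  sv <- series_voxels(series, fit_mask, options$min_signal_frac)
  Y <- sv$Y
  vals <- matrix(NA_real_, sv$dims[1], sv$dims[2])
  msk <- matrix(FALSE, sv$dims[1], sv$dims[2])
  qual <- matrix(NA_real_, sv$dims[1], sv$dims[2])
  if (ncol(Y) > 0) {
    fit <- wlls_exp(Y, x)
    slope <- fit$slope
    if (options$refine == "nls") {
      ok0 <- is.finite(slope) & slope < 0
      if (any(ok0)) {
        r <- nls_exp_refine(Y[, ok0, drop = FALSE], x, -slope[ok0])
        slope[ok0] <- -r
        ## recompute linear-scale R^2 at the refined rate
        U <- exp(outer(x, slope[ok0]))
        n <- nrow(Y); Vk <- sum(ok0)
        Yk <- Y[, ok0, drop = FALSE]
        m0 <- .colSums(U * Yk, n, Vk) / .colSums(U * U, n, Vk)
        rss <- .colSums((Yk - U * matrix(m0, n, Vk, byrow = TRUE))^2, n, Vk)
        Sy <- .colSums(Yk, n, Vk)
        tss <- .colSums(Yk * Yk, n, Vk) - Sy^2 / n
        fit$r2[ok0] <- 1 - rss / tss
      }
    }
    v <- value_fun(slope)
    at_upper <- is.finite(v) & v >= bounds[2]
    v[at_upper] <- bounds[2]
    ok <- is.finite(v) & fit$usable >= min_usable &
      v > bounds[1] & v < bounds[2] & fit$r2 >= options$r2_floor
    ok <- !is.na(ok) & ok
    vals[sv$idx] <- v
    qual[sv$idx] <- fit$r2
    msk[sv$idx] <- ok
  }
  param_map(kind, vals, msk, qual,
            meta = list(model = paste0("wlls", if (options$refine == "nls")
                        "+nls" else ""),
                        axis = x, snr = series$snr,
                        series_seed = series$seed, options = options))
}
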
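## Forward MRI signal models and magnitude (Rician) noise.

#' MRI signal models
#'
#' Closed-form magnitude signals of the three acquisitions:
#' \describe{
#'   \item{`signal_ir()`}{Inversion recovery with a non-selective inversion
#'     pulse and full-relaxation TR term:
#'     `|m0 * (1 - (1 + inv_eff) * exp(-ti/t1) + exp(-tr/t1))|`.}
#'   \item{`signal_t2()`}{Mono-exponential spin-echo decay
#'     `m0 * exp(-te/t2)`, no offset term.}
#'   \item{`signal_dwi()`}{Mono-exponential diffusion decay
#'     `s0 * exp(-b * adc * 1e-3)` with `adc` in 1e-3 mm^2/s and `b`
#'     in s/mm^2.}
#' }
#'
#' @param t1_ms,t2_ms Relaxation times in ms, strictly positive.
#' @param ti_ms,te_ms Inversion/echo times in ms.
#' @param tr_ms Repetition time in ms.
#' @param m0,s0 Equilibrium signal (arbitrary units).
#' @param inv_eff Inversion efficiency in (0, 1]; 1 is an ideal pulse.
#' @param adc Apparent diffusion coefficient in 1e-3 mm^2/s.
#' @param b Diffusion weighting in s/mm^2.
#' @return Numeric vector of non-negative magnitude signals.
#' @export
signal_ir <- function(t1_ms, ti_ms, tr_ms = 18000, m0 = 1, inv_eff = 1) {
  if (any(t1_ms <= 0)) abort("t1_ms must be strictly positive.")
  if (inv_eff <= 0 || inv_eff > 1) abort("inv_eff must be in (0, 1].")
  abs(m0 * (1 - (1 + inv_eff) * exp(-ti_ms / t1_ms) + exp(-tr_ms / t1_ms)))
}

#' @rdname signal_ir
#' @export
signal_t2 <- function(t2_ms, te_ms, m0 = 1) {
  if (any(t2_ms <= 0)) abort("t2_ms must be strictly positive.")
  m0 * exp(-te_ms / t2_ms)
}

#' @rdname signal_ir
#' @export
signal_dwi <- function(adc, b, s0 = 1) {
  if (any(adc < 0)) abort("adc must be non-negative.")
  s0 * exp(-b * adc * 1e-3)
}

#' Default acquisition protocol
#'
#' The three-sequence protocol of the study: a 13-TI single-shot inversion
#' recovery series (TR 18000 ms), a 7-echo multi-echo series (TE 11-77 ms in
#' steps of 11 ms) and a 7-b-value DWI series (0-800 s/mm^2). SNR is defined
#' at the equilibrium signal `s0_scale`.
#'
#' @param ti_ms,te_ms,b_s_mm2 Acquisition parameter axes.
#' @param tr_ms IR repetition time in ms.
#' @param snr Signal-to-noise ratio at `s0_scale`; `Inf` disables noise.
#' @param s0_scale Equilibrium signal scale.
#' @param inv_eff Inversion efficiency.
#' @return A named list.
#' @export
default_protocol <- function(
    ti_ms = c(30, 100, 200, 300, 500, 700, 1000, 1200, 1500, 2000, 3000,
              5000, 8000),
    te_ms = seq(11, 77, by = 11),
    b_s_mm2 = c(0, 100, 200, 300, 400, 600, 800),
    tr_ms = 18000, snr = 40, s0_scale = 1, inv_eff = 1) {
  list(ti_ms = ti_ms, te_ms = te_ms, b_s_mm2 = b_s_mm2, tr_ms = tr_ms,
       snr = snr, s0_scale = s0_scale, inv_eff = inv_eff)
}

#' Construct an acquisition series
#'
#' A 4D magnitude image stack (x, y, slice = 1, measurement) plus its
#' acquisition-parameter axis and noise/scale metadata.
#'
#' @param kind `"IR_T1"`, `"ME_T2"` or `"DWI"`.
#' @param data 4D array, non-negative, last dimension matching `param_axis`.
#' @param param_axis Strictly increasing vector of TI (ms), TE (ms) or
#'   b (s/mm^2) values.
#' @param tr_ms Repetition time (IR series).
#' @param s0_scale Equilibrium signal scale.
#' @param snr SNR at `s0_scale` (`Inf` = noiseless).
#' @param seed Noise seed (NA if noiseless).
#' @return An `acq_series` object.
#' @export
acq_series <- function(kind, data, param_axis, tr_ms = NA_real_,
                       s0_scale = 1, snr = Inf, seed = NA_integer_) {
  kind <- match.arg(kind, c("IR_T1", "ME_T2", "DWI"))
  if (length(dim(data)) != 4) abort("`data` must be a 4D array.")
  if (dim(data)[4] != length(param_axis)) {
    abort("Length of `param_axis` must match the 4th dimension of `data`.")
  }
  if (is.unsorted(param_axis, strictly = TRUE)) {
    abort("`param_axis` must be strictly increasing.")
  }
  if (any(data < 0)) abort("Magnitude data must be non-negative.")
  structure(list(kind = kind, data = data, param_axis = param_axis,
                 tr_ms = tr_ms, s0_scale = s0_scale, snr = snr,
                 seed = seed),
            class = "acq_series")
}

#' @export
print.acq_series <- function(x, ...) {
  cat(sprintf("<acq_series> %s: %s, %d measurements, snr %s\n", x$kind,
              paste(dim(x$data)[1:3], collapse = " x "),
              length(x$param_axis),
              if (is.infinite(x$snr)) "Inf (noiseless)" else format(x$snr)))
  invisible(x)
}

#' Add Rician magnitude noise to a series
#'
#' Each voxel value s is replaced by `sqrt((s + n1)^2 + n2^2)` with
#' independent `n1, n2 ~ N(0, sigma^2)` and `sigma = s0_scale / snr` -- the
#' noise model of magnitude-reconstructed MR images.
#'
#' @param series An `acq_series`.
#' @param snr SNR at `s0_scale`; `Inf` returns the input unchanged.
#' @param seed Integer seed; output is reproducible given the seed.
#' @return A noisy `acq_series`.
#' @export
add_rician_noise <- function(series, snr, seed) {
  stopifnot(inherits(series, "acq_series"))
  if (snr <= 0) abort("snr must be positive.")
  if (is.infinite(snr)) return(series)
  sigma <- series$s0_scale / snr
  d <- series$data
  withr::with_seed(seed, {
    n1 <- array(rnorm(length(d), sd = sigma), dim = dim(d))
    n2 <- array(rnorm(length(d), sd = sigma), dim = dim(d))
  })
  series$data <- sqrt((d + n1)^2 + n2^2)
  series$snr <- snr
  series$seed <- as.integer(seed)
  series
}

## Evaluate a per-voxel decay model over a parameter axis into a 4D stack.
build_stack <- function(value_grid, axis, fun) {
  nx <- nrow(value_grid); ny <- ncol(value_grid)
  out <- array(0, dim = c(nx, ny, 1, length(axis)))
  tissue <- value_grid > 0
  v <- value_grid[tissue]
  for (k in seq_along(axis)) {
    plane <- matrix(0, nx, ny)
    plane[tissue] <- fun(v, axis[k])
    out[, , 1, k] <- plane
  }
  out
}

#' Forward-simulate the three acquisitions from a phantom
#'
#' Evaluates the closed-form signal models on the phantom truth grids and adds
#' Rician noise. Background voxels have zero clean signal. The three series
#' get independent noise streams derived from `seed`.
#'
#' @param phantom A `kidney_phantom`.
#' @param protocol Protocol list, see [default_protocol()].
#' @param seed Integer master seed for the subject.
#' @return A named list of three `acq_series`: `ir`, `me`, `dwi`.
#' @export
synthesize_subject <- function(phantom, protocol = default_protocol(),
                               seed = 1) {
  stopifnot(inherits(phantom, "kidney_phantom"))
  p <- protocol
  m0 <- p$s0_scale
  ir <- acq_series("IR_T1",
    build_stack(phantom$truth_t1, p$ti_ms,
                function(t1, ti) signal_ir(t1, ti, p$tr_ms, m0, p$inv_eff)),
    p$ti_ms, tr_ms = p$tr_ms, s0_scale = m0)
  me <- acq_series("ME_T2",
    build_stack(phantom$truth_t2, p$te_ms,
                function(t2, te) signal_t2(t2, te, m0)),
    p$te_ms, s0_scale = m0)
  dwi <- acq_series("DWI",
    build_stack(phantom$truth_adc, p$b_s_mm2,
                function(adc, b) signal_dwi(adc, b, m0)),
    p$b_s_mm2, s0_scale = m0)
  if (is.finite(p$snr)) {
    seed <- as.integer(seed)
    ir <- add_rician_noise(ir, p$snr, seed)
    me <- add_rician_noise(me, p$snr, seed + 1L)
    dwi <- add_rician_noise(dwi, p$snr, seed + 2L)
  }
  list(ir = ir, me = me, dwi = dwi)
}
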
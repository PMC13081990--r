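# Image preprocessing and DAPI-based drift registration.
#
# The fixed chain is background_correct -> gamma_adjust -> lowpass, applied
# per channel, all planewise in (y, x): the voxels are strongly anisotropic
# (1000 nm z vs 103 nm x/y), so an isotropic 3D sigma would be ill-defined.

#' Preprocessing parameter defaults
#'
#' @return list with `bg_sigma` (3 px), `gamma` (1.6), `lowpass_sigma` (1 px),
#'   `lowpass_kernel` (3 px), `normalize_percentile` (99.9).
#' @export
preprocess_params <- function() {
  list(bg_sigma = 3, gamma = 1.6, lowpass_sigma = 1, lowpass_kernel = 3,
       normalize_percentile = 99.9)
}

#' Gaussian background subtraction
#'
#' Per z-plane, a wide Gaussian blur (sigma = `bg_sigma`) estimates the local
#' background, which is subtracted from the plane; negative values are
#' clipped to zero.
#'
#' @param stack an `image_stack`.
#' @param bg_sigma blur sigma in pixels (default 3).
#' @param radius kernel truncation radius in pixels; default `3 * bg_sigma`.
#' @return background-corrected `image_stack`.
#' @export
background_correct <- function(stack, bg_sigma = 3,
                               radius = ceiling(3 * bg_sigma)) {
  stopifnot(inherits(stack, "image_stack"), bg_sigma > 0)
  bg <- gauss_blur_planes(stack$data, bg_sigma, radius)
  out <- stack$data - bg
  out[out < 0] <- 0
  stack$data <- out
  stack
}

#' Gamma contrast adjustment
#'
#' Intensities are scaled to `[0, 1]` by the stated percentile (values above
#' it clip to 1), raised to the power `gamma`, then rescaled to the original
#' maximum. `gamma > 1` suppresses residual low background after
#' subtraction; set `inverse = TRUE` for the `v^(1/gamma)` convention.
#'
#' @param stack an `image_stack` (non-negative).
#' @param gamma exponent (default 1.6).
#' @param normalize_percentile percentile (0-100) used as the normalization
#'   ceiling; default 99.9, robust to hot pixels.
#' @param inverse apply `v^(1/gamma)` instead of `v^gamma`.
#' @return adjusted `image_stack`; an all-zero stack is returned unchanged.
#' @export
gamma_adjust <- function(stack, gamma = 1.6, normalize_percentile = 99.9,
                         inverse = FALSE) {
  stopifnot(inherits(stack, "image_stack"), gamma > 0)
  mx <- max(stack$data)
  if (mx == 0) return(stack)
  ceiling_val <- stats::quantile(stack$data, normalize_percentile / 100,
                                 names = FALSE)
  if (ceiling_val == 0) ceiling_val <- mx
  v <- pmin(stack$data / ceiling_val, 1)
  g <- if (inverse) 1 / gamma else gamma
  stack$data <- array(v^g * mx, dim(stack$data))
  stack
}

#' Low-pass Gaussian noise filter
#'
#' Per-plane truncated Gaussian convolution; the kernel is normalized, so
#' mean intensity is preserved away from borders.
#'
#' @param stack an `image_stack`.
#' @param sigma Gaussian sigma in pixels (default 1).
#' @param kernel odd kernel size in pixels (default 3).
#' @return smoothed `image_stack`.
#' @export
lowpass <- function(stack, sigma = 1, kernel = 3) {
  stopifnot(inherits(stack, "image_stack"))
  if (kernel %% 2 != 1) stop("'kernel' must be odd")
  stack$data <- gauss_blur_planes(stack$data, sigma, (kernel - 1L) %/% 2L)
  stack
}

#' Run the full preprocessing chain
#'
#' `background_correct` then `gamma_adjust` then `lowpass`, with the
#' defaults from [preprocess_params()].
#'
#' @param stack an `image_stack`.
#' @param params list as returned by [preprocess_params()].
#' @return preprocessed `image_stack`.
#' @export
preprocess_stack <- function(stack, params = preprocess_params()) {
  stack <- background_correct(stack, params$bg_sigma)
  stack <- gamma_adjust(stack, params$gamma, params$normalize_percentile)
  lowpass(stack, params$lowpass_sigma, params$lowpass_kernel)
}

#' Maximum-intensity projection along z
#'
#' @param stack an `image_stack`.
#' @return 2D matrix `(y, x)` with `out[y, x] = max over z`.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  apply(stack$data, c(2, 3), max)
}

#' Measure round-to-round drift by phase correlation
#'
#' Both stacks are max-projected along z and the translational offset is
#' taken as the argmax of the inverse-transformed normalized cross-power
#' spectrum (integer pixels, no subpixel upsampling). The returned
#' `(dy, dx)` is the measured drift of the moving image relative to the
#' reference: `register_round(shift(I, d), I) = d`. To correct a moving
#' stack, apply the negated offset with [apply_shift()].
#'
#' @param moving_dapi,reference_dapi DAPI `image_stack`s of equal (y, x)
#'   shape.
#' @return list `(round_id, dy, dx)` — a drift offset record.
#' @export
register_round <- function(moving_dapi, reference_dapi) {
  a <- max_project(reference_dapi)
  b <- max_project(moving_dapi)
  if (!all(dim(a) == dim(b))) stop("projections must share (y, x) shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("no registration signal: constant projection")
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cross <- fb * Conj(fa)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- 1
  corr <- Re(stats::fft(cross / mag, inverse = TRUE))
  peak <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  d <- dim(a)
  wrap <- function(p, n) if (p - 1 > n / 2) p - 1 - n else p - 1
  list(round_id = moving_dapi$round_id,
       dy = as.integer(wrap(peak[1], d[1])),
       dx = as.integer(wrap(peak[2], d[2])))
}

#' Translate every z-plane of a stack by an integer (dy, dx)
#'
#' Vacated pixels are zero-filled (no wrap-around), so no spurious content
#' crosses the borders; a pixel at `(y, x)` moves to `(y + dy, x + dx)`.
#' To undo a measured drift, pass the negated offset.
#'
#' @param stack an `image_stack`.
#' @param offset list with integer `dy`, `dx` (as from [register_round()]).
#' @return shifted `image_stack`, same shape.
#' @export
apply_shift <- function(stack, offset) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  dy <- as.integer(offset$dy); dx <- as.integer(offset$dx)
  if (abs(dy) >= d[2] || abs(dx) >= d[3])
    stop("shift magnitude must be smaller than the image extent")
  out <- array(0, d)
  ys <- seq_len(d[2]); xs <- seq_len(d[3])
  y_to <- ys + dy; x_to <- xs + dx
  oky <- y_to >= 1 & y_to <= d[2]; okx <- x_to >= 1 & x_to <= d[3]
  out[, y_to[oky], x_to[okx]] <- stack$data[, ys[oky], xs[okx]]
  stack$data <- out
  stack
}

#' Negate a drift offset
#'
#' Convenience for turning a measured drift into its correction.
#'
#' @param offset list with `dy`, `dx`.
#' @return the offset with both components negated.
#' @export
negate_offset <- function(offset) {
  offset$dy <- -offset$dy; offset$dx <- -offset$dx
  offset
}
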
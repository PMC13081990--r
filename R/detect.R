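# Single-molecule spot detection, dense-region decomposition, and the
# two-channel colocalization specificity assay.

#' Detection parameter defaults
#'
#' @param voxel_size_nm voxel size (z, y, x) in nm; default
#'   `c(1000, 103, 103)`.
#' @param spot_radius_nm expected spot radius (z, y, x) in nm; default
#'   `c(1050, 300, 300)`.
#' @param intensity_threshold manual threshold on the LoG-filtered
#'   intensity; there is no silent default — it must be set per experiment.
#' @return list of detection parameters, including `sigma_px` (the per-axis
#'   LoG sigma, `spot_radius_nm / voxel_size_nm / sqrt(3)`) and
#'   `min_separation` (voxels, `round(spot_radius_nm / voxel_size_nm)`
#'   floored at 1).
#' @export
detection_params <- function(voxel_size_nm = DEFAULT_VOXEL_NM,
                             spot_radius_nm = c(1050, 300, 300),
                             intensity_threshold = NA_real_) {
  stopifnot(all(voxel_size_nm > 0), all(spot_radius_nm > 0))
  radius_px <- spot_radius_nm / voxel_size_nm
  list(voxel_size_nm = voxel_size_nm,
       spot_radius_nm = spot_radius_nm,
       sigma_px = radius_px / sqrt(3),
       min_separation = pmax(1L, as.integer(round(radius_px))),
       intensity_threshold = intensity_threshold)
}

# negative Laplacian of the Gaussian-smoothed volume; per-axis sigma in
# voxels, second differences with replicate borders
log_filter <- function(arr, sigma_zyx) {
  sm <- gauss_blur_3d(arr, sigma_zyx)
  d <- dim(arr)
  out <- array(0, d)
  for (i in 1:3) {
    if (d[i] < 2) next
    lo <- pmax(seq_len(d[i]) - 1L, 1L)
    hi <- pmin(seq_len(d[i]) + 1L, d[i])
    shift_lo <- switch(i, sm[lo, , , drop = FALSE],
                       sm[, lo, , drop = FALSE], sm[, , lo, drop = FALSE])
    shift_hi <- switch(i, sm[hi, , , drop = FALSE],
                       sm[, hi, , drop = FALSE], sm[, , hi, drop = FALSE])
    # scale-normalize so anisotropic axes contribute comparably
    out <- out + sigma_zyx[i]^2 * (shift_lo + shift_hi - 2 * sm)
  }
  -out
}

#' Detect diffraction-limited spots
#'
#' Laplacian-of-Gaussian filtering with per-axis sigma derived from the
#' expected spot radius, followed by local-maximum extraction: a voxel is a
#' candidate iff its filtered value equals the maximum over the
#' `min_separation` box neighborhood and exceeds `intensity_threshold`.
#' Candidates closer than `min_separation` (per axis) are suppressed in
#' lexicographic (z, y, x) order. A margin of `min_separation` pixels at
#' the y/x borders is excluded, where the replicate-padded filter response
#' is unreliable; the z borders are kept because axial truncation of real
#' spots there is expected.
#'
#' @param stack a preprocessed `image_stack`.
#' @param params list from [detection_params()]; `intensity_threshold` must
#'   be a positive number.
#' @param gene gene name recorded on the output rows.
#' @param exclude_border `(z, y, x)` margins in voxels within which no
#'   candidate is accepted; default `c(0, min_separation[2:3])`.
#' @return a `spot_table`; `intensity` is the raw stack value at the voxel.
#' @export
detect_spots <- function(stack, params, gene = "unknown",
                         exclude_border = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  thr <- params$intensity_threshold
  if (!is.finite(thr) || thr <= 0)
    stop("intensity_threshold must be a positive number")
  if (max(stack$data) == 0) return(spot_table())
  resp <- log_filter(stack$data, params$sigma_px)
  sep <- params$min_separation
  boxmax <- running_max(resp, sep)
  cand <- which(resp >= boxmax & resp > thr, arr.ind = TRUE)
  if (is.null(exclude_border))
    exclude_border <- c(0L, sep[2], sep[3])
  d <- dim(stack$data)
  ok <- rep(TRUE, nrow(cand))
  for (i in 1:3)
    if (exclude_border[i] > 0)
      ok <- ok & cand[, i] > exclude_border[i] &
        cand[, i] <= d[i] - exclude_border[i]
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(spot_table())
  ord <- order(cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      close <- abs(cand[j, 1] - cand[i, 1]) <= sep[1] &
        abs(cand[j, 2] - cand[i, 2]) <= sep[2] &
        abs(cand[j, 3] - cand[i, 3]) <= sep[3]
      keep[j][close] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  spot_table(data.frame(
    spot_id = seq_len(nrow(cand)),
    gene = gene,
    round_id = stack$round_id,
    channel_id = stack$channel_id,
    z = as.numeric(cand[, 1]), y = as.numeric(cand[, 2]),
    x = as.numeric(cand[, 3]),
    intensity = stack$data[cand]))
}

# box maximum filter via running max along each axis (separable)
running_max <- function(arr, radius_zyx) {
  out <- arr
  d <- dim(arr)
  for (i in 1:3) {
    r <- radius_zyx[i]
    if (r < 1 || d[i] < 2) next
    acc <- out
    for (t in seq.int(-r, r)) {
      if (t == 0) next
      idx <- pmin(pmax(seq_len(d[i]) + t, 1L), d[i])
      shifted <- switch(i, out[idx, , , drop = FALSE],
                        out[, idx, , drop = FALSE],
                        out[, , idx, drop = FALSE])
      acc <- pmax(acc, shifted)
    }
    out <- acc
  }
  out
}

# sum of raw intensity in a box around one voxel
box_integral <- function(arr, zyx, radius_zyx) {
  d <- dim(arr)
  zr <- max(1, zyx[1] - radius_zyx[1]):min(d[1], zyx[1] + radius_zyx[1])
  yr <- max(1, zyx[2] - radius_zyx[2]):min(d[2], zyx[2] + radius_zyx[2])
  xr <- max(1, zyx[3] - radius_zyx[3]):min(d[3], zyx[3] + radius_zyx[3])
  sum(arr[zr, yr, xr])
}

#' Decompose dense regions into single-molecule signals
#'
#' Builds a reference single-molecule signal as the median box-integrated
#' intensity of isolated detections (no neighbor within twice the detection
#' separation). Connected bright regions whose integrated intensity exceeds
#' twice the reference integral are re-estimated to hold
#' `round(region integral / reference integral)` molecules; missing spots
#' are added at the region's brightest remaining local maxima. All other
#' spots pass through unchanged.
#'
#' @param stack the `image_stack` the spots were detected in.
#' @param spots a `spot_table` from [detect_spots()].
#' @param params list from [detection_params()].
#' @param region_threshold intensity level defining "bright" voxels for
#'   region growth; default half the median detected spot intensity.
#' @return a `spot_table` with `n >= nrow(spots)` rows.
#' @export
decompose_dense <- function(stack, spots, params, region_threshold = NULL) {
  if (!nrow(spots)) return(spots)
  sep <- params$min_separation
  co <- as.matrix(spots[, c("z", "y", "x")])
  n <- nrow(co)
  isolated <- vapply(seq_len(n), function(i) {
    if (n == 1) return(TRUE)
    dz <- abs(co[, 1] - co[i, 1]); dy <- abs(co[, 2] - co[i, 2])
    dx <- abs(co[, 3] - co[i, 3])
    sum(dz <= 2 * sep[1] & dy <= 2 * sep[2] & dx <= 2 * sep[3]) == 1
  }, NA)
  if (is.null(region_threshold))
    region_threshold <- 0.5 * stats::median(spots$intensity)
  lab <- label_components(stack$data > region_threshold)
  spot_region <- lab[round(co)]
  # net signal per region: sum over the region's bounding box padded by the
  # spot separation, minus the image's median baseline. The box captures the
  # full (sub-threshold) tails, so a merged pair integrates to ~2x a single;
  # the baseline keeps noise from diluting the ratio in large boxes.
  baseline <- stats::median(stack$data)
  d <- dim(stack$data)
  region_integral <- vapply(seq_len(max(lab)), function(r) {
    vox <- which(lab == r, arr.ind = TRUE)
    lo <- pmax(apply(vox, 2, min) - sep, 1)
    hi <- pmin(apply(vox, 2, max) + sep, d)
    box <- stack$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sum(box) - baseline * length(box)
  }, 0)
  # reference = one molecule's worth of supra-threshold signal, the median
  # over regions holding a single isolated detection
  ref_regions <- spot_region[isolated & spot_region > 0]
  ref_regions <- ref_regions[tabulate(spot_region[spot_region > 0],
                                      max(lab))[ref_regions] == 1]
  if (!length(ref_regions)) {
    warning("no isolated spots to build a reference; dense regions passed through")
    return(spots)
  }
  # lower quartile, not median: a merged pair detected as one spot passes
  # the isolation test and contaminates the reference set only upward
  ref_integral <- stats::quantile(region_integral[ref_regions], 0.25,
                                  names = FALSE)
  # unsuppressed LoG local maxima: merged molecules keep their own maximum
  # even when non-maximum suppression discarded it during detection
  resp <- log_filter(stack$data, params$sigma_px)
  # 1-voxel neighborhood: molecules closer than the detection separation
  # still carry distinct maxima at this scale
  is_locmax <- resp >= running_max(resp, c(1L, 1L, 1L))
  extra <- list()
  for (rg in setdiff(unique(spot_region), 0L)) {
    members <- which(spot_region == rg)
    vox <- which(lab == rg, arr.ind = TRUE)
    integral <- region_integral[rg]
    if (integral <= 2 * ref_integral) next
    n_target <- max(length(members), round(integral / ref_integral))
    n_add <- n_target - length(members)
    if (n_add <= 0) next
    # distinct local maxima first, then the brightest remaining voxels
    ord <- order(-is_locmax[vox], -resp[vox])
    claimed <- co[members, , drop = FALSE]
    added <- 0
    for (vi in ord) {
      if (added >= n_add) break
      p <- vox[vi, ]
      dmin <- min(sqrt(rowSums(sweep(claimed, 2, p)^2)))
      if (dmin < 1) next
      claimed <- rbind(claimed, p)
      extra[[length(extra) + 1]] <- data.frame(
        gene = spots$gene[members[1]], round_id = spots$round_id[members[1]],
        channel_id = spots$channel_id[members[1]],
        z = as.numeric(p[1]), y = as.numeric(p[2]), x = as.numeric(p[3]),
        intensity = stack$data[p[1], p[2], p[3]])
      added <- added + 1
    }
  }
  if (!length(extra)) return(spots)
  add_df <- do.call(rbind, extra)
  add_df$spot_id <- max(spots$spot_id) + seq_len(nrow(add_df))
  spot_table(rbind(as.data.frame(spots), add_df[SPOT_COLUMNS]))
}

# 3D connected-component labeling (6-connectivity) of a logical array
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_lin <- which(mask)
  if (!length(idx_lin)) return(lab)
  coords <- arrayInd(idx_lin, d)
  for (s in seq_along(idx_lin)) {
    if (lab[idx_lin[s]] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(coords[s, ], ncol = 3)
    lab[idx_lin[s]] <- nxt
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (off in list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                       c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))) {
        q <- p + off
        if (any(q < 1L) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

#' Two-channel colocalization efficiency
#'
#' For every channel-1 dot, the Euclidean nearest neighbor among channel-2
#' dots is found over `(z, y, x)` with z in slice units; a dot is
#' colocalized iff that distance is `<= radius_px`. Matching is
#' non-exclusive: one channel-2 dot may serve several channel-1 dots.
#'
#' @param ch1,ch2 `spot_table`s from the same registered field.
#' @param radius_px colocalization radius in pixels (default 2).
#' @param two_d ignore z and match in (y, x) only.
#' @return list `n_ch1, n_colocalized, efficiency, radius_px`.
#' @export
colocalization_efficiency <- function(ch1, ch2, radius_px = 2, two_d = FALSE) {
  if (!nrow(ch1)) stop("no reference dots in channel 1")
  if (!nrow(ch2))
    return(list(n_ch1 = nrow(ch1), n_colocalized = 0L, efficiency = 0,
                radius_px = radius_px))
  cols <- if (two_d) c("y", "x") else c("z", "y", "x")
  a <- as.matrix(ch1[, cols]); b <- as.matrix(ch2[, cols])
  # squared-distance matrix in one shot; tables here are small enough
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  nn <- sqrt(pmax(apply(d2, 1, min), 0))
  n_col <- sum(nn <= radius_px)
  list(n_ch1 = nrow(ch1), n_colocalized = as.integer(n_col),
       efficiency = n_col / nrow(ch1), radius_px = radius_px)
}
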
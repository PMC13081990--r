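# Probabilistic transcript-to-nucleus assignment.
#
# Model, per z-slice: each nuclear mask cross-section is fitted with an
# ellipse from the principal components of its pixel coordinates; doubling
# the mask's length and width along those axes gives an ellipse twice the
# mask's size (semi-axes capped at 15 px). A transcript inside a mask is
# hard-assigned. A transcript outside every mask but inside at least one
# doubled ellipse is soft-assigned under a 2-D Gaussian mixture whose
# component i has mean c_i (mask centroid), covariance
# R_i diag(a_i^2, b_i^2) R_i^T (standard deviations = the semi-axes) and
# mixture weight sqrt(a_i * b_i), which cancels the bias against larger
# nuclei that equal weights would introduce. Transcripts outside every
# ellipse stay unassigned.

#' Fit per-slice nuclear ellipses from a label mask
#'
#' For every (label, z) cross-section with >= 3 pixels: center = pixel
#' centroid; orientation = first principal component of the pixel (y, x)
#' coordinates; the mask extent (max - min of projected pixel-center
#' coordinates, floored at 1 px) along the first/second principal axes,
#' after doubling the mask, becomes the ellipse semi-axes `(a, b)` with
#' `a >= b`, each capped at `max_semi_axis`. Cross-sections with < 3 pixels
#' get an isotropic ellipse with `a = b = min(2 * max(1, sqrt(area / pi)),
#' max_semi_axis)`. The mixture weight is `sqrt(a * b)`.
#'
#' @param mask a `label_mask` (3D integer array, 0 = background).
#' @param max_semi_axis ceiling on each semi-axis in pixels (default 15).
#' @return data.frame with one row per (label, z): `label, z, cy, cx, a, b,
#'   uy, ux` (unit first principal axis), `weight`, `n_px`.
#' @export
fit_ellipses <- function(mask, max_semi_axis = 15) {
  d <- dim(mask)
  vox <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(vox))
    return(data.frame(label = integer(), z = integer(), cy = numeric(),
                      cx = numeric(), a = numeric(), b = numeric(),
                      uy = numeric(), ux = numeric(), weight = numeric(),
                      n_px = integer()))
  lab <- mask[vox]
  key <- split(seq_len(nrow(vox)), list(lab, vox[, 1]), drop = TRUE)
  rows <- lapply(key, function(ii) {
    z <- vox[ii[1], 1]
    lb <- lab[ii[1]]
    yx <- vox[ii, c(2, 3), drop = FALSE]
    cy <- mean(yx[, 1]); cx <- mean(yx[, 2])
    n_px <- nrow(yx)
    if (n_px < 3) {
      a <- b <- min(2 * max(1, sqrt(n_px / pi)), max_semi_axis)
      u <- c(1, 0)
    } else {
      cen <- sweep(yx, 2, c(cy, cx))
      ev <- eigen(crossprod(cen) / n_px, symmetric = TRUE)
      u1 <- ev$vectors[, 1]; u2 <- ev$vectors[, 2]
      p1 <- cen %*% u1; p2 <- cen %*% u2
      ext1 <- max(1, max(p1) - min(p1))
      ext2 <- max(1, max(p2) - min(p2))
      # doubling the mask makes the full axis 2*extent, so semi-axis = extent
      a <- min(ext1, max_semi_axis)
      b <- min(ext2, max_semi_axis)
      u <- u1
      if (b > a) { tmp <- a; a <- b; b <- tmp; u <- u2 }
    }
    data.frame(label = lb, z = z, cy = cy, cx = cx, a = a, b = b,
               uy = u[1], ux = u[2], weight = sqrt(a * b), n_px = n_px)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$label, out$z), ]
  rownames(out) <- NULL
  out
}

#' Eligible nuclei for one spot
#'
#' The spot's slice is `round(z)`. If the mask voxel at the rounded
#' coordinate is nonzero the spot is inside that nucleus (hard assignment).
#' Otherwise the eligible nuclei are those whose doubled ellipse at that
#' slice contains `(y, x)` under the quadratic-form test
#' `((p - c) . u1 / a)^2 + ((p - c) . u2 / b)^2 <= 1`.
#'
#' @param spot numeric `(z, y, x)`.
#' @param mask a `label_mask`.
#' @param ellipses data.frame from [fit_ellipses()].
#' @return list `containing` (label or NA) and `eligible` (integer labels,
#'   possibly empty).
#' @export
eligibility <- function(spot, mask, ellipses) {
  d <- dim(mask)
  zi <- as.integer(round(spot[1]))
  if (zi < 1 || zi > d[1]) stop("spot slice ", zi, " outside the stack")
  yi <- as.integer(round(spot[2])); xi <- as.integer(round(spot[3]))
  containing <- NA_integer_
  if (yi >= 1 && yi <= d[2] && xi >= 1 && xi <= d[3]) {
    v <- mask[zi, yi, xi]
    if (v > 0) return(list(containing = as.integer(v), eligible = as.integer(v)))
  }
  e <- ellipses[ellipses$z == zi, , drop = FALSE]
  if (!nrow(e)) return(list(containing = containing, eligible = integer()))
  dy <- spot[2] - e$cy; dx <- spot[3] - e$cx
  p1 <- dy * e$uy + dx * e$ux
  p2 <- dy * (-e$ux) + dx * e$uy
  inside <- (p1 / e$a)^2 + (p2 / e$b)^2 <= 1
  list(containing = containing, eligible = as.integer(e$label[inside]))
}

#' Soft-assign one perinuclear spot over its eligible nuclei
#'
#' Responsibility of nucleus i is
#' `w_i * phi(p; c_i, Sigma_i) / sum_j w_j * phi(p; c_j, Sigma_j)` with
#' `phi` the full 2-D normal density (normalizing constants included, since
#' covariances differ between nuclei), `Sigma_i = R_i diag(a_i^2, b_i^2)
#' R_i^T` and `w_i = sqrt(a_i * b_i)`. Computed in log space to avoid
#' underflow at the ellipse margins.
#'
#' @param spot numeric `(z, y, x)` (z unused beyond slice selection).
#' @param ellipses the eligible rows of a [fit_ellipses()] table.
#' @return named numeric vector of responsibilities summing to 1, names =
#'   nucleus labels.
#' @export
soft_assign <- function(spot, ellipses) {
  stopifnot(nrow(ellipses) >= 1)
  dy <- spot[2] - ellipses$cy; dx <- spot[3] - ellipses$cx
  p1 <- dy * ellipses$uy + dx * ellipses$ux
  p2 <- dy * (-ellipses$ux) + dx * ellipses$uy
  log_phi <- -log(2 * pi) - log(ellipses$a * ellipses$b) -
    0.5 * ((p1 / ellipses$a)^2 + (p2 / ellipses$b)^2)
  log_w <- 0.5 * log(ellipses$a * ellipses$b)
  lp <- log_w + log_phi
  lp <- lp - max(lp)
  r <- exp(lp) / sum(exp(lp))
  stats::setNames(r, ellipses$label)
}

#' Assign every spot and build the cell-by-gene matrix
#'
#' Routes each spot through [eligibility()]: in-mask spots are
#' hard-assigned, perinuclear spots soft-assigned with [soft_assign()],
#' spots outside every ellipse (or outside the mask's z extent) are
#' unassigned. Per-(nucleus, gene) responsibilities are summed over all
#' spots and slices into a `cell_gene_matrix`.
#'
#' @param spots a `spot_table`.
#' @param mask a `label_mask` registered to the same frame.
#' @param max_semi_axis ellipse semi-axis cap in pixels (default 15).
#' @param worm_id,sex metadata stamped on the matrix cells.
#' @param ellipses optionally precomputed [fit_ellipses()] table.
#' @return list with `assignments` (data.frame `spot_id, gene, status,
#'   label` — argmax label, NA when unassigned), `probabilities` (long
#'   data.frame `spot_id, label, prob` over soft/hard spots), `matrix` (a
#'   `cell_gene_matrix` over all mask labels), and `unassigned` (per-gene
#'   counts).
#' @export
assign_all <- function(spots, mask, max_semi_axis = 15,
                       worm_id = "worm1", sex = "hermaphrodite",
                       ellipses = NULL) {
  if (is.null(ellipses)) ellipses <- fit_ellipses(mask, max_semi_axis)
  labels <- sort(unique(ellipses$label))
  genes <- sort(unique(as.character(spots$gene)))
  values <- matrix(0, length(labels), max(length(genes), 0),
                   dimnames = list(labels, genes))
  n <- nrow(spots)
  status <- character(n); arg <- rep(NA_integer_, n)
  prob_rows <- vector("list", n)
  d <- dim(mask)
  for (i in seq_len(n)) {
    p <- c(spots$z[i], spots$y[i], spots$x[i])
    zi <- round(p[1])
    if (zi < 1 || zi > d[1]) {
      warning("spot ", spots$spot_id[i], " lies outside the mask z extent")
      status[i] <- "unassigned"
      next
    }
    el <- eligibility(p, mask, ellipses)
    if (!is.na(el$containing)) {
      status[i] <- "hard"; arg[i] <- el$containing
      r <- stats::setNames(1, el$containing)
    } else if (length(el$eligible)) {
      status[i] <- "soft"
      cand <- ellipses[ellipses$z == zi & ellipses$label %in% el$eligible, ,
                       drop = FALSE]
      r <- soft_assign(p, cand)
      arg[i] <- as.integer(names(r)[which.max(r)])
    } else {
      status[i] <- "unassigned"
      next
    }
    g <- as.character(spots$gene[i])
    values[as.character(names(r)), g] <-
      values[as.character(names(r)), g] + r
    prob_rows[[i]] <- data.frame(spot_id = spots$spot_id[i],
                                 label = as.integer(names(r)),
                                 prob = as.numeric(r))
  }
  probabilities <- do.call(rbind, prob_rows[!vapply(prob_rows, is.null, NA)])
  if (is.null(probabilities))
    probabilities <- data.frame(spot_id = integer(), label = integer(),
                                prob = numeric())
  unassigned <- stats::setNames(
    as.integer(table(factor(spots$gene[status == "unassigned"],
                            levels = genes))), genes)
  meta <- data.frame(label = labels,
                     worm_id = rep(worm_id, length(labels)),
                     neuron_class = rep("unassigned", length(labels)),
                     sex = rep(sex, length(labels)))
  list(assignments = data.frame(spot_id = spots$spot_id,
                                gene = as.character(spots$gene),
                                status = status, label = arg),
       probabilities = probabilities,
       matrix = cell_gene_matrix(values, meta, genes),
       unassigned = unassigned)
}
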
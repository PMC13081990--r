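# Synthetic whole-worm-like experiments with full ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# non-overlapping ellipsoidal nuclei rendered into a DAPI channel;
# per-cell per-gene transcript counts Poisson around configurable means;
# each transcript either uniform inside its nucleus's mask or, in the
# perinuclear zone, drawn from the truncated 2-D Gaussian defined by that
# nucleus's doubled fitted ellipse at a random z-slice — exactly the
# distribution the assignment model assumes, so parameter-recovery tests
# are well-posed. A model-mismatch mode (uniform over the ellipse) is
# included to measure robustness. Rounds after the first carry cumulative
# x/y drift.

#' Simulation configuration
#'
#' Defaults mirror the acquisition scales the pipeline assumes: voxel
#' (1000, 103, 103) nm geometry with 9 z-slices, 20 nuclei, 10 genes (two
#' readout channels per round), spot amplitude 1 with Gaussian noise SD 0.2
#' (SNR 5).
#'
#' @param shape volume `(Z, Y, X)` in voxels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_semi_axes list with ranges `a` (in-plane long semi-axis,
#'   px), `b` (short, px), `rz` (z half-extent, slices).
#' @param n_genes number of genes; gene g is imaged in round
#'   `ceiling(g / 2)` on channel `CH_647`/`CH_CY3B` alternating.
#' @param expression per-(cell, gene) mean count matrix, or NULL to sample
#'   means from a log-normal (`meanlog = log(3)`, `sdlog = 0.4`).
#' @param inside_fraction probability a transcript falls inside its
#'   nucleus's mask (default 0.4).
#' @param spot_amplitude rendered spot peak intensity.
#' @param psf_sigma_px rendered spot Gaussian sigma `(z, y, x)` in voxels.
#' @param noise_sd additive Gaussian noise SD (negatives clipped to 0).
#' @param drift_per_round per-round `(dy, dx)` drift in pixels, applied
#'   cumulatively to rounds after the first.
#' @param rounds number of hybridization rounds; default `ceiling(n_genes
#'   / 2)`.
#' @param perinuclear_mode `"gaussian"` (the assignment model's
#'   distribution) or `"uniform"` (model-mismatch ring).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(shape = c(9, 160, 160),
                       n_nuclei = 20,
                       nucleus_semi_axes = list(a = c(4, 7), b = c(3, 5),
                                                rz = c(1.2, 2.2)),
                       n_genes = 10,
                       expression = NULL,
                       inside_fraction = 0.4,
                       spot_amplitude = 1,
                       psf_sigma_px = c(0.6, 1.7, 1.7),
                       noise_sd = 0.2,
                       drift_per_round = c(1, -2),
                       rounds = NULL,
                       perinuclear_mode = c("gaussian", "uniform"),
                       seed = 1L) {
  stopifnot(all(shape > 0), inside_fraction >= 0, inside_fraction <= 1)
  if (is.null(rounds)) rounds <- max(1L, as.integer(ceiling(n_genes / 2)))
  structure(list(shape = as.integer(shape), n_nuclei = n_nuclei,
                 nucleus_semi_axes = nucleus_semi_axes, n_genes = n_genes,
                 expression = expression, inside_fraction = inside_fraction,
                 spot_amplitude = spot_amplitude, psf_sigma_px = psf_sigma_px,
                 noise_sd = noise_sd, drift_per_round = drift_per_round,
                 rounds = as.integer(rounds),
                 perinuclear_mode = match.arg(perinuclear_mode),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# canonical C. elegans neuron class names used for the synthetic class map
NEURON_CLASS_POOL <- c("AVA", "AVB", "AVD", "AVE", "PVC", "ASH", "AWA",
                       "AWB", "AWC", "ASE", "AIY", "AIZ", "RIB", "RIM",
                       "SMD", "RMD", "PLM", "ALM", "AVM", "PVM", "AIB",
                       "RIA", "ADL", "ASI", "ASJ", "ASK", "AFD", "BAG",
                       "URX", "AQR")

# place non-overlapping ellipsoids; returns data.frame of nucleus geometry
place_nuclei <- function(cfg) {
  d <- cfg$shape
  ax <- cfg$nucleus_semi_axes
  margin <- max(ax$a) + 15 + abs(cfg$drift_per_round) * cfg$rounds
  # margin per axis (y, x); keep every perinuclear ellipse and all drifted
  # content inside the frame
  my <- min(margin[1], d[2] / 4); mx <- min(margin[2], d[3] / 4)
  out <- NULL
  tries <- 0
  while (is.null(out) || nrow(out) < cfg$n_nuclei) {
    tries <- tries + 1
    if (tries > 20000)
      stop("could not place ", cfg$n_nuclei, " non-overlapping nuclei; ",
           "use fewer or smaller nuclei or a larger volume")
    a <- stats::runif(1, ax$a[1], ax$a[2])
    b <- stats::runif(1, ax$b[1], ax$b[2])
    rz <- stats::runif(1, ax$rz[1], ax$rz[2])
    rz <- min(rz, (d[1] - 1.1) / 2)  # thin volumes cap the z half-extent
    cz <- stats::runif(1, 1 + rz, d[1] - rz)
    cy <- stats::runif(1, 1 + my, d[2] - my)
    cx <- stats::runif(1, 1 + mx, d[3] - mx)
    theta <- stats::runif(1, 0, pi)
    if (!is.null(out)) {
      dist <- sqrt((out$cy - cy)^2 + (out$cx - cx)^2)
      if (any(dist < out$a + a + 2)) next
    }
    row <- data.frame(label = if (is.null(out)) 1L else nrow(out) + 1L,
                      cz = cz, cy = cy, cx = cx, a = a, b = b, rz = rz,
                      theta = theta)
    out <- rbind(out, row)
  }
  out
}

# rasterize ellipsoid nuclei into a label mask
rasterize_nuclei <- function(nuclei, shape) {
  mask <- array(0L, shape)
  if (is.null(nuclei) || !nrow(nuclei)) return(label_mask(mask))
  grid_y <- seq_len(shape[2]); grid_x <- seq_len(shape[3])
  for (i in seq_len(nrow(nuclei))) {
    n <- nuclei[i, ]
    u1 <- c(cos(n$theta), sin(n$theta)); u2 <- c(-sin(n$theta), cos(n$theta))
    for (z in seq_len(shape[1])) {
      f <- 1 - ((z - n$cz) / n$rz)^2
      if (f <= 0) next
      s <- sqrt(f)
      ys <- grid_y[abs(grid_y - n$cy) <= n$a]
      xs <- grid_x[abs(grid_x - n$cx) <= n$a]
      if (!length(ys) || !length(xs)) next
      dy <- outer(ys - n$cy, rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - n$cx)
      p1 <- dy * u1[1] + dx * u1[2]
      p2 <- dy * u2[1] + dx * u2[2]
      inside <- (p1 / (n$a * s))^2 + (p2 / (n$b * s))^2 <= 1
      mask[z, ys, xs][inside] <- n$label
    }
  }
  label_mask(mask)
}

# sample one perinuclear position from a fitted-ellipse row
sample_perinuclear <- function(erow, mode) {
  repeat {
    if (mode == "gaussian") {
      p1 <- stats::rnorm(1, 0, erow$a); p2 <- stats::rnorm(1, 0, erow$b)
    } else {
      p1 <- stats::runif(1, -erow$a, erow$a)
      p2 <- stats::runif(1, -erow$b, erow$b)
    }
    if ((p1 / erow$a)^2 + (p2 / erow$b)^2 <= 1) break
  }
  c(y = erow$cy + p1 * erow$uy - p2 * erow$ux,
    x = erow$cx + p1 * erow$ux + p2 * erow$uy)
}

# render a set of spots as 3D Gaussians into a zero array
render_spots <- function(shape, spots_zyx, amplitude, sigma) {
  img <- array(0, shape)
  if (!nrow(spots_zyx)) return(img)
  r <- ceiling(3 * sigma)
  for (i in seq_len(nrow(spots_zyx))) {
    s <- as.numeric(spots_zyx[i, ])
    zr <- max(1, floor(s[1] - r[1])):min(shape[1], ceiling(s[1] + r[1]))
    yr <- max(1, floor(s[2] - r[2])):min(shape[2], ceiling(s[2] + r[2]))
    xr <- max(1, floor(s[3] - r[3])):min(shape[3], ceiling(s[3] + r[3]))
    gz <- exp(-(zr - s[1])^2 / (2 * sigma[1]^2))
    gy <- exp(-(yr - s[2])^2 / (2 * sigma[2]^2))
    gx <- exp(-(xr - s[3])^2 / (2 * sigma[3]^2))
    img[zr, yr, xr] <- img[zr, yr, xr] +
      amplitude * (gz %o% gy %o% gx)
  }
  img
}

#' Simulate a full sequential smFISH experiment
#'
#' Places nuclei, rasterizes the ground-truth label mask, draws transcripts
#' per cell and gene, renders DAPI and readout-channel stacks round by
#' round with cumulative drift and additive noise, and returns everything
#' alongside the complete ground truth. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `stacks` (per round: `DAPI`, `CH_647`, `CH_CY3B`
#'   `image_stack`s), `gene_map` (gene to round/channel), and `truth`
#'   (`mask`, `nuclei`, `spots` — a `spot_table` plus `true_label` and
#'   `true_inside` columns, `matrix` — true integer counts, `offsets` —
#'   cumulative per-round drift, `annotations` — neuron-name coordinates,
#'   `class_map`).
#' @export
simulate_experiment <- function(config = sim_config()) {
  with_seed(config$seed, function() simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  d <- cfg$shape
  nuclei <- if (cfg$n_nuclei > 0) place_nuclei(cfg) else NULL
  mask <- rasterize_nuclei(nuclei, d)
  n_cells <- if (is.null(nuclei)) 0L else nrow(nuclei)
  genes <- if (cfg$n_genes > 0) sprintf("gene%02d", seq_len(cfg$n_genes))
           else character()
  gene_map <- data.frame(
    gene = genes,
    round_id = if (length(genes)) as.integer(ceiling(seq_along(genes) / 2) - 1)
               else integer(),
    channel_id = if (length(genes))
      c("CH_647", "CH_CY3B")[(seq_along(genes) - 1) %% 2 + 1] else character())
  expr <- cfg$expression
  if (is.null(expr) && n_cells > 0 && cfg$n_genes > 0)
    expr <- matrix(stats::rlnorm(n_cells * cfg$n_genes,
                                 meanlog = log(3), sdlog = 0.4),
                   n_cells, cfg$n_genes)
  ellipses <- fit_ellipses(mask)
  mask_vox <- which(unclass(mask) > 0, arr.ind = TRUE)
  mask_lab <- mask[mask_vox]

  spot_rows <- list()
  true_counts <- matrix(0L, n_cells, cfg$n_genes)
  sid <- 0L
  for (ci in seq_len(n_cells)) {
    own_vox <- mask_vox[mask_lab == ci, , drop = FALSE]
    own_ell <- ellipses[ellipses$label == ci, , drop = FALSE]
    for (gi in seq_len(cfg$n_genes)) {
      n_t <- stats::rpois(1, expr[ci, gi])
      true_counts[ci, gi] <- n_t
      if (n_t == 0) next
      for (t in seq_len(n_t)) {
        if (nrow(own_vox) == 0 && nrow(own_ell) == 0) next
        sid <- sid + 1L
        use_inside <- (stats::runif(1) < cfg$inside_fraction ||
                         nrow(own_ell) == 0) && nrow(own_vox) > 0
        if (use_inside) {
          v <- own_vox[sample.int(nrow(own_vox), 1), ]
          jit <- stats::runif(3, -0.45, 0.45)
          pos <- c(v[1], v[2] + jit[2], v[3] + jit[3])
          inside <- TRUE
        } else {
          er <- own_ell[sample.int(nrow(own_ell), 1), ]
          yx <- sample_perinuclear(er, cfg$perinuclear_mode)
          pos <- c(er$z, yx["y"], yx["x"])
          inside <- FALSE
        }
        spot_rows[[sid]] <- data.frame(
          spot_id = sid, gene = genes[gi],
          round_id = gene_map$round_id[gi],
          channel_id = gene_map$channel_id[gi],
          z = as.numeric(pos[1]), y = as.numeric(pos[2]),
          x = as.numeric(pos[3]),
          intensity = cfg$spot_amplitude,
          true_label = ci, true_inside = inside)
      }
    }
  }
  spots <- if (length(spot_rows)) do.call(rbind, spot_rows) else
    cbind(as.data.frame(spot_table()), true_label = integer(),
          true_inside = logical())

  # cumulative drift per round (round 0 is the reference)
  offsets <- data.frame(round_id = seq_len(cfg$rounds) - 1L)
  offsets$dy <- as.integer(round(offsets$round_id * cfg$drift_per_round[1]))
  offsets$dx <- as.integer(round(offsets$round_id * cfg$drift_per_round[2]))

  dapi_clean <- gauss_blur_3d(array(as.numeric(unclass(mask) > 0), d),
                              c(0.5, 1.2, 1.2))
  stacks <- vector("list", cfg$rounds)
  for (r in seq_len(cfg$rounds) - 1L) {
    off <- list(dy = offsets$dy[r + 1], dx = offsets$dx[r + 1])
    mk <- function(clean, channel) {
      st <- image_stack(clean, round_id = r, channel_id = channel)
      if (off$dy != 0 || off$dx != 0) st <- apply_shift(st, off)
      noisy <- st$data + stats::rnorm(length(st$data), 0, cfg$noise_sd)
      noisy[noisy < 0] <- 0
      st$data <- noisy
      st
    }
    round_stacks <- list(DAPI = mk(dapi_clean, "DAPI"))
    for (ch in c("CH_647", "CH_CY3B")) {
      g <- gene_map$gene[gene_map$round_id == r & gene_map$channel_id == ch]
      sp <- spots[spots$gene %in% g, c("z", "y", "x"), drop = FALSE]
      clean <- render_spots(d, sp, cfg$spot_amplitude, cfg$psf_sigma_px)
      round_stacks[[ch]] <- mk(clean, ch)
    }
    stacks[[r + 1]] <- round_stacks
  }

  class_map <- if (n_cells > 0)
    data.frame(label = seq_len(n_cells),
               neuron_class = rep_len(NEURON_CLASS_POOL, n_cells))
  else data.frame(label = integer(), neuron_class = character())
  annotations <- if (n_cells > 0)
    data.frame(neuron_name = class_map$neuron_class,
               x = nuclei$cx, y = nuclei$cy, z = nuclei$cz,
               worm_id = "sim_worm", sex = "male")
  else data.frame(neuron_name = character(), x = numeric(), y = numeric(),
                  z = numeric(), worm_id = character(), sex = character())

  true_matrix <- cell_gene_matrix(
    true_counts,
    data.frame(label = seq_len(n_cells),
               worm_id = rep("sim_worm", n_cells),
               neuron_class = class_map$neuron_class[seq_len(n_cells)],
               sex = rep("male", n_cells)),
    genes)

  list(stacks = stacks, gene_map = gene_map,
       truth = list(mask = mask, nuclei = nuclei,
                    spots = spots, matrix = true_matrix,
                    offsets = offsets, annotations = annotations,
                    class_map = class_map))
}

#' Simulate a transcriptome FASTA fixture
#'
#' Random sequences at ~50% GC named `gene01..geneNN`, plus optional decoy
#' transcripts into which exact k-mers copied from designated target
#' windows are planted, to exercise the off-target screens.
#'
#' @param n_genes number of target transcripts.
#' @param length_range transcript length range in nt.
#' @param n_decoys number of decoy (non-target) transcripts.
#' @param planted optional data.frame `target, target_start, k, decoy`:
#'   copy the `k`-mer of `target` beginning at `target_start` into the
#'   middle of decoy number `decoy`.
#' @param seed integer RNG seed.
#' @param path optional FASTA output path.
#' @return named character vector of sequences (targets then decoys named
#'   `decoy01..`); written as FASTA when `path` is given.
#' @export
simulate_transcriptome <- function(n_genes, length_range = c(1000, 3000),
                                   n_decoys = 0, planted = NULL, seed = 1L,
                                   path = NULL) {
  seqs <- with_seed(seed, function() {
    rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                         replace = TRUE), collapse = "")
    lens <- sample(length_range[1]:length_range[2], n_genes + n_decoys,
                   replace = TRUE)
    s <- vapply(lens, rand_seq, "")
    names(s) <- c(sprintf("gene%02d", seq_len(n_genes)),
                  if (n_decoys > 0) sprintf("decoy%02d", seq_len(n_decoys)))
    s
  })
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      p <- planted[i, ]
      frag <- substr(seqs[[p$target]], p$target_start,
                     p$target_start + p$k - 1)
      decoy_name <- if (is.character(p$decoy)) p$decoy else
        sprintf("decoy%02d", p$decoy)
      at <- max(1, nchar(seqs[[decoy_name]]) %/% 2)
      substr(seqs[[decoy_name]], at, at + p$k - 1) <- frag
    }
  }
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  }
  seqs
}
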
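# Independent oracles and fixture builders shared across tests. These are
# deliberately naive (dense loops, quadratic scans) so they stay independent
# of the implementation paths they check.

# longest common substring length between two strings, O(n*m) DP
lcs_length <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  prev <- integer(length(vb)); best <- 0L
  for (i in seq_along(va)) {
    cur <- integer(length(vb))
    for (j in seq_along(vb)) {
      if (va[i] == vb[j]) {
        cur[j] <- if (j == 1) 1L else prev[j - 1] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

rc <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))

# longest shared substring in either orientation
lcs_both <- function(a, b) max(lcs_length(a, b), lcs_length(a, rc(b)))

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = "")

# brute-force weighted-Gaussian-mixture responsibilities via explicit
# covariance matrices (no log-space, no shared code with soft_assign)
gmm_oracle <- function(spot_yx, ells) {
  dens <- numeric(nrow(ells))
  for (i in seq_len(nrow(ells))) {
    e <- ells[i, ]
    R <- cbind(c(e$uy, e$ux), c(-e$ux, e$uy))
    Sigma <- R %*% diag(c(e$a^2, e$b^2)) %*% t(R)
    d <- c(spot_yx[1] - e$cy, spot_yx[2] - e$cx)
    q <- drop(t(d) %*% solve(Sigma) %*% d)
    dens[i] <- sqrt(e$a * e$b) *
      exp(-q / 2) / (2 * pi * sqrt(det(Sigma)))
  }
  dens / sum(dens)
}

# random per-slice ellipse tables for GMM checks
random_ellipses <- function(n, z = 1) {
  th <- runif(n, 0, pi)
  a <- runif(n, 2, 8)
  b <- a * runif(n, 0.4, 1)
  data.frame(label = seq_len(n), z = z,
             cy = runif(n, 10, 50), cx = runif(n, 10, 50),
             a = a, b = b, uy = cos(th), ux = sin(th),
             weight = sqrt(a * b), n_px = 10L)
}

# render an image stack holding Gaussian spots at given (z, y, x)
render_field <- function(shape, spots_zyx, amplitude = 1,
                         sigma = c(0.6, 1.7, 1.7), noise_sd = 0) {
  img <- wormfish:::render_spots(shape, spots_zyx, amplitude, sigma)
  if (noise_sd > 0) {
    img <- img + rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0
  }
  image_stack(img)
}

# blob image for registration tests: scattered bright nuclei-like discs
nuclei_image <- function(shape = c(3, 64, 64), n = 15, seed = 1) {
  withr::with_seed(seed, {
    img <- array(0, shape)
    for (i in seq_len(n)) {
      y <- sample(8:(shape[2] - 8), 1); x <- sample(8:(shape[3] - 8), 1)
      z <- sample(seq_len(shape[1]), 1)
      img[z, y + (-2:2), x + (-2:2)] <- runif(1, 0.5, 1)
    }
    image_stack(img)
  })
}

# small annotated cell-by-gene matrix for quantify tests
toy_matrix <- function(values, classes, worm_id = "w1", sex = "male",
                       genes = paste0("g", seq_len(ncol(values)))) {
  cell_gene_matrix(values,
                   data.frame(label = seq_len(nrow(values)),
                              worm_id = worm_id, neuron_class = classes,
                              sex = sex),
                   genes)
}
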
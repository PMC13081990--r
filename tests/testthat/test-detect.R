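test_that("a rendered spot is detected within one voxel of its position", {
  truth <- data.frame(z = 5, y = 20.3, x = 21.4)
  st <- render_field(c(9, 40, 40), truth, amplitude = 10)
  dp <- detection_params(intensity_threshold = 1)
  sp <- detect_spots(st, dp)
  expect_equal(nrow(sp), 1)
  expect_lte(abs(sp$z - truth$z), 1)
  expect_lte(abs(sp$y - truth$y), 1)
  expect_lte(abs(sp$x - truth$x), 1)
})

test_that("thresholds above the response maximum yield no spots", {
  st <- render_field(c(9, 40, 40), data.frame(z = 5, y = 20, x = 20),
                     amplitude = 1)
  dp <- detection_params(intensity_threshold = 100)
  expect_equal(nrow(detect_spots(st, dp)), 0)
  expect_error(detect_spots(st, detection_params(intensity_threshold = 0)),
               "positive")
  empty <- image_stack(array(0, c(3, 10, 10)))
  expect_equal(nrow(detect_spots(empty,
                                 detection_params(intensity_threshold = 1))), 0)
})

test_that("well-separated noise-free spots are recovered exactly", {
  withr::with_seed(23, {
    n <- 50
    pos <- data.frame(z = sample(2:8, n, TRUE),
                      y = rep(seq(12, 116, by = 13), length.out = n) +
                        runif(n, -2, 2),
                      x = rep(seq(12, 116, by = 13), each = 9,
                              length.out = n) + runif(n, -2, 2))
    st <- render_field(c(9, 128, 128), pos, amplitude = 1)
    sp <- detect_spots(st, detection_params(intensity_threshold = 0.05))
    expect_equal(nrow(sp), n)
    d2 <- outer(sp$z, pos$z, "-")^2 + outer(sp$y, pos$y, "-")^2 +
      outer(sp$x, pos$x, "-")^2
    expect_true(all(apply(d2, 1, min) <= 3))   # precision 1
    expect_true(all(apply(d2, 2, min) <= 3))   # recall 1
  })
})

test_that("detected spot count is monotone non-increasing in the threshold", {
  withr::with_seed(24, {
    pos <- data.frame(z = sample(2:8, 20, TRUE), y = runif(20, 10, 86),
                      x = runif(20, 10, 86))
    st <- render_field(c(9, 96, 96), pos, amplitude = 1, noise_sd = 0.15)
    thresholds <- seq(0.02, 0.6, length.out = 20)
    counts <- vapply(thresholds, function(t)
      nrow(detect_spots(st, detection_params(intensity_threshold = t))), 0L)
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("dense-region decomposition splits a merged spot pair", {
  withr::with_seed(25, {
    # ten isolated molecules to build the reference, one coincident pair
    # placed well away from all of them
    iso <- data.frame(z = rep(c(3, 5, 7), length.out = 10),
                      y = seq(10, 85, length.out = 10),
                      x = rep(c(15, 30), length.out = 10))
    pair <- data.frame(z = c(5, 5), y = c(50.0, 51.0), x = c(70.0, 70.5))
    st <- render_field(c(9, 96, 96), rbind(iso, pair), amplitude = 1)
    dp <- detection_params(intensity_threshold = 0.05)
    sp <- detect_spots(st, dp)
    expect_equal(nrow(sp), 11)  # the pair merges into one detection
    out <- decompose_dense(st, sp, dp)
    expect_equal(nrow(out), 12)
    # the added spot lies in the pair's region
    extra <- out[!out$spot_id %in% sp$spot_id, ]
    expect_lt(sqrt((extra$y - 50.5)^2 + (extra$x - 70.25)^2), 4)
  })
})

test_that("decomposition passes isolated spots and empty tables through", {
  st <- render_field(c(9, 40, 40), data.frame(z = 5, y = 20, x = 20))
  dp <- detection_params(intensity_threshold = 0.05)
  sp <- detect_spots(st, dp)
  expect_equal(nrow(decompose_dense(st, sp, dp)), nrow(sp))
  empty <- spot_table()
  expect_equal(nrow(decompose_dense(st, empty, dp)), 0)
})

test_that("decomposition never decreases the spot count", {
  withr::with_seed(26, {
    pos <- data.frame(z = sample(3:7, 30, TRUE), y = runif(30, 10, 86),
                      x = runif(30, 10, 86))
    st <- render_field(c(9, 96, 96), pos, amplitude = 1, noise_sd = 0.1)
    dp <- detection_params(intensity_threshold = 0.08)
    sp <- detect_spots(st, dp)
    out <- suppressWarnings(decompose_dense(st, sp, dp))
    expect_gte(nrow(out), nrow(sp))
  })
})

test_that("colocalization matches hand-computed and oracle results", {
  mk <- function(m) spot_table(data.frame(
    spot_id = seq_len(nrow(m)), gene = "ctrl", round_id = 0,
    channel_id = "CH_647", z = m[, 1], y = m[, 2], x = m[, 3],
    intensity = 1))
  ch1 <- mk(rbind(c(1, 1, 1), c(1, 11, 11)))
  ch2 <- mk(rbind(c(1, 1, 2)))
  res <- colocalization_efficiency(ch1, ch2)
  expect_equal(res$efficiency, 0.5)  # distances 1 and sqrt(200)
  expect_equal(res$n_colocalized, 1)

  expect_equal(colocalization_efficiency(ch1, ch1)$efficiency, 1.0)
  expect_error(colocalization_efficiency(spot_table(), ch2),
               "no reference dots")
})

test_that("colocalization equals the all-pairs oracle on random tables", {
  withr::with_seed(27, {
    mk <- function(n) spot_table(data.frame(
      spot_id = seq_len(n), gene = "ctrl", round_id = 0,
      channel_id = "CH_647", z = runif(n, 1, 9), y = runif(n, 1, 128),
      x = runif(n, 1, 128), intensity = 1))
    ch1 <- mk(500); ch2 <- mk(500)
    res <- colocalization_efficiency(ch1, ch2)
    # O(n^2) double-loop oracle
    hits <- 0L
    for (i in seq_len(nrow(ch1))) {
      best <- Inf
      for (j in seq_len(nrow(ch2))) {
        d <- sqrt((ch1$z[i] - ch2$z[j])^2 + (ch1$y[i] - ch2$y[j])^2 +
                    (ch1$x[i] - ch2$x[j])^2)
        if (d < best) best <- d
      }
      if (best <= 2) hits <- hits + 1L
    }
    expect_identical(res$n_colocalized, hits)

    # joint rigid translation of both channels leaves the result unchanged
    sh1 <- ch1; sh1$y <- sh1$y + 5.5; sh1$x <- sh1$x - 3.2
    sh2 <- ch2; sh2$y <- sh2$y + 5.5; sh2$x <- sh2$x - 3.2
    expect_equal(colocalization_efficiency(sh1, sh2)$efficiency,
                 res$efficiency)
  })
})
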
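test_that("ellipse fitting reproduces hand-derived rectangle geometry", {
  # axis-aligned filled rectangle, 10 px along y, 4 px along x
  m <- array(0L, c(1, 20, 20)); m[1, 5:14, 8:11] <- 1L
  e <- fit_ellipses(label_mask(m))
  expect_equal(nrow(e), 1)
  expect_equal(e$cy, 9.5); expect_equal(e$cx, 9.5)
  # extents along principal axes: max - min of projections = 9 and 3
  expect_equal(e$a, 9); expect_equal(e$b, 3)
  expect_equal(e$weight, sqrt(27))
  expect_equal(abs(e$uy), 1, tolerance = 1e-12)  # long axis along y
  expect_equal(e$weight^2, e$a * e$b)
})

test_that("near-circular masks give near-equal semi-axes", {
  m <- array(0L, c(1, 40, 40))
  for (y in 1:40) for (x in 1:40)
    if ((y - 20)^2 + (x - 20)^2 <= 64) m[1, y, x] <- 1L
  e <- fit_ellipses(label_mask(m))
  expect_lt(abs(e$a - e$b) / e$a, 0.1)
})

test_that("semi-axes are capped at the configured ceiling", {
  m <- array(0L, c(1, 60, 20)); m[1, 5:55, 9:11] <- 1L  # extent 50 along y
  e <- fit_ellipses(label_mask(m), max_semi_axis = 15)
  expect_equal(e$a, 15)
  e30 <- fit_ellipses(label_mask(m), max_semi_axis = 30)
  expect_equal(e30$a, 30)
})

test_that("tiny cross-sections fall back to isotropic ellipses", {
  m <- array(0L, c(2, 20, 20))
  m[1, 5, 5] <- 1L                 # single pixel
  m[2, 10, 10:11] <- 2L            # two collinear pixels
  e <- fit_ellipses(label_mask(m))
  expect_equal(e$a, e$b)
  expect_true(all(e$a > 0))
})

test_that("eligibility separates hard, soft and unassigned cases", {
  m <- array(0L, c(1, 40, 40)); m[1, 15:25, 15:25] <- 1L
  mask <- label_mask(m)
  ells <- fit_ellipses(mask)
  # on a mask pixel: hard
  el <- eligibility(c(1, 20, 20), mask, ells)
  expect_equal(el$containing, 1L)
  # outside the mask but inside the doubled ellipse: eligible
  el2 <- eligibility(c(1, 20, 28), mask, ells)
  expect_true(is.na(el2$containing))
  expect_equal(el2$eligible, 1L)
  # far beyond every ellipse: unassigned
  el3 <- eligibility(c(1, 2, 2), mask, ells)
  expect_length(el3$eligible, 0)
  expect_error(eligibility(c(9, 20, 20), mask, ells), "outside")
})

test_that("soft assignment reproduces hand-derived responsibilities", {
  one <- data.frame(label = 1, z = 1, cy = 5, cx = 5, a = 3, b = 2,
                    uy = 1, ux = 0, weight = sqrt(6))
  expect_equal(unname(soft_assign(c(1, 6, 5), one)), 1)

  # two identical circular nuclei equidistant from the spot: exactly 1/2
  twin <- data.frame(label = 1:2, z = 1, cy = 0, cx = c(0, 4), a = 3, b = 3,
                     uy = 1, ux = 0, weight = 3)
  r <- soft_assign(c(1, 0, 2), twin)
  expect_equal(unname(r), c(0.5, 0.5), tolerance = 1e-12)

  # circular nuclei sigma 2 at x=0 and sigma 4 at x=4, spot at x=1.5:
  # responsibilities from the weighted-density oracle
  pair <- data.frame(label = 1:2, z = 1, cy = 0, cx = c(0, 4),
                     a = c(2, 4), b = c(2, 4), uy = 1, ux = 0,
                     weight = c(2, 4))
  r2 <- soft_assign(c(1, 0, 1.5), pair)
  oracle <- gmm_oracle(c(0, 1.5), pair)
  expect_equal(unname(r2), oracle, tolerance = 1e-12)
  expect_equal(unname(r2), c(0.6473, 0.3527), tolerance = 1e-3)
})

test_that("responsibilities match the brute-force mixture oracle", {
  withr::with_seed(31, {
    worst <- 0
    for (rep in 1:50) {
      ells <- random_ellipses(sample(2:5, 1))
      for (s in 1:5) {
        spot <- c(1, runif(1, 5, 55), runif(1, 5, 55))
        r <- soft_assign(spot, ells)
        o <- gmm_oracle(spot[2:3], ells)
        worst <- max(worst, max(abs(r - o) / pmax(o, 1e-300)))
      }
    }
    expect_lt(worst, 1e-9)
  })
})

test_that("responsibilities are invariant to global weight scaling and
           equivariant under mirror reflection", {
  withr::with_seed(32, {
    ells <- random_ellipses(4)
    spot <- c(1, 30, 28)
    r <- soft_assign(spot, ells)
    # scaling all weights is a no-op because they normalize out; the weight
    # column itself is derived from (a, b), so scale via the oracle instead
    dens <- gmm_oracle(spot[2:3], ells)
    expect_equal(unname(r), dens, tolerance = 1e-9)
    # mirror the whole configuration about the y-axis (x -> -x)
    mir <- ells; mir$cx <- -mir$cx; mir$ux <- -mir$ux
    r_m <- soft_assign(c(1, 30, -28), mir)
    expect_equal(unname(r_m), unname(r), tolerance = 1e-9)
  })
})

test_that("the sqrt(ab) weighting pulls unequal nuclei toward parity", {
  # two concentric circular nuclei, spot at equal Mahalanobis distance
  ells <- data.frame(label = 1:2, z = 1, cy = 0, cx = 0, a = c(2, 6),
                     b = c(2, 6), uy = 1, ux = 0, weight = c(2, 6))
  spot_small <- c(1, 0, 2)   # 1 sigma from the small nucleus
  # evaluate at 1 sigma of each: compare responsibilities at x chosen so
  # Mahalanobis distance is 1 for both -> same point impossible; instead
  # test at a common point and compare with the unweighted mixture
  p <- c(1, 0, 3)
  weighted <- soft_assign(p, ells)
  unif <- ells; # uniform weights: densities only
  d1 <- stats::dnorm(3, 0, 2) * stats::dnorm(0, 0, 2)
  d2 <- stats::dnorm(3, 0, 6) * stats::dnorm(0, 0, 6)
  unweighted <- c(d1, d2) / (d1 + d2)
  # weighting must shrink the gap to parity for the larger nucleus
  expect_lt(abs(weighted[2] - 0.5), abs(unweighted[2] - 0.5))
})

test_that("assign_all conserves every spot, exactly per gene", {
  sim <- simulate_experiment(sim_config(seed = 41, n_nuclei = 8,
                                        n_genes = 4, shape = c(9, 96, 96)))
  tr <- sim$truth
  sp <- spot_table(tr$spots[, c("spot_id", "gene", "round_id", "channel_id",
                                "z", "y", "x", "intensity")])
  res <- assign_all(sp, tr$mask)
  genes <- colnames(res$matrix$values)
  input_per_gene <- table(factor(tr$spots$gene, levels = genes))
  got <- colSums(res$matrix$values) + res$unassigned[genes]
  expect_equal(unname(got), as.numeric(input_per_gene), tolerance = 1e-9)
  # status bookkeeping
  a <- res$assignments
  expect_true(all(a$status %in% c("hard", "soft", "unassigned")))
  expect_true(all(is.na(a$label[a$status == "unassigned"])))
  # soft probabilities sum to 1 per spot
  pr <- res$probabilities
  sums <- tapply(pr$prob, pr$spot_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("no nuclei means every spot is unassigned", {
  m <- label_mask(array(0L, c(3, 20, 20)))
  sp <- spot_table(data.frame(spot_id = 1:3, gene = "g", round_id = 0,
                              channel_id = "CH_647", z = 2, y = 10,
                              x = c(5, 10, 15), intensity = 1))
  res <- assign_all(sp, m)
  expect_true(all(res$assignments$status == "unassigned"))
  expect_equal(nrow(res$matrix$values), 0)
})

test_that("generative recovery: hard spots perfect, perinuclear spots >= 90%", {
  sim <- simulate_experiment(sim_config(seed = 1))
  tr <- sim$truth
  sp <- spot_table(tr$spots[, c("spot_id", "gene", "round_id", "channel_id",
                                "z", "y", "x", "intensity")])
  res <- assign_all(sp, tr$mask)
  a <- res$assignments
  hard <- a$status == "hard"; soft <- a$status == "soft"
  expect_equal(mean(a$label[hard] == tr$spots$true_label[hard]), 1.0)
  expect_gte(mean(a$label[soft] == tr$spots$true_label[soft]), 0.9)
  # per-cell totals track the truth closely when assigning true positions
  soft_tot <- rowSums(res$matrix$values)
  true_tot <- rowSums(tr$matrix$values)
  expect_lte(sqrt(mean((soft_tot - true_tot)^2)) / mean(true_tot), 0.15)
})
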
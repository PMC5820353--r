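test_that("difference of Gaussians of a constant image is zero", {
  a <- array(1234L, c(10L, 12L, 14L))
  d <- difference_of_gaussians(a)
  expect_true(all(d == 0))
})

test_that("DoG of an impulse matches a direct convolution oracle", {
  n <- 21L
  a <- array(0, c(n, n, n))
  a[11, 11, 11] <- 1000
  d <- difference_of_gaussians(a, c(0.7, 2.0))
  # oracle: explicit separable kernel evaluation, no edge effects at center
  kern <- function(sigma) {
    r <- max(1L, ceiling(4 * sigma))
    w <- dnorm(-r:r, sd = sigma)
    w / sum(w)
  }
  smooth1 <- function(x, w) {
    r <- (length(w) - 1L) %/% 2L
    out <- array(0, dim(x))
    for (k in -r:r) {
      sl <- pmin(pmax(seq_len(n) + k, 1L), n) # only exact away from edges
      out <- out + w[k + r + 1L] * x[sl, , ]
    }
    out
  }
  oracle <- function(sigma) {
    w <- kern(sigma)
    x <- smooth1(a, w)
    x <- aperm(smooth1(aperm(x, c(2, 3, 1)), w), c(3, 1, 2))
    aperm(smooth1(aperm(x, c(3, 1, 2)), w), c(2, 3, 1))
  }
  ref <- oracle(0.7) - oracle(2.0)
  ref[ref < 0] <- 0
  ref <- ref * (2^16 - 1) / max(ref)
  ctr <- 9:13 # fully interior windows, identical edge handling
  expect_gt(d[11, 11, 11], 0)
  expect_equal(d[ctr, ctr, ctr], ref[ctr, ctr, ctr], tolerance = 1e-6)
})

test_that("DoG response peaks at the center of a Gaussian blob", {
  n <- 25L
  g <- dnorm(seq_len(n), mean = 13, sd = 1)
  a <- outer(outer(g, g), g) * 1e6
  d <- difference_of_gaussians(array(a, c(n, n, n)))
  expect_equal(arrayInd(which.max(d), c(n, n, n))[1, ], c(13L, 13L, 13L))
})

test_that("Ridler-Calvard finds the midpoint of a two-level histogram", {
  x <- c(rep(10, 500), rep(20, 500))
  rc <- ridler_calvard_threshold(x)
  expect_false(rc$degenerate)
  expect_equal(rc$threshold, 15)
})

test_that("Ridler-Calvard flags constant images as degenerate", {
  rc <- ridler_calvard_threshold(array(7L, c(4, 4, 4)))
  expect_true(rc$degenerate)
  expect_equal(rc$threshold, 7)
})

test_that("Ridler-Calvard agrees with an exhaustive fixed-point search", {
  set.seed(42)
  for (i in 1:1000) {
    # random bimodal-ish 8-bit histogram
    n1 <- sample(50:200, 1); n2 <- sample(50:200, 1)
    x <- round(c(rnorm(n1, runif(1, 30, 90), runif(1, 5, 25)),
                 rnorm(n2, runif(1, 120, 220), runif(1, 5, 25))))
    x <- pmin(pmax(x, 0), 255)
    rc <- ridler_calvard_threshold(x)
    # oracle: scan every integer split level for ISODATA fixed points
    fp <- c()
    for (s in min(x):(max(x) - 1)) {
      lo <- x[x <= s]; hi <- x[x > s]
      if (!length(lo) || !length(hi)) next
      m <- (mean(lo) + mean(hi)) / 2
      if (floor(m) == s || abs(m - s) < 0.5) fp <- c(fp, m)
    }
    expect_true(any(abs(rc$threshold - fp) < 1),
                label = sprintf("case %d: T=%.2f fixed points %s", i,
                                rc$threshold, paste(round(fp, 2),
                                                    collapse = ",")))
  }
})

test_that("size gate keeps only volumes inside the window", {
  vv <- 0.267 * 0.267 * 0.25 # 0.017822 um^3
  expect_false(size_gate(2 * vv)) # 0.0356
  expect_true(size_gate(3 * vv)) # 0.0535
  expect_true(size_gate(39 * vv)) # 0.695
  expect_false(size_gate(40 * vv)) # 0.713
})

test_that("an isolated in-gate blob equals single-threshold segmentation", {
  dims <- c(12L, 24L, 24L)
  f <- array(0, dims)
  f[5:7, 10:12, 10:12] <- 5000 # 27 voxels, 0.48 um^3
  masks <- iterative_segmentation(f, t0 = 1000, channel = "vgat")
  expect_equal(nrow(masks), 1L)
  ref <- oracle_segment_at(f, 1000)
  expect_setequal(
    gadpuncta:::vox_linear(masks$voxels[[1]], dims),
    ref[[1]]
  )
})

test_that("threshold laddering splits bridged blobs into two masks", {
  dims <- c(12L, 40L, 24L)
  f <- array(0, dims)
  f[5:7, 8:10, 10:12] <- 5000   # blob A: 27 voxels (in gate alone)
  f[5:7, 20:22, 10:12] <- 5000  # blob B: 27 voxels
  f[6, 11:19, 11] <- 1010       # dim bridge joins them at t0
  # at t0 = 1000: one 63-voxel component (1.1 um^3, over the gate)
  masks <- iterative_segmentation(f, t0 = 1000, channel = "vgat")
  # oracle: exhaustive scan over the +25 ladder finds the first threshold
  # at which components fall inside the gate
  found <- list()
  for (t in seq(1000, 65535, by = 25)) {
    found <- oracle_segment_at(f, t)
    if (length(found)) break
  }
  expect_equal(nrow(masks), 2L)
  expect_equal(length(found), 2L)
  got <- lapply(masks$voxels, gadpuncta:::vox_linear, dims = dims)
  expect_setequal(sort(unlist(got)), sort(unlist(found)))
})

test_that("empty images produce no masks", {
  masks <- iterative_segmentation(array(0, c(8, 10, 10)), channel = "vgat")
  expect_equal(nrow(masks), 0L)
})

test_that("all returned masks satisfy the gate and are voxel-disjoint", {
  cfg <- quick_config(seed = 31, field = 96L, density = 5)
  st <- render_stack(generate_scene(cfg), cfg)
  masks <- segment_channel(st, "vgat")
  expect_true(all(size_gate(masks$volume_um3)))
  lin <- unlist(lapply(masks$voxels, gadpuncta:::vox_linear,
                       dims = dim(st$channels$vgat)))
  expect_equal(anyDuplicated(lin), 0L)
})

test_that("noise-free well-separated blobs are recovered one-for-one", {
  for (s in 1:10) {
    cfg <- clean_config(seed = s, density = 2)
    sc <- generate_scene(cfg)
    # keep blobs fully represented in the volume (the real pipeline's crop
    # and depth QC serve this purpose)
    sc$puncta <- dplyr::filter(
      sc$puncta,
      z_um > 1, z_um < cfg$n_zplanes * 0.25 - 1,
      y_um > 1, y_um < cfg$field_size_px[1] * 0.267 - 1,
      x_um > 1, x_um < cfg$field_size_px[2] * 0.267 - 1
    )
    st <- render_stack(sc, cfg)
    masks <- segment_channel(st, "vgat")
    expect_equal(nrow(masks), nrow(sc$puncta))
    # match each truth center to nearest mask centroid, in voxel units
    if (nrow(sc$puncta)) {
      tz <- sc$puncta$z_um / 0.25 - 0.5
      ty <- sc$puncta$y_um / 0.267 - 0.5
      tx <- sc$puncta$x_um / 0.267 - 0.5
      for (i in seq_len(nrow(sc$puncta))) {
        d <- sqrt((masks$cz - tz[i])^2 + (masks$cy - ty[i])^2 +
                    (masks$cx - tx[i])^2)
        expect_lt(min(d), 1)
      }
    }
  }
})

test_that("threshold step size does not inflate counts on clean scenes", {
  cfg <- clean_config(seed = 77, density = 2)
  sc <- generate_scene(cfg)
  st <- render_stack(sc, cfg)
  filt <- difference_of_gaussians(st$channels$vgat)
  counts <- vapply(c(5, 25, 100), function(step) {
    nrow(iterative_segmentation(
      filt, segmentation_params(threshold_step = step), channel = "vgat"
    ))
  }, numeric(1))
  # on resolvable scenes the step size must not create or destroy puncta
  expect_equal(length(unique(counts)), 1L)
  expect_lte(counts[1], nrow(sc$puncta))
})
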
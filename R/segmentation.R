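#' Segmentation parameters
#'
#' @param dog_sigmas Small and large Gaussian sigmas (pixels) for the
#'   difference-of-Gaussians band-pass used to build the segmentation channel.
#' @param threshold_step Gray-level increment between successive threshold
#'   iterations.
#' @param size_gate_um3 Minimum and maximum accepted object volume in um^3.
#' @param connectivity 3D neighborhood: 26 (default) or 6.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(dog_sigmas = c(0.7, 2.0),
                                threshold_step = 25,
                                size_gate_um3 = c(0.05, 0.7),
                                connectivity = 26L) {
  if (dog_sigmas[1] >= dog_sigmas[2]) abort("dog_sigmas must be increasing.")
  if (size_gate_um3[1] >= size_gate_um3[2]) abort("size gate min must be < max.")
  if (threshold_step < 1) abort("threshold_step must be >= 1.")
  if (!connectivity %in% c(6L, 26L)) abort("connectivity must be 6 or 26.")
  structure(list(dog_sigmas = dog_sigmas, threshold_step = threshold_step,
                 size_gate_um3 = size_gate_um3,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

# separable 3D Gaussian smoothing of a (z, y, x) array; truncated at 4 sigma
# with per-voxel edge renormalization, so constant inputs are reproduced
# exactly (the difference of Gaussians of a constant is identically zero)
gaussian_smooth3d <- function(a, sigma) {
  d <- dim(a)
  .gaussian_smooth3d_cpp(as.numeric(a), as.integer(d), sigma)
}

#' Difference-of-Gaussians segmentation channel
#'
#' Smooths the channel with two Gaussians (sigmas in pixels, applied along
#' all three axes), subtracts the wide from the narrow, clips negative values
#' to zero, and rescales linearly so the maximum maps to the top of the bit
#' depth. The rescaling keeps the fixed gray-level threshold step meaningful
#' on the filtered data. The output is used for segmentation only; intensity
#' measurements are always taken on the unfiltered channels.
#'
#' @param channel 3D integer array (z, y, x).
#' @param sigmas Two increasing sigmas in pixels.
#' @param bit_depth Output scale; maximum output is `2^bit_depth - 1`.
#' @return 3D numeric array of the same shape, values in `[0, 2^bit_depth-1]`.
#' @export
difference_of_gaussians <- function(channel, sigmas = c(0.7, 2.0),
                                    bit_depth = 16L) {
  if (length(dim(channel)) != 3L) abort("`channel` must be a 3D array.")
  if (sigmas[1] >= sigmas[2]) abort("sigmas must be increasing.")
  # single fused pass: smooth with both kernels, subtract, clip negatives,
  # rescale so the maximum maps to the top of the bit depth; a response at
  # numerical-noise scale (constant input) comes back as all zeros rather
  # than floating-point dust blown up to full range
  .dog3d_cpp(as.numeric(channel), as.integer(dim(channel)),
             sigmas[1], sigmas[2], 2^bit_depth - 1)
}

#' Ridler-Calvard (ISODATA) threshold
#'
#' Iterates `T <- (mean(x[x <= T]) + mean(x[x > T])) / 2` from the global mean
#' until the update is below 0.5 gray levels (at most 100 iterations). The
#' fixed point splits the histogram so the threshold is midway between the
#' below- and above-threshold means.
#'
#' Intensities are binned at integer gray-level resolution (matching the
#' camera's quantization), which makes each iteration O(1) on the cumulative
#' histogram.
#'
#' @param x Numeric array or vector of gray levels.
#' @return A list with `threshold`, `degenerate` (TRUE when the image is
#'   constant, in which case the threshold equals that constant), and
#'   `iterations`.
#' @export
ridler_calvard_threshold <- function(x) {
  if (!length(x)) abort("empty input.")
  x <- round(as.numeric(x))
  lo_val <- min(x)
  if (max(x) == lo_val) {
    return(list(threshold = lo_val, degenerate = TRUE, iterations = 0L))
  }
  # histogram over gray levels lo_val..max, O(1) class means per iteration
  h <- tabulate(x - lo_val + 1L, nbins = max(x) - lo_val + 1L)
  g <- seq.int(lo_val, max(x))
  cn <- cumsum(h)
  cs <- cumsum(h * g)
  n <- cn[length(cn)]
  s <- cs[length(cs)]
  t_cur <- s / n # global mean
  for (it in seq_len(100L)) {
    split <- floor(t_cur) - lo_val + 1L
    i <- min(length(g), max(1L, split))
    n_lo <- cn[i]
    if (n_lo == 0L || n_lo == n) break
    mu_lo <- cs[i] / n_lo
    mu_hi <- (s - cs[i]) / (n - n_lo)
    t_new <- (mu_lo + mu_hi) / 2
    # converged when the update is sub-half-gray AND the integer split level
    # is self-consistent (a true fixed point of the discrete iteration)
    converged <- abs(t_new - t_cur) < 0.5 &&
      floor(t_new) - lo_val + 1L == i
    t_cur <- t_new
    if (converged) {
      return(list(threshold = t_cur, degenerate = FALSE, iterations = it))
    }
  }
  list(threshold = t_cur, degenerate = FALSE, iterations = 100L)
}

# 26- or 6-connected components over a set of linear voxel indices;
# returns an integer membership vector parallel to `idx`
label_components <- function(idx, dims, connectivity = 26L) {
  if (!length(idx)) return(integer(0))
  .label_components_cpp(as.numeric(idx), as.integer(dims),
                        as.integer(connectivity))
}

#' Volume-based size gate
#'
#' An object is kept when its volume (voxel count times voxel volume) lies
#' inside the closed gate interval.
#'
#' @param volume_um3 Object volume(s) in um^3.
#' @param gate Length-2 numeric, minimum and maximum volume in um^3.
#' @return Logical vector: keep (TRUE) or reject (FALSE).
#' @export
size_gate <- function(volume_um3, gate = c(0.05, 0.7)) {
  volume_um3 >= gate[1] & volume_um3 <= gate[2]
}

#' Iterative multi-threshold segmentation
#'
#' Thresholds the filtered channel at the seed threshold and labels connected
#' components. Components inside the size gate are accepted and frozen;
#' components above the gate are recursively re-thresholded at successively
#' higher thresholds (step `threshold_step`) within their own voxel set until
#' the pieces fall inside the gate or the threshold exceeds the bit-depth
#' maximum (unsplittable over-gate components are discarded); components
#' below the gate minimum are discarded. Accepted masks are voxel-disjoint by
#' construction.
#'
#' @param filtered 3D numeric array from [difference_of_gaussians()].
#' @param params A [segmentation_params()].
#' @param voxel_size_um Voxel size (x, y, z) in um.
#' @param t0 Seed threshold; defaults to the Ridler-Calvard threshold of
#'   `filtered`.
#' @param channel Channel name recorded on the masks.
#' @param bit_depth Gray-level ceiling for the threshold ladder.
#' @return A mask table: tibble with one row per accepted mask and columns
#'   `mask_id`, `channel`, `n_vox`, `volume_um3`, 0-based voxel centroid
#'   columns `cz`, `cy`, `cx`, `threshold`, and a list-column `voxels` of
#'   1-based (z, y, x) index matrices.
#' @export
iterative_segmentation <- function(filtered, params = segmentation_params(),
                                   voxel_size_um = c(0.267, 0.267, 0.25),
                                   t0 = NULL, channel = "channel",
                                   bit_depth = 16L) {
  dims <- dim(filtered)
  if (length(dims) != 3L) abort("`filtered` must be a 3D array.")
  vox_vol <- voxel_volume_um3(voxel_size_um)
  gate <- params$size_gate_um3
  step <- params$threshold_step
  tmax <- 2^bit_depth - 1
  if (is.null(t0)) {
    rc <- ridler_calvard_threshold(filtered)
    if (rc$degenerate) {
      return(empty_mask_table(channel))
    }
    t0 <- rc$threshold
  }

  accepted <- list()
  # stack of (voxel index set, threshold) work items; per-component recursion.
  # Threshold steps that drop no voxel of a component cannot change it, so
  # each over-gate component jumps to the first step-multiple threshold that
  # removes at least one voxel -- identical results, far fewer labelings.
  work <- list(list(idx = which(filtered > t0), t = t0))
  while (length(work)) {
    item <- work[[length(work)]]
    work[[length(work)]] <- NULL
    idx <- item$idx
    if (!length(idx)) next
    memb <- label_components(idx, dims, params$connectivity)
    for (comp in split(idx, memb)) {
      vol <- length(comp) * vox_vol
      if (vol < gate[1]) next
      if (vol <= gate[2]) {
        accepted[[length(accepted) + 1L]] <-
          list(idx = comp, t = item$t)
      } else {
        vmin <- min(filtered[comp])
        k <- max(1, ceiling((vmin - item$t) / step))
        t_next <- item$t + k * step
        if (t_next <= tmax) {
          work[[length(work) + 1L]] <-
            list(idx = comp[filtered[comp] > t_next], t = t_next)
        }
      }
    }
  }
  if (!length(accepted)) return(empty_mask_table(channel))
  vox_list <- lapply(accepted, function(comp) {
    vox <- arrayInd(comp$idx, dims)
    colnames(vox) <- c("z", "y", "x")
    vox
  })
  cen <- vapply(vox_list, colMeans, numeric(3)) - 1 # 0-based centroids
  n_vox <- vapply(vox_list, nrow, integer(1))
  tibble(
    mask_id = seq_along(accepted), channel = channel,
    n_vox = n_vox, volume_um3 = n_vox * vox_vol,
    cz = cen[1, ], cy = cen[2, ], cx = cen[3, ],
    threshold = vapply(accepted, `[[`, numeric(1), "t"),
    voxels = vox_list
  )
}

empty_mask_table <- function(channel = character(0)) {
  tibble(
    mask_id = integer(), channel = character(), n_vox = integer(),
    volume_um3 = double(), cz = double(), cy = double(), cx = double(),
    threshold = double(), voxels = list()
  )
}

#' Measure mask intensities on the unfiltered channels
#'
#' For each mask, sums and averages the raw (non-filtered) intensity of every
#' stack channel over the mask's voxels. The sum reflects the total amount of
#' protein in the terminal-scale object; the mean reflects its concentration
#' (relative amount).
#'
#' @param masks A mask table from [iterative_segmentation()].
#' @param stack The [voxel_stack()] the masks were segmented from.
#' @return The mask table with added columns `sum_<channel>` and
#'   `mean_<channel>` for each of the five channels.
#' @export
measure_masks <- function(masks, stack) {
  stopifnot(inherits(stack, "voxel_stack"))
  dims <- dim(stack$channels[[1]])
  for (ch in gp_channels) {
    a <- stack$channels[[ch]]
    sums <- vapply(masks$voxels, function(vox) {
      idx <- vox[, 1] + (vox[, 2] - 1) * dims[1] +
        (vox[, 3] - 1) * dims[1] * dims[2]
      sum(as.numeric(a[idx]))
    }, numeric(1))
    masks[[paste0("sum_", ch)]] <- sums
    masks[[paste0("mean_", ch)]] <- sums / masks$n_vox
  }
  masks
}

#' Segment one channel of a stack end to end
#'
#' Convenience wrapper: difference-of-Gaussians, Ridler-Calvard seed
#' threshold, iterative size-gated segmentation, then intensity measurement
#' on the raw channels.
#'
#' @inheritParams measure_masks
#' @param channel Channel name to segment (one of [gp_channels], not
#'   `"lipofuscin"`, which is masked without a size gate by
#'   [mask_lipofuscin()]).
#' @param params A [segmentation_params()].
#' @return A measured mask table.
#' @export
segment_channel <- function(stack, channel, params = segmentation_params()) {
  stopifnot(inherits(stack, "voxel_stack"))
  filtered <- difference_of_gaussians(stack$channels[[channel]],
                                      params$dog_sigmas, stack$bit_depth)
  masks <- iterative_segmentation(
    filtered, params, voxel_size_um = stack$voxel_size_um,
    channel = channel, bit_depth = stack$bit_depth
  )
  measure_masks(masks, stack)
}
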
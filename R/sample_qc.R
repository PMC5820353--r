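#' Keep masks whose centers fall in the central XY analysis window
#'
#' Restricting analysis to the central `crop_px` x `crop_px` pixels (490 of
#' 512 by default) guarantees every retained object is fully represented in
#' the imaged volume.
#'
#' @param masks A mask table (0-based centroid columns `cy`, `cx`).
#' @param field_size Field size in pixels, `(y, x)` or a single value.
#' @param crop_px Side of the centered analysis window, default 490.
#' @return The filtered mask table. Idempotent; never adds masks.
#' @export
crop_xy <- function(masks, field_size = c(512L, 512L), crop_px = 490L) {
  if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
  if (any(field_size < crop_px)) {
    abort(sprintf("field (%s px) smaller than the %d px analysis window.",
                  paste(field_size, collapse = "x"), crop_px))
  }
  my <- (field_size[1] - crop_px) / 2
  mx <- (field_size[2] - crop_px) / 2
  masks |>
    filter(.data$cy >= my, .data$cy < field_size[1] - my,
           .data$cx >= mx, .data$cx < field_size[2] - mx)
}

#' Normalize a z position onto the 40-bin depth scale
#'
#' Stacks have varying plane counts, so object depth is rescaled onto a
#' common 40-bin axis: `normalized = z * 40 / n_zplanes`, and the bin is
#' `floor(normalized) + 1` (bins 1..40).
#'
#' @param z_centroid 0-based (possibly fractional) z position(s), in
#'   `[0, n_zplanes)`.
#' @param n_zplanes Number of z planes in the stack.
#' @return A tibble with columns `normalized` and `bin`.
#' @export
normalize_z <- function(z_centroid, n_zplanes) {
  if (n_zplanes < 1) abort("`n_zplanes` must be >= 1.")
  if (any(z_centroid < 0 | z_centroid >= n_zplanes)) {
    abort("`z_centroid` must lie in [0, n_zplanes).")
  }
  normalized <- z_centroid * 40 / n_zplanes
  tibble(normalized = normalized,
         bin = pmin(40L, as.integer(floor(normalized)) + 1L))
}

#' Per-stack depth-bin profiles of object counts and intensities
#'
#' For each stack and channel, places every mask into one of 40 normalized
#' depth bins and records the object count and the mean (over objects) of the
#' mask mean intensity on its own channel.
#'
#' @param mask_tables Named list (by stack id) of measured mask tables, each
#'   covering one or more channels.
#' @param n_zplanes Named vector or single value: z-plane count per stack.
#' @return Tibble with columns `stack_id`, `channel`, `bin`, `n_objects`,
#'   `mean_intensity` (NA in empty bins).
#' @export
zbin_profile <- function(mask_tables, n_zplanes) {
  stacks <- names(mask_tables)
  if (is.null(stacks)) stacks <- as.character(seq_along(mask_tables))
  if (length(n_zplanes) == 1L) {
    n_zplanes <- setNames(rep(n_zplanes, length(stacks)), stacks)
  }
  rows <- purrr::map2(mask_tables, stacks, function(mt, sid) {
    if (!nrow(mt)) return(NULL)
    bins <- normalize_z(mt$cz, n_zplanes[[sid]])$bin
    own <- vapply(seq_len(nrow(mt)), function(i) {
      mt[[paste0("mean_", mt$channel[i])]][i]
    }, numeric(1))
    tibble(stack_id = sid, channel = mt$channel, bin = bins, intensity = own)
  })
  obs <- bind_rows(rows)
  if (!nrow(obs)) {
    return(tibble(stack_id = character(), channel = character(),
                  bin = integer(), n_objects = integer(),
                  mean_intensity = double()))
  }
  grid <- tidyr::expand_grid(
    stack_id = stacks,
    channel = unique(obs$channel),
    bin = 1:40
  )
  obs |>
    group_by(.data$stack_id, .data$channel, .data$bin) |>
    summarise(n_objects = dplyr::n(),
              mean_intensity = mean(.data$intensity), .groups = "drop") |>
    dplyr::right_join(grid, by = c("stack_id", "channel", "bin")) |>
    mutate(n_objects = tidyr::replace_na(.data$n_objects, 0L)) |>
    arrange(.data$stack_id, .data$channel, .data$bin)
}

#' Select the unbiased range of depth bins
#'
#' For each tested channel and metric (object counts per bin for
#' `count_channels`; mean object intensity per bin for `intensity_channels`),
#' runs a one-way ANOVA across the 40 depth bins with stacks as replicates;
#' when the omnibus test is significant at `alpha`, Tukey HSD pairwise
#' comparisons identify bin pairs that differ. The selected window is the
#' longest contiguous run of bins containing no significant pair for any
#' channel or metric, with ties broken toward the coverslip (lower bins).
#' This controls z-edge effects, antibody penetration gradients, and
#' fluorochrome differences.
#'
#' @param profiles Output of [zbin_profile()] over at least two stacks.
#' @param alpha Significance level for ANOVA and Tukey HSD.
#' @param count_channels Channels whose per-bin object counts are tested.
#' @param intensity_channels Channels whose per-bin mean object intensity is
#'   tested (vGAT and GAD67 by default).
#' @return A `zbin_selection`: list with `z_bins` (contiguous integer bin
#'   range), `sig_pairs` (tibble of significant bin pairs with their family),
#'   and `alpha`.
#' @export
select_zbins <- function(profiles, alpha = 0.05,
                         count_channels = c("marker", "vgat", "gad65", "gad67"),
                         intensity_channels = c("vgat", "gad67")) {
  n_stacks <- length(unique(profiles$stack_id))
  if (n_stacks < 2L) abort("bin selection needs at least 2 replicate stacks.")
  present <- unique(profiles$channel)
  fams <- bind_rows(
    tibble(channel = intersect(count_channels, present), metric = "count"),
    tibble(channel = intersect(intensity_channels, present),
           metric = "intensity")
  )
  sig <- list()
  for (i in seq_len(nrow(fams))) {
    ch <- fams$channel[i]; met <- fams$metric[i]
    d <- profiles |> filter(.data$channel == ch)
    if (met == "count") {
      d <- d |> mutate(value = as.numeric(.data$n_objects))
    } else {
      d <- d |> mutate(value = .data$mean_intensity) |>
        filter(!is.na(.data$value))
    }
    # bins with fewer than 2 replicates cannot be tested
    ok_bins <- d |> dplyr::count(.data$bin) |> filter(.data$n >= 2L) |>
      pull(.data$bin)
    d <- d |> filter(.data$bin %in% ok_bins)
    if (length(unique(d$bin)) < 2L) next
    a <- oneway_anova(d, value = "value", group = "bin")
    if (a$degenerate || is.na(a$p_value) || a$p_value >= alpha) next
    tk <- tukey_hsd(d, value = "value", group = "bin", alpha = alpha)
    pr <- tk$comparisons |> filter(.data$significant)
    if (nrow(pr)) {
      sig[[length(sig) + 1L]] <- tibble(
        channel = ch, metric = met,
        bin_a = as.integer(as.character(pr$group1)),
        bin_b = as.integer(as.character(pr$group2))
      )
    }
  }
  sig <- if (length(sig)) bind_rows(sig) else
    tibble(channel = character(), metric = character(),
           bin_a = integer(), bin_b = integer())
  run <- longest_clean_run(sig, n_bins = 40L)
  if (is.null(run) || length(run) < 3L) {
    abort("no contiguous run of at least 3 compatible depth bins; inspect the profiles.")
  }
  structure(list(z_bins = run, sig_pairs = sig, alpha = alpha),
            class = "zbin_selection")
}

# longest contiguous 1..n_bins run containing no significant pair; ties go to
# the lower (coverslip-side) start
longest_clean_run <- function(sig_pairs, n_bins = 40L) {
  bad <- matrix(FALSE, n_bins, n_bins)
  if (nrow(sig_pairs)) {
    ii <- pmin(sig_pairs$bin_a, sig_pairs$bin_b)
    jj <- pmax(sig_pairs$bin_a, sig_pairs$bin_b)
    bad[cbind(ii, jj)] <- TRUE
  }
  best <- NULL
  for (a in seq_len(n_bins)) {
    b <- a
    while (b < n_bins && !any(bad[a:b, b + 1L])) b <- b + 1L
    if (is.null(best) || (b - a) > (best[2] - best[1])) best <- c(a, b)
  }
  if (is.null(best)) return(NULL)
  best[1]:best[2]
}

#' @export
print.zbin_selection <- function(x, ...) {
  cat("<zbin_selection> bins", min(x$z_bins), "-", max(x$z_bins),
      sprintf("(%d of 40), alpha = %g, %d significant pair(s)\n",
              length(x$z_bins), x$alpha, nrow(x$sig_pairs)))
  invisible(x)
}

#' Keep masks whose depth bin lies in the selected window
#'
#' @param masks Mask table.
#' @param selection A `zbin_selection` from [select_zbins()], or an integer
#'   vector of bins.
#' @param n_zplanes Plane count of the stack the masks came from.
#' @return Filtered mask table.
#' @export
apply_zbin_window <- function(masks, selection, n_zplanes) {
  bins <- if (inherits(selection, "zbin_selection")) selection$z_bins else selection
  if (!nrow(masks)) return(masks)
  b <- normalize_z(masks$cz, n_zplanes)$bin
  masks[b %in% bins, , drop = FALSE]
}

#' Mask lipofuscin autofluorescence
#'
#' Lipofuscin fluoresces across the visible spectrum, so it is imaged in a
#' dedicated channel and masked by Ridler-Calvard thresholding plus connected
#' components, with no size gate (blobs of any size are masked). The channel
#' is lightly Gaussian-smoothed first so the threshold separates the blob
#' population from camera noise rather than splitting the noise itself.
#' Because the threshold assumes a bright sparse population over background,
#' channels in which the above-threshold fraction exceeds
#' `max_foreground_frac` are treated as lipofuscin-free (the threshold landed
#' inside the noise).
#'
#' @param channel 3D integer array: the lipofuscin channel.
#' @param voxel_size_um Voxel size (x, y, z) in um.
#' @param connectivity 26 (default) or 6.
#' @param smooth_sigma Gaussian sigma (pixels) for pre-threshold noise
#'   suppression; 0 disables smoothing.
#' @param max_foreground_frac Sanity ceiling on the above-threshold volume
#'   fraction.
#' @return A mask table (channel `"lipofuscin"`).
#' @export
mask_lipofuscin <- function(channel, voxel_size_um = c(0.267, 0.267, 0.25),
                            connectivity = 26L, smooth_sigma = 2,
                            max_foreground_frac = 0.05) {
  sm <- if (smooth_sigma > 0) {
    gaussian_smooth3d(channel, smooth_sigma)
  } else channel
  rc <- ridler_calvard_threshold(sm)
  if (rc$degenerate) return(empty_mask_table("lipofuscin"))
  idx <- which(sm > rc$threshold)
  if (length(idx) > max_foreground_frac * length(channel)) {
    return(empty_mask_table("lipofuscin"))
  }
  dims <- dim(channel)
  memb <- label_components(idx, dims, connectivity)
  vox_vol <- voxel_volume_um3(voxel_size_um)
  comps <- split(idx, memb)
  rows <- lapply(seq_along(comps), function(i) {
    vox <- arrayInd(comps[[i]], dims)
    colnames(vox) <- c("z", "y", "x")
    cen <- colMeans(vox) - 1
    tibble(mask_id = i, channel = "lipofuscin",
           n_vox = nrow(vox), volume_um3 = nrow(vox) * vox_vol,
           cz = cen[["z"]], cy = cen[["y"]], cx = cen[["x"]],
           threshold = rc$threshold, voxels = list(vox))
  })
  bind_rows(rows)
}

#' Remove masks that touch a lipofuscin mask
#'
#' Any mask sharing at least one voxel with any lipofuscin mask is
#' eliminated; masks are never edited, only dropped.
#'
#' @param masks Mask table to filter.
#' @param lipo_masks Lipofuscin mask table from [mask_lipofuscin()].
#' @param dims Volume dimensions (z, y, x), needed to index voxels.
#' @return Filtered mask table. Idempotent and monotone.
#' @export
exclude_lipofuscin <- function(masks, lipo_masks, dims) {
  if (!nrow(masks) || !nrow(lipo_masks)) return(masks)
  lin <- function(vox) {
    vox[, 1] + (vox[, 2] - 1) * dims[1] + (vox[, 3] - 1) * dims[1] * dims[2]
  }
  lipo_set <- unique(unlist(lapply(lipo_masks$voxels, lin)))
  hit <- vapply(masks$voxels, function(vox) any(lin(vox) %in% lipo_set),
                logical(1))
  masks[!hit, , drop = FALSE]
}
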
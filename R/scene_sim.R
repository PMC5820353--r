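#' Generate the ground truth for one synthetic scene
#'
#' Draws a Poisson number of terminals for the configured density, places
#' their centers uniformly in the field subject to a minimum center-to-center
#' spacing (rejection sampling), assigns each terminal a GAD content class
#' from the configured mixture, and draws per-class true volumes and true
#' integrated channel intensities. All channels of one terminal share the
#' same center, mirroring the center-overlap classification rule. Lipofuscin
#' blobs are placed independently.
#'
#' @param config A [scene_config()].
#' @return A `scene_truth` object: list with `puncta` (tibble, one row per
#'   terminal: center in um, volume, `gad_class`, true integrated intensity
#'   per channel), `lipofuscin` (tibble of blob centers, radii, intensities)
#'   and the `config`. A `GAD65` terminal has zero true GAD67 intensity and
#'   vice versa.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    ext_um <- c(
      x = config$field_size_px[2] * config$voxel_size_um[1],
      y = config$field_size_px[1] * config$voxel_size_um[2],
      z = config$n_zplanes * config$voxel_size_um[3]
    )
    vol_um3 <- prod(ext_um)
    n <- rpois(1L, config$density_per_1000um3 * vol_um3 / 1000)
    centers <- place_centers(n, ext_um, config$min_spacing_um,
                             config$density_per_1000um3)
    if (n > 0) {
      cls <- sample(gp_gad_classes, n, replace = TRUE, prob = config$gad_mixture)
      vols <- draw_volumes(cls, config$volume_params)
      ints <- draw_intensities(cls, config$intensity_params,
                               volumes = vols,
                               volume_params = config$volume_params)
      puncta <- tibble(
        punctum_id = seq_len(n),
        x_um = centers[, 1], y_um = centers[, 2], z_um = centers[, 3],
        volume_um3 = vols,
        gad_class = cls
      ) |> dplyr::bind_cols(ints)
    } else {
      puncta <- tibble(
        punctum_id = integer(), x_um = double(), y_um = double(),
        z_um = double(), volume_um3 = double(), gad_class = character(),
        int_marker = double(), int_vgat = double(),
        int_gad65 = double(), int_gad67 = double()
      )
    }
    n_lipo <- rpois(1L, config$lipofuscin_density * vol_um3 / 1000)
    lipofuscin <- tibble(
      blob_id = seq_len(n_lipo),
      x_um = runif(n_lipo, 0, ext_um["x"]),
      y_um = runif(n_lipo, 0, ext_um["y"]),
      z_um = runif(n_lipo, 0, ext_um["z"]),
      radius_um = pmax(0.4, rnorm(n_lipo, 1.0, 0.2)),
      intensity = rep(config$lipofuscin_intensity, n_lipo)
    )
    structure(
      list(puncta = puncta, lipofuscin = lipofuscin, config = config),
      class = "scene_truth"
    )
  })
}

# sequential placement with a cell-hash neighbor check; errors if the
# requested density cannot be packed at the configured spacing
place_centers <- function(n, ext_um, min_spacing, density,
                          max_tries_per_point = 200L) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  if (min_spacing <= 0) {
    return(cbind(runif(n, 0, ext_um[1]), runif(n, 0, ext_um[2]),
                 runif(n, 0, ext_um[3])))
  }
  cell <- min_spacing
  cells <- new.env(hash = TRUE, parent = emptyenv())
  pts <- matrix(NA_real_, n, 3)
  key_of <- function(ci) paste(ci, collapse = ",")
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries_per_point)) {
      p <- c(runif(1, 0, ext_um[1]), runif(1, 0, ext_um[2]),
             runif(1, 0, ext_um[3]))
      ci <- floor(p / cell)
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        k <- key_of(ci + c(dx, dy, dz))
        if (!is.null(cells[[k]])) {
          for (j in cells[[k]]) {
            if (sum((pts[j, ] - p)^2) < min_spacing^2) { ok <- FALSE; break }
          }
        }
        if (!ok) break
      }
      if (ok) {
        pts[i, ] <- p
        k <- key_of(ci)
        cells[[k]] <- c(cells[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "cannot place %d terminals at density %.3g/1000um^3 with %.2f um minimum spacing; reduce the density or the spacing",
        n, density, min_spacing
      ))
    }
  }
  pts
}

# truncated-normal volume draws kept inside the detectable size range
draw_volumes <- function(cls, volume_params, lower = 0.08, upper = 0.65) {
  lut <- volume_params
  m <- lut$mean_um3[match(cls, lut$gad_class)]
  s <- lut$sd_um3[match(cls, lut$gad_class)]
  v <- rnorm(length(cls), m, s)
  bad <- which(v < lower | v > upper)
  guard <- 0L
  while (length(bad) > 0 && guard < 100L) {
    v[bad] <- rnorm(length(bad), m[bad], s[bad])
    bad <- which(v < lower | v > upper)
    guard <- guard + 1L
  }
  v[v < lower] <- lower
  v[v > upper] <- upper
  v
}

# true integrated intensities: log-normal about the class median, scaled by
# the terminal's volume relative to its class mean -- larger terminals hold
# proportionally more protein, so total fluorescence tracks volume
draw_intensities <- function(cls, intensity_params, volumes = NULL,
                             volume_params = NULL) {
  n <- length(cls)
  vol_scale <- rep(1, n)
  if (!is.null(volumes) && !is.null(volume_params)) {
    vbar <- volume_params$mean_um3[match(cls, volume_params$gad_class)]
    vol_scale <- volumes / vbar
  }
  out <- tibble(
    int_marker = numeric(n), int_vgat = numeric(n),
    int_gad65 = numeric(n), int_gad67 = numeric(n)
  )
  has_channel <- function(cl, ch) {
    switch(ch,
      marker = TRUE, vgat = TRUE,
      gad65 = cl %in% c("GAD65", "GAD65_67"),
      gad67 = cl %in% c("GAD67", "GAD65_67")
    )
  }
  for (ch in c("marker", "vgat", "gad65", "gad67")) {
    ip <- intensity_params[intensity_params$channel == ch, ]
    med <- ip$median[match(cls, ip$gad_class)]
    sig <- ip$sigma[match(cls, ip$gad_class)]
    present <- vapply(cls, has_channel, logical(1), ch = ch) &
      !is.na(med)
    vals <- numeric(n)
    idx <- which(present)
    if (length(idx)) {
      vals[idx] <- vol_scale[idx] * rlnorm(length(idx),
                                           meanlog = log(med[idx]),
                                           sdlog = sig[idx])
    }
    out[[paste0("int_", ch)]] <- vals
  }
  out
}

#' Construct a five-channel voxel stack
#'
#' @param channels Named list of five 3D integer arrays in (z, y, x) order,
#'   named as in [gp_channels].
#' @param voxel_size_um Voxel size (x, y, z) in micrometers.
#' @param bit_depth Bit depth of the intensity data (16).
#' @return A `voxel_stack` object.
#' @export
voxel_stack <- function(channels, voxel_size_um = c(0.267, 0.267, 0.25),
                        bit_depth = 16L) {
  if (!setequal(names(channels), gp_channels)) {
    abort("`channels` must be named marker, vgat, gad65, gad67, lipofuscin.")
  }
  channels <- channels[gp_channels]
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) abort("channels must be 3D arrays.")
  if (!all(vapply(dims, identical, TRUE, y = dims[[1]]))) {
    abort("all channels must share dimensions.")
  }
  maxval <- 2^bit_depth - 1
  for (ch in gp_channels) {
    v <- channels[[ch]]
    if (any(v < 0 | v > maxval)) abort("intensities must lie in [0, 2^bit_depth - 1].")
    storage.mode(channels[[ch]]) <- "integer"
  }
  structure(
    list(channels = channels, voxel_size_um = as.numeric(voxel_size_um),
         bit_depth = as.integer(bit_depth)),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<voxel_stack>", paste(d, collapse = " x "), "(z y x), 5 channels,",
      x$bit_depth, "bit, voxel",
      paste(signif(x$voxel_size_um, 3), collapse = " x "), "um\n")
  invisible(x)
}

#' Render a ground-truth scene into a noisy five-channel stack
#'
#' Each terminal is rendered as an anisotropic Gaussian blob whose sigma is
#' chosen so that the half-maximum isosurface encloses the terminal's true
#' volume; the discrete kernel is normalized over its in-bounds support so
#' that the blob's summed intensity equals the true integrated intensity
#' before noise. Terminals are stamped into the marker and vGAT channels and
#' into GAD65/GAD67 according to their class. Lipofuscin blobs, which
#' fluoresce across the visible spectrum, are added to all five channels.
#' A linear z-edge attenuation ramp is applied, then Poisson noise (photon
#' gain) followed by Gaussian read noise and a constant baseline, and values
#' are clipped to the bit depth.
#'
#' @param scene A `scene_truth` from [generate_scene()].
#' @param config The [scene_config()] used to generate the scene.
#' @return A [voxel_stack()].
#' @export
render_stack <- function(scene, config = scene$config) {
  stopifnot(inherits(scene, "scene_truth"), inherits(config, "scene_config"))
  dims <- c(config$n_zplanes, config$field_size_px[1], config$field_size_px[2])
  vs <- config$voxel_size_um # (x, y, z)
  acc <- lapply(gp_channels, function(ch) array(0, dims))
  names(acc) <- gp_channels

  hm <- sqrt(2 * log(2)) # half-max radius in sigmas
  p <- scene$puncta
  for (i in seq_len(nrow(p))) {
    sigma_um <- (3 * p$volume_um3[i] / (4 * pi))^(1 / 3) / hm
    kern <- blob_kernel(
      center_um = c(p$x_um[i], p$y_um[i], p$z_um[i]),
      sigma_um = rep(sigma_um, 3), vs = vs, dims = dims
    )
    if (is.null(kern)) next
    chans <- c("marker", "vgat",
               if (p$gad_class[i] %in% c("GAD65", "GAD65_67")) "gad65",
               if (p$gad_class[i] %in% c("GAD67", "GAD65_67")) "gad67")
    for (ch in chans) {
      intensity <- p[[paste0("int_", ch)]][i]
      acc[[ch]][kern$zi, kern$yi, kern$xi] <-
        acc[[ch]][kern$zi, kern$yi, kern$xi] + intensity * kern$k
    }
  }
  lp <- scene$lipofuscin
  for (i in seq_len(nrow(lp))) {
    sigma_um <- lp$radius_um[i] / hm
    kern <- blob_kernel(
      center_um = c(lp$x_um[i], lp$y_um[i], lp$z_um[i]),
      sigma_um = rep(sigma_um, 3), vs = vs, dims = dims, normalize = FALSE
    )
    if (is.null(kern)) next
    for (ch in gp_channels) {
      acc[[ch]][kern$zi, kern$yi, kern$xi] <-
        acc[[ch]][kern$zi, kern$yi, kern$xi] + lp$intensity[i] * kern$k
    }
  }

  att <- z_attenuation(config$n_zplanes, config$edge_attenuation_frac)
  maxval <- 2^config$bit_depth - 1
  noise <- config$noise
  out <- with_seed(if (is.null(config$seed)) NULL else config$seed + 1L, {
    lapply(acc, function(a) {
      .finalize_channel_cpp(
        a, dims, att, !is.null(noise),
        noise$gain %||% 0.1, noise$read_sd %||% 0,
        noise$baseline %||% 0, maxval
      )
    })
  })
  voxel_stack(out, voxel_size_um = vs, bit_depth = config$bit_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# separable Gaussian kernel over the in-bounds support window around a center
# given in um; returns index ranges (z, y, x) and the kernel block. When
# `normalize` is TRUE the in-bounds kernel sums to exactly 1 so that stamped
# mass equals the true integrated intensity; otherwise the kernel peaks at 1
# (peak-amplitude blobs such as lipofuscin).
blob_kernel <- function(center_um, sigma_um, vs, dims, normalize = TRUE,
                        support_sigmas = 3.5) {
  # continuous 1-based voxel coordinates of the center, per axis (x, y, z)
  cx <- center_um[1] / vs[1] + 0.5
  cy <- center_um[2] / vs[2] + 0.5
  cz <- center_um[3] / vs[3] + 0.5
  sx <- sigma_um[1] / vs[1]; sy <- sigma_um[2] / vs[2]; sz <- sigma_um[3] / vs[3]
  rng <- function(c, s, d) {
    r <- ceiling(support_sigmas * s)
    lo <- max(1L, floor(c - r)); hi <- min(d, ceiling(c + r))
    if (lo > hi) NULL else lo:hi
  }
  xi <- rng(cx, sx, dims[3]); yi <- rng(cy, sy, dims[2]); zi <- rng(cz, sz, dims[1])
  if (is.null(xi) || is.null(yi) || is.null(zi)) return(NULL)
  kx <- exp(-0.5 * ((xi - cx) / sx)^2)
  ky <- exp(-0.5 * ((yi - cy) / sy)^2)
  kz <- exp(-0.5 * ((zi - cz) / sz)^2)
  k <- outer(outer(kz, ky), kx) # dims (z, y, x)
  if (normalize) k <- k / sum(k)
  list(zi = zi, yi = yi, xi = xi, k = k)
}

# per-plane multiplicative attenuation: linear ramp from `floor_frac` at each
# z face up to 1 over the first/last `frac` of planes
z_attenuation <- function(n_zplanes, frac, floor_frac = 0.2) {
  att <- rep(1, n_zplanes)
  n_edge <- floor(frac * n_zplanes)
  if (n_edge >= 1) {
    ramp <- seq(floor_frac, 1, length.out = n_edge + 1L)[seq_len(n_edge)]
    att[seq_len(n_edge)] <- ramp
    att[n_zplanes + 1L - seq_len(n_edge)] <- ramp
  }
  att
}
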
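# shared fixtures: all synthetic, built in code at test time

# a small, fast scene configuration
quick_config <- function(marker = "CB", seed = 1L, field = 128L, nz = 12L,
                         density = 3, ...) {
  scene_config(
    marker = marker, field_size_px = c(field, field), n_zplanes = nz,
    density_per_1000um3 = density, seed = seed, ...
  )
}

# noise-free, artifact-free configuration with well-separated puncta
clean_config <- function(seed = 1L, field = 96L, nz = 12L, density = 3,
                         marker = "CB") {
  scene_config(
    marker = marker, field_size_px = c(field, field), n_zplanes = nz,
    density_per_1000um3 = density, lipofuscin_density = 0,
    edge_attenuation_frac = 0, noise = NULL, min_spacing_um = 2.0,
    seed = seed
  )
}

# build a mask-table row from an explicit voxel matrix (1-based z, y, x)
mask_row <- function(id, vox, channel = "vgat",
                     voxel_size = c(0.267, 0.267, 0.25)) {
  vox <- matrix(as.integer(vox), ncol = 3,
                dimnames = list(NULL, c("z", "y", "x")))
  cen <- colMeans(vox) - 1
  tibble::tibble(
    mask_id = id, channel = channel, n_vox = nrow(vox),
    volume_um3 = nrow(vox) * prod(voxel_size),
    cz = cen[["z"]], cy = cen[["y"]], cx = cen[["x"]],
    threshold = 0, voxels = list(vox)
  )
}

# axis-aligned box of voxels
box_vox <- function(z, y, x) {
  as.matrix(expand.grid(z = z, y = y, x = x))[, c("z", "y", "x")]
}

# independent connected-component labeling oracle: repeated set expansion
# over explicit neighbor offsets (slow, for tiny inputs only)
oracle_label <- function(idx, dims, connectivity = 26L) {
  if (!length(idx)) return(integer(0))
  co <- arrayInd(idx, dims)
  key <- paste(co[, 1], co[, 2], co[, 3])
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1L, ]
  lab <- rep(0L, length(idx))
  cur <- 0L
  for (s in seq_along(idx)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- sweep(off, 2, co[v, ], `+`)
        j <- match(paste(nb[, 1], nb[, 2], nb[, 3]), key)
        j <- j[!is.na(j)]
        j <- j[lab[j] == 0L]
        lab[j] <- cur
        nxt <- c(nxt, j)
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# reference single-threshold segmentation: label components above t, keep
# those inside the volume gate
oracle_segment_at <- function(filtered, t, gate = c(0.05, 0.7),
                              voxel_size = c(0.267, 0.267, 0.25)) {
  idx <- which(filtered > t)
  lab <- oracle_label(idx, dim(filtered))
  comps <- split(idx, lab)
  vv <- prod(voxel_size)
  comps[vapply(comps, function(c) {
    v <- length(c) * vv
    v >= gate[1] && v <= gate[2]
  }, logical(1))]
}
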
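#' Write a five-channel stack as a multipage TIFF with a JSON sidecar
#'
#' Planes are written in CZYX order (all z planes of channel 1, then channel
#' 2, ...) as 16-bit grayscale. A JSON sidecar (`<path>.json`) records the
#' channel names, voxel size, layer, identifiers and seed.
#'
#' @param stack A [voxel_stack()].
#' @param path Output TIFF path.
#' @param metadata Optional list with elements `layer`, `subject_id`,
#'   `section_id`, `stack_id`, `seed`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata = list()) {
  stopifnot(inherits(stack, "voxel_stack"))
  maxval <- 2^stack$bit_depth - 1
  pages <- list()
  for (ch in gp_channels) {
    a <- stack$channels[[ch]]
    for (z in seq_len(dim(a)[1])) {
      pages[[length(pages) + 1L]] <- a[z, , ] / maxval
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  side <- list(
    channel_names = gp_channels,
    voxel_size_um = stack$voxel_size_um,
    bit_depth = stack$bit_depth,
    n_zplanes = dim(stack$channels[[1]])[1],
    layer = metadata$layer,
    subject_id = metadata$subject_id,
    section_id = metadata$section_id,
    stack_id = metadata$stack_id,
    seed = metadata$seed
  )
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a five-channel stack written by [write_stack()]
#'
#' @param path TIFF path. The JSON sidecar `<path>.json` is read if present;
#'   if it is missing, default channel names and the default voxel size
#'   (0.267, 0.267, 0.25) um are assumed with a warning.
#' @return A list with elements `stack` (a [voxel_stack()]) and `metadata`
#'   (list of channel names, voxel size, layer and identifiers).
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    abort("inconsistent plane shapes in stack TIFF.")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    warn("sidecar JSON missing; assuming default channel order and voxel size (0.267, 0.267, 0.25) um.")
    meta <- list()
  }
  if (is.null(meta$voxel_size_um)) {
    if (file.exists(sidecar)) {
      warn("sidecar lacks voxel size; using default (0.267, 0.267, 0.25) um.")
    }
    meta$voxel_size_um <- c(0.267, 0.267, 0.25)
  }
  meta$channel_names <- meta$channel_names %||% gp_channels
  n_ch <- length(meta$channel_names)
  if (n_ch != 5L) abort(sprintf("expected 5 channels, sidecar names %d.", n_ch))
  if (length(pages) %% n_ch != 0L) {
    abort(sprintf("page count %d is not a multiple of the channel count 5.",
                  length(pages)))
  }
  nz <- length(pages) %/% n_ch
  if (!is.null(meta$n_zplanes) && meta$n_zplanes != nz) {
    abort("sidecar n_zplanes disagrees with page count.")
  }
  d2 <- dim(pages[[1]])
  channels <- list()
  for (ci in seq_len(n_ch)) {
    a <- array(0L, c(nz, d2[1], d2[2]))
    for (z in seq_len(nz)) {
      pl <- pages[[(ci - 1L) * nz + z]]
      if (!is.integer(pl)) {
        if (any(pl != round(pl))) abort("non-integer pixel data in stack TIFF.")
        pl <- as.integer(round(pl))
      }
      a[z, , ] <- pl
    }
    channels[[meta$channel_names[ci]]] <- a
  }
  stack <- voxel_stack(channels, voxel_size_um = meta$voxel_size_um,
                       bit_depth = meta$bit_depth %||% 16L)
  list(stack = stack, metadata = meta)
}

#' Write puncta masks as a 32-bit label volume
#'
#' Background is 0; the i-th mask in `masks` is written with label i.
#'
#' @param masks A mask table (see [iterative_segmentation()]); all masks must
#'   belong to one channel and be voxel-disjoint.
#' @param dims Volume dimensions (z, y, x).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(masks, dims, path) {
  lab <- array(0, dims)
  for (i in seq_len(nrow(masks))) {
    vox <- masks$voxels[[i]]
    idx <- vox[, 1] + (vox[, 2] - 1) * dims[1] + (vox[, 3] - 1) * dims[1] * dims[2]
    if (any(idx < 1 | idx > prod(dims))) abort("mask voxels outside volume.")
    if (any(lab[idx] != 0)) abort("overlapping masks in one label volume.")
    lab[idx] <- i
  }
  pages <- lapply(seq_len(dims[1]), function(z) lab[z, , ] / (2^32 - 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#'
#' @param path TIFF path.
#' @return A 3D integer array (z, y, x) of labels, background 0.
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nz <- length(pages)
  d2 <- dim(pages[[1]])
  a <- array(0L, c(nz, d2[1], d2[2]))
  for (z in seq_len(nz)) a[z, , ] <- as.integer(round(pages[[z]]))
  a
}
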
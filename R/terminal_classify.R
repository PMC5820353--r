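# linear voxel indices of a (z, y, x) index matrix
vox_linear <- function(vox, dims) {
  vox[, 1] + (vox[, 2] - 1) * dims[1] + (vox[, 3] - 1) * dims[1] * dims[2]
}

# 1-based (z, y, x) voxel containing a mask's center: floor of the 0-based
# continuous centroid, then back to 1-based indexing
center_voxel <- function(vox) {
  floor(colMeans(vox) - 1) + 1L
}

#' Do two masks overlap each other's centers?
#'
#' TRUE iff the voxel containing A's centroid belongs to B's voxel set and
#' the voxel containing B's centroid belongs to A's voxel set. This mutual
#' center criterion is the object-based colocalization rule used for terminal
#' classification.
#'
#' @param vox_a,vox_b Integer (z, y, x) voxel index matrices of the two masks
#'   (same stack geometry).
#' @param dims Volume dimensions (z, y, x).
#' @return Logical.
#' @export
centers_mutually_overlap <- function(vox_a, vox_b, dims) {
  ca <- center_voxel(vox_a)
  cb <- center_voxel(vox_b)
  lin_a <- vox_linear(vox_a, dims)
  lin_b <- vox_linear(vox_b, dims)
  ca_lin <- ca[1] + (ca[2] - 1) * dims[1] + (ca[3] - 1) * dims[1] * dims[2]
  cb_lin <- cb[1] + (cb[2] - 1) * dims[1] + (cb[3] - 1) * dims[1] * dims[2]
  (ca_lin %in% lin_b) && (cb_lin %in% lin_a)
}

# for each mask in `masks`, the mask_id of the mask in `others` whose voxel
# set contains its center voxel (NA if none); masks in `others` are assumed
# voxel-disjoint, so the containing mask is unique
containing_mask <- function(masks, others, dims) {
  if (!nrow(masks)) return(integer(0))
  if (!nrow(others)) return(rep(NA_integer_, nrow(masks)))
  other_lin <- lapply(others$voxels, vox_linear, dims = dims)
  lut_idx <- unlist(other_lin)
  lut_id <- rep(others$mask_id, lengths(other_lin))
  centers <- vapply(masks$voxels, function(v) {
    cv <- center_voxel(v)
    cv[1] + (cv[2] - 1) * dims[1] + (cv[3] - 1) * dims[1] * dims[2]
  }, numeric(1))
  lut_id[match(centers, lut_idx)]
}

# mutual-center partner of each mask in `a` among masks `b`; returns the
# partner mask_id or NA. Because masks within one channel are voxel-disjoint,
# a mask's center lies in at most one partner, making the pairing one-to-one;
# residual conflicts (possible only with overlapping inputs) are resolved by
# nearest centroid, then lowest mask id.
mutual_partner <- function(a, b, dims) {
  if (!nrow(a)) return(integer(0))
  cand <- containing_mask(a, b, dims) # b-mask containing a's center
  rev_map <- containing_mask(b, a, dims) # a-mask containing b's center
  out <- rep(NA_integer_, nrow(a))
  for (i in seq_len(nrow(a))) {
    bi <- cand[i]
    if (is.na(bi)) next
    j <- match(bi, b$mask_id)
    if (!is.na(rev_map[j]) && rev_map[j] == a$mask_id[i]) out[i] <- bi
  }
  # defensive many-to-one resolution
  dup <- out[!is.na(out)][duplicated(out[!is.na(out)])]
  for (bi in unique(dup)) {
    claimants <- which(!is.na(out) & out == bi)
    j <- match(bi, b$mask_id)
    d2 <- (a$cz[claimants] - b$cz[j])^2 + (a$cy[claimants] - b$cy[j])^2 +
      (a$cx[claimants] - b$cx[j])^2
    keep <- claimants[order(d2, a$mask_id[claimants])][1]
    out[setdiff(claimants, keep)] <- NA_integer_
  }
  out
}

# does each mask in `masks` share any voxel with any mask in `others`?
overlaps_any_voxel <- function(masks, others, dims) {
  if (!nrow(masks)) return(logical(0))
  if (!nrow(others)) return(rep(FALSE, nrow(masks)))
  other_set <- unique(unlist(lapply(others$voxels, vox_linear, dims = dims)))
  vapply(masks$voxels, function(v) any(vox_linear(v, dims) %in% other_set),
         logical(1))
}

#' Classify vGAT masks by GAD content
#'
#' A vGAT mask is `GAD65_67` when it mutually center-overlaps both a GAD65
#' and a GAD67 mask; `GAD65` when it mutually center-overlaps a GAD65 mask
#' and does not overlap any GAD67 mask (and symmetrically for `GAD67`);
#' otherwise it is unclassified (`NA`) and excluded from terminal counts.
#' The exclusion overlap is any-voxel overlap by default (`overlap_mode =
#' "voxel"`), the stricter reading of "did not overlap"; `"center"` restricts
#' exclusion to mutual center overlap.
#'
#' @param vgat,gad65,gad67 Mask tables for the three channels (post-QC).
#' @param dims Volume dimensions (z, y, x).
#' @param overlap_mode `"voxel"` or `"center"`.
#' @return The vGAT mask table with columns `gad_class` (factor over
#'   [gp_gad_classes], NA when unclassified), `gad65_id`, `gad67_id`.
#' @export
classify_gad <- function(vgat, gad65, gad67, dims,
                         overlap_mode = c("voxel", "center")) {
  overlap_mode <- match.arg(overlap_mode)
  p65 <- mutual_partner(vgat, gad65, dims)
  p67 <- mutual_partner(vgat, gad67, dims)
  if (overlap_mode == "voxel") {
    hit65 <- overlaps_any_voxel(vgat, gad65, dims)
    hit67 <- overlaps_any_voxel(vgat, gad67, dims)
  } else {
    hit65 <- !is.na(p65)
    hit67 <- !is.na(p67)
  }
  cls <- rep(NA_character_, nrow(vgat))
  both <- !is.na(p65) & !is.na(p67)
  only65 <- !is.na(p65) & !both & !hit67
  only67 <- !is.na(p67) & !both & !hit65
  cls[both] <- "GAD65_67"
  cls[only65] <- "GAD65"
  cls[only67] <- "GAD67"
  vgat$gad_class <- factor(cls, levels = gp_gad_classes)
  vgat$gad65_id <- ifelse(is.na(cls) | cls == "GAD67", NA_integer_, p65)
  vgat$gad67_id <- ifelse(is.na(cls) | cls == "GAD65", NA_integer_, p67)
  vgat
}

#' Classify marker puncta as terminals
#'
#' A marker (CB, CR, or PV) punctum is a terminal when it mutually
#' center-overlaps a GAD-classified vGAT mask; it inherits that mask's GAD
#' class. Marker puncta without a classified vGAT partner are excluded from
#' terminal statistics.
#'
#' @param marker_masks Measured mask table of the marker channel (post-QC).
#' @param vgat_classified Output of [classify_gad()] (measured masks).
#' @param gad65,gad67 Measured mask tables used to report per-terminal GAD
#'   intensities from the linked GAD masks (optional).
#' @param dims Volume dimensions (z, y, x).
#' @param marker Marker name recorded on each terminal.
#' @return Terminal table: one row per terminal with `marker`, `gad_class`,
#'   `volume_um3` (marker mask volume), mask link ids, the marker and vGAT
#'   mask intensity measures, and the linked GAD masks' own-channel
#'   intensities (`gad65_sum`, `gad67_sum`, and means).
#' @export
classify_marker_terminals <- function(marker_masks, vgat_classified,
                                      gad65 = NULL, gad67 = NULL, dims,
                                      marker = "CB") {
  partner <- mutual_partner(marker_masks, vgat_classified, dims)
  keep <- !is.na(partner)
  if (any(keep)) {
    j <- match(partner[keep], vgat_classified$mask_id)
    keep[keep] <- !is.na(vgat_classified$gad_class[j])
  }
  mm <- marker_masks[keep, , drop = FALSE]
  if (!nrow(mm)) return(empty_terminal_table())
  j <- match(partner[keep], vgat_classified$mask_id)
  vg <- vgat_classified[j, , drop = FALSE]
  pull_gad <- function(tab, ids, col) {
    if (is.null(tab) || !length(ids)) return(rep(NA_real_, nrow(mm)))
    tab[[col]][match(ids, tab$mask_id)]
  }
  tibble(
    marker = marker,
    gad_class = vg$gad_class,
    marker_id = mm$mask_id,
    vgat_id = vg$mask_id,
    gad65_id = vg$gad65_id,
    gad67_id = vg$gad67_id,
    volume_um3 = mm$volume_um3,
    cz = mm$cz, cy = mm$cy, cx = mm$cx,
    marker_sum = mm$sum_marker, marker_mean = mm$mean_marker,
    vgat_sum = vg$sum_vgat, vgat_mean = vg$mean_vgat,
    gad65_sum = pull_gad(gad65, vg$gad65_id, "sum_gad65"),
    gad65_mean = pull_gad(gad65, vg$gad65_id, "mean_gad65"),
    gad67_sum = pull_gad(gad67, vg$gad67_id, "sum_gad67"),
    gad67_mean = pull_gad(gad67, vg$gad67_id, "mean_gad67")
  )
}

empty_terminal_table <- function() {
  tibble(
    marker = character(), gad_class = factor(character(), gp_gad_classes),
    marker_id = integer(), vgat_id = integer(), gad65_id = integer(),
    gad67_id = integer(), volume_um3 = double(), cz = double(), cy = double(),
    cx = double(), marker_sum = double(), marker_mean = double(),
    vgat_sum = double(), vgat_mean = double(), gad65_sum = double(),
    gad65_mean = double(), gad67_sum = double(), gad67_mean = double()
  )
}

#' Classify somatic GAD mRNA expression from molecule counts
#'
#' A GABAergic neuron specifically expresses a GAD transcript when its soma
#' contains at least 5 molecules of that transcript and the somatic density
#' exceeds 2.5 times the neuropil density of the same transcript.
#'
#' @param records Tibble with columns `cell_id`, `gad65_count`,
#'   `gad67_count`, `soma_area` (same units as the neuropil density
#'   denominator).
#' @param neuropil_density_gad65,neuropil_density_gad67 Neuropil molecule
#'   densities (molecules per unit area).
#' @param min_count Molecule count threshold (5).
#' @param density_ratio Required somatic/neuropil density ratio (2.5).
#' @return `records` with logical columns `expresses_gad65`,
#'   `expresses_gad67`.
#' @export
classify_soma_mrna <- function(records, neuropil_density_gad65,
                               neuropil_density_gad67,
                               min_count = 5, density_ratio = 2.5) {
  if (any(records$soma_area <= 0)) abort("soma_area must be positive.")
  if (any(records$gad65_count < 0 | records$gad67_count < 0)) {
    abort("molecule counts must be >= 0.")
  }
  records |>
    mutate(
      expresses_gad65 = .data$gad65_count >= min_count &
        .data$gad65_count / .data$soma_area >
          density_ratio * neuropil_density_gad65,
      expresses_gad67 = .data$gad67_count >= min_count &
        .data$gad67_count / .data$soma_area >
          density_ratio * neuropil_density_gad67
    )
}
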
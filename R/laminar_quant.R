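#' Cortical layer boundaries as fractional depth intervals
#'
#' Layer boundaries estimated from the pia (depth 0) to the gray/white matter
#' border (depth 1): L1 0-10%, L2 10-20%, L3 20-50%, L4 50-60%, L5 60-80%,
#' L6 80-100%. Intervals are half-open at the lower edge, with the upper
#' boundary of layer 6 closed, so the intervals partition [0, 1].
#'
#' @return Tibble with columns `layer`, `lower`, `upper`.
#' @export
layer_scheme <- function() {
  tibble(
    layer = 1:6,
    lower = c(0, 0.10, 0.20, 0.50, 0.60, 0.80),
    upper = c(0.10, 0.20, 0.50, 0.60, 0.80, 1.0)
  )
}

#' Assign a cortical layer from a fractional depth
#'
#' @param depth_fraction Depth(s) from the pial surface as a fraction of the
#'   pia-to-white-matter distance, in `[0, 1]`.
#' @return Integer layer(s) 1-6.
#' @export
assign_layer <- function(depth_fraction) {
  if (any(depth_fraction < 0 | depth_fraction > 1)) {
    abort("`depth_fraction` must lie in [0, 1].")
  }
  ls <- layer_scheme()
  out <- findInterval(depth_fraction, ls$lower)
  out[depth_fraction >= 1] <- 6L
  as.integer(out)
}

#' Place a systematic-random sampling grid
#'
#' Lays a regular `grid_um` lattice over the region with one random offset
#' (the same for every cell) and selects `n` cells uniformly without
#' replacement; one image stack is acquired at each selected position.
#'
#' @param extent_um Region extent `(width, height)` in micrometers.
#' @param grid_um Grid period (180 um).
#' @param n Number of stacks to sample (10).
#' @param seed Integer seed.
#' @return Tibble with columns `x_um`, `y_um`, one row per selected position.
#' @export
place_sampling_grid <- function(extent_um, grid_um = 180, n = 10L,
                                seed = NULL) {
  ncell <- floor(extent_um / grid_um)
  n_cells <- prod(ncell)
  if (n_cells < n) {
    abort(sprintf("region holds only %d grid cell(s); %d required.",
                  n_cells, n))
  }
  with_seed(seed, {
    offset <- runif(2, 0, grid_um)
    cells <- tidyr::expand_grid(ix = seq_len(ncell[1]) - 1L,
                                iy = seq_len(ncell[2]) - 1L)
    pick <- cells[sample.int(n_cells, n), ]
    tibble(x_um = pick$ix * grid_um + offset[1],
           y_um = pick$iy * grid_um + offset[2])
  })
}

#' Hierarchical (stack, layer, section, subject) averaging
#'
#' Aggregates a per-terminal or per-stack measure with strict mean-of-means:
#' values are averaged within stack, stack means within layer, layer means
#' within section, and section means within subject - never pooled. Groups
#' named in `by` (e.g. marker, GAD class, or `layer` itself for laminar
#' summaries) are carried through every level; naming `layer` in `by`
#' suppresses the across-layer averaging step. Cells with no data propagate
#' as missing, not zero.
#'
#' @param data Tibble with columns `subject_id`, `section_id`, `layer`,
#'   `stack_id` plus the measure.
#' @param value Name of the measure column (string).
#' @param by Character vector of extra grouping columns to keep.
#' @return Tibble with `subject_id`, the `by` columns, and `mean_value`.
#' @export
hierarchical_average <- function(data, value, by = character(0)) {
  if (!value %in% names(data)) {
    abort(sprintf("measure `%s` not found in `data`.", value))
  }
  need <- c("subject_id", "section_id", "layer", "stack_id")
  if (!all(need %in% names(data))) {
    abort("`data` must label subject_id, section_id, layer and stack_id.")
  }
  keep_layer <- "layer" %in% by
  by_other <- setdiff(by, c(need))
  g1 <- c("subject_id", "section_id", "layer", "stack_id", by_other)
  out <- data |>
    group_by(dplyr::across(dplyr::all_of(g1))) |>
    summarise(mean_value = mean(.data[[value]], na.rm = TRUE),
              .groups = "drop")
  # stack means -> layer means (within section)
  g2 <- c("subject_id", "section_id", "layer", by_other)
  out <- out |>
    group_by(dplyr::across(dplyr::all_of(g2))) |>
    summarise(mean_value = mean(.data$mean_value, na.rm = TRUE),
              .groups = "drop")
  if (!keep_layer) {
    g3 <- c("subject_id", "section_id", by_other)
    out <- out |>
      group_by(dplyr::across(dplyr::all_of(g3))) |>
      summarise(mean_value = mean(.data$mean_value, na.rm = TRUE),
                .groups = "drop")
  }
  g4 <- c("subject_id", if (keep_layer) "layer", by_other)
  out |>
    group_by(dplyr::across(dplyr::all_of(g4))) |>
    summarise(mean_value = mean(.data$mean_value, na.rm = TRUE),
              .groups = "drop")
}

#' Per-stack terminal densities by class
#'
#' Counts terminals per stack, marker and GAD class against the QC-analyzed
#' volume of the stack (central XY window times the selected depth bins), in
#' terminals per 1000 um^3. Class combinations absent from a stack get
#' density 0 (a true zero count, not missing data).
#'
#' @param terminals Terminal table with columns `subject_id`, `section_id`,
#'   `layer`, `stack_id`, `marker`, `gad_class`.
#' @param analyzed_volumes Tibble with columns `stack_id` and
#'   `analyzed_volume_um3` (see [analyzed_volume_um3()]).
#' @return Tibble of per-stack class densities.
#' @export
terminal_densities <- function(terminals, analyzed_volumes) {
  counts <- terminals |>
    group_by(.data$subject_id, .data$section_id, .data$layer, .data$stack_id,
             .data$marker, .data$gad_class) |>
    summarise(n_terminals = dplyr::n(), .groups = "drop")
  # complete GAD classes within each observed stack x marker
  frame <- counts |>
    distinct(.data$subject_id, .data$section_id, .data$layer, .data$stack_id,
             .data$marker) |>
    tidyr::crossing(gad_class = factor(gp_gad_classes, gp_gad_classes))
  frame |>
    left_join(counts, by = c("subject_id", "section_id", "layer", "stack_id",
                             "marker", "gad_class")) |>
    mutate(n_terminals = tidyr::replace_na(.data$n_terminals, 0L)) |>
    left_join(analyzed_volumes, by = "stack_id") |>
    mutate(density_per_1000um3 =
             1000 * .data$n_terminals / .data$analyzed_volume_um3)
}

#' QC-analyzed volume of one stack
#'
#' @param n_zplanes Plane count.
#' @param z_bins Selected depth bins (integer vector).
#' @param voxel_size_um Voxel size (x, y, z) in um.
#' @param crop_px XY analysis window side in pixels.
#' @return Volume in um^3.
#' @export
analyzed_volume_um3 <- function(n_zplanes, z_bins,
                                voxel_size_um = c(0.267, 0.267, 0.25),
                                crop_px = 490L) {
  n_z <- n_zplanes * length(z_bins) / 40
  crop_px^2 * n_z * voxel_volume_um3(voxel_size_um)
}

#' Class proportions within a grouping
#'
#' Converts class values (e.g. densities) into proportions of the group
#' total. Proportions sum to 1 within each group; groups with zero total get
#' missing proportions rather than a division error.
#'
#' @param data Tibble of class values.
#' @param value Name of the value column.
#' @param class_col Column defining the classes (e.g. `"gad_class"` or
#'   `"marker"`).
#' @param by Character vector of grouping columns (e.g. `"subject_id"`).
#' @return `data` with an added `proportion` column.
#' @export
class_proportions <- function(data, value, class_col, by = character(0)) {
  data |>
    group_by(dplyr::across(dplyr::all_of(by))) |>
    mutate(proportion = {
      tot <- sum(.data[[value]], na.rm = TRUE)
      if (isTRUE(tot > 0)) .data[[value]] / tot else NA_real_
    }) |>
    ungroup()
}
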
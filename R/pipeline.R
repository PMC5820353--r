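#' Lay out a multi-subject sampling design
#'
#' One row per image stack: subjects contribute `sections_per_subject`
#' sections, each sampled with `stacks_per_section` stacks per marker
#' experiment (markers are stained in separate experiments, so each stack
#' carries one marker). Per-stack seeds are drawn reproducibly from the
#' design seed.
#'
#' @param n_subjects Number of subjects.
#' @param sections_per_subject Sections per subject (2 in the standard
#'   design).
#' @param stacks_per_section Stacks per section and marker: a single count,
#'   or a vector named by marker (e.g. `c(CB = 2, CR = 2, PV = 1)`) to
#'   balance terminal yield across experiments of different densities.
#' @param markers Markers simulated (each in its own staining experiment).
#' @param layers Layer label(s) cycled over stacks within a section.
#' @param seed Design seed; every stack receives a derived seed.
#' @return Design tibble with columns `subject_id`, `section_id`, `layer`,
#'   `stack_id`, `marker`, `seed`.
#' @export
experiment_design <- function(n_subjects = 5L, sections_per_subject = 2L,
                              stacks_per_section = 1L,
                              markers = c("CB", "CR", "PV"),
                              layers = 3L, seed = 1L) {
  if (n_subjects < 1 || sections_per_subject < 1 ||
      any(stacks_per_section < 1)) {
    abort("design counts must be >= 1.")
  }
  if (is.null(names(stacks_per_section))) {
    stacks_per_section <- setNames(rep(stacks_per_section[1], length(markers)),
                                   markers)
  }
  d <- tidyr::expand_grid(
    subject = seq_len(n_subjects),
    section = seq_len(sections_per_subject),
    marker = markers,
    stack = seq_len(max(stacks_per_section))
  ) |>
    filter(.data$stack <= stacks_per_section[.data$marker]) |>
    mutate(
      subject_id = sprintf("S%02d", .data$subject),
      section_id = sprintf("S%02d-sec%d", .data$subject, .data$section),
      layer = rep_len(layers, dplyr::n())[dplyr::row_number()],
      stack_id = sprintf("S%02d-sec%d-%s-st%d", .data$subject, .data$section,
                         .data$marker, .data$stack)
    )
  d$seed <- with_seed(seed, sample.int(2^31 - 2, nrow(d)))
  d |> select("subject_id", "section_id", "layer", "stack_id", "marker", "seed")
}

# simulate, render and segment one stack; returns cropped measured mask
# tables plus the stack geometry
process_stack <- function(cfg, params, crop_px) {
  scene <- generate_scene(cfg)
  stack <- render_stack(scene, cfg)
  dims <- dim(stack$channels[[1]])
  masks <- lapply(c("marker", "vgat", "gad65", "gad67"), function(ch) {
    segment_channel(stack, ch, params) |>
      crop_xy(field_size = dims[2:3], crop_px = crop_px)
  })
  names(masks) <- c("marker", "vgat", "gad65", "gad67")
  lipo <- mask_lipofuscin(stack$channels$lipofuscin, stack$voxel_size_um)
  list(masks = masks, lipo = lipo, dims = dims, scene = scene,
       voxel_size_um = stack$voxel_size_um)
}

#' Run the full synthetic pipeline: simulate, segment, QC, classify, quantify
#'
#' For every stack in the design: generates a ground-truth scene, renders the
#' noisy five-channel stack, segments the marker, vGAT, GAD65 and GAD67
#' channels (difference-of-Gaussians, Ridler-Calvard seed, iterative
#' size-gated thresholding), and restricts masks to the central XY window.
#' Depth bins are then selected per marker experiment from the replicate
#' stacks' count/intensity profiles, lipofuscin-overlapping masks are
#' eliminated, vGAT masks are classified by GAD content and marker puncta by
#' mutual center overlap, and densities, GAD-class mixtures and marker
#' proportions are aggregated with hierarchical averaging. The stage order
#' (segment, XY crop, depth-bin selection, lipofuscin exclusion,
#' classification) is fixed.
#'
#' @param design An [experiment_design()] tibble. Every row must carry a
#'   non-missing seed.
#' @param scene_args Named list of per-marker overrides passed to
#'   [scene_config()], e.g. `list(CB = list(density_per_1000um3 = 2))`.
#' @param stack_args Overrides shared by all stacks (e.g. `n_zplanes`,
#'   `field_size_px`, `noise`).
#' @param params A [segmentation_params()].
#' @param alpha Significance level for depth-bin selection.
#' @param crop_px XY analysis window (490 px in a 512 px field).
#' @param zbin_scope `"pooled"` (default) selects one depth window from the
#'   profiles of all stacks — the experiments share one imaging protocol, so
#'   depth artifacts are common and a single window keeps analyzed volumes
#'   comparable across marker experiments; `"experiment"` selects a window
#'   per marker experiment.
#' @param verbose Emit per-stack progress messages.
#' @return A `gp_pipeline_result`: list with `terminals` (one row per
#'   classified terminal), `densities` (per stack, marker and GAD class),
#'   `subject_marker_proportions`, `marker_proportions` (group mean, percent),
#'   `subject_gad_mixtures`, `gad_mixtures` (group mean, percent),
#'   `zbin_selections` (per marker), `analyzed_volumes`, and the `design`.
#' @export
run_pipeline <- function(design, scene_args = list(), stack_args = list(),
                         params = segmentation_params(), alpha = 0.05,
                         crop_px = 490L,
                         zbin_scope = c("pooled", "experiment"),
                         verbose = FALSE) {
  zbin_scope <- match.arg(zbin_scope)
  need <- c("subject_id", "section_id", "layer", "stack_id", "marker", "seed")
  if (!all(need %in% names(design))) {
    abort(sprintf("design must have columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(is.na(design$seed))) {
    abort("every stack in the design needs a seed before any computation runs.")
  }
  markers <- unique(design$marker)
  all_terminals <- list()
  all_volumes <- list()
  selections <- list()

  processed_all <- list()
  for (mk in markers) {
    rows <- design |> filter(.data$marker == mk)
    processed <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      cfg_args <- c(
        list(marker = mk, layer = rows$layer[i], seed = rows$seed[i]),
        scene_args[[mk]] %||% list(),
        stack_args
      )
      cfg <- do.call(scene_config, cfg_args[!duplicated(names(cfg_args))])
      if (verbose) {
        message(sprintf("[%s] stack %s", mk, rows$stack_id[i]))
      }
      processed[[i]] <- process_stack(cfg, params, crop_px)
    }
    names(processed) <- rows$stack_id
    processed_all[[mk]] <- processed
  }

  pooled_sel <- NULL
  if (zbin_scope == "pooled") {
    everything <- do.call(c, unname(processed_all))
    combined <- lapply(everything, function(p) bind_rows(p$masks))
    nz <- vapply(everything, function(p) p$dims[1], numeric(1))
    pooled_sel <- select_zbins(zbin_profile(combined, nz), alpha = alpha)
  }

  for (mk in markers) {
    rows <- design |> filter(.data$marker == mk)
    processed <- processed_all[[mk]]

    if (zbin_scope == "pooled") {
      sel <- pooled_sel
    } else {
      # depth-bin QC across the replicate stacks of this experiment
      combined <- lapply(processed, function(p) bind_rows(p$masks))
      nz <- vapply(processed, function(p) p$dims[1], numeric(1))
      sel <- select_zbins(zbin_profile(combined, nz), alpha = alpha)
    }
    selections[[mk]] <- sel

    for (i in seq_len(nrow(rows))) {
      p <- processed[[i]]
      dims <- p$dims
      f <- lapply(p$masks, function(m) {
        m |>
          apply_zbin_window(sel, dims[1]) |>
          exclude_lipofuscin(p$lipo, dims)
      })
      vgat_cls <- classify_gad(f$vgat, f$gad65, f$gad67, dims)
      terms <- classify_marker_terminals(
        f$marker, vgat_cls, f$gad65, f$gad67, dims, marker = mk
      )
      terms$subject_id <- rows$subject_id[i]
      terms$section_id <- rows$section_id[i]
      terms$layer <- rows$layer[i]
      terms$stack_id <- rows$stack_id[i]
      all_terminals[[rows$stack_id[i]]] <- terms
      all_volumes[[rows$stack_id[i]]] <- tibble(
        stack_id = rows$stack_id[i],
        analyzed_volume_um3 = analyzed_volume_um3(
          dims[1], sel$z_bins, p$voxel_size_um, crop_px
        )
      )
    }
  }

  terminals <- bind_rows(all_terminals)
  analyzed_volumes <- bind_rows(all_volumes)
  quantify_terminals(terminals, analyzed_volumes, design,
                     selections = selections)
}

#' Aggregate a terminal table into densities, mixtures and proportions
#'
#' @param terminals Terminal table labeled with `subject_id`, `section_id`,
#'   `layer`, `stack_id`, `marker`, `gad_class`.
#' @param analyzed_volumes Per-stack analyzed volumes.
#' @param design The sampling design (used to keep empty stacks as zeros).
#' @param selections Optional named list of depth-bin selections (metadata).
#' @return A `gp_pipeline_result`; see [run_pipeline()].
#' @export
quantify_terminals <- function(terminals, analyzed_volumes, design,
                               selections = NULL) {
  dens <- terminal_densities(terminals, analyzed_volumes)

  # per-stack total marker density -> subject-level -> proportions by marker
  stack_total <- dens |>
    group_by(.data$subject_id, .data$section_id, .data$layer, .data$stack_id,
             .data$marker) |>
    summarise(density = sum(.data$density_per_1000um3), .groups = "drop")
  subj_marker <- hierarchical_average(stack_total, "density", by = "marker") |>
    rename(density = "mean_value") |>
    class_proportions("density", "marker", by = "subject_id")
  marker_prop <- subj_marker |>
    group_by(.data$marker) |>
    summarise(percent = 100 * mean(.data$proportion), .groups = "drop")

  # per-stack GAD-class percentages -> hierarchical average per subject
  stack_mix <- dens |>
    group_by(.data$subject_id, .data$section_id, .data$layer, .data$stack_id,
             .data$marker) |>
    mutate(share = if (sum(.data$n_terminals) > 0) {
      .data$n_terminals / sum(.data$n_terminals)
    } else NA_real_) |>
    ungroup() |>
    filter(!is.na(.data$share))
  subj_mix <- hierarchical_average(stack_mix, "share",
                                   by = c("marker", "gad_class")) |>
    rename(share = "mean_value")
  gad_mix <- subj_mix |>
    group_by(.data$marker, .data$gad_class) |>
    summarise(percent = 100 * mean(.data$share), .groups = "drop")

  structure(
    list(
      terminals = terminals,
      densities = dens,
      subject_marker_proportions = subj_marker,
      marker_proportions = marker_prop,
      subject_gad_mixtures = subj_mix,
      gad_mixtures = gad_mix,
      zbin_selections = selections,
      analyzed_volumes = analyzed_volumes,
      design = design
    ),
    class = "gp_pipeline_result"
  )
}

#' @export
print.gp_pipeline_result <- function(x, ...) {
  cat("<gp_pipeline_result>", nrow(x$terminals), "terminals,",
      nrow(x$design), "stacks,",
      length(unique(x$design$subject_id)), "subjects\n")
  cat("marker proportions (%):\n")
  print(x$marker_proportions)
  cat("GAD-class mixtures (%):\n")
  print(x$gad_mixtures)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes the terminal table and per-stack densities as CSV and the summary
#' proportions plus run metadata as JSON.
#'
#' @param result A `gp_pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  terms <- result$terminals |> select(-dplyr::any_of("voxels"))
  utils::write.csv(terms, file.path(dir, "terminals.csv"), row.names = FALSE)
  utils::write.csv(result$densities, file.path(dir, "densities.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(
      marker_proportions = result$marker_proportions,
      gad_mixtures = result$gad_mixtures,
      z_bins = lapply(result$zbin_selections, function(s) range(s$z_bins)),
      n_terminals = nrow(result$terminals)
    ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
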
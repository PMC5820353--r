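#' Channel names used throughout the pipeline
#'
#' Every stack carries five channels: the calcium-binding protein marker
#' (calbindin, calretinin, or parvalbumin, depending on the staining
#' experiment), the vesicular GABA transporter (vGAT) that anchors terminal
#' classification, the two GABA-synthesizing enzyme isoforms GAD65 and GAD67,
#' and a lipofuscin autofluorescence channel used only for artifact exclusion.
#'
#' @format A character vector of length 5.
#' @export
gp_channels <- c("marker", "vgat", "gad65", "gad67", "lipofuscin")

#' GAD content classes of a GABAergic terminal
#'
#' Terminals contain GAD65 only, GAD67 only, or both isoforms.
#'
#' @format A character vector of length 3.
#' @export
gp_gad_classes <- c("GAD65", "GAD67", "GAD65_67")

# default per-class terminal volume distributions (mean/sd, um^3), anchored to
# reported subtype mean volumes; draws are truncated to [0.08, 0.65] um^3 so
# every simulated terminal is within the detectable size range
default_volume_params <- function() {
  tibble::tribble(
    ~gad_class,  ~mean_um3, ~sd_um3,
    "GAD65",     0.32,      0.06,
    "GAD67",     0.41,      0.06,
    "GAD65_67",  0.52,      0.06
  )
}

# default true integrated intensities (log-normal median in a.u., log-sd) per
# marker, terminal class and channel; GAD medians follow the reported per-class
# intensity ratios, vGAT medians follow the reported vGAT ratios, and the
# marker-channel level is a neutral assumption
default_intensity_params <- function(marker) {
  base <- switch(marker,
    CB = tibble::tribble(
      ~gad_class,  ~channel, ~median,
      "GAD65",     "gad65",  27500,
      "GAD65_67",  "gad65",  36300,  # +32% total GAD65 vs GAD65-only
      "GAD67",     "gad67",  22400,
      "GAD65_67",  "gad67",  35840,  # +60% total GAD67 vs GAD67-only
      "GAD65",     "vgat",   13500,
      "GAD67",     "vgat",   20000,  # +48% vGAT vs GAD65-only
      "GAD65_67",  "vgat",   27800   # +39% vGAT vs GAD67-only
    ),
    CR = tibble::tribble(
      ~gad_class,  ~channel, ~median,
      "GAD65",     "gad65",  55043,
      "GAD65_67",  "gad65",  77366,
      "GAD67",     "gad67",  35638,
      "GAD65_67",  "gad67",  58025,
      "GAD65",     "vgat",   30000,
      "GAD67",     "vgat",   33600,
      "GAD65_67",  "vgat",   51400
    ),
    PV = tibble::tribble(
      ~gad_class,  ~channel, ~median,
      "GAD65_67",  "gad65",  25000,
      "GAD67",     "gad67",  15197,
      "GAD65_67",  "gad67",  30277,
      "GAD67",     "vgat",   15000,
      "GAD65_67",  "vgat",   38550   # +157% vGAT vs GAD67-only
    )
  )
  marker_rows <- tibble::tibble(
    gad_class = gp_gad_classes, channel = "marker", median = 25000
  )
  dplyr::bind_rows(base, marker_rows) |>
    dplyr::mutate(sigma = 0.25)
}

# default GAD class mixtures per marker (total gray matter compositions);
# parvalbumin terminals comprise only two subsets, so its GAD65-only
# component is zero
default_gad_mixture <- function(marker) {
  switch(marker,
    CB = c(GAD65 = 0.25, GAD67 = 0.40, GAD65_67 = 0.35),
    CR = c(GAD65 = 0.18, GAD67 = 0.37, GAD65_67 = 0.45),
    PV = c(GAD65 = 0.00, GAD67 = 0.22, GAD65_67 = 0.78)
  )
}

# default terminal densities per marker (terminals per 1000 um^3). Absolute
# densities are not reported, only relative proportions (~50% PV, ~31% CB,
# ~19% CR); these defaults realize that composition at a desk-scale total of
# 8 terminals per 1000 um^3 (an order of magnitude below real cortical
# bouton densities, but enough for stable per-stack statistics).
default_density <- function(marker) {
  switch(marker, CB = 2.48, CR = 1.52, PV = 4.00)
}

#' Configure a synthetic terminal scene
#'
#' Builds the configuration for one simulated image stack: a field of
#' GABAergic terminals of a single calcium-binding protein marker, each
#' carrying vGAT plus GAD65, GAD67 or both, together with lipofuscin
#' autofluorescence blobs, z-edge signal attenuation, and Poisson + Gaussian
#' camera noise. One stack corresponds to one (subject, section, layer, grid
#' position) sampling unit.
#'
#' @param marker Calcium-binding protein of the simulated staining experiment:
#'   `"CB"`, `"CR"`, or `"PV"`.
#' @param field_size_px Integer pair, XY field size in pixels.
#' @param n_zplanes Number of z planes (at least 8).
#' @param voxel_size_um Voxel size in micrometers, order (x, y, z).
#' @param layer Cortical layer label 1-6 attached to the stack.
#' @param density_per_1000um3 Expected terminal density (count per 1000 um^3).
#' @param gad_mixture Named proportions over `GAD65`, `GAD67`, `GAD65_67`
#'   summing to 1. For `marker = "PV"` the `GAD65` component must be 0.
#' @param intensity_params Tibble with columns `gad_class`, `channel`,
#'   `median`, `sigma`: per-class log-normal true integrated intensity (a.u.).
#' @param volume_params Tibble with columns `gad_class`, `mean_um3`, `sd_um3`.
#' @param lipofuscin_density Expected lipofuscin blob density (per 1000 um^3).
#' @param lipofuscin_intensity Peak amplitude (a.u.) of lipofuscin blobs,
#'   rendered into all five channels.
#' @param edge_attenuation_frac Fraction of z planes at each z face over which
#'   signal ramps down toward the faces (linear ramp to 20% at the face).
#'   Set to 0 to disable.
#' @param noise List with elements `gain` (photon gain for Poisson noise),
#'   `read_sd` (Gaussian read noise SD in gray levels), `baseline` (camera
#'   offset in gray levels), or `NULL` for a noise-free render.
#' @param min_spacing_um Minimum distance between terminal centers, enforced
#'   by rejection sampling so that ground truth stays resolvable.
#' @param seed Integer seed controlling scene generation (and, offset by one,
#'   the render noise).
#'
#' @return A `scene_config` object (a named list).
#' @export
scene_config <- function(marker = c("CB", "CR", "PV"),
                         field_size_px = c(512L, 512L),
                         n_zplanes = 20L,
                         voxel_size_um = c(0.267, 0.267, 0.25),
                         layer = 3L,
                         density_per_1000um3 = default_density(marker),
                         gad_mixture = default_gad_mixture(marker),
                         intensity_params = default_intensity_params(marker),
                         volume_params = default_volume_params(),
                         lipofuscin_density = 0.03,
                         lipofuscin_intensity = 1200,
                         edge_attenuation_frac = 0.10,
                         noise = list(gain = 0.1, read_sd = 10, baseline = 100),
                         min_spacing_um = 0.8,
                         seed = 1L) {
  marker <- match.arg(marker)
  cfg <- list(
    marker = marker,
    field_size_px = as.integer(field_size_px),
    n_zplanes = as.integer(n_zplanes),
    voxel_size_um = as.numeric(voxel_size_um),
    layer = as.integer(layer),
    density_per_1000um3 = density_per_1000um3,
    gad_mixture = gad_mixture,
    intensity_params = intensity_params,
    volume_params = volume_params,
    lipofuscin_density = lipofuscin_density,
    lipofuscin_intensity = lipofuscin_intensity,
    edge_attenuation_frac = edge_attenuation_frac,
    noise = noise,
    min_spacing_um = min_spacing_um,
    bit_depth = 16L,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  if (length(cfg$field_size_px) != 2L || any(cfg$field_size_px < 8L)) {
    abort("`field_size_px` must be two integers >= 8.")
  }
  if (cfg$n_zplanes < 8L) abort("`n_zplanes` must be at least 8.")
  if (length(cfg$voxel_size_um) != 3L || any(cfg$voxel_size_um <= 0)) {
    abort("`voxel_size_um` must be three positive numbers (x, y, z).")
  }
  if (!cfg$layer %in% 1:6) abort("`layer` must be in 1..6.")
  if (cfg$density_per_1000um3 < 0) abort("densities must be >= 0.")
  if (cfg$lipofuscin_density < 0) abort("densities must be >= 0.")
  mix <- cfg$gad_mixture
  if (!setequal(names(mix), gp_gad_classes)) {
    abort("`gad_mixture` must be named over GAD65, GAD67, GAD65_67.")
  }
  if (abs(sum(mix) - 1) > 1e-9) abort("`gad_mixture` must sum to 1.")
  if (any(mix < 0)) abort("`gad_mixture` components must be >= 0.")
  if (cfg$marker == "PV" && mix[["GAD65"]] != 0) {
    abort("PV terminals comprise only GAD67 and GAD65/GAD67 subsets; the GAD65 mixture component must be 0.")
  }
  if (cfg$edge_attenuation_frac < 0 || cfg$edge_attenuation_frac > 0.45) {
    abort("`edge_attenuation_frac` must be in [0, 0.45].")
  }
  if (cfg$min_spacing_um < 0) abort("`min_spacing_um` must be >= 0.")
  cfg
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>", x$marker, "terminals,",
      paste(x$field_size_px, collapse = "x"), "px x", x$n_zplanes, "planes,",
      "density", x$density_per_1000um3, "/1000um^3, seed", x$seed, "\n")
  invisible(x)
}
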
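# gadpuncta

Quantitative 3D analysis of GABAergic axon terminal subtypes in multiplex
fluorescence image stacks of cortical tissue.

## The problem

In human prefrontal cortex, GABAergic interneurons are marked largely
non-overlappingly by calbindin (CB), calretinin (CR) or parvalbumin (PV),
and their axon terminals (boutons) synthesize GABA with two enzyme isoforms
— GAD65, GAD67, or both. Quantifying how these terminal subtypes distribute
across cortical layers requires five-channel 3D confocal stacks (marker,
vGAT, GAD65, GAD67, plus a lipofuscin autofluorescence channel), segmented
and classified object by object. `gadpuncta` implements that pipeline:

- **Segmentation** — per-channel difference of Gaussians (σ = 0.7, 2 px),
  Ridler–Calvard (ISODATA) seed threshold, then iterative re-thresholding in
  +25 gray-level steps with a 0.05–0.7 µm³ volume gate, producing disjoint
  3D puncta masks measured on the unfiltered channels.
- **Quality control** — masks restricted to the central 490 × 490 pixels;
  object counts and intensities profiled over 40 normalized depth bins;
  ANOVA + Tukey HSD across bins selects the longest artifact-free contiguous
  depth window; lipofuscin masks (thresholded with no size gate) eliminate
  any overlapping analysis mask.
- **Classification** — object-based colocalization by mutual center overlap:
  vGAT masks become GAD65+, GAD67+ or GAD65/GAD67+ terminals; marker puncta
  become CB/CR/PV terminals by mutual center overlap with a classified vGAT
  mask.
- **Quantification** — densities per 1000 µm³ of QC-analyzed volume,
  laminar assignment by fractional depth, and strict hierarchical averaging
  (stack → layer → section → subject).
- **Inference** — one-way ANOVA, Tukey HSD, two-sample t tests, and the
  Dunnett T3 test (Welch pairwise statistics against the studentized maximum
  modulus distribution, computed by numerical integration). All procedures
  accept raw values or printed (n, mean, SD) summaries.
- **Simulation** — a ground-truth scene generator and renderer
  (Gaussian-blob terminals with center-aligned channels, lipofuscin blobs in
  all channels, z-edge attenuation, Poisson + Gaussian noise) used to
  validate the pipeline end to end, since no raw imaging data are deposited.

See `vignettes/gadpuncta-methods.Rmd` for the full methods account.

## Worked example

Simulate one calbindin-stained stack, segment it, and classify terminals:

```r
library(gadpuncta)

cfg <- scene_config("CB", seed = 42)
scene <- generate_scene(cfg)
stack <- render_stack(scene, cfg)

masks <- lapply(c("marker", "vgat", "gad65", "gad67"),
                function(ch) segment_channel(stack, ch))
names(masks) <- c("marker", "vgat", "gad65", "gad67")
dims <- dim(stack$channels$vgat)

vgat_cls <- classify_gad(masks$vgat, masks$gad65, masks$gad67, dims)
terminals <- classify_marker_terminals(masks$marker, vgat_cls,
                                       masks$gad65, masks$gad67,
                                       dims, marker = "CB")
table(terminals$gad_class)
#>
#>    GAD65    GAD67 GAD65_67
#>       62      104       79
```

The stack was simulated at a GAD-class mixture of 25/40/35 — the classified
counts (25%, 42%, 32% of 245 terminals) recover it within sampling noise of
a single field.

A full multi-subject experiment with depth-bin QC and hierarchical
averaging:

```r
design <- experiment_design(n_subjects = 2, sections_per_subject = 2,
                            markers = c("CB", "PV"), seed = 7)
res <- run_pipeline(design)
res$gad_mixtures
```

Statistics work directly from printed summary values — for example, the
contrast of GAD65 levels between single- and dual-labeled CB terminals:

```r
cb <- tibble::tibble(group = c("GAD65", "dual"), n = 20,
                     mean = c(6887, 5129), sd = c(1726, 1146))
two_sample_t(cb, welch = TRUE)
#> Two-sample t (Welch): t(33.0) = 3.79, p = 0.0005996
round(percent_difference(6887, 5129))
#> [1] 34
```

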
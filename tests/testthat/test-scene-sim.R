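test_that("zero density yields an empty scene", {
  cfg <- quick_config(density = 0, seed = 3)
  sc <- generate_scene(cfg)
  expect_identical(nrow(sc$puncta), 0L)
})

test_that("scene generation is deterministic for a fixed seed", {
  cfg <- quick_config(seed = 11)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_equal(a$puncta, b$puncta)
  expect_equal(a$lipofuscin, b$lipofuscin)
  sa <- render_stack(a, cfg)
  sb <- render_stack(b, cfg)
  expect_identical(sa$channels, sb$channels)
})

test_that("config invariants are enforced", {
  expect_error(scene_config("CB", gad_mixture = c(GAD65 = 0.5, GAD67 = 0.4,
                                                  GAD65_67 = 0.2)),
               "sum to 1")
  expect_error(scene_config("PV", gad_mixture = c(GAD65 = 0.1, GAD67 = 0.2,
                                                  GAD65_67 = 0.7)),
               "PV")
  expect_error(scene_config("CB", n_zplanes = 4), "at least 8")
  expect_error(scene_config("CB", density_per_1000um3 = -1), ">= 0")
})

test_that("PV scenes contain no GAD65-only terminals", {
  cfg <- quick_config("PV", density = 6, seed = 5)
  sc <- generate_scene(cfg)
  expect_false(any(sc$puncta$gad_class == "GAD65"))
  # GAD65-only terminals carry no true GAD67 signal and vice versa
  cb <- generate_scene(quick_config("CB", density = 6, seed = 6))
  expect_true(all(cb$puncta$int_gad67[cb$puncta$gad_class == "GAD65"] == 0))
  expect_true(all(cb$puncta$int_gad65[cb$puncta$gad_class == "GAD67"] == 0))
})

test_that("empirical GAD-class fractions track the configured mixture", {
  # ~10,000 terminals; spacing disabled so only the label mixing is tested
  mix <- c(GAD65 = 0.25, GAD67 = 0.40, GAD65_67 = 0.35)
  cfg <- scene_config("CB", field_size_px = c(512L, 512L), n_zplanes = 70L,
                      density_per_1000um3 = 32, gad_mixture = mix,
                      min_spacing_um = 0, seed = 99)
  sc <- generate_scene(cfg)
  n <- nrow(sc$puncta)
  expect_gt(n, 8000)
  frac <- table(factor(sc$puncta$gad_class, names(mix))) / n
  se <- sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(frac - mix) <= 3 * se))
})

test_that("mixture proportions pass a chi-square GOF sweep over seeds", {
  mix <- c(GAD65 = 0.25, GAD67 = 0.40, GAD65_67 = 0.35)
  pass <- vapply(1:100, function(s) {
    cfg <- scene_config("CB", field_size_px = c(512L, 512L), n_zplanes = 70L,
                        density_per_1000um3 = 32, gad_mixture = mix,
                        min_spacing_um = 0, seed = s)
    sc <- generate_scene(cfg)
    obs <- table(factor(sc$puncta$gad_class, names(mix)))
    suppressWarnings(stats::chisq.test(obs, p = mix)$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 95)
})

test_that("minimum spacing is honored and impossible densities error", {
  cfg <- quick_config(density = 8, seed = 21)
  sc <- generate_scene(cfg)
  p <- sc$puncta
  if (nrow(p) > 1) {
    d <- as.matrix(stats::dist(cbind(p$x_um, p$y_um, p$z_um)))
    diag(d) <- Inf
    expect_gte(min(d), cfg$min_spacing_um)
  }
  dense <- scene_config("CB", field_size_px = c(16L, 16L), n_zplanes = 8L,
                        density_per_1000um3 = 5e4, min_spacing_um = 0.8,
                        seed = 1)
  expect_error(generate_scene(dense), "density")
})

test_that("noise-free rendered mass matches the true integrated intensity", {
  cfg <- clean_config(seed = 8, density = 0.5)
  sc <- generate_scene(cfg)
  # keep puncta well inside the field
  sc$puncta <- sc$puncta[sc$puncta$z_um > 0.8 &
                           sc$puncta$z_um < cfg$n_zplanes * 0.25 - 0.8, ]
  sc$puncta <- sc$puncta[1, , drop = FALSE]
  st <- render_stack(sc, cfg)
  expect_equal(sum(as.numeric(st$channels$vgat)), sc$puncta$int_vgat[1],
               tolerance = 0.01)
  expect_equal(sum(as.numeric(st$channels$marker)), sc$puncta$int_marker[1],
               tolerance = 0.01)
})

test_that("empty scene renders to all-zero channels without noise", {
  cfg <- clean_config(seed = 2, density = 0)
  cfg$lipofuscin_density <- 0
  sc <- generate_scene(cfg)
  st <- render_stack(sc, cfg)
  for (ch in gp_channels) expect_true(all(st$channels[[ch]] == 0L))
})

test_that("lipofuscin blobs appear in all five channels", {
  cfg <- clean_config(seed = 4, density = 0)
  sc <- generate_scene(cfg)
  sc$lipofuscin <- tibble::tibble(
    blob_id = 1L, x_um = 12, y_um = 12, z_um = 1.5, radius_um = 0.9,
    intensity = 3000
  )
  st <- render_stack(sc, cfg)
  vz <- round(1.5 / 0.25 + 0.5); vy <- round(12 / 0.267 + 0.5)
  for (ch in gp_channels) {
    expect_gt(st$channels[[ch]][vz, vy, vy], 0)
  }
})

test_that("z-edge attenuation depresses face-plane signal", {
  cfg <- scene_config("CB", field_size_px = c(64L, 64L), n_zplanes = 10L,
                      density_per_1000um3 = 0, lipofuscin_density = 0,
                      edge_attenuation_frac = 0.15, noise = NULL, seed = 1)
  att <- gadpuncta:::z_attenuation(10L, 0.15)
  expect_equal(att[1], 0.2)
  expect_equal(att[10], 0.2)
  expect_true(all(att[2:9] == 1))
})
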
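dims <- c(12L, 30L, 30L)

test_that("mutual center overlap requires both centers inside the partner", {
  a <- box_vox(3:5, 3:5, 3:5)
  b <- box_vox(3:5, 3:5, 3:5)
  expect_true(centers_mutually_overlap(a, b, dims))
  expect_false(centers_mutually_overlap(a, box_vox(8:10, 8:10, 8:10), dims))
  # L-shaped A whose own centroid voxel falls outside A but inside box B
  l_shape <- rbind(box_vox(3, 3:8, 3), box_vox(3, 8, 3:8))
  cen <- gadpuncta:::center_voxel(l_shape) # (3, 6, 4): not a voxel of A
  expect_false(any(l_shape[, 1] == cen[1] & l_shape[, 2] == cen[2] &
                     l_shape[, 3] == cen[3]))
  b2 <- box_vox(2:4, 5:7, 3:5) # contains A's centroid voxel
  expect_false(centers_mutually_overlap(b2, l_shape, dims))
})

# one terminal-like mask trio at a given center
trio <- function(id, z, y, x) {
  list(
    vgat = mask_row(id, box_vox(z + (-1:1), y + (-1:1), x + (-1:1)), "vgat"),
    gad = box_vox(z + (-1:1), y + (-1:1), x + (-1:1))
  )
}

test_that("GAD classification follows the mutual-center and exclusion rules", {
  vgat <- dplyr::bind_rows(
    mask_row(1L, box_vox(3:5, 3:5, 3:5), "vgat"),    # partner GAD65 only
    mask_row(2L, box_vox(3:5, 12:14, 12:14), "vgat"), # partner both
    mask_row(3L, box_vox(3:5, 22:24, 22:24), "vgat")  # no GAD partner
  )
  gad65 <- dplyr::bind_rows(
    mask_row(1L, box_vox(3:5, 3:5, 3:5), "gad65"),
    mask_row(2L, box_vox(3:5, 12:14, 12:14), "gad65")
  )
  gad67 <- mask_row(1L, box_vox(3:5, 12:14, 12:14), "gad67")
  cls <- classify_gad(vgat, gad65, gad67, dims)
  expect_equal(as.character(cls$gad_class), c("GAD65", "GAD65_67", NA))
  expect_equal(cls$gad65_id, c(1L, 2L, NA))
  expect_equal(cls$gad67_id, c(NA, 1L, NA))
})

test_that("any-voxel GAD67 contact blocks the GAD65-only class", {
  vgat <- mask_row(1L, box_vox(3:5, 3:5, 3:5), "vgat")
  gad65 <- mask_row(1L, box_vox(3:5, 3:5, 3:5), "gad65")
  # GAD67 mask sharing one voxel with the vGAT mask, centers not mutual
  gad67 <- mask_row(1L, box_vox(5:7, 5:7, 5:7), "gad67")
  cls <- classify_gad(vgat, gad65, gad67, dims)
  expect_true(is.na(cls$gad_class[1]))
  # under the center-overlap exclusion reading it stays GAD65
  cls2 <- classify_gad(vgat, gad65, gad67, dims, overlap_mode = "center")
  expect_equal(as.character(cls2$gad_class[1]), "GAD65")
})

test_that("classification is symmetric in the two GAD channels", {
  set.seed(5)
  cfg <- quick_config(seed = 5, field = 96L, density = 5)
  st <- render_stack(generate_scene(cfg), cfg)
  vgat <- segment_channel(st, "vgat")
  g65 <- segment_channel(st, "gad65")
  g67 <- segment_channel(st, "gad67")
  d <- dim(st$channels$vgat)
  a <- classify_gad(vgat, g65, g67, d)
  b <- classify_gad(vgat, g67, g65, d) # swapped channels
  swap <- c(GAD65 = "GAD67", GAD67 = "GAD65", GAD65_67 = "GAD65_67")
  expect_equal(as.character(a$gad_class),
               unname(swap[as.character(b$gad_class)]))
})

test_that("marker puncta become terminals only via classified vGAT partners", {
  marker <- dplyr::bind_rows(
    mask_row(1L, box_vox(3:5, 3:5, 3:5), "marker"),   # partner: GAD67 vGAT
    mask_row(2L, box_vox(3:5, 12:14, 12:14), "marker"), # partner: unclassified
    mask_row(3L, box_vox(3:5, 22:24, 22:24), "marker")  # no vGAT partner
  )
  vgat <- dplyr::bind_rows(
    mask_row(1L, box_vox(3:5, 3:5, 3:5), "vgat"),
    mask_row(2L, box_vox(3:5, 12:14, 12:14), "vgat")
  )
  gad67 <- mask_row(1L, box_vox(3:5, 3:5, 3:5), "gad67")
  cls <- classify_gad(vgat, gadpuncta:::empty_mask_table("gad65"), gad67, dims)
  # measured columns required by the terminal table
  for (tab in c("marker", "vgat")) {
    t_ <- get(tab)
    for (ch in gp_channels) {
      t_[[paste0("sum_", ch)]] <- 1
      t_[[paste0("mean_", ch)]] <- 1
    }
    assign(tab, t_)
  }
  cls2 <- cls
  for (ch in gp_channels) {
    cls2[[paste0("sum_", ch)]] <- 1
    cls2[[paste0("mean_", ch)]] <- 1
  }
  terms <- classify_marker_terminals(marker, cls2, dims = dims, marker = "CB")
  expect_equal(nrow(terms), 1L)
  expect_equal(terms$marker_id, 1L)
  expect_equal(as.character(terms$gad_class), "GAD67")
  expect_equal(terms$marker, "CB")
})

test_that("somatic GAD mRNA expression needs 5 molecules above 2.5x neuropil", {
  rec <- tibble::tibble(
    cell_id = 1:4,
    gad65_count = c(5L, 4L, 0L, 10L),
    gad67_count = c(0L, 20L, 3L, 10L),
    soma_area = c(10, 10, 10, 10)
  )
  out <- classify_soma_mrna(rec, neuropil_density_gad65 = 0,
                            neuropil_density_gad67 = 0.5)
  expect_equal(out$expresses_gad65, c(TRUE, FALSE, FALSE, TRUE))
  # 20/10 = 2 > 1.25 TRUE; 10/10 = 1 < 1.25 FALSE
  expect_equal(out$expresses_gad67, c(FALSE, TRUE, FALSE, FALSE))
  expect_error(
    classify_soma_mrna(dplyr::mutate(rec, soma_area = 0), 0, 0),
    "soma_area"
  )
})

test_that("classified scenes partition vGAT masks and recover the mixture", {
  cfg <- quick_config(seed = 13, field = 128L, density = 5,
                      edge_attenuation_frac = 0, lipofuscin_density = 0)
  sc <- generate_scene(cfg)
  st <- render_stack(sc, cfg)
  vgat <- segment_channel(st, "vgat")
  g65 <- segment_channel(st, "gad65")
  g67 <- segment_channel(st, "gad67")
  cls <- classify_gad(vgat, g65, g67, dim(st$channels$vgat))
  # each classified mask has exactly one class; proportions sum to 1
  p <- table(cls$gad_class) / sum(!is.na(cls$gad_class))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  truth <- table(factor(sc$puncta$gad_class, gp_gad_classes)) /
    nrow(sc$puncta)
  expect_true(all(abs(p - truth) < 0.12)) # small-n scene, coarse agreement
})
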
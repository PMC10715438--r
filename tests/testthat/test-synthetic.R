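test_that("homogeneous sampling realizes the Poisson mean", {
  # 100 cells/mm2 on a 1 mm^2 all-stroma ROI
  cfg <- simulation_config(seed = 1, roi_width_um = 1000, roi_height_um = 1000,
                           pixel_size_um = 2, tci_fraction = 0,
                           n_vessels_per_roi = 0L,
                           phenotype_intensities = list(OTHER = c(stroma = 100,
                                                                  tci = 0)),
                           pv_enrichment = c(OTHER = 1),
                           n_seeded_clusters_per_roi = 0L)
  set.seed(61)
  g <- generate_roi_geometry(cfg, "r")
  n <- nrow(sample_cells(g, cfg, "untreated_DF")$cells)
  expect_gte(n, qpois(0.005, 100))
  expect_lte(n, qpois(0.995, 100))
})

test_that("perivascular enrichment is recovered from the point process", {
  base <- list(seed = 1, roi_width_um = 300, roi_height_um = 300,
               pixel_size_um = 2, tci_fraction = 0, n_vessels_per_roi = 2L,
               n_seeded_clusters_per_roi = 0L)
  run_ratio <- function(rho, n_roi) {
    cfg <- do.call(simulation_config, c(base, list(
      phenotype_intensities = list(TAM = c(stroma = 200, tci = 0)),
      pv_enrichment = c(TAM = rho))))
    cnt <- c(pv = 0, nonpv = 0); ar <- c(pv = 0, nonpv = 0)
    for (i in seq_len(n_roi)) {
      g <- generate_roi_geometry(cfg, "r")
      a <- compartment_areas(g)
      cells <- sample_cells(g, cfg, "untreated_DF")$cells
      cmp <- as.character(classify_cells(cells, g))
      cnt <- cnt + c(sum(cmp == "STROMA_PV"), sum(cmp == "STROMA_NONPV"))
      ar <- ar + c(a$area_mm2[a$compartment == "STROMA_PV"],
                   a$area_mm2[a$compartment == "STROMA_NONPV"])
    }
    (cnt[1] / ar[1]) / (cnt[2] / ar[2])
  }
  set.seed(62)
  expect_equal(unname(run_ratio(1, 60)), 1, tolerance = 0.1)
  set.seed(63)
  expect_equal(unname(run_ratio(3, 200)), 3, tolerance = 0.1)
})

test_that("no generated cell lies strictly inside a vessel", {
  cfg <- small_config(n_vessels_per_roi = 5L)
  set.seed(64)
  g <- generate_roi_geometry(cfg, "r")
  cells <- sample_cells(g, cfg, "NAC_Mets")$cells
  expect_true(all(distance_to_vessel(cells$x_um, cells$y_um, g) >= 0))
})

test_that("group effects scale expected and realized densities", {
  cfg <- small_config()
  set.seed(65)
  g <- generate_roi_geometry(cfg, "r")
  ed <- sample_cells(g, cfg, "NAC_DF")$expected_density
  ed0 <- sample_cells(g, cfg, "NAC_Mets")$expected_density
  tam <- ed$expected_per_mm2[ed$phenotype == "TAM"]
  tam0 <- ed0$expected_per_mm2[ed0$phenotype == "TAM"]
  expect_equal(tam, 2 * tam0)                  # default NAC_DF TAM effect
  other <- ed$phenotype != "TAM"
  expect_equal(ed$expected_per_mm2[other], ed0$expected_per_mm2[other])
  # PV enrichment is encoded in the expected densities
  expect_equal(
    ed$expected_per_mm2[ed$phenotype == "CD4_T" & ed$compartment == "STROMA_PV"],
    3 * ed$expected_per_mm2[ed$phenotype == "CD4_T" &
                            ed$compartment == "STROMA_NONPV"])
})

test_that("seeded clusters sit wholly in perivascular stroma under contact", {
  cfg <- small_config(n_seeded_clusters_per_roi = 5L)
  set.seed(66)
  g <- generate_roi_geometry(cfg, "r")
  sc <- sample_cells(g, cfg, "untreated_Mets")
  se <- seed_clusters(g, sc$cells, cfg, "untreated_Mets")
  expect_identical(length(se$seeded_ids), 5L)
  seeded <- se$cells[se$cells$seeded, ]
  expect_identical(nrow(seeded), 15L)
  lab <- as.character(classify_cells(seeded, g))
  expect_true(all(lab == "STROMA_PV"))
  for (trip in se$seeded_ids) {
    m <- se$cells[match(trip, se$cells$cell_id), ]
    expect_lte(max(dist(m[, c("x_um", "y_um")])), cfg$contact_threshold_um)
  }
  # n = 0 leaves the table untouched
  cfg0 <- small_config(n_seeded_clusters_per_roi = 0L)
  expect_identical(seed_clusters(g, sc$cells, cfg0, "untreated_Mets")$cells,
                   sc$cells)
  # impossible placement errors out
  gnv <- roi_geometry("r", 400, 400, pixel_size_um = 2)   # no vessels
  expect_error(seed_clusters(gnv, sc$cells, cfg, "untreated_Mets"),
               "no perivascular stroma")
})

test_that("cohort generation is deterministic and correctly sized", {
  cfg <- simulation_config(seed = 9, n_tumors_per_group = 2L,
                           rois_per_tumor = 3L, roi_width_um = 300,
                           roi_height_um = 300, pixel_size_um = 2.5,
                           n_vessels_per_roi = 2L,
                           n_seeded_clusters_per_roi = 1L)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(nrow(b1$manifest), 8L)      # 4 groups x 2 tumors
  expect_identical(length(b1$rois), 24L)       # x 3 ROIs
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(lapply(b1$rois, `[[`, "cells"),
                   lapply(b2$rois, `[[`, "cells"))
  expect_identical(lapply(b1$rois, `[[`, "geometry"),
                   lapply(b2$rois, `[[`, "geometry"))
})

test_that("a written study directory is byte-identical across runs and loads back", {
  cfg <- simulation_config(seed = 13, n_tumors_per_group = 1L,
                           rois_per_tumor = 2L, roi_width_um = 300,
                           roi_height_um = 300, pixel_size_um = 2.5,
                           n_vessels_per_roi = 2L,
                           n_seeded_clusters_per_roi = 1L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, out_dir = d1)
  generate_cohort(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1)); h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  # round trip through the readers
  b <- load_cohort(d1, pixel_size_um = 2.5)
  expect_identical(nrow(b$manifest), 4L)
  rid <- names(b$rois)[1]
  orig <- generate_cohort(cfg)$rois[[rid]]
  expect_identical(b$rois[[rid]]$cells$cell_id, orig$cells$cell_id)
  expect_equal(b$rois[[rid]]$cells$x_um, orig$cells$x_um)
  for (m in MARKERS)
    expect_identical(b$rois[[rid]]$cells[[m]], orig$cells[[m]])
})
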
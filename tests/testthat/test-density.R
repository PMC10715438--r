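area_fixture <- function(roi = "r1", pv = 0.25, nonpv = 0.5, tci_pv = 0,
                         tci_nonpv = 0.1) {
  data.frame(roi_id = roi,
             compartment = pvniche:::ALL_COMPARTMENTS,
             area_mm2 = c(tci_pv, tci_nonpv, pv, nonpv, 0.01))
}

test_that("roi_density divides counts by compartment area, NA on zero area", {
  cells <- gate_cells(make_cells(
    c("CD163"), c("CD163"), c("CD163"), c("CD163"), c("CD163"),
    c("CD3", "CD4")))
  cells$compartment <- c(rep("STROMA_PV", 5), "STROMA_NONPV")
  d <- roi_density(cells, area_fixture(), c(TAM = "phenotype == 'TAM'"))
  expect_equal(d$density_per_mm2[d$compartment == "STROMA_PV"], 20)   # 5/0.25
  expect_equal(d$density_per_mm2[d$compartment == "STROMA_NONPV"], 0)
  expect_true(is.na(d$density_per_mm2[d$compartment == "TCI_PV"]))
  expect_error(roi_density(cells, area_fixture(), "unnamed"), "named")
})

test_that("selector-based counting matches a brute-force row filter", {
  set.seed(30)
  cfg <- small_config()
  g <- generate_roi_geometry(cfg, "r")
  cells <- gate_cells(sample_cells(g, cfg, "NAC_DF")$cells)
  cells$compartment <- classify_cells(cells, g)
  areas <- compartment_areas(g)
  sel <- "phenotype == 'TAM' & tam_tim3 & !tam_pdl1"
  d <- roi_density(cells, areas, c(x = sel))
  for (cmp in pvniche:::COMPARTMENTS) {
    manual <- sum(cells$phenotype == "TAM" & cells$tam_tim3 %in% TRUE &
                  cells$tam_pdl1 %in% FALSE & cells$compartment == cmp)
    expect_identical(d$count[d$compartment == cmp], manual)
  }
})

test_that("two-level aggregation: tumor mean over ROIs, group mean +/- SEM", {
  rows <- data.frame(
    roi_id = c("r1", "r2", "r3", "r4", "r5"),
    compartment = "STROMA_PV", phenotype_selector = "TAM",
    count = 1L, area_mm2 = 1,
    density_per_mm2 = c(10, 20, 30, 10, 20))
  map <- data.frame(roi_id = paste0("r", 1:5),
                    tumor_id = c("t1", "t1", "t1", "t2", "t2"),
                    group = "NAC_DF")
  agg <- aggregate_density(rows, map)
  expect_equal(agg$tumor$value, c(20, 15))        # {10,20,30} -> 20; {10,20} -> 15
  expect_equal(agg$group$mean, 17.5)
  expect_equal(agg$group$sem, sd(c(20, 15)) / sqrt(2))
  expect_identical(agg$group$n, 2L)
  # permuting ROI order leaves aggregates unchanged
  agg2 <- aggregate_density(rows[c(4, 2, 5, 1, 3), ], map)
  expect_equal(agg2$group, agg$group)
  # group of tumors {10, 20}: mean 15, SEM 5
  agg3 <- aggregate_density(rows[4:5, ],
                            data.frame(roi_id = c("r4", "r5"),
                                       tumor_id = c("a", "b"), group = "g"))
  expect_equal(agg3$group$mean, 15)
  expect_equal(agg3$group$sem, 5)
})

test_that("NA ROIs are dropped from tumor means, not zero-filled", {
  rows <- data.frame(roi_id = c("r1", "r2"), compartment = "TCI_PV",
                     phenotype_selector = "TAM", count = c(0L, 4L),
                     area_mm2 = c(0, 0.1),
                     density_per_mm2 = c(NA, 40))
  map <- data.frame(roi_id = c("r1", "r2"), tumor_id = "t1", group = "g")
  agg <- aggregate_density(rows, map)
  expect_equal(agg$tumor$value, 40)
  expect_identical(agg$tumor$n_roi, 1L)
  # tumor with zero non-NA ROIs warns and yields NA
  rows$density_per_mm2 <- NA_real_
  expect_warning(agg0 <- aggregate_density(rows, map), "no non-NA ROI")
  expect_true(is.na(agg0$tumor$value))
})

test_that("density is additive over disjoint phenotype selectors", {
  set.seed(33)
  cfg <- small_config()
  g <- generate_roi_geometry(cfg, "r")
  cells <- gate_cells(sample_cells(g, cfg, "untreated_DF")$cells)
  cells$compartment <- classify_cells(cells, g)
  areas <- compartment_areas(g)
  d <- roi_density(cells, areas,
                   c(all = "phenotype == 'TAM'",
                     pos = "phenotype == 'TAM' & tam_pdl1",
                     neg = "phenotype == 'TAM' & !tam_pdl1"))
  for (cmp in pvniche:::COMPARTMENTS) {
    sub <- d[d$compartment == cmp, ]
    if (!any(is.na(sub$density_per_mm2)))
      expect_equal(sub$density_per_mm2[sub$phenotype_selector == "all"],
                   sum(sub$density_per_mm2[sub$phenotype_selector != "all"]))
  }
})

test_that("tumors contribute equally regardless of ROI count", {
  rows <- data.frame(
    roi_id = sprintf("r%d", 1:11),
    compartment = "STROMA_PV", phenotype_selector = "TAM",
    count = 1L, area_mm2 = 1,
    density_per_mm2 = c(rep(100, 10), 0))
  map <- data.frame(roi_id = sprintf("r%d", 1:11),
                    tumor_id = c(rep("big", 10), "small"), group = "g")
  agg <- aggregate_density(rows, map)
  expect_equal(agg$group$mean, 50)   # (100 + 0) / 2, not 1000/11
})
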
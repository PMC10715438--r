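test_that("contact_graph matches explicit distances and edge cases", {
  cells <- data.frame(x_um = c(0, 11, 50, 50), y_um = c(0, 0, 50, 50))
  e <- contact_graph(cells, 12)
  expect_identical(nrow(e), 2L)                # (1,2) at 11um, (3,4) at 0um
  expect_identical(e[, "i"], c(1, 3))
  e0 <- contact_graph(cells, 0)
  expect_identical(nrow(e0), 1L)               # only the coincident pair
  expect_identical(unname(e0[1, c("i", "j")]), c(3, 4))
  expect_error(contact_graph(cells, -1), ">= 0")
})

test_that("spatial-index edge set equals the brute-force all-pairs set", {
  set.seed(40)
  for (rep in 1:3) {
    n <- 100
    cells <- data.frame(x_um = runif(n, 0, 150), y_um = runif(n, 0, 150))
    th <- c(8, 12, 25)[rep]
    e <- contact_graph(cells, th)
    dm <- as.matrix(dist(cells))
    brute <- which(upper.tri(dm) & dm <= th, arr.ind = TRUE)
    brute <- brute[order(brute[, 1], brute[, 2]), , drop = FALSE]
    expect_identical(unname(e[, c("i", "j")]),
                     unname(cbind(as.numeric(brute[, 1]),
                                  as.numeric(brute[, 2]))))
  }
})

triple_cells <- function(phenos, x, y) {
  df <- data.frame(cell_id = sprintf("c%d", seq_along(phenos)),
                   x_um = x, y_um = y,
                   phenotype = phenos,
                   activation = ifelse(phenos %in% c("CD4_T", "CD8_T"),
                                       "NAIVE", NA),
                   tam_pdl1 = ifelse(phenos == "TAM", FALSE, NA),
                   tam_tim3 = ifelse(phenos == "TAM", FALSE, NA))
  df
}

test_that("find_triples requires the exact TAM / T cell / Treg composition", {
  # TAM + CD4 + CD4: no Treg, no cluster
  t1 <- triple_cells(c("TAM", "CD4_T", "CD4_T"), c(0, 5, 10), c(0, 5, 0))
  expect_identical(nrow(find_triples(t1, 12)), 0L)
  # TAM + CD4 + Treg triangle: one cluster
  t2 <- triple_cells(c("TAM", "CD4_T", "TREG"), c(0, 5, 10), c(0, 5, 0))
  r2 <- find_triples(t2, 12)
  expect_identical(nrow(r2), 1L)
  expect_identical(r2$tcell_lineage, "CD4_T")
  # TAM + CD4 + CD8 + Treg all mutually in contact: two clusters
  t3 <- triple_cells(c("TAM", "CD4_T", "CD8_T", "TREG"),
                     c(0, 6, 0, 6), c(0, 0, 6, 6))
  r3 <- find_triples(t3, 12)
  expect_identical(nrow(r3), 2L)
  expect_setequal(r3$tcell_lineage, c("CD4_T", "CD8_T"))
  # triangle mode requires the Treg to touch both others
  t4 <- triple_cells(c("TAM", "CD4_T", "TREG"), c(0, 10, 20), c(0, 0, 0))
  expect_identical(nrow(find_triples(t4, 12)), 0L)
  expect_identical(nrow(find_triples(t4, 12, mode = "path")), 1L)
})

test_that("triangle enumeration equals the full triple scan", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 150
    cells <- data.frame(
      cell_id = sprintf("c%d", 1:n),
      x_um = runif(n, 0, 120), y_um = runif(n, 0, 120),
      phenotype = sample(c("TAM", "CD4_T", "CD8_T", "TREG", "OTHER"),
                         n, replace = TRUE),
      activation = "NAIVE", tam_pdl1 = FALSE, tam_tim3 = FALSE)
    th <- 15
    got <- find_triples(cells, th)
    dm <- as.matrix(dist(cells[, c("x_um", "y_um")]))
    tams <- which(cells$phenotype == "TAM")
    ts <- which(cells$phenotype %in% c("CD4_T", "CD8_T"))
    tgs <- which(cells$phenotype == "TREG")
    brute <- 0L
    for (a in tams) for (b in ts) for (c in tgs)
      if (dm[a, b] <= th && dm[a, c] <= th && dm[b, c] <= th)
        brute <- brute + 1L
    expect_identical(nrow(got), brute)
  }
})

test_that("triple count is monotone in the contact threshold", {
  set.seed(42)
  n <- 200
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:n),
    x_um = runif(n, 0, 200), y_um = runif(n, 0, 200),
    phenotype = sample(c("TAM", "CD4_T", "CD8_T", "TREG"), n, replace = TRUE),
    activation = "NAIVE", tam_pdl1 = FALSE, tam_tim3 = FALSE)
  counts <- vapply(c(5, 10, 15, 20, 30), function(th)
    nrow(find_triples(cells, th)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("cluster density and composition summarize detected triples", {
  tri <- data.frame(
    roi_id = "r1",
    tam_id = sprintf("m%d", 1:10), tcell_id = sprintf("t%d", 1:10),
    treg_id = sprintf("g%d", 1:10),
    tcell_lineage = "CD4_T",
    tcell_activation = c(rep("NAIVE", 4), rep("ACTIVE", 6)),
    tam_pdl1 = rep(FALSE, 10), tam_tim3 = rep(c(TRUE, FALSE), 5),
    x_um = 1:10, y_um = 1, max_pairwise_um = 6,
    compartment = c(rep("STROMA_PV", 2), rep("STROMA_NONPV", 8)))
  areas <- data.frame(roi_id = "r1",
                      compartment = pvniche:::ALL_COMPARTMENTS,
                      area_mm2 = c(0.1, 0.1, 0.5, 0.8, 0))
  cd <- cluster_density(tri, areas)
  expect_equal(cd$density_per_mm2[cd$compartment == "STROMA_PV" &
                                  cd$phenotype_selector == "cluster_CD4"], 4)
  expect_equal(sum(cd$count[cd$phenotype_selector == "cluster_CD8"]), 0L)
  cc <- cluster_composition(tri)
  expect_equal(cc$p_naive, 0.4)
  expect_equal(cc$p_active, 0.6)
  expect_equal(cc$p_exhausted, 0)
  expect_equal(cc$p_naive + cc$p_active + cc$p_exhausted, 1)
  expect_equal(cc$p_tam_pdl1_neg, 1)
  expect_equal(cc$p_tam_pdl1_pos + cc$p_tam_pdl1_neg, 1)
  expect_equal(cc$tim3_ratio_in_pdl1neg, 1)     # 5 TIM3+ : 5 TIM3-
})

test_that("disjoint counting keeps compact clusters and shares no members", {
  tri <- data.frame(
    roi_id = "r", tam_id = c("m1", "m1"), tcell_id = c("t1", "t2"),
    treg_id = c("g1", "g1"), tcell_lineage = "CD4_T",
    tcell_activation = "NAIVE", tam_pdl1 = FALSE, tam_tim3 = FALSE,
    x_um = 0, y_um = 0, max_pairwise_um = c(8, 5))
  dj <- disjoint_clusters(tri)
  expect_identical(nrow(dj), 1L)
  expect_identical(dj$tcell_id, "t2")           # the more compact triple wins
})
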
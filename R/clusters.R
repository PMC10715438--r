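#' Contact graph of cells
#'
#' Builds the undirected graph with an edge between every pair of cells
#' whose centroid distance is `<=` the contact threshold. Candidate pairs
#' are found with a grid spatial index (bucket side = threshold), so typical
#' cost is O(n k), but the edge set is identical to the all-pairs
#' computation.
#'
#' @param cells data frame with `x_um`, `y_um`.
#' @param contact_threshold_um non-negative contact distance in micrometers
#'   (default 12, roughly two touching leukocyte radii).
#' @return integer matrix with columns `i`, `j` (row indices into `cells`,
#'   `i < j`) and a numeric `dist_um` attribute-free third column.
#' @export
contact_graph <- function(cells, contact_threshold_um = 12) {
  if (contact_threshold_um < 0) stop("contact threshold must be >= 0")
  n <- nrow(cells)
  empty <- cbind(i = integer(), j = integer(), dist_um = numeric())
  if (n < 2L) return(empty)
  x <- cells$x_um; y <- cells$y_um
  h <- max(contact_threshold_um, 1e-9)
  gx <- floor(x / h); gy <- floor(y / h)
  key <- paste(gx, gy)
  buckets <- split(seq_len(n), key)
  bkey <- function(a, b) paste(a, b)
  pairs_i <- integer(); pairs_j <- integer()
  # each cell checked against its own and 4 forward-neighbor buckets, so
  # every unordered pair is examined exactly once
  offs <- list(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))
  for (b in names(buckets)) {
    ii <- buckets[[b]]
    g <- as.numeric(strsplit(b, " ", fixed = TRUE)[[1L]])
    for (o in offs) {
      jj <- if (o[1] == 0 && o[2] == 0) ii
            else buckets[[bkey(g[1] + o[1], g[2] + o[2])]]
      if (is.null(jj)) next
      if (o[1] == 0 && o[2] == 0) {
        if (length(ii) < 2L) next
        cmb <- utils::combn(ii, 2L)
        pairs_i <- c(pairs_i, cmb[1L, ]); pairs_j <- c(pairs_j, cmb[2L, ])
      } else {
        pi <- rep(ii, times = length(jj)); pj <- rep(jj, each = length(ii))
        pairs_i <- c(pairs_i, pmin(pi, pj)); pairs_j <- c(pairs_j, pmax(pi, pj))
      }
    }
  }
  if (!length(pairs_i)) return(empty)
  d <- sqrt((x[pairs_i] - x[pairs_j])^2 + (y[pairs_i] - y[pairs_j])^2)
  keep <- d <= contact_threshold_um
  e <- cbind(i = pairs_i[keep], j = pairs_j[keep], dist_um = d[keep])
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Detect three-cell perivascular-style clusters
#'
#' Enumerates all triangles (mutually contacting triples) in the contact
#' graph whose members are exactly one TAM, one CD4+ or CD8+ T cell, and one
#' Treg. Each unique id-triple is reported once; a cell may appear in
#' several triples (see [disjoint_clusters()] for the greedy disjoint
#' count). In `mode = "path"`, the TAM-Treg contact is not required (the
#' triple need only be connected through the T cell or any chain).
#'
#' @param cells labeled cell table (phenotyped, with `cell_id`, `x_um`,
#'   `y_um`; a `compartment` column is copied into the output if present).
#' @param contact_threshold_um contact distance, as [contact_graph()].
#' @param geometry optional [roi_geometry]; when supplied, each cluster
#'   centroid is classified into a compartment (ties cannot occur: the
#'   centroid has one compartment; the TAM's compartment is retained as
#'   `tam_compartment` for reference).
#' @param pv_threshold_um perivascular threshold for centroid
#'   classification.
#' @param mode `"triangle"` (default; all three pairwise contacts required)
#'   or `"path"` (connected triple).
#' @return data frame of cluster records: member ids, `tcell_lineage`,
#'   `tcell_activation`, `tam_pdl1`, `tam_tim3`, centroid coordinates,
#'   `max_pairwise_um`, and `compartment` when `geometry` is given.
#' @export
find_triples <- function(cells, contact_threshold_um = 12, geometry = NULL,
                         pv_threshold_um = 50,
                         mode = c("triangle", "path")) {
  mode <- match.arg(mode)
  stopifnot(all(c("phenotype", "cell_id", "x_um", "y_um") %in% names(cells)))
  ph <- as.character(cells$phenotype)
  keep <- ph %in% c("TAM", "CD4_T", "CD8_T", "TREG")
  idx <- which(keep)
  edges <- contact_graph(cells[idx, , drop = FALSE], contact_threshold_um)
  # adjacency over the kept subset
  nk <- length(idx)
  adj <- vector("list", nk)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  phk <- ph[idx]
  tams <- which(phk == "TAM")
  recs <- list()
  dist2 <- function(a, b)
    sqrt((cells$x_um[idx[a]] - cells$x_um[idx[b]])^2 +
         (cells$y_um[idx[a]] - cells$y_um[idx[b]])^2)
  for (m in tams) {
    nb <- adj[[m]]
    if (length(nb) < 1L || (mode == "triangle" && length(nb) < 2L)) next
    tcells <- nb[phk[nb] %in% c("CD4_T", "CD8_T")]
    tregs <- nb[phk[nb] == "TREG"]
    for (tc in tcells) for (tg in tregs) {
      ok <- if (mode == "triangle") tg %in% adj[[tc]] else TRUE
      if (!ok) next
      recs[[length(recs) + 1L]] <- c(m, tc, tg)
    }
    if (mode == "path") {
      # connected-but-not-mutual triples: chains centered on the T cell
      # (Treg touches the T cell, not the TAM) or on the Treg (T cell
      # touches the Treg, not the TAM)
      for (tc in tcells) {
        tg2 <- adj[[tc]][phk[adj[[tc]]] == "TREG"]
        for (tg in setdiff(tg2, tregs))
          recs[[length(recs) + 1L]] <- c(m, tc, tg)
      }
      for (tg in tregs) {
        tc2 <- adj[[tg]][phk[adj[[tg]]] %in% c("CD4_T", "CD8_T")]
        for (tc in setdiff(tc2, tcells))
          recs[[length(recs) + 1L]] <- c(m, tc, tg)
      }
    }
  }
  if (!length(recs)) {
    out <- data.frame(roi_id = character(), tam_id = character(),
                      tcell_id = character(), treg_id = character(),
                      tcell_lineage = character(),
                      tcell_activation = character(),
                      tam_pdl1 = logical(), tam_tim3 = logical(),
                      x_um = numeric(), y_um = numeric(),
                      max_pairwise_um = numeric())
    if (!is.null(geometry)) out$compartment <- character()
    return(out)
  }
  tri <- unique(do.call(rbind, recs))
  gi <- function(k) idx[tri[, k]]
  roi <- if ("roi_id" %in% names(cells)) as.character(cells$roi_id[gi(1L)])
         else NA_character_
  cx <- (cells$x_um[gi(1L)] + cells$x_um[gi(2L)] + cells$x_um[gi(3L)]) / 3
  cy <- (cells$y_um[gi(1L)] + cells$y_um[gi(2L)] + cells$y_um[gi(3L)]) / 3
  maxd <- pmax(dist2(tri[, 1L], tri[, 2L]), dist2(tri[, 1L], tri[, 3L]),
               dist2(tri[, 2L], tri[, 3L]))
  out <- data.frame(
    roi_id = roi,
    tam_id = as.character(cells$cell_id[gi(1L)]),
    tcell_id = as.character(cells$cell_id[gi(2L)]),
    treg_id = as.character(cells$cell_id[gi(3L)]),
    tcell_lineage = ph[gi(2L)],
    tcell_activation = as.character(cells$activation[gi(2L)]),
    tam_pdl1 = as.logical(cells$tam_pdl1[gi(1L)]),
    tam_tim3 = as.logical(cells$tam_tim3[gi(1L)]),
    x_um = cx, y_um = cy, max_pairwise_um = maxd)
  if (!is.null(geometry)) {
    out$compartment <- as.character(classify_cells(out, geometry,
                                                   pv_threshold_um))
    if ("compartment" %in% names(cells))
      out$tam_compartment <- as.character(cells$compartment[gi(1L)])
  }
  out[order(out$tam_id, out$tcell_id, out$treg_id), , drop = FALSE]
}

#' Greedy disjoint cluster count
#'
#' Alternative counting rule in which no cell belongs to more than one
#' cluster: triples are accepted greedily by compactness (smallest maximum
#' pairwise distance first), skipping any triple sharing a member with an
#' accepted one.
#'
#' @param triples output of [find_triples()].
#' @return subset of `triples` with pairwise-disjoint members.
#' @export
disjoint_clusters <- function(triples) {
  if (nrow(triples) == 0L) return(triples)
  ord <- order(triples$max_pairwise_um, triples$tam_id, triples$tcell_id,
               triples$treg_id)
  used <- character()
  keep <- logical(nrow(triples))
  for (r in ord) {
    ids <- c(triples$tam_id[r], triples$tcell_id[r], triples$treg_id[r])
    if (!any(ids %in% used)) {
      keep[r] <- TRUE
      used <- c(used, ids)
    }
  }
  triples[keep, , drop = FALSE]
}

#' Cluster densities per compartment
#'
#' Clusters per mm2 by compartment (each cluster assigned by its centroid's
#' compartment) and T-cell lineage, in the same row format as
#' [roi_density()] so that [aggregate_density()] applies unchanged.
#'
#' @param triples output of [find_triples()] with a `compartment` column.
#' @param areas compartment area table from [compartment_areas()].
#' @param by_lineage split counts by `tcell_lineage` (default `TRUE`).
#' @return density rows (`roi_id`, `compartment`, `phenotype_selector`,
#'   `count`, `area_mm2`, `density_per_mm2`).
#' @export
cluster_density <- function(triples, areas, by_lineage = TRUE) {
  a <- areas[areas$compartment %in% COMPARTMENTS, ]
  sels <- if (by_lineage)
    c(cluster_CD4 = "CD4_T", cluster_CD8 = "CD8_T") else c(cluster = NA)
  out <- do.call(rbind, lapply(names(sels), function(nm) {
    sub <- if (is.na(sels[[nm]])) triples else
      triples[triples$tcell_lineage == sels[[nm]], , drop = FALSE]
    cnt <- vapply(a$compartment, function(cmp)
      sum(sub$compartment == cmp), integer(1L))
    data.frame(roi_id = a$roi_id, compartment = a$compartment,
               phenotype_selector = nm, count = as.integer(cnt),
               area_mm2 = a$area_mm2,
               density_per_mm2 = ifelse(a$area_mm2 > 0, cnt / a$area_mm2,
                                        NA_real_))
  }))
  rownames(out) <- NULL
  out
}

#' Cluster composition by activation state and TAM PD-L1 status
#'
#' Within each stratum, the fraction of clusters whose T cell is naive,
#' active or exhausted (summing to 1) and whose TAM is PD-L1+ vs PD-L1-
#' (summing to 1), plus the TIM-3+:TIM-3- TAM ratio within PD-L1- clusters.
#' Strata with no clusters yield `NA` proportions.
#'
#' @param triples output of [find_triples()].
#' @param strata character vector of grouping columns present in `triples`
#'   (e.g. `c("group", "tcell_lineage")`); may be empty.
#' @return data frame with one row per stratum: `n_clusters`, activation
#'   fractions `p_naive`, `p_active`, `p_exhausted`, `p_tam_pdl1_pos`,
#'   `p_tam_pdl1_neg`, and `tim3_ratio_in_pdl1neg` (TIM-3+ : TIM-3- among
#'   PD-L1- TAMs; `Inf` when no TIM-3- are present, `NA` when no PD-L1-
#'   clusters exist).
#' @export
cluster_composition <- function(triples, strata = character()) {
  if (length(strata)) {
    key <- interaction(triples[strata], drop = TRUE, sep = "\r")
    groups <- split(seq_len(nrow(triples)), key)
  } else groups <- list(all = seq_len(nrow(triples)))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    n <- length(i)
    act <- triples$tcell_activation[i]
    pdl1 <- triples$tam_pdl1[i]
    tim3 <- triples$tam_tim3[i]
    prop <- function(x) if (n > 0) sum(x, na.rm = TRUE) / n else NA_real_
    npos <- sum(!pdl1 & tim3, na.rm = TRUE)
    nneg <- sum(!pdl1 & !tim3, na.rm = TRUE)
    base <- data.frame(
      n_clusters = n,
      p_naive = prop(act == "NAIVE"),
      p_active = prop(act == "ACTIVE"),
      p_exhausted = prop(act == "EXHAUSTED"),
      p_tam_pdl1_pos = prop(pdl1),
      p_tam_pdl1_neg = prop(!pdl1),
      tim3_ratio_in_pdl1neg =
        if (npos + nneg == 0) NA_real_
        else if (nneg == 0) Inf else npos / nneg)
    if (length(strata)) {
      lv <- strsplit(g, "\r", fixed = TRUE)[[1L]]
      for (k in seq_along(strata)) base[[strata[k]]] <- lv[k]
      base <- base[c(strata, setdiff(names(base), strata))]
    }
    base
  }))
  rownames(out) <- NULL
  out
}
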
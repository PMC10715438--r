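#' Cohort groups of the 2 x 2 study design
#'
#' Treatment (untreated vs neoadjuvant chemotherapy, NAC) crossed with
#' three-year outcome (disease-free, DF, vs distant metastasis, Mets).
#' @export
GROUPS <- c("untreated_DF", "untreated_Mets", "NAC_DF", "NAC_Mets")

#' Simulation configuration for the synthetic tumor-map generator
#'
#' Defines the full study conditions: cohort design, ROI geometry, the
#' per-compartment intensity (cells/mm2) of each phenotype's inhomogeneous
#' Poisson process, perivascular enrichment factors, group effects, marker
#' co-expression probabilities, and seeded three-cell clusters. The seed
#' fully determines every output.
#'
#' Default intensities and enrichment emulate the qualitative structure of
#' immune landscapes in triple-negative breast cancer: immune cells are
#' mainly stromal (immune exclusion), CD4+ T cells and (after NAC) TAMs and
#' Tregs are perivascular-enriched, cancer cells fill the tumor cell
#' islands, and the NAC disease-free group carries a 2x stromal TAM density
#' effect with elevated TIM-3 co-expression. Vessel size/density defaults
#' are unanchored placeholders (no vessel statistics are available for such
#' cohorts) and are freely configurable.
#'
#' @param seed integer seed.
#' @param n_tumors_per_group tumors per cohort group (default 9, a cohort
#'   of 36).
#' @param rois_per_tumor imaged fields per tumor (default 20).
#' @param roi_width_um,roi_height_um ROI extent in micrometers (default
#'   600 x 600).
#' @param pixel_size_um raster resolution (default 0.5).
#' @param tci_fraction target areal fraction of tumor cell islands, in
#'   (0, 1); exactly 0 yields an all-stroma ROI.
#' @param n_vessels_per_roi,vessel_radius_um circular vessels per ROI and
#'   their radius.
#' @param phenotype_intensities named list: phenotype ->
#'   `c(stroma =, tci =)` base intensity in cells/mm2.
#' @param pv_enrichment named vector: phenotype -> multiplicative intensity
#'   factor inside the perivascular band (>= 0).
#' @param group_effects nested list: group -> phenotype -> multiplicative
#'   factor (scalar, or named `c(stroma =, tci =)`).
#' @param n_seeded_clusters_per_roi seeded TAM + T cell + Treg contact
#'   triples per ROI.
#' @param contact_threshold_um contact distance used when seeding clusters;
#'   must match the detector's threshold.
#' @param marker_coexpression list with a `default` entry (and optional
#'   per-group overrides) of probabilities: `tam_pdl1`, `tam_tim3`
#'   (P(PD-L1+), P(TIM-3+) for TAMs), `t_pd1`, `t_lag3_given_pd1` (T-cell
#'   activation markers).
#' @param double_positive_fraction probability a generated T cell is
#'   CD4+CD8+ (default 0: marker logic stays consistent with exclusive
#'   gating).
#' @param pv_threshold_um perivascular threshold (default 50).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    n_tumors_per_group = 9L,
    rois_per_tumor = 20L,
    roi_width_um = 600, roi_height_um = 600,
    pixel_size_um = 0.5,
    tci_fraction = 0.3,
    n_vessels_per_roi = 4L,
    vessel_radius_um = 8,
    phenotype_intensities = list(
      TAM    = c(stroma = 150, tci = 25),
      CD4_T  = c(stroma = 100, tci = 15),
      CD8_T  = c(stroma = 80,  tci = 20),
      TREG   = c(stroma = 40,  tci = 8),
      CANCER = c(stroma = 0,   tci = 1500),
      OTHER  = c(stroma = 60,  tci = 60)),
    pv_enrichment = c(TAM = 2, CD4_T = 3, CD8_T = 1, TREG = 2,
                      CANCER = 1, OTHER = 1),
    group_effects = list(NAC_DF = list(TAM = 2)),
    n_seeded_clusters_per_roi = 2L,
    contact_threshold_um = 12,
    marker_coexpression = list(
      default = list(tam_pdl1 = 0.2, tam_tim3 = 0.3,
                     t_pd1 = 0.4, t_lag3_given_pd1 = 0.25),
      NAC_DF = list(tam_tim3 = 0.55)),
    double_positive_fraction = 0,
    pv_threshold_um = 50) {
  stopifnot(rois_per_tumor >= 1L, n_tumors_per_group >= 1L,
            roi_width_um > 0, roi_height_um > 0, pixel_size_um > 0,
            tci_fraction >= 0, tci_fraction < 1,
            n_vessels_per_roi >= 0L, vessel_radius_um > 0,
            n_seeded_clusters_per_roi >= 0L, contact_threshold_um > 0,
            double_positive_fraction >= 0, double_positive_fraction <= 1,
            pv_threshold_um > 0)
  if (any(unlist(phenotype_intensities) < 0))
    stop("phenotype intensities must be >= 0")
  if (any(pv_enrichment < 0)) stop("pv_enrichment factors must be >= 0")
  structure(as.list(environment()), class = "simulation_config")
}

# effective per-compartment intensity map for one phenotype in one group
.intensity_map <- function(config, group, phenotype) {
  base <- config$phenotype_intensities[[phenotype]]
  eff <- config$group_effects[[group]][[phenotype]] %||% 1
  eff <- if (length(eff) == 1L && is.null(names(eff)))
    c(stroma = unname(eff), tci = unname(eff))
  else c(stroma = unname(eff["stroma"] %||% 1), tci = unname(eff["tci"] %||% 1))
  eff[is.na(eff)] <- 1
  rho <- unname(config$pv_enrichment[[phenotype]] %||% 1)
  c(STROMA_NONPV = unname(base["stroma"]) * eff[["stroma"]],
    STROMA_PV    = unname(base["stroma"]) * eff[["stroma"]] * rho,
    TCI_NONPV    = unname(base["tci"]) * eff[["tci"]],
    TCI_PV       = unname(base["tci"]) * eff[["tci"]] * rho)
}

.coexpression <- function(config, group) {
  co <- config$marker_coexpression$default
  ov <- config$marker_coexpression[[group]]
  for (nm in names(ov)) co[[nm]] <- ov[[nm]]
  co
}

#' Generate one synthetic ROI geometry
#'
#' Places non-overlapping tumor-cell-island blobs (Fourier-perturbed
#' ellipses) whose total area approximates `tci_fraction` of the ROI
#' (within 20 percent), then circular vessels whose centers lie in the
#' stroma. Consumes the session RNG stream; seed before calling (or use
#' [generate_cohort()], which seeds from the config).
#'
#' @param config a [simulation_config()].
#' @param roi_id identifier for the new ROI.
#' @return an [roi_geometry].
#' @export
generate_roi_geometry <- function(config, roi_id = "roi") {
  W <- config$roi_width_um; H <- config$roi_height_um
  target <- config$tci_fraction * W * H
  blobs <- list()
  centers <- matrix(numeric(), ncol = 3) # cx, cy, bounding radius
  area_sofar <- 0
  attempts <- 0L
  n_fail <- 0L
  while (target > 0 && area_sofar < 0.85 * target) {
    attempts <- attempts + 1L
    if (attempts > 5000L)
      stop("could not reach target TCI fraction ", config$tci_fraction,
           " after 5000 placement attempts; reduce tci_fraction or blob size")
    remaining <- target - area_sofar
    # aim each blob at a share of the remaining area, capped by ROI size;
    # proposals shrink after placement failures so gaps get filled
    shrink <- 0.92^n_fail
    a <- sqrt(remaining / pi) * stats::runif(1, 0.55, 1.0) * shrink
    a <- max(6, min(a, 0.18 * min(W, H)))
    b <- a * stats::runif(1, 0.55, 1.0)
    rmax <- a * 1.25
    cx <- stats::runif(1, rmax, W - rmax)
    cy <- stats::runif(1, rmax, H - rmax)
    th <- seq(0, 2 * pi, length.out = 49L)[-49L]
    pert <- 1 + 0.10 * cos(2 * th + stats::runif(1, 0, 2 * pi)) +
      0.06 * cos(3 * th + stats::runif(1, 0, 2 * pi))
    rot <- stats::runif(1, 0, pi)
    px <- a * cos(th) * pert; py <- b * sin(th) * pert
    xy <- cbind(cx + px * cos(rot) - py * sin(rot),
                cy + px * sin(rot) + py * cos(rot))
    if (nrow(centers) > 0) {
      # bounding-circle quick check, then vertex containment both ways
      dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      cand <- which(dd < centers[, 3] + rmax)
      if (length(cand)) {
        hit <- any(.points_in_polys(xy[, 1], xy[, 2], blobs[cand])) ||
          any(vapply(cand, function(ci)
            any(.points_in_polys(blobs[[ci]][, 1], blobs[[ci]][, 2],
                                 list(xy))), logical(1)))
        if (hit) { n_fail <- n_fail + 1L; next }
      }
    }
    A <- polygon_area(xy)
    if (area_sofar + A > 1.2 * target) {
      sc <- sqrt((1.05 * target - area_sofar) / A)
      if (sc < 0.35) { n_fail <- n_fail + 1L; next }
      xy <- cbind(cx + (xy[, 1] - cx) * sc, cy + (xy[, 2] - cy) * sc)
      A <- A * sc^2
    }
    n_fail <- max(0L, n_fail - 1L)
    blobs[[length(blobs) + 1L]] <- xy
    centers <- rbind(centers, c(cx, cy, max(sqrt((xy[, 1] - cx)^2 +
                                                 (xy[, 2] - cy)^2))))
    area_sofar <- area_sofar + A
  }
  vessels <- list()
  r <- config$vessel_radius_um
  attempts <- 0L
  while (length(vessels) < config$n_vessels_per_roi) {
    attempts <- attempts + 1L
    if (attempts > 2000L)
      stop("could not place ", config$n_vessels_per_roi,
           " vessels in stroma after 2000 attempts")
    cx <- stats::runif(1, r, W - r); cy <- stats::runif(1, r, H - r)
    if (.points_in_polys(cx, cy, blobs)) next
    clash <- FALSE
    for (v in vessels)
      if (sqrt((v$cx - cx)^2 + (v$cy - cy)^2) < 2 * r + 2) clash <- TRUE
    if (clash) next
    vessels[[length(vessels) + 1L]] <- list(type = "circle", cx = cx,
                                            cy = cy, r = r)
  }
  roi_geometry(roi_id, W, H, config$pixel_size_um, tci = blobs,
               vessels = vessels)
}

#' Sample cells for one ROI from the inhomogeneous Poisson model
#'
#' Draws each phenotype from an inhomogeneous Poisson process whose
#' intensity is the compartment base rate times the group effect times the
#' perivascular enrichment inside the PV band (zero inside vessels), via
#' thinning of a homogeneous process at the maximum intensity. Marker
#' booleans are assigned consistently with the phenotype's gating rule plus
#' group co-expression probabilities.
#'
#' @param geometry an [roi_geometry] from [generate_roi_geometry()].
#' @param config a [simulation_config()].
#' @param group cohort group name (one of [GROUPS]).
#' @return list with `cells` (cell table with hidden `true_phenotype`
#'   column) and `expected_density` (data frame: phenotype, compartment,
#'   expected cells/mm2).
#' @export
sample_cells <- function(geometry, config, group) {
  stopifnot(group %in% GROUPS)
  area_mm2 <- geometry$width_um * geometry$height_um / 1e6
  co <- .coexpression(config, group)
  all_cells <- list()
  exp_rows <- list()
  counter <- 0L
  for (ph in names(config$phenotype_intensities)) {
    lam <- .intensity_map(config, group, ph)
    if (any(lam < 0)) stop("negative intensity for ", ph, " in ", group)
    exp_rows[[ph]] <- data.frame(phenotype = ph, compartment = names(lam),
                                 expected_per_mm2 = unname(lam))
    lmax <- max(lam)
    if (lmax == 0) next
    n <- stats::rpois(1L, lmax * area_mm2)
    if (n == 0L) next
    x <- stats::runif(n, 0, geometry$width_um)
    y <- stats::runif(n, 0, geometry$height_um)
    cmp <- as.character(classify_cells(data.frame(x_um = x, y_um = y),
                                       geometry, config$pv_threshold_um))
    p_keep <- ifelse(cmp == "VESSEL_EXCLUDED", 0, lam[cmp] / lmax)
    keep <- stats::runif(n) <= p_keep
    if (!any(keep)) next
    x <- x[keep]; y <- y[keep]
    mk <- .sample_markers(ph, sum(keep), co, config$double_positive_fraction)
    ids <- sprintf("c%05d", counter + seq_len(sum(keep)))
    counter <- counter + sum(keep)
    all_cells[[ph]] <- cbind(
      data.frame(cell_id = ids, x_um = x, y_um = y), mk,
      data.frame(true_phenotype = ph, seeded = FALSE))
  }
  cells <- if (length(all_cells)) do.call(rbind, all_cells) else
    .empty_cell_table()
  rownames(cells) <- NULL
  list(cells = cells,
       expected_density = do.call(rbind, c(exp_rows,
                                           list(make.row.names = FALSE))))
}

.empty_cell_table <- function() {
  df <- data.frame(cell_id = character(), x_um = numeric(), y_um = numeric())
  for (m in MARKERS) df[[m]] <- logical()
  df$true_phenotype <- character(); df$seeded <- logical()
  df
}

# marker booleans consistent with the gating rules, plus co-expression
.sample_markers <- function(phenotype, n, co, dp_frac = 0) {
  m <- as.data.frame(matrix(FALSE, nrow = n, ncol = length(MARKERS),
                            dimnames = list(NULL, MARKERS)))
  bern <- function(p) stats::runif(n) < p
  switch(phenotype,
    TAM = {
      m$CD163 <- TRUE
      m$PDL1 <- bern(co$tam_pdl1)
      m$TIM3 <- bern(co$tam_tim3)
    },
    CD4_T = {
      m$CD3 <- TRUE; m$CD4 <- TRUE
      m$CD8 <- bern(dp_frac)
      m$PD1 <- bern(co$t_pd1)
      m$LAG3 <- m$PD1 & bern(co$t_lag3_given_pd1)
    },
    CD8_T = {
      m$CD3 <- TRUE; m$CD8 <- TRUE
      m$CD4 <- bern(dp_frac)
      m$PD1 <- bern(co$t_pd1)
      m$LAG3 <- m$PD1 & bern(co$t_lag3_given_pd1)
    },
    TREG = { m$CD3 <- TRUE; m$CD4 <- TRUE; m$FOXP3 <- TRUE },
    CANCER = { m$PanCK <- TRUE },
    ENDOTHELIAL = { m$CD31 <- TRUE },
    OTHER = { })
  m
}

#' Seed three-cell contact clusters in the perivascular stroma
#'
#' Appends `n_seeded_clusters_per_roi` triples — one TAM, one CD4+ or CD8+
#' T cell, and one Treg — centered at random perivascular stromal
#' locations, with every member in the PV stroma and all pairwise distances
#' below the contact threshold (members sit on a circle of radius 3.5 um
#' around the center, pairwise about 6.1 um).
#'
#' @param geometry an [roi_geometry].
#' @param cells cell table from [sample_cells()].
#' @param config a [simulation_config()].
#' @param group cohort group (for marker co-expression of members).
#' @return list with `cells` (input plus seeded members, `seeded = TRUE`)
#'   and `seeded_ids` (list of member-id triples).
#' @export
seed_clusters <- function(geometry, cells, config, group) {
  n_clu <- config$n_seeded_clusters_per_roi
  if (n_clu == 0L) return(list(cells = cells, seeded_ids = list()))
  co <- .coexpression(config, group)
  margin <- 4
  rad <- 3.5
  seeded <- list()
  ids <- list()
  for (k in seq_len(n_clu)) {
    placed <- FALSE
    for (att in seq_len(400L)) {
      cx <- stats::runif(1, rad, geometry$width_um - rad)
      cy <- stats::runif(1, rad, geometry$height_um - rad)
      th0 <- stats::runif(1, 0, 2 * pi)
      px <- cx + rad * cos(th0 + 2 * pi * (0:2) / 3)
      py <- cy + rad * sin(th0 + 2 * pi * (0:2) / 3)
      d <- distance_to_vessel(c(cx, px), c(cy, py), geometry)
      if (any(d < margin) || any(d > config$pv_threshold_um - margin)) next
      if (any(.in_tci(c(cx, px), c(cy, py), geometry))) next
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place seeded cluster ", k,
           ": no perivascular stroma available in ROI ", geometry$roi_id)
    lineage <- if (stats::runif(1) < 0.5) "CD4_T" else "CD8_T"
    phs <- c("TAM", lineage, "TREG")
    mk <- do.call(rbind, lapply(phs, .sample_markers, n = 1L, co = co,
                                dp_frac = 0))
    trip_ids <- sprintf("s%02d_%s", k, c("tam", "tcell", "treg"))
    seeded[[k]] <- cbind(
      data.frame(cell_id = trip_ids, x_um = px, y_um = py), mk,
      data.frame(true_phenotype = phs, seeded = TRUE))
    ids[[k]] <- trip_ids
  }
  out <- rbind(cells, do.call(rbind, seeded))
  rownames(out) <- NULL
  list(cells = out, seeded_ids = ids)
}

#' Generate a complete synthetic cohort
#'
#' Produces the full 2 x 2 study bundle: a manifest of
#' `4 * n_tumors_per_group` tumors, per-ROI geometries, cell tables with
#' seeded clusters, compartment areas, and a ground-truth record (expected
#' densities per compartment x phenotype, seeded cluster member ids,
#' realized compartment areas). Fully determined by `config$seed`; when
#' `out_dir` is given the study directory is written (manifest CSV, cell
#' CSVs, geometry JSON + labeled TIFF masks, ground-truth JSON) and is
#' byte-identical across runs with the same seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory to write the study to.
#' @return invisible study bundle: list with `manifest` (with `rois`
#'   list-column), `rois` (named list of `geometry`, `areas`, `cells`,
#'   `ground_truth`), and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  manifest <- do.call(rbind, lapply(GROUPS, function(g) {
    tr <- sub("_(DF|Mets)$", "", g)
    oc <- sub("^.*_", "", g)
    data.frame(tumor_id = sprintf("%s_T%02d", g, seq_len(config$n_tumors_per_group)),
               treatment = tr, outcome = oc, group = g)
  }))
  manifest$rois <- lapply(manifest$tumor_id, function(tid)
    sprintf("%s_R%02d", tid, seq_len(config$rois_per_tumor)))
  rois <- list()
  for (i in seq_len(nrow(manifest))) {
    g <- manifest$group[i]
    for (rid in manifest$rois[[i]]) {
      geom <- generate_roi_geometry(config, roi_id = rid)
      areas <- compartment_areas(geom, config$pv_threshold_um)
      sc <- sample_cells(geom, config, g)
      se <- seed_clusters(geom, sc$cells, config, g)
      rois[[rid]] <- list(
        geometry = geom, areas = areas, cells = se$cells,
        ground_truth = list(expected_density = sc$expected_density,
                            seeded_ids = se$seeded_ids,
                            areas = areas))
    }
  }
  bundle <- list(manifest = manifest, rois = rois, config = config)
  if (!is.null(out_dir)) write_cohort(bundle, out_dir)
  invisible(bundle)
}

#' Write a study bundle to a directory
#'
#' Layout: `manifest.csv` (tumor_id, treatment, outcome, roi_ids separated
#' by `;`), `cells/<roi>.csv`, `geometry/<roi>.json` and
#' `geometry/<roi>.tif`, `ground_truth.json`.
#'
#' @param bundle study bundle from [generate_cohort()].
#' @param out_dir target directory.
#' @export
write_cohort <- function(bundle, out_dir) {
  for (d in c("cells", "geometry"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  mf <- bundle$manifest
  mf_out <- data.frame(tumor_id = mf$tumor_id, treatment = mf$treatment,
                       outcome = mf$outcome,
                       roi_ids = vapply(mf$rois, paste, "", collapse = ";"))
  utils::write.csv(mf_out, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- list()
  for (rid in names(bundle$rois)) {
    roi <- bundle$rois[[rid]]
    keep <- setdiff(names(roi$cells), c("true_phenotype", "seeded"))
    write_cell_table(roi$cells[keep],
                     file.path(out_dir, "cells", paste0(rid, ".csv")))
    write_geometry(roi$geometry,
                   json_path = file.path(out_dir, "geometry",
                                         paste0(rid, ".json")),
                   tiff_path = file.path(out_dir, "geometry",
                                         paste0(rid, ".tif")))
    gt[[rid]] <- list(expected_density = roi$ground_truth$expected_density,
                      seeded_ids = roi$ground_truth$seeded_ids,
                      areas = roi$ground_truth$areas)
  }
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}

#' Load a study directory written by [write_cohort()]
#'
#' @param dir study directory.
#' @param geometry_format `"json"` (vector polygons; default) or `"tiff"`
#'   (labeled raster masks).
#' @param pixel_size_um pixel size for raster geometry input.
#' @return study bundle (`manifest`, `rois` with `geometry` and `cells`).
#' @export
load_cohort <- function(dir, geometry_format = c("json", "tiff"),
                        pixel_size_um = 0.5) {
  geometry_format <- match.arg(geometry_format)
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  mf$rois <- strsplit(mf$roi_ids, ";", fixed = TRUE)
  mf$roi_ids <- NULL
  rois <- list()
  for (i in seq_len(nrow(mf))) for (rid in mf$rois[[i]]) {
    gpath <- file.path(dir, "geometry",
                       paste0(rid, if (geometry_format == "json") ".json"
                              else ".tif"))
    geom <- read_geometry(gpath, pixel_size_um = pixel_size_um, roi_id = rid)
    cells <- read_cell_table(file.path(dir, "cells", paste0(rid, ".csv")),
                             extent = c(geom$width_um, geom$height_um),
                             required_markers = character())
    rois[[rid]] <- list(geometry = geom, cells = cells)
  }
  list(manifest = mf, rois = rois)
}
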
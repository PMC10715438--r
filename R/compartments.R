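#' Compartment labels
#'
#' Every cell is assigned to exactly one of five analysis compartments:
#' `TCI_PV`, `TCI_NONPV`, `STROMA_PV`, `STROMA_NONPV`, or the sentinel
#' `VESSEL_EXCLUDED` for cells lying inside a vessel region (vessel wall and
#' lumen are excluded from all perivascular areas). Perivascular (PV) means
#' within `pv_threshold_um` of the nearest vessel boundary; the boundary tie
#' at exactly the threshold is PV.
#'
#' @name compartment-labels
#' @keywords internal
NULL

COMPARTMENTS <- c("TCI_PV", "TCI_NONPV", "STROMA_PV", "STROMA_NONPV")
ALL_COMPARTMENTS <- c(COMPARTMENTS, "VESSEL_EXCLUDED")

#' Classify cells into spatial compartments
#'
#' Assigns each cell (by its centroid) to one of the four region x
#' vascularity compartments or `VESSEL_EXCLUDED`. Region is TCI if the
#' centroid lies inside a tumor-cell-island region, else stroma; vascularity
#' is PV if the distance to the nearest vessel boundary is `<=`
#' `pv_threshold_um`. PV status cross-cuts region, so `TCI_PV` exists.
#'
#' @param cells data frame with `x_um`, `y_um` columns (one row per cell).
#' @param geometry an [roi_geometry].
#' @param pv_threshold_um perivascular distance threshold in micrometers
#'   (default 50).
#' @return factor of compartment labels, one per row of `cells`, with levels
#'   `TCI_PV, TCI_NONPV, STROMA_PV, STROMA_NONPV, VESSEL_EXCLUDED`.
#' @export
classify_cells <- function(cells, geometry, pv_threshold_um = 50) {
  stopifnot(is.data.frame(cells), all(c("x_um", "y_um") %in% names(cells)),
            pv_threshold_um > 0)
  n <- nrow(cells)
  if (n == 0L)
    return(factor(character(), levels = ALL_COMPARTMENTS))
  d <- distance_to_vessel(cells$x_um, cells$y_um, geometry)
  in_vessel <- d < 0
  tci <- .in_tci(cells$x_um, cells$y_um, geometry)
  pv <- d <= pv_threshold_um
  lab <- ifelse(in_vessel, "VESSEL_EXCLUDED",
         ifelse(tci,
                ifelse(pv, "TCI_PV", "TCI_NONPV"),
                ifelse(pv, "STROMA_PV", "STROMA_NONPV")))
  factor(lab, levels = ALL_COMPARTMENTS)
}

#' Compartment areas of an ROI
#'
#' Rasterizes the ROI at its stated pixel size and integrates pixel areas
#' per compartment: the four region x vascularity compartments plus the
#' vessel area. Vessel interiors are excluded from all four analysis
#' compartments; the five areas sum to the ROI area exactly (each pixel is
#' counted once, by its center).
#'
#' @param geometry an [roi_geometry].
#' @param pv_threshold_um perivascular threshold in micrometers (default 50).
#' @param pixel_size_um optional raster resolution override; defaults to the
#'   geometry's `pixel_size_um`.
#' @return data frame with columns `roi_id`, `compartment`, `area_mm2`
#'   (5 rows).
#' @export
compartment_areas <- function(geometry, pv_threshold_um = 50,
                              pixel_size_um = NULL) {
  stopifnot(inherits(geometry, "roi_geometry"), pv_threshold_um > 0)
  s <- if (is.null(pixel_size_um)) geometry$pixel_size_um else pixel_size_um
  if (is.null(s) || !is.finite(s) || s <= 0)
    stop("pixel size missing or invalid; supply pixel_size_um")

  if (!is.null(geometry$mask) && s == geometry$pixel_size_um) {
    lab <- geometry$mask
    dmat <- geometry$vessel_dist_um
    tci <- lab == 1L
    vessel <- lab == 2L
  } else {
    nx <- max(1L, round(geometry$width_um / s))
    ny <- max(1L, round(geometry$height_um / s))
    cx <- (seq_len(nx) - 0.5) * s
    cy <- (seq_len(ny) - 0.5) * s
    px <- rep(cx, each = ny)
    py <- rep(cy, times = nx)
    dmat <- matrix(.pixel_vessel_distance(px, py, geometry, s, ny, nx),
                   nrow = ny, ncol = nx)
    tci <- matrix(.points_in_polys(px, py, geometry$tci), nrow = ny, ncol = nx)
    vessel <- dmat < 0
  }
  pv <- dmat >= 0 & dmat <= pv_threshold_um
  nonvessel <- !(dmat < 0)
  px_mm2 <- (s / 1000)^2
  counts <- c(
    TCI_PV          = sum(tci & pv & nonvessel),
    TCI_NONPV       = sum(tci & !pv & nonvessel),
    STROMA_PV       = sum(!tci & pv & nonvessel),
    STROMA_NONPV    = sum(!tci & !pv & nonvessel),
    VESSEL_EXCLUDED = sum(!nonvessel))
  data.frame(roi_id = geometry$roi_id,
             compartment = names(counts),
             area_mm2 = as.numeric(counts) * px_mm2,
             row.names = NULL)
}

# exact signed distance for vector geometries at pixel centers; falls back to
# a distance transform when vessels are polygons (cost at raster scale)
.pixel_vessel_distance <- function(px, py, geometry, s, ny, nx) {
  vs <- geometry$vessels
  if (length(vs) == 0L) return(rep(Inf, length(px)))
  circles <- Filter(function(v) identical(v$type, "circle"), vs)
  polys <- Filter(function(v) identical(v$type, "polygon"), vs)
  d <- rep(Inf, length(px))
  for (v in circles) d <- pmin(d, .signed_dist_to_vessel(px, py, v))
  if (length(polys)) {
    inside <- .points_in_polys(px, py, lapply(polys, `[[`, "xy"))
    m <- matrix(ifelse(inside, 2L, 0L), nrow = ny, ncol = nx)
    dpoly <- .signed_vessel_distmap(m, s)
    d <- pmin(d, as.numeric(dpoly))
  }
  d
}
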
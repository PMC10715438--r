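#' ROI geometry container
#'
#' An `roi_geometry` holds the region structure of one imaged field (ROI):
#' the tumor-cell-island (TCI) polygons, the vessel regions, the physical
#' extent in micrometers and the pixel size used for raster operations.
#' Vessels may be exact circles (as produced by the synthetic generator) or
#' arbitrary polygons (as read from masks or polygon files); all downstream
#' distance computations accept both.
#'
#' Coordinates are continuous micrometers with the origin at the top-left of
#' the ROI and y increasing downward (image convention). Raster pixels are
#' half-open `[i*s, (i+1)*s)` with centers at `(i + 0.5) * s`.
#'
#' @param roi_id character scalar identifying the ROI.
#' @param width_um,height_um positive ROI extent in micrometers.
#' @param pixel_size_um positive raster pixel size in micrometers.
#' @param tci list of TCI polygons, each a 2-column (x, y) matrix in
#'   micrometers. Polygons need not repeat the first vertex.
#' @param vessels list of vessel regions; each either
#'   `list(type = "circle", cx =, cy =, r =)` or
#'   `list(type = "polygon", xy = <2-column matrix>)`.
#' @return an object of class `roi_geometry`.
#' @export
roi_geometry <- function(roi_id, width_um, height_um, pixel_size_um = 0.5,
                         tci = list(), vessels = list()) {
  stopifnot(is.character(roi_id), length(roi_id) == 1L,
            width_um > 0, height_um > 0, pixel_size_um > 0)
  tci <- lapply(tci, .as_poly_matrix)
  vessels <- lapply(vessels, .validate_vessel)
  structure(
    list(roi_id = roi_id, width_um = width_um, height_um = height_um,
         pixel_size_um = pixel_size_um, tci = tci, vessels = vessels),
    class = "roi_geometry")
}

#' @export
print.roi_geometry <- function(x, ...) {
  cat(sprintf("<roi_geometry> %s: %.0f x %.0f um @ %.3g um/px, %d TCI region(s), %d vessel(s)\n",
              x$roi_id, x$width_um, x$height_um, x$pixel_size_um,
              length(x$tci), length(x$vessels)))
  invisible(x)
}

.as_poly_matrix <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L)
    stop("a polygon must be a matrix with 2 columns (x, y) and >= 3 vertices")
  storage.mode(p) <- "double"
  # drop a duplicated closing vertex; closure is implicit everywhere
  if (isTRUE(all.equal(p[1L, ], p[nrow(p), ]))) p <- p[-nrow(p), , drop = FALSE]
  unname(p)
}

.validate_vessel <- function(v) {
  if (is.matrix(v) || is.data.frame(v)) v <- list(type = "polygon", xy = v)
  if (identical(v$type, "circle")) {
    stopifnot(is.numeric(v$cx), is.numeric(v$cy), v$r > 0)
    v[c("type", "cx", "cy", "r")]
  } else if (identical(v$type, "polygon")) {
    v$xy <- .as_poly_matrix(v$xy)
    v[c("type", "xy")]
  } else stop("vessel must have type 'circle' or 'polygon'")
}

# circle -> polygon approximation (used only for serialization)
.circle_to_polygon <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Polygon area (shoelace formula)
#' @param xy 2-column vertex matrix (closure implicit).
#' @return absolute area in squared input units.
#' @export
polygon_area <- function(xy) {
  xy <- .as_poly_matrix(xy)
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L])) / 2
}

# logical: is each point inside any of the polygons in `polys`?
.points_in_polys <- function(x, y, polys) {
  if (length(polys) == 0L || length(x) == 0L)
    return(rep(FALSE, length(x)))
  bnd <- do.call(rbind, lapply(polys, function(p)
    rbind(p, p[1L, ], c(NA_real_, NA_real_))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, cbind(x, y))
}

# min distance from points to the edges of one polygon (unsigned)
.dist_to_polygon_edges <- function(x, y, xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  d2 <- rep(Inf, length(x))
  for (e in seq_len(n)) {
    ax <- xy[e, 1L]; ay <- xy[e, 2L]
    bx <- xy[j[e], 1L]; by <- xy[j[e], 2L]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# signed distance from points to one vessel boundary: negative strictly inside
.signed_dist_to_vessel <- function(x, y, v) {
  if (identical(v$type, "circle")) {
    sqrt((x - v$cx)^2 + (y - v$cy)^2) - v$r
  } else {
    d <- .dist_to_polygon_edges(x, y, v$xy)
    inside <- .points_in_polys(x, y, list(v$xy))
    ifelse(inside, -d, d)
  }
}

#' Signed distance from points to the nearest vessel boundary
#'
#' Distance is measured to the vessel boundary (the abluminal surface), not
#' the centroid: 0 on the boundary, positive outside, negative strictly
#' inside a vessel (interior flag), and `+Inf` when the geometry contains no
#' vessels.
#'
#' @param x,y point coordinates in micrometers (recycled to common length).
#' @param geometry an [roi_geometry].
#' @return numeric vector of signed distances in micrometers.
#' @export
distance_to_vessel <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "roi_geometry"))
  k <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), k); y <- rep_len(as.numeric(y), k)
  if (any(x < 0 | x > geometry$width_um | y < 0 | y > geometry$height_um))
    stop("point outside ROI extent [0, ", geometry$width_um, "] x [0, ",
         geometry$height_um, "]")
  if (!is.null(geometry$mask)) {
    if (!any(geometry$mask == 2L)) return(rep(Inf, k))
    s <- geometry$pixel_size_um
    i <- pmin(nrow(geometry$mask), pmax(1L, floor(y / s) + 1L))
    j <- pmin(ncol(geometry$mask), pmax(1L, floor(x / s) + 1L))
    return(geometry$vessel_dist_um[cbind(i, j)])
  }
  if (length(geometry$vessels) == 0L) return(rep(Inf, k))
  d <- rep(Inf, k)
  for (v in geometry$vessels) d <- pmin(d, .signed_dist_to_vessel(x, y, v))
  d
}

# build an roi_geometry backed by a labeled raster mask
# (0 = stroma, 1 = TCI, 2 = vessel); rows index y, columns index x
mask_geometry <- function(roi_id, mask, pixel_size_um) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  bad <- setdiff(unique(as.integer(mask)), c(0L, 1L, 2L))
  if (length(bad))
    stop("unknown mask label value(s): ", paste(bad, collapse = ", "),
         " (expected 0 = stroma, 1 = TCI, 2 = vessel)")
  storage.mode(mask) <- "integer"
  g <- roi_geometry(roi_id,
                    width_um = ncol(mask) * pixel_size_um,
                    height_um = nrow(mask) * pixel_size_um,
                    pixel_size_um = pixel_size_um)
  g$mask <- mask
  g$vessel_dist_um <- .signed_vessel_distmap(mask, pixel_size_um)
  g
}

# signed pixel-center distance map to the vessel region of a labeled mask
.signed_vessel_distmap <- function(mask, s) {
  vessel <- mask == 2L
  if (!any(vessel)) return(matrix(Inf, nrow(mask), ncol(mask)))
  outside <- EBImage::distmap(matrix(as.numeric(!vessel), nrow(mask)))
  inside <- EBImage::distmap(matrix(as.numeric(vessel), nrow(mask)))
  (as.matrix(outside) - as.matrix(inside)) * s
}

# logical: points inside any TCI region
.in_tci <- function(x, y, geometry) {
  if (!is.null(geometry$mask)) {
    lab <- .mask_lookup(x, y, geometry)
    return(lab == 1L)
  }
  .points_in_polys(x, y, geometry$tci)
}

# nearest-pixel label lookup for mask-backed geometry
.mask_lookup <- function(x, y, geometry) {
  s <- geometry$pixel_size_um
  i <- pmin(nrow(geometry$mask), pmax(1L, floor(y / s) + 1L))
  j <- pmin(ncol(geometry$mask), pmax(1L, floor(x / s) + 1L))
  geometry$mask[cbind(i, j)]
}
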
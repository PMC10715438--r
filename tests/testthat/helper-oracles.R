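# Independent geometric oracles, deliberately written from scratch so they
# share no code path with the package implementation.

# ray-casting point-in-polygon (crossing number), one point at a time
oracle_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# min distance from one point to a polygon boundary, edge by edge
oracle_dist_to_boundary <- function(px, py, xy) {
  n <- nrow(xy)
  best <- Inf
  j <- n
  for (i in seq_len(n)) {
    ax <- xy[j, 1]; ay <- xy[j, 2]
    bx <- xy[i, 1]; by <- xy[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else
      min(1, max(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    best <- min(best, sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2))
    j <- i
  }
  best
}

# full brute-force compartment classification for polygon-only geometry
oracle_classify <- function(px, py, tci_polys, vessel_polys, pv = 50) {
  d <- Inf
  inside_vessel <- FALSE
  for (v in vessel_polys) {
    dv <- oracle_dist_to_boundary(px, py, v)
    if (oracle_in_polygon(px, py, v)) { inside_vessel <- TRUE; dv <- -dv }
    d <- min(d, dv)
  }
  if (inside_vessel || d < 0) return("VESSEL_EXCLUDED")
  in_tci <- any(vapply(tci_polys, function(p)
    oracle_in_polygon(px, py, p), logical(1)))
  region <- if (in_tci) "TCI" else "STROMA"
  paste0(region, if (d <= pv) "_PV" else "_NONPV")
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n_a * (n_a + 1) / 2
  }
  u_obs <- u_of(seq_len(n_a))
  mu <- n_a * length(b) / 2
  combs <- utils::combn(length(pooled), n_a)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# all-pairs concordance AUC (ties count 1/2)
oracle_auc <- function(scores_pos, scores_neg) {
  s <- 0
  for (p in scores_pos) for (n in scores_neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(scores_pos) * length(scores_neg))
}

# small test fixtures -------------------------------------------------------

# a labeled cell table built directly from marker vectors
make_cells <- function(..., x = NULL, y = NULL) {
  rows <- list(...)
  df <- data.frame(cell_id = sprintf("c%02d", seq_along(rows)))
  n <- length(rows)
  df$x_um <- if (is.null(x)) seq_len(n) * 10 else x
  df$y_um <- if (is.null(y)) rep(10, n) else y
  for (m in pvniche::MARKERS)
    df[[m]] <- vapply(rows, function(r) m %in% r, logical(1))
  df
}

small_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_tumors_per_group = 2L, rois_per_tumor = 2L,
         roi_width_um = 400, roi_height_um = 400, pixel_size_um = 2,
         n_vessels_per_roi = 3L),
    list(...))
  do.call(simulation_config, args)
}
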
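#' Per-ROI compartmental densities
#'
#' Counts cells matching each phenotype selector per compartment and divides
#' by the compartment area in mm2. Compartments with zero area yield `NA`
#' density (absence of the compartment, not absence of cells); the
#' `VESSEL_EXCLUDED` sentinel is never a density compartment.
#'
#' @param cells labeled cell table with a `compartment` column (from
#'   [classify_cells()]) and phenotype columns (from [gate_cells()]).
#' @param areas compartment area table from [compartment_areas()].
#' @param selectors named character vector/list of phenotype selectors (see
#'   [select_cells()]), e.g. `c(TAM = "phenotype == 'TAM'")`.
#' @return data frame with one row per compartment x selector:
#'   `roi_id`, `compartment`, `phenotype_selector`, `count`, `area_mm2`,
#'   `density_per_mm2`.
#' @export
roi_density <- function(cells, areas, selectors) {
  stopifnot(is.data.frame(cells), "compartment" %in% names(cells))
  selectors <- unlist(selectors)
  if (is.null(names(selectors)) || any(names(selectors) == ""))
    stop("selectors must be named")
  a <- areas[areas$compartment %in% COMPARTMENTS, ]
  out <- do.call(rbind, lapply(names(selectors), function(nm) {
    sel <- select_cells(cells, selectors[[nm]])
    cnt <- vapply(a$compartment, function(cmp)
      sum(sel & cells$compartment == cmp), integer(1L))
    data.frame(roi_id = a$roi_id, compartment = a$compartment,
               phenotype_selector = nm, count = as.integer(cnt),
               area_mm2 = a$area_mm2,
               density_per_mm2 = ifelse(a$area_mm2 > 0,
                                        cnt / a$area_mm2, NA_real_),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate ROI densities to tumor and group level
#'
#' Two-level aggregation: the tumor value is the unweighted mean of its ROI
#' densities (`NA` ROIs dropped — a missing compartment does not contribute
#' a zero), and the group value is the mean of tumor values with
#' SEM = sd/sqrt(n) over tumors. Tumors contribute equally regardless of
#' their ROI count.
#'
#' @param roi_rows stacked [roi_density()] rows across ROIs; a `value`
#'   column other than `density_per_mm2` may be selected with `value_col`.
#' @param manifest study manifest mapping `roi_id` to `tumor_id` and
#'   `group`: either a manifest with a `rois` list-column or a data frame
#'   with one row per ROI (`roi_id`, `tumor_id`, `group`).
#' @param value_col name of the value column (default `density_per_mm2`).
#' @return list of data frames `roi`, `tumor`
#'   (`tumor_id, group, compartment, phenotype_selector, n_roi, value`), and
#'   `group` (`group, compartment, phenotype_selector, n, mean, sem`).
#' @export
aggregate_density <- function(roi_rows, manifest,
                              value_col = "density_per_mm2") {
  stopifnot(value_col %in% names(roi_rows))
  map <- roi_map(manifest)
  idx <- match(roi_rows$roi_id, map$roi_id)
  if (anyNA(idx))
    stop("ROI(s) not present in manifest: ",
         paste(unique(roi_rows$roi_id[is.na(idx)]), collapse = ", "))
  roi_rows$tumor_id <- map$tumor_id[idx]
  roi_rows$group <- map$group[idx]

  v <- roi_rows[[value_col]]
  tum_key <- interaction(roi_rows$tumor_id, roi_rows$compartment,
                         roi_rows$phenotype_selector, drop = TRUE, sep = "\r")
  tumor <- do.call(rbind, lapply(split(seq_along(v), tum_key), function(i) {
    vi <- v[i]
    ok <- !is.na(vi)
    if (!any(ok))
      warning("tumor ", roi_rows$tumor_id[i[1L]], " has no non-NA ROI for ",
              roi_rows$compartment[i[1L]], " / ",
              roi_rows$phenotype_selector[i[1L]])
    data.frame(tumor_id = roi_rows$tumor_id[i[1L]],
               group = roi_rows$group[i[1L]],
               compartment = roi_rows$compartment[i[1L]],
               phenotype_selector = roi_rows$phenotype_selector[i[1L]],
               n_roi = sum(ok),
               value = if (any(ok)) mean(vi[ok]) else NA_real_)
  }))
  rownames(tumor) <- NULL

  grp_key <- interaction(tumor$group, tumor$compartment,
                         tumor$phenotype_selector, drop = TRUE, sep = "\r")
  group <- do.call(rbind, lapply(split(seq_len(nrow(tumor)), grp_key),
                                 function(i) {
    vi <- tumor$value[i]
    ok <- !is.na(vi)
    data.frame(group = tumor$group[i[1L]],
               compartment = tumor$compartment[i[1L]],
               phenotype_selector = tumor$phenotype_selector[i[1L]],
               n = sum(ok),
               mean = if (any(ok)) mean(vi[ok]) else NA_real_,
               sem = if (sum(ok) > 1L) stats::sd(vi[ok]) / sqrt(sum(ok))
                     else NA_real_)
  }))
  rownames(group) <- NULL
  list(roi = roi_rows, tumor = tumor, group = group)
}

# normalize a manifest into a roi_id -> (tumor_id, group) map
roi_map <- function(manifest) {
  if (all(c("roi_id", "tumor_id") %in% names(manifest))) {
    if (!"group" %in% names(manifest))
      manifest$group <- paste(manifest$treatment, manifest$outcome, sep = "_")
    return(manifest[c("roi_id", "tumor_id", "group")])
  }
  if (!"rois" %in% names(manifest))
    stop("manifest must have either a roi_id column or a rois list-column")
  do.call(rbind, lapply(seq_len(nrow(manifest)), function(i)
    data.frame(roi_id = unlist(manifest$rois[[i]]),
               tumor_id = manifest$tumor_id[i],
               group = manifest$group[i])))
}

#' Pooled-count density aggregation (sensitivity mode)
#'
#' Alternative to the per-ROI-mean aggregation: pools counts and areas over
#' a tumor's ROIs before dividing, weighting ROIs by compartment area. The
#' per-ROI unweighted mean is the primary mode (it mirrors per-section
#' averaging across a fixed ROI panel); this pooled mode is offered for
#' sensitivity analysis.
#'
#' @inheritParams aggregate_density
#' @return as [aggregate_density()].
#' @export
aggregate_density_pooled <- function(roi_rows, manifest) {
  map <- roi_map(manifest)
  idx <- match(roi_rows$roi_id, map$roi_id)
  roi_rows$tumor_id <- map$tumor_id[idx]
  roi_rows$group <- map$group[idx]
  key <- interaction(roi_rows$tumor_id, roi_rows$compartment,
                     roi_rows$phenotype_selector, drop = TRUE, sep = "\r")
  tumor <- do.call(rbind, lapply(split(seq_len(nrow(roi_rows)), key),
                                 function(i) {
    ct <- sum(roi_rows$count[i]); ar <- sum(roi_rows$area_mm2[i])
    data.frame(tumor_id = roi_rows$tumor_id[i[1L]],
               group = roi_rows$group[i[1L]],
               compartment = roi_rows$compartment[i[1L]],
               phenotype_selector = roi_rows$phenotype_selector[i[1L]],
               n_roi = length(i),
               value = if (ar > 0) ct / ar else NA_real_)
  }))
  rownames(tumor) <- NULL
  out <- aggregate_density(
    transform(tumor, roi_id = tumor_id, density_per_mm2 = value),
    data.frame(roi_id = tumor$tumor_id, tumor_id = tumor$tumor_id,
               group = tumor$group))
  list(roi = roi_rows, tumor = tumor, group = out$group)
}
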
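#' Read a per-ROI cell table
#'
#' Reads a delimited cell table: one row per segmented cell with a unique
#' `cell_id`, centroid coordinates `x_um`, `y_um` (micrometers, origin
#' top-left), and one 0/1 (or true/false) column per marker. Additional
#' columns pass through untouched. Validation failures name the offending
#' row and column.
#'
#' @param path path to a CSV file (UTF-8, header required).
#' @param extent optional `c(width_um, height_um)`; when given, coordinates
#'   are checked against it.
#' @param required_markers marker columns that must be present (default
#'   the T-cell/macrophage panel; PanCK and CD31 are optional because
#'   cell tables restricted to immune cells may omit them).
#' @return data frame of validated cells, row order preserved; marker
#'   columns coerced to logical.
#' @export
read_cell_table <- function(path, extent = NULL,
                            required_markers = setdiff(MARKERS, c("PanCK", "CD31"))) {
  if (!file.exists(path)) stop("cell table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "x_um", "y_um", required_markers)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cell table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    for (m in intersect(MARKERS, names(df))) df[[m]] <- logical()
    return(df)
  }
  df$cell_id <- as.character(df$cell_id)
  dup <- duplicated(df$cell_id)
  if (any(dup))
    stop("duplicate cell_id '", df$cell_id[which(dup)[1L]], "' at row ",
         which(dup)[1L], " in ", path)
  for (co in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[co]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop("invalid coordinate in column ", co, " at row ", bad[1L],
           " in ", path)
    df[[co]] <- v
  }
  if (!is.null(extent)) {
    out <- which(df$x_um > extent[1L] | df$y_um > extent[2L])
    if (length(out))
      stop("coordinate outside ROI extent at row ", out[1L], " in ", path)
  }
  for (m in intersect(MARKERS, names(df))) {
    v <- df[[m]]
    lv <- rep(NA, length(v))
    lv[v %in% c(1, "1", TRUE, "true", "TRUE", "True")] <- TRUE
    lv[v %in% c(0, "0", FALSE, "false", "FALSE", "False")] <- FALSE
    bad <- which(is.na(lv) & !is.na(v))
    if (length(bad))
      stop("non-boolean marker value '", v[bad[1L]], "' in column ", m,
           " at row ", bad[1L], " in ", path)
    df[[m]] <- lv
  }
  df
}

#' Write a cell table
#' @param cells data frame of cells; logical marker columns are written 0/1.
#' @param path output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  out <- cells
  for (m in intersect(MARKERS, names(out))) out[[m]] <- as.integer(out[[m]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ROI geometry from a labeled mask or polygon file
#'
#' Two input dialects yield equivalent geometry:
#' \itemize{
#'   \item a single-channel TIFF whose uint8 labels are 0 = stroma,
#'     1 = TCI, 2 = vessel (requires `pixel_size_um`);
#'   \item a JSON file with `width_um`, `height_um`, `pixel_size_um`,
#'     `tci` (list of rings, each a list of `[x, y]` vertices in
#'     micrometers) and `vessels` (circles or polygon rings).
#' }
#'
#' @param path path to a `.tif`/`.tiff` or `.json` file.
#' @param pixel_size_um micrometers per pixel; required for raster input,
#'   overrides the stored value for JSON input when given.
#' @param roi_id ROI identifier; defaults to the file name without extension.
#' @return an [roi_geometry] (mask-backed for TIFF input).
#' @export
read_geometry <- function(path, pixel_size_um = NULL, roi_id = NULL) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  if (is.null(roi_id)) roi_id <- sub("\\.[^.]+$", "", basename(path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.null(pixel_size_um))
      stop("pixel_size_um is required for raster geometry input: ", path)
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    mask <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
    mask_geometry(roi_id, mask, pixel_size_um)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    ring <- function(r) do.call(rbind, lapply(r, function(v)
      c(as.numeric(v[[1L]]), as.numeric(v[[2L]]))))
    vessels <- lapply(j$vessels, function(v) {
      if (identical(v$type, "circle"))
        list(type = "circle", cx = as.numeric(v$cx), cy = as.numeric(v$cy),
             r = as.numeric(v$r))
      else list(type = "polygon", xy = ring(v$xy))
    })
    roi_geometry(roi_id = j$roi_id %||% roi_id,
                 width_um = as.numeric(j$width_um),
                 height_um = as.numeric(j$height_um),
                 pixel_size_um = pixel_size_um %||%
                   as.numeric(j$pixel_size_um %||% 0.5),
                 tci = lapply(j$tci, ring),
                 vessels = vessels)
  } else stop("unrecognized geometry format (expect .tif/.tiff or .json): ", path)
}

#' Write ROI geometry
#'
#' Writes the polygon JSON dialect, the labeled raster mask TIFF, or both.
#' Circles are polygonized (64-gon) only if the raster is requested from a
#' vector geometry; the mask is produced by pixel-center rasterization with
#' vessel winning over TCI on conflict.
#'
#' @param geometry an [roi_geometry].
#' @param json_path,tiff_path output paths (either may be `NULL`).
#' @export
write_geometry <- function(geometry, json_path = NULL, tiff_path = NULL) {
  stopifnot(inherits(geometry, "roi_geometry"))
  if (!is.null(json_path)) {
    unring <- function(p) lapply(seq_len(nrow(p)), function(i)
      c(p[i, 1L], p[i, 2L]))
    vessels <- lapply(geometry$vessels, function(v)
      if (identical(v$type, "circle")) v else
        list(type = "polygon", xy = unring(v$xy)))
    jsonlite::write_json(
      list(roi_id = geometry$roi_id, width_um = geometry$width_um,
           height_um = geometry$height_um,
           pixel_size_um = geometry$pixel_size_um,
           tci = lapply(geometry$tci, unring), vessels = vessels),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tiff_path)) {
    mask <- rasterize_geometry(geometry)
    tiff::writeTIFF(mask / 255, tiff_path, bits.per.sample = 8L,
                    compression = "none")
  }
  invisible(geometry)
}

#' Rasterize a vector geometry to a labeled mask
#'
#' Pixel centers inside a vessel get label 2 (vessel wins over TCI on
#' overlap), inside a TCI label 1, else 0 (stroma).
#'
#' @param geometry an [roi_geometry].
#' @param pixel_size_um optional resolution override.
#' @return integer matrix (rows = y, columns = x).
#' @export
rasterize_geometry <- function(geometry, pixel_size_um = NULL) {
  if (!is.null(geometry$mask)) return(geometry$mask)
  s <- pixel_size_um %||% geometry$pixel_size_um
  nx <- max(1L, round(geometry$width_um / s))
  ny <- max(1L, round(geometry$height_um / s))
  px <- rep((seq_len(nx) - 0.5) * s, each = ny)
  py <- rep((seq_len(ny) - 0.5) * s, times = nx)
  d <- .pixel_vessel_distance(px, py, geometry, s, ny, nx)
  tci <- .points_in_polys(px, py, geometry$tci)
  lab <- ifelse(d < 0, 2L, ifelse(tci, 1L, 0L))
  matrix(as.integer(lab), nrow = ny, ncol = nx)
}

#' Read a study manifest
#'
#' The manifest assigns tumors to the 2 x 2 cohort design: columns
#' `tumor_id`, `treatment` (`untreated`/`NAC`), `outcome` (`DF`/`Mets`).
#' A `group` column (`treatment_outcome`) is derived.
#'
#' @param path CSV path.
#' @return validated manifest data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tumor_id", "treatment", "outcome")
  missing <- setdiff(need, names(mf))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (any(is.na(mf$treatment) | is.na(mf$outcome)))
    stop("manifest has missing treatment/outcome values")
  bad <- setdiff(unique(mf$treatment), c("untreated", "NAC"))
  if (length(bad)) stop("unknown treatment value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(mf$outcome), c("DF", "Mets"))
  if (length(bad)) stop("unknown outcome value(s): ", paste(bad, collapse = ", "))
  mf$group <- paste(mf$treatment, mf$outcome, sep = "_")
  mf
}

#' Write result tables plus run metadata
#'
#' Writes each table in `tables` as a tidy CSV (empty tables become
#' header-only files) and a `run_metadata.json` with the seed, package
#' version and a hash of the configuration, so a run is reproducible from
#' its output directory alone.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if absent).
#' @param meta named list merged into the metadata record (e.g. seed,
#'   config).
#' @return invisible character vector of written paths.
#' @export
write_results <- function(tables, out_dir, meta = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta$package_version <- as.character(utils::packageVersion("pvniche"))
  if (!is.null(meta$config))
    meta$config_hash <- .stable_hash(meta$config)
  mp <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, mp))
}

# md5 of a canonical serialization, via a temp file (tools::md5sum is
# file-based); used for provenance records only
.stable_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}
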
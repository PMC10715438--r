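#' Marker panel
#'
#' The ten-marker panel plus PanCK used throughout: PanCK (epithelium/cancer),
#' CD31 (endothelium), CD3/CD4/CD8/FOXP3 (T-cell lineages), PD1/LAG3 (T-cell
#' activation and exhaustion), CD163 (macrophages), PDL1/TIM3 (negative
#' checkpoint regulators on macrophages and cancer cells).
#' @export
MARKERS <- c("PanCK", "CD31", "CD3", "CD4", "CD8", "FOXP3",
             "PD1", "PDL1", "TIM3", "LAG3", "CD163")

PHENOTYPES <- c("ENDOTHELIAL", "TAM", "CD8_T", "TREG", "CD4_T", "CANCER", "OTHER")
ACTIVATION_STATES <- c("NAIVE", "ACTIVE", "EXHAUSTED")

#' Default gating configuration
#'
#' Gating is data, not code: an ordered list of rules, each naming the
#' markers that must be positive (`pos`) and negative (`neg`) for a label.
#' Rules are applied in priority order and the first match wins, so
#' conflicting co-expression (e.g. CD163+CD3+) resolves deterministically;
#' conflicts of interest are tallied in the QC summary rather than hidden.
#'
#' The default priority is endothelial > TAM > CD8 T > Treg > CD4 T > cancer,
#' with `OTHER` as the fallback:
#' \itemize{
#'   \item ENDOTHELIAL: CD31+
#'   \item TAM: CD163+ (PD-L1/TIM-3 status recorded as attributes)
#'   \item CD8_T: CD3+CD8+ (CD4 not conditioned on; CD8+FOXP3+ stays CD8_T)
#'   \item TREG: CD3+CD4+FOXP3+
#'   \item CD4_T: CD3+CD4+ (FOXP3- by exclusion from TREG)
#'   \item CANCER: PanCK+
#' }
#' T-cell activation: PD-1- is naive, PD-1+LAG-3- active, PD-1+LAG-3+
#' exhausted. A LAG-3 single positive (PD-1-) is classified naive (PD-1
#' negativity dominates) and counted in the QC tally.
#'
#' @return a `gating_config`: list with elements `rules` (ordered list of
#'   `list(label, pos, neg)`) and `fallback`.
#' @export
default_gating <- function() {
  structure(list(
    rules = list(
      list(label = "ENDOTHELIAL", pos = "CD31", neg = character()),
      list(label = "TAM", pos = "CD163", neg = character()),
      list(label = "CD8_T", pos = c("CD3", "CD8"), neg = character()),
      list(label = "TREG", pos = c("CD3", "CD4", "FOXP3"), neg = character()),
      list(label = "CD4_T", pos = c("CD3", "CD4"), neg = "FOXP3"),
      list(label = "CANCER", pos = "PanCK", neg = character())),
    fallback = "OTHER"), class = "gating_config")
}

#' Read a gating configuration from YAML or JSON
#'
#' The file holds `rules:` as an ordered list of `{label, pos, neg}` entries
#' plus an optional `fallback:` (default `OTHER`). Markers are referenced by
#' column name, so extended panels pass through without code change.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `gating_config`.
#' @export
read_gating <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  rules <- lapply(raw$rules, function(r)
    list(label = r$label,
         pos = as.character(unlist(r$pos %||% character())),
         neg = as.character(unlist(r$neg %||% character()))))
  structure(list(rules = rules, fallback = raw$fallback %||% "OTHER"),
            class = "gating_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gate cells: marker booleans to phenotype labels
#'
#' Total, deterministic function from a cell's marker booleans to a
#' phenotype label, a T-cell activation state, and TAM checkpoint-regulator
#' attributes. See [default_gating()] for the rule order.
#'
#' @param cells data frame with one logical/0-1 column per marker referenced
#'   by the gating rules (see [MARKERS]).
#' @param gating a `gating_config` (default [default_gating()]).
#' @return `cells` with columns added: `phenotype` (factor), `activation`
#'   (factor, `NA` for non-T cells), `tam_pdl1`, `tam_tim3` (logical, `NA`
#'   for non-TAMs).
#' @export
gate_cells <- function(cells, gating = default_gating()) {
  stopifnot(is.data.frame(cells), inherits(gating, "gating_config"))
  n <- nrow(cells)
  used <- unique(unlist(lapply(gating$rules, function(r) c(r$pos, r$neg))))
  missing <- setdiff(used, names(cells))
  if (length(missing))
    stop("gating rules reference missing marker column(s): ",
         paste(missing, collapse = ", "))
  mk <- function(m) as.logical(cells[[m]])

  label <- rep(NA_character_, n)
  for (r in gating$rules) {
    hit <- rep(TRUE, n)
    for (m in r$pos) hit <- hit & mk(m)
    for (m in r$neg) hit <- hit & !mk(m)
    label[is.na(label) & hit] <- r$label
  }
  label[is.na(label)] <- gating$fallback

  is_t <- label %in% c("CD4_T", "CD8_T")
  activation <- rep(NA_character_, n)
  if (any(is_t)) {
    pd1 <- mk("PD1"); lag3 <- mk("LAG3")
    activation[is_t & !pd1] <- "NAIVE"
    activation[is_t & pd1 & !lag3] <- "ACTIVE"
    activation[is_t & pd1 & lag3] <- "EXHAUSTED"
  }
  is_tam <- label == "TAM"
  cells$phenotype <- factor(label, levels = unique(c(
    vapply(gating$rules, `[[`, "", "label"), gating$fallback)))
  cells$activation <- factor(activation, levels = ACTIVATION_STATES)
  cells$tam_pdl1 <- ifelse(is_tam, mk("PDL1"), NA)
  cells$tam_tim3 <- ifelse(is_tam, mk("TIM3"), NA)
  cells
}

#' Phenotype a cell table with QC summary
#'
#' Runs [gate_cells()] and tallies gating anomalies: CD4/CD8 double-positive
#' T cells (assigned CD8_T by priority), CD8+FOXP3+ cells (kept CD8_T; Tregs
#' are defined within CD4 only), LAG-3 single-positive T cells (classified
#' naive), and CD163+CD3+ co-expression (assigned TAM by priority).
#'
#' @inheritParams gate_cells
#' @return list with `cells` (the labeled table) and `qc` (named integer
#'   vector of anomaly tallies).
#' @export
phenotype_table <- function(cells, gating = default_gating()) {
  out <- gate_cells(cells, gating)
  mk <- function(m) if (m %in% names(cells)) as.logical(cells[[m]]) else
    rep(FALSE, nrow(cells))
  qc <- c(
    n_cells = nrow(out),
    cd4_cd8_double = sum(mk("CD3") & mk("CD4") & mk("CD8")),
    cd8_foxp3 = sum(mk("CD3") & mk("CD8") & mk("FOXP3")),
    lag3_single_positive_t = sum(out$phenotype %in% c("CD4_T", "CD8_T") &
                                   mk("LAG3") & !mk("PD1")),
    cd163_cd3 = sum(mk("CD163") & mk("CD3")))
  list(cells = out, qc = qc)
}

#' Subset proportions within strata
#'
#' Computes numerator/denominator proportions within strata, e.g. the
#' fraction of CD163+ TAMs expressing TIM-3 per compartment per group (the
#' percent-of-parent quantities shown at bar bases in compartmental plots).
#' Predicates are selector strings evaluated on the table columns (see
#' [select_cells()]).
#'
#' @param cells labeled cell table (from [gate_cells()]).
#' @param numerator,denominator selector strings; the numerator is evaluated
#'   within the denominator subset.
#' @param strata character vector of column names to stratify by (may be
#'   empty for a single overall proportion).
#' @return data frame with stratum columns plus `n_num`, `n_den`,
#'   `proportion` (`NA` with a warning where the denominator is empty).
#' @export
subset_proportion <- function(cells, numerator, denominator = "TRUE",
                              strata = character()) {
  den <- select_cells(cells, denominator)
  num <- den & select_cells(cells, numerator)
  if (length(strata) == 0L) {
    if (sum(den) == 0L) {
      warning("empty denominator; proportion is NA")
      return(data.frame(n_num = 0L, n_den = 0L, proportion = NA_real_))
    }
    return(data.frame(n_num = sum(num), n_den = sum(den),
                      proportion = sum(num) / sum(den)))
  }
  key <- interaction(cells[strata], drop = FALSE, sep = "\r")
  n_den <- tapply(den, key, sum, default = 0L)
  n_num <- tapply(num, key, sum, default = 0L)
  lev <- strsplit(names(n_den), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, lev), stringsAsFactors = FALSE)
  names(out) <- strata
  out$n_num <- as.integer(n_num)
  out$n_den <- as.integer(n_den)
  out$proportion <- ifelse(out$n_den > 0, out$n_num / out$n_den, NA_real_)
  if (any(out$n_den == 0))
    warning("empty denominator in ", sum(out$n_den == 0),
            " stratum/strata; proportion is NA there")
  rownames(out) <- NULL
  out
}

#' Evaluate a phenotype selector on a labeled cell table
#'
#' Selectors are R logical expressions over the table's columns, e.g.
#' `"phenotype == 'TAM' & tam_tim3 & !tam_pdl1"` or
#' `"phenotype %in% c('CD4_T','CD8_T') & activation == 'NAIVE'"`.
#' `NA`s (e.g. `tam_pdl1` on non-TAMs) evaluate to not-selected.
#'
#' @param cells labeled cell table.
#' @param selector selector string.
#' @return logical vector, one element per row, never `NA`.
#' @export
select_cells <- function(cells, selector) {
  expr <- tryCatch(str2lang(selector),
                   error = function(e) stop("unparseable selector: ", selector))
  v <- eval(expr, envir = cells, enclos = baseenv())
  if (length(v) == 1L) v <- rep(v, nrow(cells))
  if (!is.logical(v) || length(v) != nrow(cells))
    stop("selector must evaluate to a logical vector over rows: ", selector)
  v & !is.na(v)
}
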
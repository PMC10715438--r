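#' Monte-Carlo calibration of the planned group comparison
#'
#' Estimates the operating characteristics of the Mann-Whitney +
#' Bonferroni procedure under the synthetic generator: the family-wise
#' rejection rate under the null (`effect = 1`; type-I error) or under a
#' multiplicative density effect (power). Tissue geometries are generated
#' once per tumor and held fixed across replicates (the calibration is
#' conditional on tissue architecture); the Poisson cell sampling,
#' gating, compartment classification and density aggregation are re-run
#' through the standard pipeline functions in every replicate.
#'
#' @param config a [simulation_config()]; its `rois_per_tumor`, geometry
#'   and intensity settings define the simulation conditions. Group
#'   effects are overridden by `effect`.
#' @param effect multiplicative density factor applied to `phenotype` in
#'   the first arm (`"NAC_DF"`); 1 is the null.
#' @param phenotype affected phenotype (default `"TAM"`).
#' @param n_reps Monte-Carlo replicates.
#' @param n_per_arm tumors per arm.
#' @param compartments compartments tested; the Bonferroni family is this
#'   set.
#' @param alpha significance level on the adjusted p.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list: `reject_rate` (fraction of replicates with any adjusted
#'   p <= alpha in the family), `n_reps`, `effect`, `p_adjusted` (matrix
#'   replicates x compartments).
#' @export
calibrate_comparison <- function(config, effect = 1, phenotype = "TAM",
                                 n_reps = 200, n_per_arm = 10,
                                 compartments = c("STROMA_PV", "STROMA_NONPV"),
                                 alpha = 0.05, seed = config$seed) {
  arms <- c("NAC_DF", "NAC_Mets")
  cfg <- config
  cfg$group_effects <- if (effect == 1) list() else
    stats::setNames(list(stats::setNames(list(effect), phenotype)), arms[1L])
  cfg$n_seeded_clusters_per_roi <- 0L
  sel <- structure(sprintf("phenotype == '%s'", phenotype), names = phenotype)

  set.seed(seed)
  tumors <- data.frame(tumor_id = sprintf("S%02d", seq_len(2L * n_per_arm)),
                       group = rep(arms, each = n_per_arm))
  tissue <- lapply(seq_len(nrow(tumors)), function(i)
    lapply(seq_len(cfg$rois_per_tumor), function(r) {
      g <- generate_roi_geometry(cfg, sprintf("%s_R%02d", tumors$tumor_id[i], r))
      list(geometry = g, areas = compartment_areas(g, cfg$pv_threshold_um))
    }))

  m <- length(compartments)
  p_adj <- matrix(NA_real_, n_reps, m, dimnames = list(NULL, compartments))
  for (rep_i in seq_len(n_reps)) {
    vals <- array(NA_real_, c(nrow(tumors), m))
    for (ti in seq_len(nrow(tumors))) {
      g <- tumors$group[ti]
      roi_dens <- vapply(tissue[[ti]], function(roi) {
        cells <- sample_cells(roi$geometry, cfg, g)$cells
        cells <- gate_cells(cells)
        cells$compartment <- classify_cells(cells, roi$geometry,
                                            cfg$pv_threshold_um)
        d <- roi_density(cells, roi$areas, sel)
        d$density_per_mm2[match(compartments, d$compartment)]
      }, numeric(m))
      vals[ti, ] <- rowMeans(matrix(roi_dens, nrow = m), na.rm = TRUE)
    }
    a <- tumors$group == arms[1L]
    praw <- vapply(seq_len(m), function(k)
      mann_whitney(vals[a, k], vals[!a, k])$p_raw, numeric(1L))
    p_adj[rep_i, ] <- bonferroni(praw, m = m)
  }
  list(reject_rate = mean(apply(p_adj <= alpha, 1L, any)),
       n_reps = n_reps, effect = effect, p_adjusted = p_adj)
}
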
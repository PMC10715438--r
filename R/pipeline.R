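#' Default phenotype selectors
#'
#' The cell populations quantified by default: the four immune phenotypes,
#' the TAM checkpoint-regulator subsets (PD-L1 and TIM-3, including the
#' four-way PD-L1/TIM-3 partition), and T-cell activation subsets.
#' @return named character vector of selectors (see [select_cells()]).
#' @export
default_selectors <- function() c(
  TAM    = "phenotype == 'TAM'",
  CD4_T  = "phenotype == 'CD4_T'",
  CD8_T  = "phenotype == 'CD8_T'",
  TREG   = "phenotype == 'TREG'",
  TAM_PDL1pos = "phenotype == 'TAM' & tam_pdl1",
  TAM_PDL1neg = "phenotype == 'TAM' & !tam_pdl1",
  TAM_TIM3pos = "phenotype == 'TAM' & tam_tim3",
  TAM_TIM3neg = "phenotype == 'TAM' & !tam_tim3",
  TAM_PDL1neg_TIM3pos = "phenotype == 'TAM' & !tam_pdl1 & tam_tim3",
  CD4_T_naive = "phenotype == 'CD4_T' & activation == 'NAIVE'",
  CD8_T_naive = "phenotype == 'CD8_T' & activation == 'NAIVE'")

#' Default contrast plan
#'
#' Two named Bonferroni families: `nac_outcome` (disease-free vs metastatic
#' within NAC-treated tumors; TAM and TIM-3 TAM subsets, perivascular and
#' non-perivascular stroma) and `treatment` (untreated vs NAC; stromal TAM
#' and Treg). Each family's size is the number of contrasts in its block.
#' @return plan list for [run_comparisons()].
#' @export
default_contrast_plan <- function() {
  ncmp <- function(sel, cmp) list(selector = sel, compartment = cmp,
                                  group_var = "group",
                                  arms = c("NAC_DF", "NAC_Mets"))
  tcmp <- function(sel, cmp) list(selector = sel, compartment = cmp,
                                  group_var = "treatment",
                                  arms = c("untreated", "NAC"))
  list(
    nac_outcome = list(
      ncmp("TAM", "STROMA_PV"), ncmp("TAM", "STROMA_NONPV"),
      ncmp("TAM_TIM3pos", "STROMA_PV"), ncmp("TAM_TIM3pos", "STROMA_NONPV"),
      ncmp("TAM_TIM3neg", "STROMA_PV"), ncmp("TAM_TIM3neg", "STROMA_NONPV")),
    treatment = list(
      tcmp("TAM", "STROMA_PV"), tcmp("TAM", "STROMA_NONPV"),
      tcmp("TREG", "STROMA_PV"), tcmp("TREG", "STROMA_NONPV")))
}

#' Whole-stroma tumor-level density
#'
#' Pools the PV and non-PV stroma compartments of each ROI
#' (counts / areas), then averages per tumor — the "entire stroma" density
#' used for biomarker ROC analyses.
#'
#' @param roi_table ROI-level density rows (with `tumor_id` merged in, as
#'   produced inside [run_pipeline()], or raw [roi_density()] rows plus a
#'   manifest).
#' @param selector phenotype selector name to extract.
#' @param manifest optional manifest to map ROI to tumor.
#' @return data frame `tumor_id`, `group`, `value` (cells/mm2).
#' @export
stroma_density <- function(roi_table, selector, manifest = NULL) {
  if (!"tumor_id" %in% names(roi_table)) {
    map <- roi_map(manifest)
    idx <- match(roi_table$roi_id, map$roi_id)
    roi_table$tumor_id <- map$tumor_id[idx]
    roi_table$group <- map$group[idx]
  }
  sub <- roi_table[roi_table$phenotype_selector == selector &
                   roi_table$compartment %in% c("STROMA_PV", "STROMA_NONPV"), ]
  per_roi <- do.call(rbind, lapply(split(sub, sub$roi_id), function(d)
    data.frame(tumor_id = d$tumor_id[1L], group = d$group[1L],
               value = if (sum(d$area_mm2) > 0)
                 sum(d$count) / sum(d$area_mm2) else NA_real_)))
  out <- do.call(rbind, lapply(split(per_roi, per_roi$tumor_id), function(d)
    data.frame(tumor_id = d$tumor_id[1L], group = d$group[1L],
               value = mean(d$value, na.rm = TRUE))))
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates phenotyping, compartment classification, compartmental
#' densities with ROI to tumor to group aggregation, three-cell cluster
#' detection and composition, planned group comparisons with Bonferroni
#' correction, and ROC analyses of stromal TAM subset densities for the
#' metastasis outcome in NAC-treated tumors. Deterministic given its
#' inputs: rerunning on the same study yields identical tables.
#'
#' @param study a study bundle (from [generate_cohort()] / [load_cohort()])
#'   or a study directory path.
#' @param pv_threshold_um perivascular threshold (default 50).
#' @param contact_threshold_um cluster contact distance (default 12).
#' @param gating a `gating_config` (default [default_gating()]).
#' @param selectors named selectors to quantify (default
#'   [default_selectors()]).
#' @param plan contrast plan (default [default_contrast_plan()]); `NULL`
#'   skips comparisons.
#' @param roc_selectors selectors whose whole-stroma density is tested as a
#'   metastasis biomarker within NAC tumors (default TAM and TIM-3
#'   subsets); `NULL` skips ROC.
#' @param out_dir optional directory for result CSVs, a results JSON, a
#'   markdown report, and bar-chart figures.
#' @param make_figures write PV/non-PV x stroma/TCI bar charts (PDF) when
#'   `out_dir` is given.
#' @return list: `qc`, `areas`, `densities` (`roi`/`tumor`/`group`),
#'   `clusters`, `cluster_densities`, `cluster_composition`, `comparisons`,
#'   `roc` (named list of [roc_curve()] results).
#' @export
run_pipeline <- function(study,
                         pv_threshold_um = 50,
                         contact_threshold_um = 12,
                         gating = default_gating(),
                         selectors = default_selectors(),
                         plan = default_contrast_plan(),
                         roc_selectors = c("TAM", "TAM_TIM3pos", "TAM_TIM3neg"),
                         out_dir = NULL, make_figures = FALSE) {
  if (is.character(study)) study <- load_cohort(study)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  mf <- study$manifest
  map <- roi_map(mf)

  qc_total <- NULL
  roi_rows <- list(); clu_rows <- list(); clusters <- list()
  for (rid in names(study$rois)) {
    roi <- study$rois[[rid]]
    pt <- stage("phenotype", phenotype_table(roi$cells, gating))
    cells <- pt$cells
    qc_total <- if (is.null(qc_total)) pt$qc else qc_total + pt$qc
    cells$compartment <- stage("compartments",
      classify_cells(cells, roi$geometry, pv_threshold_um))
    areas <- roi$areas %||%
      stage("compartments", compartment_areas(roi$geometry, pv_threshold_um))
    cells$roi_id <- rid
    roi_rows[[rid]] <- stage("density", roi_density(cells, areas, selectors))
    tri <- stage("clusters",
      find_triples(cells, contact_threshold_um, roi$geometry,
                   pv_threshold_um))
    tri$roi_id <- if (nrow(tri)) rid else character()
    clusters[[rid]] <- tri
    clu_rows[[rid]] <- stage("clusters", cluster_density(tri, areas))
    study$rois[[rid]]$areas <- areas
  }
  roi_table <- do.call(rbind, roi_rows); rownames(roi_table) <- NULL
  clu_table <- do.call(rbind, clu_rows); rownames(clu_table) <- NULL
  all_areas <- do.call(rbind, lapply(study$rois, `[[`, "areas"))
  rownames(all_areas) <- NULL

  dens <- stage("density", aggregate_density(roi_table, mf))
  cdens <- stage("clusters", aggregate_density(clu_table, mf))
  all_clusters <- do.call(rbind, clusters); rownames(all_clusters) <- NULL
  if (nrow(all_clusters)) {
    idx <- match(all_clusters$roi_id, map$roi_id)
    all_clusters$group <- map$group[idx]
    comp <- stage("clusters", cluster_composition(
      all_clusters[all_clusters$compartment == "STROMA_PV", ],
      strata = c("group", "tcell_lineage")))
  } else comp <- cluster_composition(all_clusters)

  tumor_table <- dens$tumor
  tumor_table$treatment <- sub("_(DF|Mets)$", "", tumor_table$group)
  tumor_table$outcome <- sub("^.*_", "", tumor_table$group)
  comparisons <- if (!is.null(plan))
    stage("stats", run_comparisons(tumor_table, plan)) else NULL

  roc <- list()
  if (!is.null(roc_selectors)) {
    nac <- mf$tumor_id[mf$treatment == "NAC"]
    for (sel in roc_selectors) {
      sd <- stage("stats", stroma_density(roi_table, sel, mf))
      sd <- sd[sd$tumor_id %in% nac, ]
      if (length(unique(sub("^.*_", "", sd$group))) == 2L)
        roc[[sel]] <- stage("stats", roc_curve(
          sd$value, sub("^.*_", "", sd$group), positive = "DF"))
    }
  }

  results <- list(qc = qc_total, areas = all_areas, densities = dens,
                  clusters = all_clusters, cluster_densities = cdens,
                  cluster_composition = comp, comparisons = comparisons,
                  roc = roc,
                  params = list(pv_threshold_um = pv_threshold_um,
                                contact_threshold_um = contact_threshold_um))
  if (!is.null(out_dir)) {
    tables <- list(roi_density = dens$roi, tumor_density = dens$tumor,
                   group_density = dens$group,
                   cluster_density_group = cdens$group,
                   cluster_composition = comp,
                   compartment_areas = all_areas)
    if (!is.null(comparisons)) tables$comparisons <- comparisons
    write_results(tables, out_dir,
                  meta = list(params = results$params,
                              seed = study$config$seed %||% NA))
    jsonlite::write_json(
      list(roc = lapply(roc, function(r)
             list(auc = r$auc, p = r$p, n_pos = r$n_pos, n_neg = r$n_neg)),
           qc = as.list(qc_total),
           n_clusters = nrow(all_clusters)),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
    writeLines(report_markdown(results), file.path(out_dir, "report.md"))
    if (make_figures) .write_figures(results, out_dir)
  }
  results
}

#' Human-readable analysis report
#'
#' Markdown summary: group density tables (mean +/- SEM), significant
#' contrasts after Bonferroni correction, ROC AUCs with the conventional
#' interpretation bands (>0.7 good, <=0.5 random), and cluster composition.
#'
#' @param results output of [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(results) {
  lines <- c("# Perivascular immune landscape report", "")
  g <- results$densities$group
  lines <- c(lines, "## Group densities (cells/mm2, mean +/- SEM)", "")
  for (i in seq_len(nrow(g)))
    lines <- c(lines, sprintf("- %s / %s / %s: %.1f +/- %.1f (n = %d)",
                              g$group[i], g$compartment[i],
                              g$phenotype_selector[i], g$mean[i],
                              ifelse(is.na(g$sem[i]), 0, g$sem[i]), g$n[i]))
  if (!is.null(results$comparisons)) {
    sig <- results$comparisons[results$comparisons$significant, ]
    lines <- c(lines, "", "## Significant contrasts (Bonferroni-adjusted)", "")
    if (nrow(sig) == 0) lines <- c(lines, "none") else
      for (i in seq_len(nrow(sig)))
        lines <- c(lines, sprintf(
          "- [%s] %s / %s: %s vs %s, U = %g, adjusted p = %.4g",
          sig$block[i], sig$phenotype_selector[i], sig$compartment[i],
          sig$group_a[i], sig$group_b[i], sig$U[i], sig$p_adjusted[i]))
  }
  if (length(results$roc)) {
    lines <- c(lines, "", "## ROC: stromal density vs metastasis (NAC tumors)", "")
    for (nm in names(results$roc)) {
      r <- results$roc[[nm]]
      band <- if (r$auc > 0.7) "good (>0.7)"
              else if (r$auc <= 0.5) "random (<=0.5)" else "weak (0.5-0.7)"
      lines <- c(lines, sprintf("- %s: AUC = %.4f, %s, p = %.4g",
                                nm, r$auc, band, r$p))
    }
  }
  lines <- c(lines, "", "## Perivascular 3-cell clusters", "")
  if (is.null(results$clusters) || nrow(results$clusters) == 0)
    lines <- c(lines, "no clusters detected")
  else {
    lines <- c(lines, sprintf("%d clusters detected", nrow(results$clusters)))
    cc <- results$cluster_composition
    for (i in seq_len(nrow(cc)))
      lines <- c(lines, sprintf(
        "- %s: n = %d, naive/active/exhausted = %.2f/%.2f/%.2f, TAM PD-L1- = %.2f",
        paste(cc[i, setdiff(names(cc), c("n_clusters", "p_naive", "p_active",
                                         "p_exhausted", "p_tam_pdl1_pos",
                                         "p_tam_pdl1_neg",
                                         "tim3_ratio_in_pdl1neg"))],
              collapse = " / "),
        cc$n_clusters[i], cc$p_naive[i], cc$p_active[i], cc$p_exhausted[i],
        cc$p_tam_pdl1_neg[i]))
  }
  lines
}

#' Compartmental density bar chart
#'
#' Group mean +/- SEM bars in the standard PV/non-PV x stroma/TCI layout.
#'
#' @param group_table group-level table from [aggregate_density()].
#' @param selector phenotype selector name to plot.
#' @return a ggplot object.
#' @export
plot_density_bars <- function(group_table, selector) {
  d <- group_table[group_table$phenotype_selector == selector, ]
  d$compartment <- factor(d$compartment, levels = COMPARTMENTS)
  ggplot2::ggplot(d, ggplot2::aes(x = compartment, y = mean, fill = group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "cells / mm²", title = selector) +
    ggplot2::theme_classic()
}

.write_figures <- function(results, out_dir) {
  sels <- unique(results$densities$group$phenotype_selector)
  for (sel in sels) {
    p <- plot_density_bars(results$densities$group, sel)
    grDevices::pdf(file.path(out_dir, paste0("fig_", sel, ".pdf")),
                   width = 6, height = 4)
    print(p)
    grDevices::dev.off()
  }
}
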
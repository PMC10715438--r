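#' Mann-Whitney U comparison of two groups
#'
#' Rank-based two-sample test with midranks for ties. The U statistic is
#' reported for the first sample (`U = sum of ranks of a - n_a(n_a+1)/2`,
#' so `0 <= U <= n_a * n_b`). The p-value is exact (full enumeration) when
#' the pooled sample size is at most 12 and tie-free, and otherwise uses
#' the normal approximation with tie correction and continuity correction.
#' Two-sided throughout.
#'
#' @param a,b numeric vectors (NAs dropped; each must retain >= 1 value).
#' @param exact_max pooled-size cutoff for the exact p-value (default 12).
#' @return data frame row: `n_a`, `n_b`, `U`, `p_raw`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L)
    stop("mann_whitney requires >= 1 non-NA value per sample")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  ties <- any(duplicated(pooled))
  u <- sum(rank(pooled)[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  use_exact <- (n_a + n_b) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  data.frame(n_a = n_a, n_b = n_b, U = u, p_raw = unname(wt$p.value),
             method = if (use_exact) "exact" else "normal_approx",
             stringsAsFactors = FALSE)
}

#' Bonferroni correction with an explicit family size
#'
#' `p_adj = min(1, m * p)`. The family size is explicit, never inferred
#' from the vector length unless left `NULL`, so a family can be corrected
#' across calls.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m family size (default `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  if (is.null(m)) m <- length(p)
  if (m < 1) stop("family size m must be >= 1")
  pmin(1, m * p)
}

#' Pearson correlation
#'
#' Product-moment correlation with a two-sided p-value from the
#' t-transform on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite variance.
#' @return data frame row: `n`, `r`, `p`.
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("pearson_cor requires n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_cor requires non-zero variance in both variables")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  data.frame(n = length(x), r = unname(ct$estimate), p = ct$p.value)
}

#' ROC curve and AUC for a binary outcome
#'
#' Curve over all unique score thresholds with the fixed orientation
#' "higher score predicts the positive class": an AUC below 0.5 is reported
#' as-is with `flipped_orientation = TRUE`, never silently inverted. The
#' AUC is the trapezoidal integral of the curve and equals the all-pairs
#' concordance probability (ties count 1/2), hence `AUC * n_pos * n_neg`
#' equals the Mann-Whitney U of the positive-class scores. The p-value
#' (AUC != 0.5) comes from that U-test equivalence.
#'
#' @param scores numeric predictor.
#' @param labels outcome labels (two classes required).
#' @param positive the label treated as positive (e.g. `"Mets"`).
#' @return list of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `p`, `n_pos`, `n_neg`, `flipped_orientation`.
#' @export
roc_curve <- function(scores, labels, positive) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.character(labels[ok])
  classes <- unique(labels)
  if (!positive %in% classes) stop("positive label not present: ", positive)
  if (length(classes) != 2L)
    stop("roc_curve requires exactly two outcome classes, got ",
         length(classes))
  negative <- setdiff(classes, positive)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  ord <- order(1 - co$specificity, co$sensitivity) # (0,0) -> (1,1)
  auc <- as.numeric(pROC::auc(r))
  pos <- scores[labels == positive]
  neg <- scores[labels == negative]
  p <- mann_whitney(pos, neg)$p_raw
  structure(list(thresholds = co$threshold[ord],
                 tpr = co$sensitivity[ord],
                 fpr = 1 - co$specificity[ord],
                 auc = auc, p = p,
                 n_pos = length(pos), n_neg = length(neg),
                 flipped_orientation = auc < 0.5),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  band <- if (x$auc > 0.7) "good (>0.7)"
          else if (x$auc <= 0.5) "random (<=0.5)" else "weak (0.5-0.7)"
  cat(sprintf("<roc_result> AUC = %.4f [%s], p = %.4g (n+ = %d, n- = %d)%s\n",
              x$auc, band, x$p, x$n_pos, x$n_neg,
              if (x$flipped_orientation) " [orientation: lower scores predict positive]" else ""))
  invisible(x)
}

#' Run a planned set of group comparisons
#'
#' Executes a contrast plan on a tumor-level density table. The plan is a
#' list of named blocks; each block lists contrasts sharing one Bonferroni
#' family (the family size is the number of contrasts in the block — the
#' family is always declared, never inferred globally). Each contrast
#' selects tumor values for one phenotype selector and compartment and
#' compares two arms of a grouping variable with [mann_whitney()].
#'
#' @param tumor_table tumor-level table from [aggregate_density()] (columns
#'   `tumor_id`, `group`, `compartment`, `phenotype_selector`, `value`).
#' @param plan list of blocks; each block is a list of contrasts, each
#'   `list(selector =, compartment =, group_var = "group", arms = c(a, b))`.
#'   `group_var` may be any column of `tumor_table` (a `treatment` /
#'   `outcome` column can be merged in beforehand).
#' @param alpha significance level on the adjusted p (default 0.05;
#'   significance means `p_adjusted <= alpha`).
#' @param blind mask arm identities in the output as "arm_A"/"arm_B"
#'   (analysis blinding; re-run with `blind = FALSE` to unblind).
#' @return data frame: block, selector, compartment, arms, n per arm, U,
#'   `p_raw`, `m` (family size), `p_adjusted`, `significant`.
#' @export
run_comparisons <- function(tumor_table, plan, alpha = 0.05, blind = FALSE) {
  rows <- list()
  for (bn in names(plan)) {
    block <- plan[[bn]]
    m <- length(block)
    for (ct in block) {
      gv <- ct$group_var %||% "group"
      if (!gv %in% names(tumor_table))
        stop("grouping variable not in tumor table: ", gv)
      sub <- tumor_table[
        tumor_table$phenotype_selector == ct$selector &
        tumor_table$compartment == ct$compartment, , drop = FALSE]
      va <- sub$value[sub[[gv]] == ct$arms[1L]]
      vb <- sub$value[sub[[gv]] == ct$arms[2L]]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) < 1L || length(vb) < 1L)
        stop("contrast '", bn, "/", ct$selector, "/", ct$compartment,
             "' has an empty arm")
      mw <- mann_whitney(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        block = bn, phenotype_selector = ct$selector,
        compartment = ct$compartment,
        group_a = if (blind) "arm_A" else ct$arms[1L],
        group_b = if (blind) "arm_B" else ct$arms[2L],
        n_a = mw$n_a, n_b = mw$n_b, U = mw$U, p_raw = mw$p_raw,
        m = m, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- unname(mapply(bonferroni, out$p_raw, out$m))
  out$significant <- out$p_adjusted <= alpha
  out
}
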
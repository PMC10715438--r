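test_that("Mann-Whitney: U statistic and exact p match full enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_raw, 0.1)                   # 2/20 orderings as extreme
  expect_equal(r$p_raw, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_identical(r$method, "exact")
  # identical multisets: U = n^2/2, p = 1
  r2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r2$U, 8)
  expect_equal(r2$p_raw, 1)
  # random tie-free small samples agree with the enumeration oracle
  set.seed(50)
  for (i in 1:5) {
    a <- round(rnorm(4), 6); b <- round(rnorm(5) + 0.5, 6)
    expect_equal(mann_whitney(a, b)$p_raw, oracle_mw_exact_p(a, b),
                 tolerance = 1e-10)
  }
  expect_error(mann_whitney(numeric(), 1:3), ">= 1")
  expect_error(mann_whitney(c(NA_real_, NA_real_), 1:3), ">= 1")
})

test_that("normal approximation tracks the exact p beyond the cutoff", {
  set.seed(51)
  for (i in 1:3) {
    a <- rnorm(8); b <- rnorm(8) + 0.8
    approx_p <- mann_whitney(a, b)$p_raw      # pooled n = 16 > 12 cutoff
    expect_identical(mann_whitney(a, b)$method, "normal_approx")
    # the continuity correction contributes up to ~0.011 near the center
    # of the null distribution at n = 8 + 8
    expect_lt(abs(approx_p - oracle_mw_exact_p(a, b)), 0.015)
  }
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(52)
  a <- rexp(6); b <- rexp(7) * 2
  base <- mann_whitney(a, b)
  for (f in list(log, sqrt, function(x) x^3 + 5)) {
    tr <- mann_whitney(f(a), f(b))
    expect_equal(tr$U, base$U)
    expect_equal(tr$p_raw, base$p_raw)
  }
})

test_that("Bonferroni clips at 1, preserves order, never decreases p", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(c(0.2, 0.7)), c(0.4, 1))   # m defaults to length
  expect_equal(bonferroni(0.3, 1), 0.3)
  p <- c(0.001, 0.01, 0.04, 0.2)
  adj <- bonferroni(p, 10)
  expect_true(all(adj >= p))
  expect_false(is.unsorted(adj))
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
  expect_error(bonferroni(0.05, 0), "m must be")
})

test_that("Pearson correlation handles exact linear and orthogonal data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_equal(pearson_cor(c(-1, 0, 1), c(1, -2, 1))$r, 0)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_cor(c(1, 2), c(1, 2)), "n >= 3")
  # p-value agrees with the t-transform
  set.seed(53)
  a <- rnorm(10); b <- a + rnorm(10)
  pc <- pearson_cor(a, b)
  tstat <- pc$r * sqrt((pc$n - 2) / (1 - pc$r^2))
  expect_equal(pc$p, 2 * pt(-abs(tstat), pc$n - 2))
})

test_that("ROC: curve endpoints, AUC identities, fixed orientation", {
  r <- roc_curve(c(1, 2, 3, 4), c("n", "n", "p", "p"), positive = "p")
  expect_equal(r$auc, 1)
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(r$fpr[length(r$fpr)], 1)
  r2 <- roc_curve(c(1, 2, 3, 4), c("n", "p", "n", "p"), positive = "p")
  expect_equal(r2$auc, 0.75)
  # anti-predictive scores are reported as-is, flagged, never flipped
  r3 <- roc_curve(c(4, 3, 2, 1), c("n", "n", "p", "p"), positive = "p")
  expect_equal(r3$auc, 0)
  expect_true(r3$flipped_orientation)
  expect_error(roc_curve(1:4, rep("p", 4), positive = "p"), "two outcome")
  expect_error(roc_curve(1:4, c("a", "b", "a", "b"), positive = "c"),
               "not present")
})

test_that("AUC equals all-pairs concordance and the U identity holds", {
  set.seed(54)
  for (i in 1:5) {
    pos <- rnorm(7) + runif(1, 0, 1.5)
    neg <- rnorm(9)
    r <- roc_curve(c(pos, neg), rep(c("p", "n"), c(7, 9)), positive = "p")
    expect_equal(r$auc, oracle_auc(pos, neg), tolerance = 1e-12)
    # AUC * n1 * n2 = U of the positive sample (tie-free data)
    expect_equal(r$auc * 7 * 9, mann_whitney(pos, neg)$U)
    expect_equal(r$p, mann_whitney(pos, neg)$p_raw)
  }
  # random scores, larger n: AUC near 0.5
  set.seed(55)
  r <- roc_curve(rnorm(400), rep(c("p", "n"), 200), positive = "p")
  expect_lt(abs(r$auc - 0.5), 0.08)
})

test_that("run_comparisons applies per-block Bonferroni families", {
  tt <- expand.grid(tumor_id = sprintf("t%d", 1:12),
                    compartment = c("STROMA_PV", "STROMA_NONPV"),
                    phenotype_selector = c("TAM", "TREG"),
                    stringsAsFactors = FALSE)
  set.seed(56)
  tt$group <- rep(rep(c("NAC_DF", "NAC_Mets"), each = 6), 4)
  tt$value <- rnorm(nrow(tt), 100, 10)
  plan <- list(main = lapply(
    as.list(as.data.frame(t(expand.grid(
      s = c("TAM", "TREG"), c = c("STROMA_PV", "STROMA_NONPV"),
      stringsAsFactors = FALSE)))),
    function(z) list(selector = z[1], compartment = z[2],
                     group_var = "group", arms = c("NAC_DF", "NAC_Mets"))))
  res <- run_comparisons(tt, plan)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$m == 4))
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 4))
  expect_true(all(res$n_a == 6 & res$n_b == 6))
  # blinded mode masks arm identities
  resb <- run_comparisons(tt, plan, blind = TRUE)
  expect_true(all(resb$group_a == "arm_A"))
  expect_equal(resb$p_raw, res$p_raw)
  # empty arm errors
  plan2 <- list(x = list(list(selector = "TAM", compartment = "STROMA_PV",
                              group_var = "group",
                              arms = c("NAC_DF", "nope"))))
  expect_error(run_comparisons(tt, plan2), "empty arm")
})
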
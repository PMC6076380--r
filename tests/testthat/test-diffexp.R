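test_that("two-sample t-test matches its oracle and handles degenerate input", {
  # identical groups
  r <- t_test_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # pooled-variance worked example, frozen from the closed-form pooled t
  # with df = 6 (independently: t.test(var.equal = TRUE))
  r2 <- t_test_two_tailed(c(1, 2, 3, 4), c(3, 4, 5, 6), var_equal = TRUE)
  expect_equal(r2$p, 0.0709876543, tolerance = 1e-8)
  expect_equal(r2$p, t.test(c(1, 2, 3, 4), c(3, 4, 5, 6),
                            var.equal = TRUE)$p.value)
  # near-separation drives p toward 0
  r3 <- t_test_two_tailed(c(0, 0, 0, 0) + rnorm(4, sd = 1e-6),
                          c(1, 1, 1, 1) + rnorm(4, sd = 1e-6))
  expect_lt(r3$p, 1e-6)
  # both groups constant
  expect_warning(r4 <- t_test_two_tailed(c(2, 2), c(5, 5)), "degenerate")
  expect_equal(r4$p, 0)
  expect_equal(t_test_two_tailed(c(2, 2), c(2, 2))$p, 1)
})

test_that("t-test p is invariant to location shifts and positive rescaling", {
  set.seed(4)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  p0 <- t_test_two_tailed(x, y)$p
  expect_equal(t_test_two_tailed(x + 100, y + 100)$p, p0)
  expect_equal(t_test_two_tailed(3.7 * x, 3.7 * y)$p, p0)
})

test_that("exact Wilcoxon matches hand values and full enumeration with ties", {
  r <- wilcoxon_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)   # 2 of the 20 arrangements are as extreme
  expect_true(r$exact)
  expect_equal(wilcoxon_exact(5, 5)$p, 1)
  # brute-force oracle over random tied samples
  set.seed(12)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    expect_equal(wilcoxon_exact(x, y)$p, brute_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon agrees with the classical exact test when untied", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(wilcoxon_exact(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("exact and approximate Wilcoxon p agree for moderate samples", {
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(30); y <- rnorm(30)
    pe <- wilcoxon_exact(x, y, exact_limit = 60)$p
    pa <- wilcoxon_exact(x, y, exact_limit = 10)$p
    expect_lt(abs(pe - pa), 0.005)
  }
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_step_up(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) > -1e-12))  # monotone in p-rank
  }
})

test_that("ROC-AUC follows the Mann-Whitney identity", {
  expect_equal(roc_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(roc_auc(c(5, 5), c(5, 5)), 0.5)
  # cases (1,3) vs controls (2,4): only the pair (3,2) is concordant
  expect_equal(roc_auc(c(1, 3), c(2, 4)), 0.25)
  set.seed(14)
  x <- rnorm(15, 1); y <- rnorm(20)
  expect_equal(roc_auc(x, y), 1 - roc_auc(y, x))
  # invariant under monotone transforms of the values
  expect_equal(roc_auc(exp(x), exp(y)), roc_auc(x, y))
  skip_if_not_installed("pROC")
  labels <- c(rep(1, 15), rep(0, 20))
  pr <- pROC::roc(labels, c(x, y), quiet = TRUE, direction = "<")
  expect_equal(roc_auc(x, y), as.numeric(pROC::auc(pr)))
})

test_that("genome-wide differential expression recovers planted markers", {
  sim <- small_sim(seed = 3)
  m <- normalize_expression(sim$expression)
  de <- run_diffexp(m, cohort_split_from_annotation(sim$annotation))
  # structural invariants
  expect_setequal(de$mirna_id, unique(probe_groups(sim$expression)))
  expect_true(all(de$q_t >= de$p_t & de$q_w >= de$p_w))
  expect_true(all(de$auc >= 0 & de$auc <= 1))
  expect_equal(de$fold_change, 2^(-de$log2_fc))
  expect_equal(de$log2_fc, de$median_cohort2 - de$median_cohort1)
  # planted miRNAs concentrate at the top of the q_t ranking
  pos <- match(sim$truth$mirna_id, de$mirna_id)
  expect_lt(median(pos), 0.2 * nrow(de))
  # down-regulated planted miRNAs have fold change > 1 (cohort1 / cohort2)
  down <- sim$truth$mirna_id[sim$truth$signed_d < 0]
  expect_true(all(de$fold_change[match(down, de$mirna_id)] > 1))
  # the two test families agree on planted data
  expect_gt(attr(de, "concordance")$r, 0.5)
  # volcano export is consistent
  vd <- volcano_data(de)
  expect_equal(nrow(vd), nrow(de))
  expect_equal(vd$significant_raw, de$p_t < 0.05)
  expect_error(run_diffexp(m, cohort_split(c("x1", "x2"), c("x3", "x4"))),
               "not in matrix")
})
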
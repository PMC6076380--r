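test_that("class weights are proportional to inverse class frequency", {
  w <- class_weights(501, 33)
  expect_equal(unname(w["class2"] / w["class1"]), 501 / 33, tolerance = 1e-12)
  expect_equal(unname(class_weights(10, 10)), c(1, 1))
  w2 <- class_weights(3, 1)
  expect_equal(unname(w2["class2"] / w2["class1"]), 3)
  expect_error(class_weights(0, 5), ">= 1")
})

test_that("ANOVA-F feature selection ranks planted effects first", {
  set.seed(41)
  v <- matrix(rnorm(100 * 60), 100, 60,
              dimnames = list(sprintf("m%03d", 1:100), paste0("s", 1:60)))
  labels <- rep(c("a", "b"), each = 30)
  v[7, labels == "b"] <- v[7, labels == "b"] + 2.5   # strongest effect
  v[23, labels == "b"] <- v[23, labels == "b"] + 1.5 # weaker effect
  sel <- anova_f_select(v, labels, 2)
  expect_equal(sel[1], "m007")
  expect_true("m023" %in% sel)
  expect_setequal(anova_f_select(v, labels, 100), rownames(v))
  expect_error(anova_f_select(v, labels, 101), "exceeds")
  # with permuted labels the selected set is unstable across shuffles
  jac <- replicate(6, {
    s1 <- anova_f_select(v, sample(labels), 5)
    s2 <- anova_f_select(v, sample(labels), 5)
    length(intersect(s1, s2)) / length(union(s1, s2))
  })
  expect_lt(mean(jac), 0.5)
})

test_that("cross-validated boosting is deterministic and recovers planted markers", {
  set.seed(47)
  v <- matrix(rnorm(80 * 90), 80, 90,
              dimnames = list(sprintf("m%03d", 1:80), paste0("s", 1:90)))
  labels <- factor(rep(c("ctrl", "case"), times = c(60, 30)),
                   levels = c("ctrl", "case"))
  v[5, labels == "case"] <- v[5, labels == "case"] + 2
  v[11, labels == "case"] <- v[11, labels == "case"] - 2
  cc <- classifier_config(n_repeats = 2, n_folds = 3,
                          feature_grid = 2L, leaves_grid = 7L,
                          trees_grid = c(25L, 50L), seed = 7)
  r1 <- cv_gbt(v, labels, cc)
  r2 <- cv_gbt(v, labels, cc)
  expect_identical(r1$grid, r2$grid)
  expect_identical(r1$signature, r2$signature)
  expect_gt(r1$auc, 85)
  expect_setequal(r1$signature, c("m005", "m011"))
  expect_equal(nrow(r1$folds), 6)
  expect_true(all(r1$grid$auc >= 0 & r1$grid$auc <= 100))
})

test_that("chance-level data yields chance-level cross-validation AUC", {
  set.seed(53)
  v <- matrix(rnorm(100 * 200), 100, 200,
              dimnames = list(sprintf("m%03d", 1:100), paste0("s", 1:200)))
  labels <- factor(sample(rep(c("a", "b"), times = c(150, 50))))
  cc <- classifier_config(n_repeats = 2, n_folds = 5, feature_grid = 3L,
                          leaves_grid = 7L, trees_grid = 50L, seed = 3)
  r <- cv_gbt(v, labels, cc)
  expect_gt(r$auc, 40)
  expect_lt(r$auc, 60)
})

test_that("in-fold feature selection avoids the optimism of whole-data selection", {
  # on pure noise, selecting features on the full data before
  # cross-validation leaks information and inflates the estimated AUC
  diffs <- sapply(1:5, function(s) {
    set.seed(400 + s)
    v <- matrix(rnorm(400 * 60), 400, 60,
                dimnames = list(sprintf("m%03d", 1:400), paste0("s", 1:60)))
    labels <- factor(rep(c("a", "b"), each = 30))
    cc <- classifier_config(n_repeats = 1, n_folds = 3, feature_grid = 5L,
                            leaves_grid = 7L, trees_grid = 50L,
                            seed = 500 + s)
    proper <- cv_gbt(v, labels, cc)$auc
    leaky_feats <- anova_f_select(v, labels, 5)
    leaky <- cv_gbt(v[leaky_feats, ], labels, cc)$auc
    leaky - proper
  })
  expect_gt(mean(diffs), 5)   # leakage inflates AUC by several points
})

test_that("ratio class weighting improves balanced accuracy under strong imbalance", {
  deltas <- sapply(1:20, function(s) {
    set.seed(700 + s)
    v <- matrix(rnorm(50 * 160), 50, 160,
                dimnames = list(sprintf("m%03d", 1:50), paste0("s", 1:160)))
    labels <- factor(rep(c("maj", "min"), times = c(150, 10)),
                     levels = c("maj", "min"))
    v[1, labels == "min"] <- v[1, labels == "min"] + 1.5
    v[2, labels == "min"] <- v[2, labels == "min"] + 1.5
    cc_w <- classifier_config(n_repeats = 1, n_folds = 5, feature_grid = 2L,
                              leaves_grid = 7L, trees_grid = 50L, seed = s)
    cc_u <- classifier_config(n_repeats = 1, n_folds = 5, feature_grid = 2L,
                              leaves_grid = 7L, trees_grid = 50L, seed = s,
                              class_weighting = "none")
    cv_gbt(v, labels, cc_w)$bal_accuracy - cv_gbt(v, labels, cc_u)$bal_accuracy
  })
  expect_gt(mean(deltas), 0)
  p <- suppressWarnings(wilcox.test(deltas, alternative = "greater")$p.value)
  expect_lt(p, 0.05)
})

test_that("pair-wise group classification produces one report per pair", {
  sim <- simulate_cohort(synth_config(
    n_mirnas = 60, n_cases = 30, n_controls = 60, frac_de = 0.2,
    effect_size_d = 2, n_replicates_per_probe = 1, seed = 59,
    history_group_probs = c(0.4, 0.2, 0.27, 0.13)))
  m <- normalize_expression(sim$expression)
  cc <- classifier_config(n_repeats = 1, n_folds = 3, feature_grid = 2L,
                          leaves_grid = 7L, trees_grid = 25L, seed = 2)
  pw <- pairwise_group_classification(m, sim$annotation,
                                      pairs = list(c(1L, 2L), c(1L, 4L)),
                                      config = cc)
  expect_equal(nrow(pw$summary), 2)
  expect_setequal(pw$summary$pair, c("1-2", "1-4"))
  # planted case-vs-control difference shows up in both pairs
  expect_gt(pw$summary$auc[pw$summary$pair == "1-2"], 60)
  expect_error(pairwise_group_classification(m, sim$annotation,
                                             pairs = list(c(1L, 9L))),
               "1..4")
})
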
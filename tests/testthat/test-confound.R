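log2_sim <- function(sim) normalize_expression(sim$expression)

test_that("two-level ANOVA screen equals the squared pooled t-test", {
  sim <- small_sim(seed = 13)
  m <- log2_sim(sim)[1:40, ]
  fac <- sim$annotation$cohort
  scr <- anova_screen(m, fac)
  v <- 2^0  # screen rows are reordered by p; compare via ids
  for (id in scr$mirna_id[1:10]) {
    x <- expr_values(m)[id, fac == "control"]
    y <- expr_values(m)[id, fac == "case"]
    ht <- t.test(x, y, var.equal = TRUE)
    row <- scr[scr$mirna_id == id, ]
    expect_equal(row$f_stat, unname(ht$statistic)^2, tolerance = 1e-9)
    expect_equal(row$p, ht$p.value, tolerance = 1e-9)
  }
})

test_that("ANOVA screen is null-calibrated and detects planted age coupling", {
  sim <- simulate_cohort(synth_config(
    n_mirnas = 300, n_cases = 30, n_controls = 90, frac_de = 0,
    n_replicates_per_probe = 1, seed = 19,
    n_age_coupled = 3, age_slope = 0.08))
  m <- log2_sim(sim)
  # an arbitrary factor independent of expression: no BH discoveries
  set.seed(1)
  fake <- sample(c("u", "v"), ncol(m), replace = TRUE)
  scr <- anova_screen(m, fake)
  expect_equal(sum(scr$q < 0.05, na.rm = TRUE), 0)
  # binned age detects the age-coupled miRNAs
  age_bin <- cut(sim$annotation$age, breaks = 3)
  scr2 <- anova_screen(m, age_bin)
  hits <- scr2$mirna_id[scr2$q < 0.05]
  expect_true(all(sim$coupled$age %in% hits))
  # levels with < 2 samples are dropped with a warning
  fac3 <- fake; fac3[1] <- "rare"
  expect_warning(anova_screen(m[1:5, ], fac3), "rare")
})

test_that("correlation screen recovers planted slopes and is quiet on noise", {
  sim <- simulate_cohort(synth_config(
    n_mirnas = 300, n_cases = 30, n_controls = 90, frac_de = 0,
    n_replicates_per_probe = 1, seed = 23,
    n_age_coupled = 3, age_slope = 0.08))
  m <- log2_sim(sim)
  scr <- correlation_screen(m, sim$annotation$age)
  hits <- scr[scr$q < 0.05, ]
  expect_true(all(sim$coupled$age %in% hits$mirna_id))
  # planted slope is positive, recovered r must be too
  expect_true(all(hits$r[hits$mirna_id %in% sim$coupled$age] > 0))
  # uncoupled miRNAs: |r| stays small at n = 120
  null_r <- scr$r[!scr$mirna_id %in% sim$coupled$age]
  expect_lt(mean(abs(null_r) > 0.3), 0.01)
  # covariate equal to a miRNA's own values: r = 1
  own <- correlation_screen(m[1:3, ], expr_values(m)[2, ])
  expect_equal(own$r[own$mirna_id == rownames(m)[2]], 1, tolerance = 1e-12)
  expect_error(correlation_screen(m, rep(1, ncol(m))), "constant")
})

test_that("four-group history analysis isolates a group-specific shift", {
  sim <- simulate_cohort(synth_config(
    n_mirnas = 150, n_cases = 40, n_controls = 120, frac_de = 0,
    n_replicates_per_probe = 1, seed = 29,
    history_group_probs = c(0.45, 0.15, 0.3, 0.1),
    n_group3_coupled = 1, group3_shift = -1.5))
  m <- log2_sim(sim)
  ha <- history_group_analysis(m, sim$annotation)
  target <- sim$coupled$group3
  # the shifted miRNA is found by the four-group ANOVA ...
  expect_lt(ha$anova$q[ha$anova$mirna_id == target], 0.05)
  # ... and its four-group p beats the group-agnostic two-cohort p,
  # since the shift lives in group 3 and is invisible to the case split
  de <- run_diffexp(m, cohort_split_from_annotation(sim$annotation))
  expect_lt(ha$anova$p[ha$anova$mirna_id == target],
            de$p_t[de$mirna_id == target])
  expect_s3_class(ha$extreme, "mirna_diffexp")
})

test_that("an extra history-linked shift strengthens the extreme-group contrast", {
  sim <- simulate_cohort(synth_config(
    n_mirnas = 100, n_cases = 40, n_controls = 120, frac_de = 0.1,
    effect_size_d = 0.8, n_replicates_per_probe = 1, seed = 31,
    history_group_probs = c(0.4, 0.1, 0.2, 0.3)))
  m <- log2_sim(sim)
  v <- expr_values(m)
  # amplify the planted case effect within group 4 (history + cancer)
  g4 <- sim$annotation$sample_id[sim$annotation$group == 4]
  idx <- match(sim$truth$mirna_id, rownames(v))
  v[idx, g4] <- v[idx, g4] + sign(sim$truth$signed_d) * 2.5
  m2 <- expr_matrix(v, state = "log2")
  ha <- history_group_analysis(m2, sim$annotation)
  de <- run_diffexp(m2, cohort_split_from_annotation(sim$annotation))
  q_extreme <- ha$extreme$q_t[match(sim$truth$mirna_id, ha$extreme$mirna_id)]
  q_cohort <- de$q_t[match(sim$truth$mirna_id, de$mirna_id)]
  expect_lt(median(q_extreme), median(q_cohort))
})

test_that("cohort balance tests match their closed forms and the matched design", {
  # Fisher 2x2 oracle: hypergeometric sum over tables as extreme as (8,2 / 1,5)
  dh <- dhyper(3:9, 10, 6, 9)
  p_obs <- dhyper(8, 10, 6, 9)
  oracle <- sum(dh[dh <= p_obs * (1 + 1e-7)])
  expect_equal(oracle, 0.03496503, tolerance = 1e-6)
  expect_equal(fisher.test(matrix(c(8, 2, 1, 5), 2, byrow = TRUE))$p.value,
               oracle, tolerance = 1e-9)
  # matched generator defaults: no covariate significantly unbalanced
  # (frozen seeds; each test is at its nominal level under matching)
  n_clean <- 0
  for (s in 1:10) {
    sim <- simulate_cohort(synth_config(
      n_mirnas = 2, n_cases = 33, n_controls = 501,
      n_replicates_per_probe = 1, frac_de = 0, seed = 100 + s))
    bal <- cohort_balance_tests(sim$annotation)
    expect_setequal(bal$variable, c("age", "packyears", "gender", "smoking"))
    if (all(bal$p >= 0.05)) n_clean <- n_clean + 1
  }
  expect_gte(n_clean, 8)
})
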
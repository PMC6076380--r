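raw_mat <- function(v, pg = NULL) {
  expr_matrix(v, state = "raw", probe_group = pg)
}

test_that("background subtraction clamps at the floor and keeps zero a no-op", {
  v <- matrix(c(100, 5, 40, 80), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  m <- raw_mat(v)
  out <- subtract_background(m, background = 20)
  expect_equal(unname(expr_values(out)["p1", "s1"]), 80)
  expect_equal(unname(expr_values(out)["p2", "s1"]), 1) # 5 - 20 clamps to floor
  expect_equal(expr_values(subtract_background(m, 0)), v)
  expect_error(subtract_background(m, -5), "nonnegative")
  # per-sample background
  out2 <- subtract_background(m, background = c(10, 30))
  expect_equal(unname(expr_values(out2)[, "s2"]), c(10, 50))
})

test_that("replicate collapsing takes per-group medians", {
  v <- matrix(c(2, 4, 6, 10, 2, 4, 6, 10), 4, 2,
              dimnames = list(paste0("p", 1:4), c("s1", "s2")))
  m <- raw_mat(v, pg = c("A", "A", "A", "B"))
  out <- collapse_replicates(m)
  expect_equal(expr_state(out), "collapsed")
  expect_equal(unname(expr_values(out)["A", ]), c(4, 4))   # median(2,4,6)
  expect_equal(unname(expr_values(out)["B", ]), c(10, 10)) # single replicate
  # even replicate count: mean of the middle pair
  m2 <- raw_mat(v[1:2, ], pg = c("A", "A"))
  expect_equal(unname(expr_values(collapse_replicates(m2))["A", ]), c(3, 3))
  expect_error(collapse_replicates(raw_mat(v)), "probe_group")
})

test_that("replicate collapsing commutes with column subsetting", {
  set.seed(1)
  v <- matrix(rexp(10 * 3 * 6, rate = 0.01), 30, 6,
              dimnames = list(paste0("p", 1:30), paste0("s", 1:6)))
  m <- raw_mat(v, pg = rep(paste0("g", 1:10), each = 3))
  whole <- collapse_replicates(m)
  sub <- collapse_replicates(m[, c(2, 4, 5)])
  expect_equal(expr_values(sub), expr_values(whole[, c(2, 4, 5)]))
})

test_that("quantile normalization matches the worked 2x2 example and its invariants", {
  v <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- quantile_normalize(expr_matrix(v, state = "collapsed"))
  expect_equal(unname(expr_values(out)), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))

  set.seed(7)
  w <- matrix(rexp(120, 0.01), 30, 4,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  qn <- quantile_normalize(expr_matrix(w, state = "collapsed"))
  qv <- expr_values(qn)
  # identical value multiset in every column
  for (j in 2:4) expect_equal(unname(sort(qv[, j])), unname(sort(qv[, 1])))
  # idempotent
  expect_equal(expr_values(quantile_normalize(qn)), qv)
  # rank order preserved within each sample (up to ties)
  for (j in 1:4) expect_true(all(diff(qv[order(w[, j]), j]) > -1e-12))
  # tied values receive the mean of their tied ranks' reference values:
  # reference distribution of (2,2,5)/(1,3,4) is (1.5, 2.5, 4.5), so the
  # tied pair shares mean(1.5, 2.5) = 2
  tied <- matrix(c(2, 2, 5, 1, 3, 4), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  qt_ <- expr_values(quantile_normalize(expr_matrix(tied, state = "collapsed")))
  expect_equal(unname(qt_[, "s1"]), c(2, 2, 4.5))
  expect_equal(unname(qt_[, "s2"]), c(1.5, 2.5, 4.5))
  # identical columns stay unchanged
  same <- matrix(c(5, 1, 9, 5, 1, 9), 3, 2,
                 dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(expr_values(quantile_normalize(expr_matrix(same, state = "collapsed"))),
               same)
  expect_error(quantile_normalize(expr_matrix(same[, 1, drop = FALSE],
                                              state = "collapsed")),
               "2 samples")
})

test_that("log2 transform is exact and rejects nonpositive values", {
  v <- matrix(c(8, 1, 2, 16), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- log2_transform(expr_matrix(v, state = "normalized"))
  expect_equal(unname(expr_values(out)), matrix(c(3, 0, 1, 4), 2, 2))
  expect_equal(2^expr_values(out), v)
  v[2, 1] <- 0
  expect_error(log2_transform(expr_matrix(v, state = "normalized")), "'b'")
})

test_that("normality screen is calibrated on Gaussian data and separates scales on log-normal data", {
  set.seed(21)
  n <- 534
  gauss <- matrix(rnorm(500 * n, mean = 100, sd = 5), 500, n,
                  dimnames = list(paste0("g", 1:500), paste0("s", 1:n)))
  scr <- normality_screen(expr_matrix(gauss, state = "normalized"))
  expect_lt(abs(scr$summary[["frac_reject_raw"]] - 0.05), 0.02)

  lnorm <- matrix(2^rnorm(500 * n, mean = 8, sd = 1), 500, n,
                  dimnames = list(paste0("g", 1:500), paste0("s", 1:n)))
  scr2 <- normality_screen(expr_matrix(lnorm, state = "normalized"))
  expect_gt(scr2$summary[["frac_reject_raw"]], scr2$summary[["frac_reject_log"]])
  expect_lt(abs(scr2$summary[["frac_reject_log"]] - 0.05), 0.02)

  const <- gauss[1:3, ]
  const[1, ] <- 7
  scr3 <- normality_screen(expr_matrix(const, state = "normalized"))
  expect_true(is.na(scr3$table$p_raw[1]) && is.na(scr3$table$p_log[1]))
  expect_false(anyNA(scr3$table$p_raw[-1]))
})

test_that("the normalization chain enforces state transitions", {
  sim <- small_sim(seed = 2)
  m <- normalize_expression(sim$expression)
  expect_equal(expr_state(m), "log2")
  expect_equal(nrow(m), sim$config$n_mirnas)
  expect_error(collapse_replicates(m), "raw")
  expect_error(subtract_background(m, 1), "raw")
  # both normalization orders are available and differ in general
  m2 <- normalize_expression(sim$expression, log_after_normalize = FALSE)
  expect_equal(expr_state(m2), "log2")
})
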
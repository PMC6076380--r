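#' Two-tailed unpaired two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] returning the statistic and
#' two-tailed p-value, with defined behaviour for degenerate inputs:
#' two equal constant groups give `t = 0, p = 1`; two unequal constant
#' groups give `p = 0` with a warning. The Welch (unequal-variance) form
#' is the default, robust under strongly unbalanced group sizes; the
#' pooled-variance form is available via `var_equal = TRUE`.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return A list with elements `t` and `p`.
#' @export
t_test_two_tailed <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  cx <- max(x) - min(x) <= 0
  cy <- max(y) - min(y) <= 0
  if (cx && cy) {
    if (x[1] == y[1]) return(list(t = 0, p = 1))
    warning("both groups constant but unequal; degenerate t-test",
            call. = FALSE)
    return(list(t = sign(x[1] - y[1]) * Inf, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Exact tie-aware Wilcoxon-Mann-Whitney test
#'
#' Unpaired two-tailed rank-sum test. For small to moderate samples
#' (total n up to `exact_limit`) the two-tailed p-value is exact: the
#' permutation distribution of the rank sum over all `choose(n1+n2, n1)`
#' group labelings is computed by dynamic programming on the observed
#' mid-ranks, so ties are handled exactly rather than by approximation.
#' Above the limit the usual normal approximation with tie correction
#' and continuity correction is used.
#'
#' The reported statistic is the Mann-Whitney U of the first group, as
#' in [stats::wilcox.test()]; the two-tailed p is twice the smaller tail
#' of the permutation distribution, capped at 1.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_limit Largest total sample size for which the exact
#'   enumeration is used.
#' @return A list with elements `W` (Mann-Whitney U of `x`), `p`, and
#'   `exact` (logical).
#' @export
wilcoxon_exact <- function(x, y, exact_limit = 50L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L)
    stop("each group needs at least 1 value", call. = FALSE)
  n <- n1 + n2
  r <- rank(c(x, y))
  w1 <- sum(r[seq_len(n1)])
  U <- w1 - n1 * (n1 + 1) / 2
  if (n <= exact_limit) {
    # doubled mid-ranks are integers; DP over (group-1 size, rank sum)
    v <- as.integer(round(2 * r))
    total <- sum(v)
    # counts[k+1, s+1] = number of size-k subsets with doubled rank sum s
    counts <- matrix(0, n1 + 1L, total + 1L)
    counts[1L, 1L] <- 1
    for (item in v) {
      upd <- counts[seq_len(n1), , drop = FALSE]
      shifted <- matrix(0, n1, total + 1L)
      shifted[, (item + 1L):(total + 1L)] <- upd[, seq_len(total + 1L - item)]
      counts[2:(n1 + 1L), ] <- counts[2:(n1 + 1L), , drop = FALSE] + shifted
    }
    dist <- counts[n1 + 1L, ]
    ncomb <- sum(dist)
    w2 <- as.integer(round(2 * w1))
    p_low <- sum(dist[seq_len(w2 + 1L)]) / ncomb
    p_high <- sum(dist[(w2 + 1L):(total + 1L)]) / ncomb
    p <- min(1, 2 * min(p_low, p_high))
    list(W = U, p = p, exact = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    list(W = unname(ht$statistic), p = ht$p.value, exact = FALSE)
  }
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()] after validating
#' the input range.
#'
#' @param p Vector of raw p-values in \[0, 1\].
#' @return Vector of BH-adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Per-feature ROC area under the curve
#'
#' The probability that a randomly chosen case value exceeds a randomly
#' chosen control value, counting ties as one half (the Mann-Whitney
#' identity). Used both to rank miRNAs by degree of up-regulation and
#' to score classifier predictions.
#'
#' @param cases,controls Numeric vectors (each non-empty).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(cases, controls) {
  n1 <- length(cases); n2 <- length(controls)
  if (n1 < 1L || n2 < 1L)
    stop("each group needs at least 1 value", call. = FALSE)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Define the two cohorts of a case-control comparison
#'
#' @param cohort1 Sample ids of cohort 1 (patients who did not develop
#'   cancer).
#' @param cohort2 Sample ids of cohort 2 (patients who developed
#'   cancer).
#' @return A list of class `cohort_split`.
#' @export
cohort_split <- function(cohort1, cohort2) {
  cohort1 <- as.character(cohort1); cohort2 <- as.character(cohort2)
  if (length(intersect(cohort1, cohort2)) > 0)
    stop("cohorts must be disjoint", call. = FALSE)
  if (length(cohort1) < 2L || length(cohort2) < 2L)
    stop("each cohort needs at least 2 samples", call. = FALSE)
  structure(list(cohort1 = cohort1, cohort2 = cohort2,
                 n1 = length(cohort1), n2 = length(cohort2)),
            class = "cohort_split")
}

#' @rdname cohort_split
#' @param annotation Sample annotation data frame with columns
#'   `sample_id` and `cohort` (`"control"` = cohort 1, `"case"` =
#'   cohort 2).
#' @export
cohort_split_from_annotation <- function(annotation) {
  cohort_split(annotation$sample_id[annotation$cohort == "control"],
               annotation$sample_id[annotation$cohort == "case"])
}

#' Genome-wide two-cohort differential expression
#'
#' For every miRNA, computes the per-cohort medians, linear fold change
#' (cohort 1 over cohort 2, so down-regulation in cases gives a fold
#' change above 1), signed log2 fold change (cohort 2 minus cohort 1),
#' Welch or pooled t-test, exact tie-aware Wilcoxon-Mann-Whitney test,
#' Benjamini-Hochberg adjusted p-values within each test family, and the
#' case-vs-control ROC-AUC. The concordance of the two test families is
#' summarized as the Pearson correlation of their raw p-value vectors.
#'
#' @param mat A log2 [expr_matrix()].
#' @param split A [cohort_split()]; its sample ids must all be matrix
#'   columns.
#' @param var_equal Passed to [t_test_two_tailed()].
#' @param exact_limit Passed to [wilcoxon_exact()].
#' @return A data frame of class `mirna_diffexp` with one row per
#'   miRNA and columns `mirna_id`, `median_cohort1`, `median_cohort2`,
#'   `fold_change`, `log2_fc`, `t_stat`, `p_t`, `q_t`, `w_stat`, `p_w`,
#'   `q_w`, `auc`, ordered by `p_t`. Attributes: `concordance` (list
#'   with Pearson `r` and `p`), `n1`, `n2`.
#' @seealso [volcano_data()], [plot.mirna_diffexp()]
#' @export
run_diffexp <- function(mat, split, var_equal = FALSE, exact_limit = 50L) {
  stopifnot(inherits(mat, "expr_matrix"), inherits(split, "cohort_split"))
  if (expr_state(mat) != "log2")
    stop("differential expression expects a 'log2' matrix, got '",
         expr_state(mat), "'", call. = FALSE)
  v <- expr_values(mat)
  missing_ids <- setdiff(c(split$cohort1, split$cohort2), colnames(v))
  if (length(missing_ids) > 0)
    stop("sample ids not in matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  v1 <- v[, split$cohort1, drop = FALSE]
  v2 <- v[, split$cohort2, drop = FALSE]

  nmir <- nrow(v)
  med1 <- apply(v1, 1L, stats::median)
  med2 <- apply(v2, 1L, stats::median)
  t_stat <- p_t <- w_stat <- p_w <- auc <- numeric(nmir)
  for (i in seq_len(nmir)) {
    a <- v1[i, ]; b <- v2[i, ]
    tt <- t_test_two_tailed(b, a, var_equal = var_equal)
    ww <- wilcoxon_exact(b, a, exact_limit = exact_limit)
    t_stat[i] <- tt$t; p_t[i] <- tt$p
    w_stat[i] <- ww$W; p_w[i] <- ww$p
    auc[i] <- roc_auc(b, a)
  }
  res <- data.frame(
    mirna_id = rownames(v),
    median_cohort1 = med1, median_cohort2 = med2,
    fold_change = 2^(med1 - med2), log2_fc = med2 - med1,
    t_stat = t_stat, p_t = p_t, q_t = benjamini_hochberg(p_t),
    w_stat = w_stat, p_w = p_w, q_w = benjamini_hochberg(p_w),
    auc = auc, row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$p_t), ]
  rownames(res) <- NULL
  conc <- if (nmir >= 3L && stats::sd(p_t) > 0 && stats::sd(p_w) > 0) {
    ct <- stats::cor.test(p_t, p_w)
    list(r = unname(ct$estimate), p = ct$p.value)
  } else list(r = NA_real_, p = NA_real_)
  structure(res, concordance = conc, n1 = split$n1, n2 = split$n2,
            class = c("mirna_diffexp", "data.frame"))
}

#' @export
print.mirna_diffexp <- function(x, ...) {
  conc <- attr(x, "concordance")
  cat(sprintf("<mirna_diffexp> %d miRNAs, cohort sizes %d vs %d\n",
              nrow(x), attr(x, "n1"), attr(x, "n2")))
  cat(sprintf("  nominally significant (raw p_t < 0.05): %d (%d down, %d up in cohort 2)\n",
              sum(x$p_t < 0.05),
              sum(x$p_t < 0.05 & x$log2_fc < 0),
              sum(x$p_t < 0.05 & x$log2_fc > 0)))
  cat(sprintf("  BH-significant: %d (t-test), %d (Wilcoxon)\n",
              sum(x$q_t < 0.05), sum(x$q_w < 0.05)))
  if (is.finite(conc$r))
    cat(sprintf("  t / Wilcoxon raw-p concordance: Pearson r = %.3f (p = %.3g)\n",
                conc$r, conc$p))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Volcano-plot data for a differential expression result
#'
#' @param x A [run_diffexp()] result.
#' @param test Which test family's p-values to use.
#' @return Data frame with `mirna_id`, `log2_fc`, `neg_log10_p`,
#'   `significant_raw` (raw p < 0.05), `significant_adjusted`
#'   (BH q < 0.05), and `direction` (`"up_cohort1"` / `"up_cohort2"` /
#'   `"ns"`).
#' @export
volcano_data <- function(x, test = c("t", "wilcoxon")) {
  stopifnot(inherits(x, "mirna_diffexp"))
  test <- match.arg(test)
  p <- if (test == "t") x$p_t else x$p_w
  q <- if (test == "t") x$q_t else x$q_w
  data.frame(
    mirna_id = x$mirna_id, log2_fc = x$log2_fc,
    neg_log10_p = -log10(pmax(p, .Machine$double.xmin)),
    significant_raw = p < 0.05, significant_adjusted = q < 0.05,
    direction = ifelse(p >= 0.05, "ns",
                       ifelse(x$log2_fc < 0, "up_cohort1", "up_cohort2")),
    stringsAsFactors = FALSE)
}

#' Volcano plot of a differential expression result
#'
#' Log2 fold change against -log10 raw p. Points with raw p < 0.05 are
#' colored by direction (green: higher in cohort 1, red: higher in
#' cohort 2); the horizontal blue line marks the Benjamini-Hochberg
#' significance boundary when any miRNA clears it.
#'
#' @param x A [run_diffexp()] result.
#' @param test Which test family's p-values to plot.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.mirna_diffexp <- function(x, test = c("t", "wilcoxon"), ...) {
  test <- match.arg(test)
  vd <- volcano_data(x, test = test)
  col <- ifelse(vd$direction == "ns", "grey60",
                ifelse(vd$direction == "up_cohort1", "forestgreen", "red3"))
  graphics::plot(vd$log2_fc, vd$neg_log10_p, col = col, pch = 16,
                 cex = 0.5, xlab = "log2 fold change (cohort 2 - cohort 1)",
                 ylab = expression(-log[10] ~ "raw p"), ...)
  p <- if (test == "t") x$p_t else x$p_w
  q <- if (test == "t") x$q_t else x$q_w
  if (any(q < 0.05))
    graphics::abline(h = -log10(max(p[q < 0.05])), col = "blue")
  invisible(vd)
}
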
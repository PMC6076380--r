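#' Per-miRNA one-way ANOVA against a categorical covariate
#'
#' Screens every miRNA for dependence of its (log2) expression on a
#' categorical clinical feature using a classical one-way fixed-effects
#' ANOVA (equal-variance F test), with Benjamini-Hochberg adjustment
#' across miRNAs. Factor levels represented by fewer than 2 samples are
#' dropped with a warning. With a two-level factor the F statistic is
#' exactly the square of the pooled-variance t statistic.
#'
#' @param mat A log2 [expr_matrix()].
#' @param covariate Factor (or coercible) of length `ncol(mat)`.
#' @return Data frame with `mirna_id`, `f_stat`, `p`, `q`.
#' @export
anova_screen <- function(mat, covariate) {
  stopifnot(inherits(mat, "expr_matrix"))
  v <- expr_values(mat)
  fac <- factor(covariate)
  if (length(fac) != ncol(v))
    stop("'covariate' must have one value per sample", call. = FALSE)
  keep_lv <- names(which(table(fac) >= 2L))
  if (length(keep_lv) < nlevels(fac))
    warning("dropping factor level(s) with < 2 samples: ",
            paste(setdiff(levels(fac), keep_lv), collapse = ", "),
            call. = FALSE)
  keep <- fac %in% keep_lv
  fac <- droplevels(fac[keep])
  if (nlevels(fac) < 2L)
    stop("need at least 2 factor levels with >= 2 samples each",
         call. = FALSE)
  v <- v[, keep, drop = FALSE]
  out <- t(apply(v, 1L, function(x) {
    ht <- tryCatch(stats::oneway.test(x ~ fac, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ht) || !is.finite(ht$statistic))
      c(NA_real_, NA_real_)
    else c(unname(ht$statistic), ht$p.value)
  }))
  res <- data.frame(mirna_id = rownames(v), f_stat = out[, 1], p = out[, 2],
                    q = benjamini_hochberg(out[, 2]),
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$p), ]
}

#' Per-miRNA Pearson correlation with a numeric covariate
#'
#' Pearson correlation coefficient and two-tailed p-value of every
#' miRNA's expression against a continuous clinical feature (age,
#' pack-years, ...), BH-adjusted across miRNAs. Missing covariate
#' values are excluded pairwise.
#'
#' @param mat A log2 [expr_matrix()].
#' @param covariate Numeric vector of length `ncol(mat)`; must not be
#'   constant.
#' @return Data frame with `mirna_id`, `r`, `p`, `q`.
#' @export
correlation_screen <- function(mat, covariate) {
  stopifnot(inherits(mat, "expr_matrix"))
  v <- expr_values(mat)
  if (length(covariate) != ncol(v))
    stop("'covariate' must have one value per sample", call. = FALSE)
  if (stats::sd(covariate, na.rm = TRUE) == 0 || all(is.na(covariate)))
    stop("'covariate' is constant; correlation undefined", call. = FALSE)
  ok <- !is.na(covariate)
  n_missing <- sum(!ok)
  if (n_missing > 0)
    message(n_missing, " samples with missing covariate excluded")
  cv <- covariate[ok]
  vv <- v[, ok, drop = FALSE]
  out <- t(apply(vv, 1L, function(x) {
    if (stats::sd(x) == 0) return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(x, cv)
    c(unname(ct$estimate), ct$p.value)
  }))
  res <- data.frame(mirna_id = rownames(v), r = out[, 1], p = out[, 2],
                    q = benjamini_hochberg(out[, 2]),
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$p), ]
}

#' Four-group cancer-history analysis
#'
#' Crosses prior cancer history with later cancer development into four
#' groups (1: no history / no cancer, 2: no history / developed cancer,
#' 3: history / no cancer, 4: history / developed cancer), runs a
#' per-miRNA four-group ANOVA, and compares the two "extreme" groups
#' (1 vs 4) with the full differential expression machinery.
#'
#' @param mat A log2 [expr_matrix()].
#' @param annotation Sample annotation with columns `sample_id` and
#'   `group` in 1..4 (see [synth_config()] for the encoding).
#' @param ... Passed to [run_diffexp()] for the extreme-group
#'   comparison.
#' @return A list of class `history_analysis` with elements `anova`
#'   (per-miRNA four-group screen, `NULL` if any group is empty) and
#'   `extreme` (a [run_diffexp()] result for groups 1 vs 4, `NULL` if
#'   either has fewer than 2 samples).
#' @export
history_group_analysis <- function(mat, annotation, ...) {
  stopifnot(inherits(mat, "expr_matrix"))
  ann <- annotation[match(colnames(mat), annotation$sample_id), ]
  if (anyNA(ann$sample_id))
    stop("annotation is missing some matrix samples", call. = FALSE)
  grp <- factor(ann$group, levels = 1:4)
  tab <- table(grp)
  anova_res <- NULL
  if (all(tab > 0)) {
    anova_res <- anova_screen(mat, grp)
  } else {
    warning("empty history group(s): ",
            paste(names(tab)[tab == 0], collapse = ", "),
            "; four-group ANOVA skipped", call. = FALSE)
  }
  extreme <- NULL
  g1 <- ann$sample_id[ann$group == 1]
  g4 <- ann$sample_id[ann$group == 4]
  if (length(g1) >= 2L && length(g4) >= 2L) {
    extreme <- run_diffexp(mat, cohort_split(g1, g4), ...)
  } else {
    warning("groups 1/4 too small for the extreme-group comparison",
            call. = FALSE)
  }
  structure(list(anova = anova_res, extreme = extreme,
                 group_sizes = as.integer(tab)),
            class = "history_analysis")
}

#' @export
print.history_analysis <- function(x, ...) {
  cat("<history_analysis> group sizes:",
      paste(x$group_sizes, collapse = " / "), "\n")
  if (!is.null(x$anova))
    cat(sprintf("  four-group ANOVA: %d BH-significant miRNAs\n",
                sum(x$anova$q < 0.05, na.rm = TRUE)))
  if (!is.null(x$extreme))
    cat(sprintf("  extreme groups 1 vs 4: %d BH-significant miRNAs (t-test)\n",
                sum(x$extreme$q_t < 0.05)))
  invisible(x)
}

#' Cohort comparability tests for matched covariates
#'
#' Checks whether the two cohorts are balanced on the matching
#' covariates: Welch t-tests for age and pack-years, Fisher's exact
#' 2x2 test for gender, and a chi-square contingency test for the
#' three-level smoking status (falling back to Fisher's exact test when
#' any expected cell count is below 5). In a well-matched design all
#' four p-values should be unremarkable.
#'
#' @param annotation Sample annotation with columns `cohort`, `age`,
#'   `packyears`, `gender`, `smoking`.
#' @return Data frame with `variable`, `test`, `p`.
#' @export
cohort_balance_tests <- function(annotation) {
  ann <- annotation
  if (length(unique(ann$cohort)) != 2L)
    stop("annotation must contain both cohorts", call. = FALSE)
  coh <- factor(ann$cohort)
  rows <- list()
  for (nm in c("age", "packyears")) {
    p <- stats::t.test(ann[[nm]] ~ coh)$p.value
    rows[[nm]] <- data.frame(variable = nm, test = "t-test", p = p,
                             stringsAsFactors = FALSE)
  }
  tab_g <- table(coh, factor(ann$gender, levels = c("f", "m")))
  rows$gender <- data.frame(variable = "gender", test = "fisher-exact",
                            p = stats::fisher.test(tab_g)$p.value,
                            stringsAsFactors = FALSE)
  tab_s <- table(coh, factor(ann$smoking,
                             levels = c("never", "past", "present")))
  tab_s <- tab_s[, colSums(tab_s) > 0, drop = FALSE]
  cs <- suppressWarnings(stats::chisq.test(tab_s))
  if (any(cs$expected < 5)) {
    rows$smoking <- data.frame(variable = "smoking", test = "fisher-exact",
                               p = stats::fisher.test(tab_s)$p.value,
                               stringsAsFactors = FALSE)
  } else {
    rows$smoking <- data.frame(variable = "smoking", test = "chi-square",
                               p = cs$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
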
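#' Subtract array background from raw intensities
#'
#' Subtracts a scalar or per-sample background from a raw probe-level
#' matrix, clamping the result at a small positive floor so that later
#' log transformation stays defined. A zero background leaves the matrix
#' untouched.
#'
#' @param mat A raw [expr_matrix()].
#' @param background Nonnegative scalar, or vector with one value per
#'   sample.
#' @param floor Lower clamp applied to subtracted values (default 1
#'   intensity unit).
#' @return A raw `expr_matrix` with background removed.
#' @export
subtract_background <- function(mat, background = 0, floor = 1) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (expr_state(mat) != "raw")
    stop("background subtraction expects a 'raw' matrix, got '",
         expr_state(mat), "'", call. = FALSE)
  if (any(!is.finite(background)) || any(background < 0))
    stop("'background' must be finite and nonnegative", call. = FALSE)
  if (!(length(background) %in% c(1L, ncol(mat))))
    stop("'background' must be a scalar or one value per sample",
         call. = FALSE)
  if (all(background == 0)) return(mat)
  v <- expr_values(mat)
  v <- pmax(sweep(v, 2L, background, `-`), floor)
  expr_matrix(v, state = "raw", probe_group = probe_groups(mat))
}

#' Collapse replicate probes to per-miRNA medians
#'
#' Computes, for every miRNA and sample, the median of that miRNA's
#' replicate probe intensities on that array. Row order of the output
#' follows the first appearance of each probe group.
#'
#' @param mat A raw [expr_matrix()] whose rows carry a `probe_group`
#'   label.
#' @return A collapsed `expr_matrix`, one row per miRNA.
#' @export
collapse_replicates <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (expr_state(mat) != "raw")
    stop("replicate collapsing expects a 'raw' matrix, got '",
         expr_state(mat), "'", call. = FALSE)
  pg <- probe_groups(mat)
  if (is.null(pg))
    stop("matrix has no 'probe_group' labels; cannot collapse replicates",
         call. = FALSE)
  v <- expr_values(mat)
  groups <- unique(pg)
  # group medians via data.table on integer keys (fast at the full
  # 2549 miRNAs x 534 samples x replicates scale)
  dt <- data.table::data.table(
    g = rep.int(match(pg, groups), ncol(v)),
    s = rep(seq_len(ncol(v)), each = nrow(v)),
    val = as.vector(v))
  # bare median() so data.table can use its optimized group-median
  med <- dt[, list(med = median(val)), by = c("s", "g")]
  data.table::setorder(med, s, g)
  out <- matrix(med$med, length(groups), ncol(v),
                dimnames = list(groups, colnames(v)))
  expr_matrix(out, state = "collapsed")
}

#' Quantile-normalize a collapsed expression matrix
#'
#' Forces every sample to share the common distribution of per-rank
#' column means: values are sorted within each sample, averaged across
#' samples at each rank, and mapped back; tied values receive the mean
#' of their tied ranks' reference values. Delegates to
#' [limma::normalizeQuantiles()] with tie handling enabled. The
#' operation is idempotent and preserves within-sample rank order up to
#' ties.
#'
#' @param mat A collapsed (or already normalized) [expr_matrix()] with
#'   at least two samples.
#' @return A normalized `expr_matrix`.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (!expr_state(mat) %in% c("collapsed", "normalized"))
    stop("quantile normalization expects a 'collapsed' matrix, got '",
         expr_state(mat), "'", call. = FALSE)
  if (ncol(mat) < 2L)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  v <- limma::normalizeQuantiles(expr_values(mat), ties = TRUE)
  dimnames(v) <- dimnames(mat)
  expr_matrix(v, state = "normalized")
}

#' Log2-transform a normalized expression matrix
#'
#' @param mat A normalized (or collapsed) [expr_matrix()] with strictly
#'   positive values.
#' @return An `expr_matrix` in state `"log2"`.
#' @export
log2_transform <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (!expr_state(mat) %in% c("collapsed", "normalized"))
    stop("log2 transform expects a 'collapsed' or 'normalized' matrix, got '",
         expr_state(mat), "'", call. = FALSE)
  v <- expr_values(mat)
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive value at row '%s', sample '%s'; cannot log2-transform",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]),
         call. = FALSE)
  expr_matrix(log2(v), state = "log2")
}

#' Normalize a raw matrix end to end
#'
#' Convenience chain: background subtraction, replicate collapsing,
#' quantile normalization on the linear scale, then log2. Normalizing
#' before taking logs is the package default; both orders occur in
#' microarray practice, and the switch keeps the choice auditable.
#'
#' @inheritParams subtract_background
#' @param log_after_normalize If `FALSE`, log2 is taken before quantile
#'   normalization instead of after.
#' @return An `expr_matrix` in state `"log2"`.
#' @export
normalize_expression <- function(mat, background = 0, floor = 1,
                                 log_after_normalize = TRUE) {
  m <- subtract_background(mat, background = background, floor = floor)
  m <- collapse_replicates(m)
  if (log_after_normalize) {
    log2_transform(quantile_normalize(m))
  } else {
    m <- log2_transform(m)
    # quantile normalization applied on the log scale: same mechanics
    v <- limma::normalizeQuantiles(expr_values(m), ties = TRUE)
    dimnames(v) <- dimnames(m)
    expr_matrix(v, state = "log2")
  }
}

#' Per-miRNA normality screen on raw and log scales
#'
#' Runs a Shapiro-Wilk test on each miRNA's values on the linear scale
#' and after log2 transformation, reporting both p-values and the
#' fraction of miRNAs rejected at `alpha` on each scale. Constant rows
#' are flagged not-applicable (`NA` p-values) and excluded from the
#' summary denominators.
#'
#' @param mat An [expr_matrix()] on the linear scale (state
#'   `"collapsed"` or `"normalized"`) with 3 to 5000 samples.
#' @param alpha Rejection level for the summary fractions.
#' @return A list with `table` (per-miRNA `p_raw`, `p_log`) and
#'   `summary` (named fractions `frac_reject_raw`, `frac_reject_log`).
#' @export
normality_screen <- function(mat, alpha = 0.05) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (!expr_state(mat) %in% c("collapsed", "normalized"))
    stop("normality screen expects linear-scale values ('collapsed' or 'normalized')",
         call. = FALSE)
  v <- expr_values(mat)
  if (ncol(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (ncol(v) > 5000L) stop("Shapiro-Wilk supports at most 5000 samples",
                            call. = FALSE)
  sw <- function(x) {
    if (max(x) - min(x) <= 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  p_raw <- apply(v, 1L, sw)
  p_log <- apply(v, 1L, function(x) if (any(x <= 0)) NA_real_ else sw(log2(x)))
  tab <- data.frame(mirna_id = rownames(v), p_raw = p_raw, p_log = p_log,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       summary = c(frac_reject_raw = mean(p_raw < alpha, na.rm = TRUE),
                   frac_reject_log = mean(p_log < alpha, na.rm = TRUE)),
       alpha = alpha)
}
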
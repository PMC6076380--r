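# vectorized two-group one-way ANOVA F per matrix row (pooled variance);
# identical to the square of the pooled t statistic
row_f_stats <- function(v, is_pos) {
  x1 <- v[, !is_pos, drop = FALSE]
  x2 <- v[, is_pos, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  (n1 * n2 / (n1 + n2)) * (m1 - m2)^2 / sp2
}

#' Select the top-k miRNAs by ANOVA F-value
#'
#' Ranks miRNAs by their one-way ANOVA F statistic between the two
#' classes and returns the k best, ties broken by lexicographic miRNA
#' id. Inside cross-validation this must be called on training folds
#' only; [cv_gbt()] does so automatically.
#'
#' @param mat A log2 [expr_matrix()] or plain numeric matrix (rows =
#'   miRNAs).
#' @param labels Two-level factor (or coercible) over the columns; the
#'   second level is treated as the positive class.
#' @param k Signature size, at most `nrow(mat)`.
#' @return Character vector of k miRNA ids, best first.
#' @export
anova_f_select <- function(mat, labels, k) {
  v <- if (inherits(mat, "expr_matrix")) expr_values(mat) else mat
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("'labels' must have exactly 2 levels", call. = FALSE)
  if (min(table(labels)) < 2L)
    stop("each class needs at least 2 samples", call. = FALSE)
  if (k > nrow(v))
    stop("'k' exceeds the number of available features", call. = FALSE)
  f <- row_f_stats(v, labels == levels(labels)[2])
  f[!is.finite(f)] <- -Inf
  rownames(v)[order(-f, rownames(v))][seq_len(k)]
}

#' Per-class weights proportional to inverse class frequency
#'
#' Weight of class c is `total / (2 * n_c)`, so the minority-to-majority
#' weight ratio equals the inverse size ratio and a balanced dataset
#' gets unit weights.
#'
#' @param n1,n2 Class sizes (>= 1).
#' @return Named numeric vector `c(class1 = w1, class2 = w2)`.
#' @examples
#' class_weights(501, 33)  # weight ratio 501/33
#' @export
class_weights <- function(n1, n2) {
  if (n1 < 1L || n2 < 1L) stop("class sizes must be >= 1", call. = FALSE)
  total <- n1 + n2
  c(class1 = total / (2 * n1), class2 = total / (2 * n2))
}

#' Configuration for cross-validated gradient-boosted-tree signatures
#'
#' Defaults follow the motivating protocol: a grid over signature sizes
#' 2-13, number of leaves and number of trees, evaluated by 5-times
#' repeated stratified 5-fold cross-validation with classes weighted by
#' their inverse ratios.
#'
#' @param n_repeats Number of cross-validation repeats.
#' @param n_folds Number of stratified folds per repeat.
#' @param feature_grid Candidate signature sizes.
#' @param leaves_grid Candidate numbers of leaves per tree.
#' @param trees_grid Candidate numbers of boosting rounds.
#' @param eta Learning rate of the boosted ensemble.
#' @param seed Integer seed; fold shuffles are derived per repeat.
#' @param class_weighting `"by-ratio"` (default) weights classes by
#'   their inverse size ratio during training; `"none"` disables
#'   weighting (useful to quantify what the weighting buys under
#'   imbalance).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(n_repeats = 5L, n_folds = 5L,
                              feature_grid = 2:13,
                              leaves_grid = c(7L, 15L, 31L),
                              trees_grid = c(50L, 100L, 200L),
                              eta = 0.3, seed = 1L,
                              class_weighting = c("by-ratio", "none")) {
  class_weighting <- match.arg(class_weighting)
  if (n_folds < 2L) stop("'n_folds' must be >= 2", call. = FALSE)
  if (length(feature_grid) == 0L || length(leaves_grid) == 0L ||
      length(trees_grid) == 0L)
    stop("all hyperparameter grids must be non-empty", call. = FALSE)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 feature_grid = sort(as.integer(feature_grid)),
                 leaves_grid = sort(as.integer(leaves_grid)),
                 trees_grid = sort(as.integer(trees_grid)),
                 eta = eta, seed = as.integer(seed),
                 class_weighting = class_weighting),
            class = "classifier_config")
}

# stratified fold assignment: within each class, samples are shuffled
# and folds filled round-robin
stratified_folds <- function(is_pos, n_folds) {
  fold <- integer(length(is_pos))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_pos == cls)
    if (length(idx) < n_folds)
      stop("stratification error: a class has fewer samples than folds",
           call. = FALSE)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

fit_gbt <- function(X, y, w, leaves, trees, eta) {
  dtr <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
  params <- list(objective = "binary:logistic", tree_method = "hist",
                 grow_policy = "lossguide", max_leaves = leaves,
                 max_depth = 0L, eta = eta, nthread = 1L)
  xgboost::xgb.train(params = params, data = dtr, nrounds = trees,
                     verbose = 0)
}

#' Cross-validated gradient-boosted-tree signature selection
#'
#' Grid search over signature size, leaves and trees in repeated
#' stratified k-fold cross-validation. Within every training fold,
#' features are re-ranked by their ANOVA F-value (no selection leakage
#' into the held-out fold), classes are weighted by their inverse
#' ratios, and a gradient-boosted tree ensemble with logistic loss is
#' fitted; held-out samples are scored and fold-level ROC-AUC and
#' accuracy are averaged per grid point. The grid point with the best
#' mean AUC wins (accuracy is reported but not used for selection, as
#' it is inflated under class imbalance); the reported signature comes
#' from refitting the winning configuration on the whole dataset.
#'
#' Fully deterministic given the configuration seed.
#'
#' @param mat A log2 [expr_matrix()] or numeric matrix, rows = miRNAs.
#' @param labels Two-level factor over the columns; second level =
#'   positive class.
#' @param config A [classifier_config()].
#' @return An object of class `gbt_report`: list with `grid` (mean AUC
#'   and accuracy per grid point, in percent), `best` (winning grid
#'   point), `signature` (miRNA ids of the final whole-data model),
#'   `auc`, `accuracy` (percent, cross-validation metrics of the winning
#'   point), `folds` (per-fold metrics of the winning point) and
#'   `config`.
#' @export
cv_gbt <- function(mat, labels, config = classifier_config()) {
  v <- if (inherits(mat, "expr_matrix")) expr_values(mat) else mat
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("'labels' must have exactly 2 levels", call. = FALSE)
  if (length(labels) != ncol(v))
    stop("'labels' must have one value per sample", call. = FALSE)
  is_pos <- labels == levels(labels)[2]
  cf <- config
  kmax <- max(cf$feature_grid)
  if (kmax > nrow(v))
    stop("largest signature size exceeds the number of features",
         call. = FALSE)

  grid <- expand.grid(k = cf$feature_grid, leaves = cf$leaves_grid,
                      trees = cf$trees_grid, KEEP.OUT.ATTRS = FALSE)
  nfold_total <- cf$n_repeats * cf$n_folds
  auc_acc <- array(0, dim = c(nrow(grid), nfold_total, 3L))
  tmax <- max(cf$trees_grid)
  weighted <- is.null(cf$class_weighting) || cf$class_weighting == "by-ratio"

  fold_i <- 0L
  for (r in seq_len(cf$n_repeats)) {
    set.seed(cf$seed + r)
    fold <- stratified_folds(is_pos, cf$n_folds)
    for (f in seq_len(cf$n_folds)) {
      fold_i <- fold_i + 1L
      tr <- fold != f
      te <- !tr
      # feature ranking on the training fold only
      fstat <- row_f_stats(v[, tr, drop = FALSE], is_pos[tr])
      fstat[!is.finite(fstat)] <- -Inf
      ranked <- rownames(v)[order(-fstat, rownames(v))]
      y_tr <- as.numeric(is_pos[tr])
      w_tr <- if (weighted) {
        cw <- class_weights(sum(!is_pos[tr]), sum(is_pos[tr]))
        ifelse(is_pos[tr], cw["class2"], cw["class1"])
      } else rep(1, sum(tr))
      y_te <- is_pos[te]
      for (k in cf$feature_grid) {
        feats <- ranked[seq_len(k)]
        X_tr <- t(v[feats, tr, drop = FALSE])
        X_te <- t(v[feats, te, drop = FALSE])
        for (lv in cf$leaves_grid) {
          booster <- fit_gbt(X_tr, y_tr, w_tr, lv, tmax, cf$eta)
          for (tt in cf$trees_grid) {
            score <- stats::predict(booster, X_te,
                                    iterationrange = c(1L, tt))
            gi <- which(grid$k == k & grid$leaves == lv & grid$trees == tt)
            auc_acc[gi, fold_i, 1L] <- roc_auc(score[y_te], score[!y_te])
            auc_acc[gi, fold_i, 2L] <- mean((score > 0.5) == y_te)
            auc_acc[gi, fold_i, 3L] <-
              (mean(score[y_te] > 0.5) + mean(score[!y_te] <= 0.5)) / 2
          }
        }
      }
    }
  }
  grid$auc <- 100 * apply(auc_acc[, , 1L, drop = FALSE], 1L, mean)
  grid$accuracy <- 100 * apply(auc_acc[, , 2L, drop = FALSE], 1L, mean)
  grid$bal_accuracy <- 100 * apply(auc_acc[, , 3L, drop = FALSE], 1L, mean)
  # best mean AUC; ties resolved toward the smaller model
  ord <- order(-grid$auc, grid$k, grid$leaves, grid$trees)
  best_i <- ord[1]
  best <- grid[best_i, ]

  # final signature: winning configuration refit on the whole dataset
  feats <- anova_f_select(v, labels, best$k)
  w <- if (weighted) {
    cw <- class_weights(sum(!is_pos), sum(is_pos))
    ifelse(is_pos, cw["class2"], cw["class1"])
  } else rep(1, length(is_pos))
  final <- fit_gbt(t(v[feats, , drop = FALSE]), as.numeric(is_pos), w,
                   best$leaves, best$trees, cf$eta)

  folds <- data.frame(fold = seq_len(nfold_total),
                      auc = 100 * auc_acc[best_i, , 1L],
                      accuracy = 100 * auc_acc[best_i, , 2L],
                      bal_accuracy = 100 * auc_acc[best_i, , 3L])
  structure(list(grid = grid, best = best, signature = feats,
                 auc = best$auc, accuracy = best$accuracy,
                 bal_accuracy = best$bal_accuracy,
                 folds = folds, positive_class = levels(labels)[2],
                 n = unname(table(labels)), config = cf, model = final),
            class = "gbt_report")
}

#' @export
print.gbt_report <- function(x, ...) {
  cat(sprintf("<gbt_report> positive class '%s' (%d vs %d samples)\n",
              x$positive_class, x$n[1], x$n[2]))
  cat(sprintf("  best grid point: %d miRNAs, %d leaves, %d trees\n",
              x$best$k, x$best$leaves, x$best$trees))
  cat(sprintf("  cross-validation AUC %.1f%%, accuracy %.1f%%\n",
              x$auc, x$accuracy))
  cat("  signature:", paste(x$signature, collapse = ", "), "\n")
  invisible(x)
}

#' Pair-wise history-group classification
#'
#' Runs [cv_gbt()] on every requested pair of cancer-history groups
#' (1..4, see [history_group_analysis()]), the second group of each
#' pair being the positive class.
#'
#' @param mat A log2 [expr_matrix()].
#' @param annotation Sample annotation with `sample_id` and `group`.
#' @param pairs List of length-2 integer vectors of group labels.
#' @param config A [classifier_config()].
#' @return A list of class `pairwise_gbt`: `summary` (one row per pair:
#'   sizes, best signature size, accuracy and AUC in percent, signature)
#'   and `reports` (the underlying `gbt_report`s).
#' @export
pairwise_group_classification <- function(mat, annotation,
                                          pairs = list(c(1L, 2L), c(3L, 4L),
                                                       c(1L, 4L), c(3L, 2L)),
                                          config = classifier_config()) {
  ann <- annotation[match(colnames(mat), annotation$sample_id), ]
  reports <- list()
  rows <- list()
  for (pr in pairs) {
    if (length(pr) != 2L || !all(pr %in% 1:4))
      stop("each pair must contain two group labels in 1..4", call. = FALSE)
    sel <- ann$group %in% pr
    if (sum(ann$group == pr[1]) == 0L || sum(ann$group == pr[2]) == 0L)
      stop("empty group in pair ", paste(pr, collapse = "-"), call. = FALSE)
    labels <- factor(ann$group[sel], levels = pr)
    rep_k <- cv_gbt(mat[, sel], labels, config = config)
    key <- paste(pr, collapse = "-")
    reports[[key]] <- rep_k
    rows[[key]] <- data.frame(
      pair = key, n1 = sum(labels == pr[1]), n2 = sum(labels == pr[2]),
      k = rep_k$best$k, accuracy = rep_k$accuracy, auc = rep_k$auc,
      signature = paste(rep_k$signature, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, reports = reports),
            class = "pairwise_gbt")
}

#' @export
print.pairwise_gbt <- function(x, ...) {
  cat("<pairwise_gbt>\n")
  print(x$summary[, c("pair", "n1", "n2", "k", "accuracy", "auc")])
  invisible(x)
}
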
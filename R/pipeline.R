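#' Configure an end-to-end pipeline run
#'
#' Collects the file paths, per-stage options and the single global seed
#' for [run_pipeline()]. Stage seeds are derived deterministically from
#' the global seed, so a whole run is reproducible bit for bit.
#'
#' @param expression Path to the probe-level expression TSV.
#' @param annotation Path to the sample annotation CSV/TSV.
#' @param gmt Optional path to a GMT category file; enrichment runs only
#'   when given.
#' @param out_dir Output directory for the result tables and manifest.
#' @param seed Integer seed propagated to every stochastic stage.
#' @param stages Which stages to run (in pipeline order); `"enrich"`
#'   requires `gmt`, and later stages always build on the normalization
#'   output.
#' @param background,floor,log_after_normalize Normalization options,
#'   see [normalize_expression()].
#' @param var_equal,exact_limit Test options, see [run_diffexp()].
#' @param ranking,convention Enrichment options, see
#'   [enrich_cutoff_free()].
#' @param classifier A [classifier_config()] (its seed is overridden by
#'   the pipeline seed).
#' @param power_alpha,power_target Power-calculation options.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, annotation, gmt = NULL,
                            out_dir = tempfile("mirprospect-run-"),
                            seed = 1L,
                            stages = c("normalize", "diffexp", "enrich",
                                       "confound", "classify", "power"),
                            background = 0, floor = 1,
                            log_after_normalize = TRUE,
                            var_equal = FALSE, exact_limit = 50L,
                            ranking = "auc", convention = "geq",
                            classifier = classifier_config(),
                            power_alpha = 0.05, power_target = 0.95) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(expression = expression, annotation = annotation, gmt = gmt,
              out_dir = out_dir, seed = as.integer(seed), stages = stages,
              background = background, floor = floor,
              log_after_normalize = log_after_normalize,
              var_equal = var_equal, exact_limit = as.integer(exact_limit),
              ranking = ranking, convention = convention,
              classifier = classifier,
              power_alpha = power_alpha, power_target = power_target)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv_out <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full biomarker discovery pipeline
#'
#' Executes, in order and as requested: normalization (background
#' subtraction, replicate collapsing, quantile normalization, log2),
#' two-cohort differential expression with both test families,
#' cutoff-free and set-based category enrichment, confounder screens
#' (age and pack-years correlations, gender and smoking ANOVA, cohort
#' balance tests, four-group history analysis), cross-validated
#' gradient-boosted-tree signature selection, and the design power
#' calculation at the observed cohort sizes. Result tables are written
#' as TSV into the output directory together with a `manifest.json`
#' recording package version, seed and a configuration hash; outputs of
#' an aborted run keep a `.partial` suffix.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `mirna_pipeline` holding each stage's result
#'   object and the written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  for (p in c(cf$expression, cf$annotation, cf$gmt)) {
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  }
  if ("enrich" %in% cf$stages && is.null(cf$gmt))
    stop("enrichment requested but no GMT path configured", call. = FALSE)
  if (!dir.exists(cf$out_dir))
    dir.create(cf$out_dir, recursive = TRUE)

  partial <- function(name) file.path(cf$out_dir, paste0(name, ".partial"))
  written <- character(0)
  emit <- function(df, name) {
    p <- write_tsv_out(df, partial(name))
    written <<- c(written, p)
    invisible(p)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list(config = cf)

  raw <- stage("read", {
    ann <- read_annotation(cf$annotation)
    mat <- read_expression_tsv(cf$expression)
    extra <- setdiff(colnames(mat), ann$sample_id)
    if (length(extra) > 0)
      stop("samples missing from annotation: ",
           paste(utils::head(extra, 5), collapse = ", "))
    list(mat = mat, ann = ann[match(colnames(mat), ann$sample_id), ])
  })
  ann <- raw$ann

  log2_mat <- stage("normalize", normalize_expression(
    raw$mat, background = cf$background, floor = cf$floor,
    log_after_normalize = cf$log_after_normalize))
  results$normalized <- log2_mat

  split <- cohort_split_from_annotation(ann)
  de <- NULL
  if ("diffexp" %in% cf$stages) {
    de <- stage("diffexp", run_diffexp(log2_mat, split,
                                       var_equal = cf$var_equal,
                                       exact_limit = cf$exact_limit))
    results$diffexp <- de
    emit(as.data.frame(de), "diffexp.tsv")
    emit(volcano_data(de), "volcano_cohorts.tsv")
  }

  if ("enrich" %in% cf$stages) {
    cats <- stage("enrich", read_gmt(cf$gmt))
    if (is.null(de))
      stop("pipeline stage 'enrich' failed: enrichment needs the diffexp stage",
           call. = FALSE)
    er <- stage("enrich", enrich_cutoff_free(de, cats,
                                             ranking = cf$ranking,
                                             convention = cf$convention))
    results$enrichment_rank <- er
    emit(as.data.frame(er), "enrichment_rank.tsv")
    sig <- de$mirna_id[de$q_t < 0.05]
    es <- stage("enrich", enrich_set_based(sig, de$mirna_id, cats))
    results$enrichment_set <- es
    emit(es, "enrichment_set.tsv")
  }

  if ("confound" %in% cf$stages) {
    conf <- stage("confound", {
      screens <- rbind(
        cbind(screen = "age", correlation_screen(log2_mat, ann$age)),
        cbind(screen = "packyears",
              correlation_screen(log2_mat, ann$packyears)))
      anovas <- rbind(
        cbind(screen = "gender", anova_screen(log2_mat, ann$gender)),
        cbind(screen = "smoking", anova_screen(log2_mat, ann$smoking)))
      list(correlations = screens, anovas = anovas,
           balance = cohort_balance_tests(ann),
           history = history_group_analysis(log2_mat, ann,
                                            var_equal = cf$var_equal,
                                            exact_limit = cf$exact_limit))
    })
    results$confound <- conf
    emit(conf$correlations, "confounder_correlations.tsv")
    emit(conf$anovas, "confounder_anova.tsv")
    emit(conf$balance, "cohort_balance.tsv")
    if (!is.null(conf$history$anova))
      emit(conf$history$anova, "history_anova.tsv")
    if (!is.null(conf$history$extreme))
      emit(volcano_data(conf$history$extreme), "volcano_extreme_groups.tsv")
  }

  if ("classify" %in% cf$stages) {
    clf_cfg <- cf$classifier
    clf_cfg$seed <- cf$seed
    clf <- stage("classify", cv_gbt(log2_mat,
                                    factor(ann$cohort,
                                           levels = c("control", "case")),
                                    config = clf_cfg))
    results$classifier <- clf
    emit(clf$grid, "classification_grid.tsv")
    emit(data.frame(k = clf$best$k, leaves = clf$best$leaves,
                    trees = clf$best$trees, accuracy = clf$accuracy,
                    auc = clf$auc,
                    signature = paste(clf$signature, collapse = ";")),
         "classification.tsv")
  }

  if ("power" %in% cf$stages) {
    pw <- stage("power", solve_effect_size(split$n2, split$n1,
                                           alpha = cf$power_alpha,
                                           power = cf$power_target))
    results$power <- pw
    emit(data.frame(n_cases = split$n2, n_controls = split$n1,
                    alpha = cf$power_alpha, power = cf$power_target,
                    effect_size_d = pw$d), "power.tsv")
  }

  manifest <- list(
    package = "mirprospect",
    version = as.character(utils::packageVersion("mirprospect")),
    seed = cf$seed,
    stages = cf$stages,
    config_hash = config_hash(cf),
    n_samples = ncol(log2_mat), n_mirnas = nrow(log2_mat))
  mpath <- file.path(cf$out_dir, "manifest.json.partial")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, mpath)

  # all stages succeeded: drop the .partial suffixes
  final <- sub("\\.partial$", "", written)
  ok <- file.rename(written, final)
  if (!all(ok)) stop("could not finalize output files", call. = FALSE)
  results$files <- final
  class(results) <- "mirna_pipeline"
  results
}

# md5 of the serialized configuration (environment-independent fields only)
config_hash <- function(cf) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  plain <- cf
  plain$out_dir <- NULL
  saveRDS(plain, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' @export
print.mirna_pipeline <- function(x, ...) {
  cat("<mirna_pipeline> completed stages:",
      paste(x$config$stages, collapse = ", "), "\n")
  cat("  outputs in:", dirname(x$files[1]), "\n")
  for (f in basename(x$files)) cat("   -", f, "\n")
  invisible(x)
}
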
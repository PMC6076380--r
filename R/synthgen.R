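#' Configuration for the synthetic cohort generator
#'
#' Describes a prospective matched case-control cohort profiled on a
#' replicated microarray: a large control group and a small group of
#' patients who later develop cancer, with a minority of miRNAs carrying
#' planted expression differences, mostly down-regulated in cases.
#' Defaults reproduce the structure of the motivating study: 2549 mature
#' miRNAs measured on 534 COPD patients (33 future cancer cases vs 501
#' matched controls), and roughly 74% of planted effects pointing down
#' in cases.
#'
#' @param n_mirnas Number of miRNAs on the array.
#' @param n_cases Number of patients who later develop cancer (cohort 2).
#' @param n_controls Number of matched controls (cohort 1).
#' @param frac_de Fraction of miRNAs with a planted case/control effect.
#' @param effect_size_d Standardized mean difference (Cohen's d) of each
#'   planted effect on the log2 scale, in units of that miRNA's log2 SD.
#' @param frac_down Fraction of planted effects that are down-regulated
#'   in cases (negative sign).
#' @param n_replicates_per_probe Replicate probes per miRNA on the array.
#' @param background_level Additive nonnegative background intensity on
#'   the linear scale.
#' @param seed Integer RNG seed; the full dataset is a deterministic
#'   function of the configuration.
#' @param history_group_probs Probabilities of the four cancer-history
#'   groups (1 = no history/no cancer, 2 = no history/developed cancer,
#'   3 = history/no cancer, 4 = history/developed cancer); must sum to 1.
#'   Group membership is drawn conditionally on the fixed cohort sizes.
#' @param log2_mean_range,log2_sd_range Ranges for per-miRNA baseline
#'   log2 mean and log2 SD (drawn uniformly).
#' @param replicate_sd Log2-scale SD of replicate probe noise around the
#'   latent sample value.
#' @param age_mean,age_sd,packyears_mean,packyears_sd,p_female,smoking_probs
#'   Covariate distributions, drawn identically in both cohorts
#'   (matched design). Defaults follow the pooled cohort description of
#'   the motivating study.
#' @param n_age_coupled Number of miRNAs whose expression is coupled to
#'   age (0 by default; the matched design assumes no coupling).
#' @param age_slope Log2 expression change per year for age-coupled
#'   miRNAs.
#' @param n_smoking_coupled Number of miRNAs shifted in present smokers.
#' @param smoking_shift Log2 shift applied to present smokers for
#'   smoking-coupled miRNAs.
#' @param n_group3_coupled Number of miRNAs with an additional shift
#'   specific to history group 3 (prior cancer, no new cancer), useful
#'   for exercising the four-group history analysis.
#' @param group3_shift Log2 shift for group-3-coupled miRNAs.
#' @param n_categories Number of category sets to emit; the first is a
#'   "signal" set enriched for planted miRNAs, the rest are random.
#' @param category_size Number of members per category set.
#' @param signal_hit_prob Probability that each planted miRNA is included
#'   in the signal category.
#' @return A validated list of class `synth_config`.
#' @seealso [simulate_cohort()]
#' @export
synth_config <- function(n_mirnas = 2549L,
                         n_cases = 33L,
                         n_controls = 501L,
                         frac_de = 0.01,
                         effect_size_d = 1.5,
                         frac_down = 199 / 269,
                         n_replicates_per_probe = 3L,
                         background_level = 0,
                         seed = 1L,
                         history_group_probs = c(0.797, 0.053, 0.141, 0.009),
                         log2_mean_range = c(4, 14),
                         log2_sd_range = c(0.5, 1.5),
                         replicate_sd = 0.25,
                         age_mean = 67, age_sd = 7.7,
                         packyears_mean = 48, packyears_sd = 37,
                         p_female = 0.35,
                         smoking_probs = c(never = 0.041, past = 0.723,
                                           present = 0.236),
                         n_age_coupled = 0L, age_slope = 0.02,
                         n_smoking_coupled = 0L, smoking_shift = 0.5,
                         n_group3_coupled = 0L, group3_shift = -1,
                         n_categories = 10L, category_size = 30L,
                         signal_hit_prob = 0.6) {
  chk_count <- function(x, nm, min = 1L) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
      stop(sprintf("invalid configuration field '%s': must be an integer >= %d",
                   nm, min), call. = FALSE)
    as.integer(x)
  }
  chk_frac <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("invalid configuration field '%s': must be in [0, 1]", nm),
           call. = FALSE)
    x
  }
  cfg <- list(
    n_mirnas = chk_count(n_mirnas, "n_mirnas"),
    n_cases = chk_count(n_cases, "n_cases"),
    n_controls = chk_count(n_controls, "n_controls"),
    frac_de = chk_frac(frac_de, "frac_de"),
    effect_size_d = effect_size_d,
    frac_down = chk_frac(frac_down, "frac_down"),
    n_replicates_per_probe = chk_count(n_replicates_per_probe,
                                       "n_replicates_per_probe"),
    background_level = background_level,
    seed = chk_count(seed, "seed", min = 0L),
    history_group_probs = history_group_probs,
    log2_mean_range = log2_mean_range,
    log2_sd_range = log2_sd_range,
    replicate_sd = replicate_sd,
    age_mean = age_mean, age_sd = age_sd,
    packyears_mean = packyears_mean, packyears_sd = packyears_sd,
    p_female = chk_frac(p_female, "p_female"),
    smoking_probs = smoking_probs,
    n_age_coupled = chk_count(n_age_coupled, "n_age_coupled", min = 0L),
    age_slope = age_slope,
    n_smoking_coupled = chk_count(n_smoking_coupled, "n_smoking_coupled",
                                  min = 0L),
    smoking_shift = smoking_shift,
    n_group3_coupled = chk_count(n_group3_coupled, "n_group3_coupled",
                                 min = 0L),
    group3_shift = group3_shift,
    n_categories = chk_count(n_categories, "n_categories", min = 0L),
    category_size = chk_count(category_size, "category_size"),
    signal_hit_prob = chk_frac(signal_hit_prob, "signal_hit_prob")
  )
  if (cfg$n_cases + cfg$n_controls < 4L)
    stop("invalid configuration field 'n_cases'/'n_controls': total cohort size must be >= 4",
         call. = FALSE)
  if (length(history_group_probs) != 4L || any(!is.finite(history_group_probs)) ||
      any(history_group_probs < 0) || abs(sum(history_group_probs) - 1) > 1e-9)
    stop("invalid configuration field 'history_group_probs': must be 4 nonnegative values summing to 1",
         call. = FALSE)
  if (length(background_level) != 1L || !is.finite(background_level) ||
      background_level < 0)
    stop("invalid configuration field 'background_level': must be a nonnegative scalar",
         call. = FALSE)
  if (!is.finite(effect_size_d))
    stop("invalid configuration field 'effect_size_d'", call. = FALSE)
  if (abs(sum(smoking_probs) - 1) > 1e-9 || length(smoking_probs) != 3L)
    stop("invalid configuration field 'smoking_probs': must be 3 probabilities summing to 1",
         call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate a prospective matched case-control miRNA cohort
#'
#' Draws a raw replicated probe-level expression matrix, a sample
#' annotation table, a ground-truth table of planted effects, and a
#' small collection of category sets (one enriched for the planted
#' miRNAs, the others random). Intensities are log-normal: each miRNA
#' has a latent per-sample log2 value drawn from a Gaussian whose mean
#' differs between cases and controls by `effect_size_d` log2 SDs for
#' planted miRNAs (signed, mostly down in cases); replicate probes are
#' noisy copies of the latent value on the linear scale plus a constant
#' background. Covariates are drawn identically in both cohorts,
#' emulating a matched design, unless coupling is configured.
#'
#' The result is a deterministic function of the configuration: the same
#' `seed` reproduces the dataset bit for bit.
#'
#' @param config A [synth_config()].
#' @return An object of class `cohort_sim`: a list with elements
#'   `expression` (raw [expr_matrix()] with replicate probe rows),
#'   `annotation` (data frame of per-sample covariates), `truth`
#'   (data frame `mirna_id`, `signed_d` of planted effects),
#'   `categories` (named list of miRNA id vectors), `coupled` (ids of
#'   covariate-coupled miRNAs, per covariate) and `config`.
#' @examples
#' sim <- simulate_cohort(synth_config(n_mirnas = 50, n_cases = 5,
#'                                     n_controls = 20, seed = 7))
#' sim$expression
#' head(sim$truth)
#' @export
simulate_cohort <- function(config = synth_config()) {
  if (!inherits(config, "synth_config"))
    stop("'config' must be created by synth_config()", call. = FALSE)
  cf <- config
  set.seed(cf$seed)

  mir_ids <- sprintf("syn-miR-%04d", seq_len(cf$n_mirnas))
  n <- cf$n_cases + cf$n_controls
  sample_ids <- sprintf("sample-%04d", seq_len(n))
  cohort <- c(rep("control", cf$n_controls), rep("case", cf$n_cases))

  # cancer-history flag, conditional on the (fixed) cohort assignment
  p <- cf$history_group_probs
  p_hist_control <- if (p[1] + p[3] > 0) p[3] / (p[1] + p[3]) else 0
  p_hist_case <- if (p[2] + p[4] > 0) p[4] / (p[2] + p[4]) else 0
  history <- ifelse(cohort == "control",
                    stats::rbinom(n, 1L, p_hist_control),
                    stats::rbinom(n, 1L, p_hist_case))
  group <- ifelse(cohort == "control", ifelse(history == 0L, 1L, 3L),
                  ifelse(history == 0L, 2L, 4L))

  age <- stats::rnorm(n, cf$age_mean, cf$age_sd)
  gender <- ifelse(stats::runif(n) < cf$p_female, "f", "m")
  smoking <- sample(c("never", "past", "present"), n, replace = TRUE,
                    prob = cf$smoking_probs)
  packyears <- pmax(stats::rnorm(n, cf$packyears_mean, cf$packyears_sd), 0)
  annotation <- data.frame(sample_id = sample_ids, cohort = cohort,
                           history = as.integer(history),
                           group = as.integer(group),
                           age = age, gender = gender, smoking = smoking,
                           packyears = packyears,
                           stringsAsFactors = FALSE)

  mu <- stats::runif(cf$n_mirnas, cf$log2_mean_range[1], cf$log2_mean_range[2])
  sdv <- stats::runif(cf$n_mirnas, cf$log2_sd_range[1], cf$log2_sd_range[2])

  n_de <- round(cf$frac_de * cf$n_mirnas)
  de_idx <- if (n_de > 0) sort(sample.int(cf$n_mirnas, n_de)) else integer(0)
  n_down <- round(cf$frac_down * n_de)
  sign_vec <- rep(1, n_de)
  if (n_down > 0) sign_vec[sample.int(n_de, n_down)] <- -1
  signed_d <- sign_vec * cf$effect_size_d
  truth <- data.frame(mirna_id = mir_ids[de_idx], signed_d = signed_d,
                      stringsAsFactors = FALSE)

  # latent log2 values: baseline + planted case shift + optional couplings
  latent <- matrix(stats::rnorm(cf$n_mirnas * n, 0, 1), cf$n_mirnas, n)
  latent <- latent * sdv + mu
  if (n_de > 0) {
    is_case <- cohort == "case"
    latent[de_idx, is_case] <- latent[de_idx, is_case] +
      signed_d * sdv[de_idx]
  }
  coupled <- list(age = character(0), smoking = character(0),
                  group3 = character(0))
  if (cf$n_age_coupled > 0) {
    idx <- sample.int(cf$n_mirnas, min(cf$n_age_coupled, cf$n_mirnas))
    latent[idx, ] <- latent[idx, ] +
      outer(rep(cf$age_slope, length(idx)), age - cf$age_mean)
    coupled$age <- mir_ids[idx]
  }
  if (cf$n_smoking_coupled > 0) {
    idx <- sample.int(cf$n_mirnas, min(cf$n_smoking_coupled, cf$n_mirnas))
    latent[idx, smoking == "present"] <- latent[idx, smoking == "present"] +
      cf$smoking_shift
    coupled$smoking <- mir_ids[idx]
  }
  if (cf$n_group3_coupled > 0) {
    idx <- sample.int(cf$n_mirnas, min(cf$n_group3_coupled, cf$n_mirnas))
    latent[idx, group == 3L] <- latent[idx, group == 3L] + cf$group3_shift
    coupled$group3 <- mir_ids[idx]
  }

  # replicate probes: noisy copies on the linear scale plus background
  r <- cf$n_replicates_per_probe
  probe_rows <- rep(seq_len(cf$n_mirnas), each = r)
  noise <- matrix(stats::rnorm(cf$n_mirnas * r * n, 0, cf$replicate_sd),
                  cf$n_mirnas * r, n)
  raw <- 2^(latent[probe_rows, , drop = FALSE] + noise) + cf$background_level
  rownames(raw) <- sprintf("%s_p%d", mir_ids[probe_rows],
                           rep(seq_len(r), times = cf$n_mirnas))
  colnames(raw) <- sample_ids
  expression <- expr_matrix(raw, state = "raw",
                            probe_group = mir_ids[probe_rows])

  categories <- list()
  if (cf$n_categories > 0) {
    size <- min(cf$category_size, cf$n_mirnas - 1L)
    planted <- truth$mirna_id
    hit <- planted[stats::runif(length(planted)) < cf$signal_hit_prob]
    filler <- sample(setdiff(mir_ids, hit), max(size - length(hit), 0L))
    categories$planted_signal <- sort(c(hit, filler))
    if (cf$n_categories > 1) {
      for (k in seq_len(cf$n_categories - 1L)) {
        categories[[sprintf("random_%02d", k)]] <- sort(sample(mir_ids, size))
      }
    }
  }

  structure(list(expression = expression, annotation = annotation,
                 truth = truth, categories = categories,
                 coupled = coupled, config = cf),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cf <- x$config
  cat(sprintf(paste0("<cohort_sim> %d miRNAs x %d samples ",
                     "(%d cases, %d controls), %d replicate probes/miRNA\n"),
              cf$n_mirnas, cf$n_cases + cf$n_controls, cf$n_cases,
              cf$n_controls, cf$n_replicates_per_probe))
  cat(sprintf("  planted effects: %d (d = %.2g, %.0f%% down-regulated in cases)\n",
              nrow(x$truth), cf$effect_size_d, 100 * cf$frac_down))
  cat(sprintf("  categories: %d, seed: %d\n", length(x$categories), cf$seed))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the four files the pipeline readers consume: `expression.tsv`
#' (probe-level, columns `miRNA`, `probe_group`, then one column per
#' sample), `annotation.csv`, `categories.gmt` (standard tab-separated
#' gene-set format) and `truth.tsv` (`mirna_id`, `signed_d`). The files
#' round-trip losslessly through [read_expression_tsv()],
#' [read_annotation()], [read_gmt()] and [read_truth()].
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.csv"),
             categories = file.path(dir, "categories.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_tsv(sim$expression, paths["expression"])
  write_annotation(sim$annotation, paths["annotation"])
  write_gmt(sim$categories, paths["categories"])
  write_truth(sim$truth, paths["truth"])
  invisible(paths)
}
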
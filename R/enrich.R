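#' Running-sum statistic of a category over a ranked miRNA list
#'
#' Walks a ranked universe of m miRNAs from top to bottom keeping a
#' running sum that increases by (m - l) whenever a member of the
#' category (of in-universe size l) is encountered and decreases by l
#' otherwise. The sum always terminates at exactly 0; the statistic is
#' the maximum over all m prefixes, large when category members
#' concentrate near the top of the ranking.
#'
#' @param ranked Character vector of miRNA ids in descending order of
#'   the ranking criterion (no duplicates, length >= 2).
#' @param members Character vector of category member ids; members
#'   absent from the universe are dropped before computing l.
#' @return A list with `observed_max`, `trace` (length-m running sum),
#'   `l`, `m`, and `hits` (logical membership indicator along the
#'   ranking).
#' @seealso [exact_running_sum_p()]
#' @export
running_sum <- function(ranked, members) {
  ranked <- as.character(ranked)
  if (anyDuplicated(ranked)) stop("ranked universe has duplicate ids",
                                  call. = FALSE)
  m <- length(ranked)
  if (m < 2L) stop("universe must contain at least 2 miRNAs", call. = FALSE)
  hits <- ranked %in% members
  l <- sum(hits)
  if (l == 0L || l == m)
    stop("degenerate category (l = 0 or l = m); statistic undefined",
         call. = FALSE)
  trace <- cumsum(ifelse(hits, m - l, -l))
  list(observed_max = max(trace), trace = trace, l = l, m = m, hits = hits)
}

# log(exp(a) + exp(b)), elementwise, tolerating -Inf
logspace_add <- function(a, b) {
  mx <- pmax(a, b)
  out <- mx + log1p(exp(pmin(a, b) - mx))
  out[mx == -Inf] <- -Inf
  out
}

# is observed_max attainable as a prefix value j*m - i*l for some valid
# prefix (i positions, j hits)?
max_attainable <- function(m, l, B) {
  for (j in seq_len(l)) {
    num <- j * m - B
    if (num %% l == 0) {
      i <- num %/% l
      if (i >= j && i - j <= m - l && i <= m) return(TRUE)
    }
  }
  FALSE
}

#' Exact p-value of the running-sum maximum
#'
#' Probability, over all `choose(m, l)` equally likely arrangements of l
#' category hits among m ranks, that the maximum prefix of the running
#' sum reaches the observed value. Computed exactly by dynamic
#' programming: arrangements whose every prefix stays below the observed
#' maximum are counted over the (position, hits-so-far) lattice — the
#' prefix sum at position i with j hits is j*m - i*l, so the constraint
#' depends only on the lattice cell — and the complement is taken.
#' Counting is done in log space, so the computation does not overflow
#' even for `m` in the thousands where `choose(m, l)` vastly exceeds
#' floating-point range.
#'
#' With the default `convention = "geq"` the count includes arrangements
#' attaining the observed maximum, so the p-value is a valid permutation
#' p (never 0, minimum `1/choose(m, l)`). `convention = "gt"` counts
#' strict exceedances only.
#'
#' @param m Universe size.
#' @param l In-universe category size, `1 <= l <= m - 1`.
#' @param observed_max Observed maximum of the running sum.
#' @param convention Count arrangements with maximum `>=` (default) or
#'   `>` the observed value.
#' @return The exact p-value.
#' @examples
#' exact_running_sum_p(4, 2, 4)  # 1/6
#' exact_running_sum_p(4, 2, 0)  # 1: the final prefix is always 0
#' @export
exact_running_sum_p <- function(m, l, observed_max,
                                convention = c("geq", "gt")) {
  convention <- match.arg(convention)
  if (l < 1L || l > m - 1L)
    stop("'l' must satisfy 1 <= l <= m - 1", call. = FALSE)
  B <- observed_max
  if (B > l * (m - l))
    stop("observed_max exceeds the attainable maximum l*(m - l)",
         call. = FALSE)
  if (B > 0 && !max_attainable(m, l, B))
    stop("observed_max is not attainable on the running-sum lattice",
         call. = FALSE)
  # P(max >= B) is 1 for B <= 0 since the final prefix is always 0
  if (convention == "geq" && B <= 0) return(1)
  if (convention == "gt" && B < 0) return(1)

  # count arrangements whose every prefix sum stays below the bound:
  # "geq": all prefixes < B;  "gt": all prefixes <= B
  lc <- lchoose(m, l)
  j <- 0:l
  f <- c(0, rep(-Inf, l))           # log counts at i = 0
  for (i in seq_len(m)) {
    f <- logspace_add(f, c(-Inf, f[seq_len(l)]))
    s <- j * m - i * l
    bad <- if (convention == "geq") s >= B else s > B
    f[bad] <- -Inf
  }
  p <- -expm1(f[l + 1L] - lc)
  min(max(p, 0), 1)
}

#' Cutoff-free running-sum enrichment over a category collection
#'
#' Ranks the measured universe by a stated criterion (per-miRNA ROC-AUC
#' descending by default, i.e., most over-expressed in cases first) and
#' tests every category for concentration of its members toward the top
#' of the ranking, using the running-sum maximum with its exact
#' dynamic-programming p-value. Categories whose in-universe size is 0
#' or m are skipped with a warning. Raw p-values and Benjamini-Hochberg
#' adjusted q-values across the tested categories are both reported.
#' Depletion (concentration at the bottom) can be tested by reversing
#' the ranking.
#'
#' @param x A [run_diffexp()] result, or a pre-ranked character vector
#'   of miRNA ids (descending).
#' @param categories Named list of category member vectors, e.g. from
#'   [read_gmt()].
#' @param ranking Ranking criterion when `x` is a diffexp table:
#'   `"auc"` (descending per-miRNA AUC) or `"signed_logp"` (descending
#'   signed -log10 raw t-test p, sign from the t statistic).
#' @param convention Passed to [exact_running_sum_p()].
#' @return A data frame of class `mirna_enrichment` with columns
#'   `category`, `l`, `observed_max`, `p`, `q`, ordered by `p`.
#' @export
enrich_cutoff_free <- function(x, categories,
                               ranking = c("auc", "signed_logp"),
                               convention = c("geq", "gt")) {
  ranking <- match.arg(ranking)
  convention <- match.arg(convention)
  if (length(categories) == 0L)
    stop("empty category collection", call. = FALSE)
  if (is.null(names(categories)) || any(names(categories) == ""))
    stop("categories must be named", call. = FALSE)
  ranked <- if (inherits(x, "mirna_diffexp")) {
    score <- if (ranking == "auc") x$auc else
      sign(x$t_stat) * -log10(pmax(x$p_t, .Machine$double.xmin))
    x$mirna_id[order(-score, x$mirna_id)]
  } else {
    ranking <- "pre-ranked"
    as.character(x)
  }
  m <- length(ranked)

  memo <- new.env(parent = emptyenv())
  rows <- lapply(names(categories), function(nm) {
    hits <- ranked %in% categories[[nm]]
    l <- sum(hits)
    if (l == 0L || l == m) {
      warning(sprintf("category '%s' skipped: degenerate in-universe size %d",
                      nm, l), call. = FALSE)
      return(NULL)
    }
    B <- max(cumsum(ifelse(hits, m - l, -l)))
    key <- paste(l, B, sep = ":")
    p <- if (exists(key, envir = memo, inherits = FALSE)) {
      get(key, envir = memo)
    } else {
      pv <- exact_running_sum_p(m, l, B, convention = convention)
      assign(key, pv, envir = memo)
      pv
    }
    data.frame(category = nm, l = l, observed_max = B, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no testable category (all degenerate)", call. = FALSE)
  res <- do.call(rbind, rows)
  res$q <- benjamini_hochberg(res$p)
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  structure(res, m = m, ranking = ranking, convention = convention,
            class = c("mirna_enrichment", "data.frame"))
}

#' @export
print.mirna_enrichment <- function(x, ...) {
  cat(sprintf("<mirna_enrichment> %d categories over a universe of %d miRNAs (ranking: %s)\n",
              nrow(x), attr(x, "m"), attr(x, "ranking")))
  cat(sprintf("  raw p < 0.05: %d; BH q < 0.05: %d\n",
              sum(x$p < 0.05), sum(x$q < 0.05)))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Set-based hypergeometric category enrichment
#'
#' Upper-tail hypergeometric test for over-representation of a
#' significant miRNA set within each category, against the measured
#' universe. The complement of the running-sum analysis: only the hard
#' significant/not-significant split enters, not the full ranking.
#'
#' @param significant Character vector of significant miRNA ids (must be
#'   a subset of `universe`).
#' @param universe Character vector of all measured miRNA ids.
#' @param categories Named list of category member vectors; members
#'   outside the universe are dropped.
#' @return Data frame with `category`, `l` (in-universe category size),
#'   `overlap`, `p` (upper-tail hypergeometric), `q` (BH across
#'   categories), ordered by `p`.
#' @export
enrich_set_based <- function(significant, universe, categories) {
  universe <- as.character(universe)
  significant <- as.character(significant)
  if (anyDuplicated(universe)) stop("universe has duplicate ids",
                                    call. = FALSE)
  extra <- setdiff(significant, universe)
  if (length(extra) > 0)
    stop("significant ids not in universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  if (length(significant) == 0L)
    warning("empty significant set; all p-values are 1", call. = FALSE)
  m <- length(universe)
  k <- length(significant)
  res <- do.call(rbind, lapply(names(categories), function(nm) {
    memb <- intersect(categories[[nm]], universe)
    l <- length(memb)
    ov <- length(intersect(memb, significant))
    p <- if (k == 0L || l == 0L) 1 else
      stats::phyper(ov - 1L, l, m - l, k, lower.tail = FALSE)
    data.frame(category = nm, l = l, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- benjamini_hochberg(res$p)
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}
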
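#' Expression matrix with an explicit processing state
#'
#' A thin wrapper around a numeric matrix (rows = probes or miRNAs,
#' columns = samples) that records where the values sit in the
#' preprocessing chain: `"raw"` probe-level intensities, `"collapsed"`
#' per-miRNA medians, `"normalized"` quantile-normalized intensities, or
#' `"log2"` log2 intensities. Raw matrices additionally carry a
#' `probe_group` vector mapping each replicate probe row to the miRNA it
#' collapses to.
#'
#' @param values Numeric matrix with unique row names (probe or miRNA
#'   identifiers) and unique column names (sample identifiers).
#' @param state Processing state, one of `"raw"`, `"collapsed"`,
#'   `"normalized"`, `"log2"`.
#' @param probe_group Character vector of length `nrow(values)` naming,
#'   for each probe row, the miRNA it belongs to. Required to collapse
#'   replicates; usually only present in `"raw"` matrices.
#' @return An object of class `expr_matrix` (a numeric matrix with
#'   `state` and optional `probe_group` attributes).
#' @examples
#' m <- matrix(2^rnorm(12, 8), 4, 3,
#'             dimnames = list(paste0("miR-", 1:4), paste0("s", 1:3)))
#' em <- expr_matrix(m, state = "collapsed")
#' expr_state(em)
#' @export
expr_matrix <- function(values,
                        state = c("raw", "collapsed", "normalized", "log2"),
                        probe_group = NULL) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row names (features) and column names (samples)",
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated row identifiers: ",
         paste(utils::head(unique(rownames(values)[duplicated(rownames(values))]), 5),
               collapse = ", "), call. = FALSE)
  if (!is.null(probe_group)) {
    if (length(probe_group) != nrow(values))
      stop("'probe_group' must have one entry per row", call. = FALSE)
    if (anyNA(probe_group))
      stop("'probe_group' contains missing values", call. = FALSE)
    probe_group <- as.character(probe_group)
    names(probe_group) <- rownames(values)
  }
  structure(values, state = state, probe_group = probe_group,
            class = c("expr_matrix", class(values)))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
expr_state <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  attr(x, "state")
}

#' @rdname expr_matrix
#' @export
probe_groups <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  attr(x, "probe_group")
}

# strip class and bookkeeping attributes, returning the bare matrix
expr_values <- function(x) {
  v <- unclass(x)
  attr(v, "state") <- NULL
  attr(v, "probe_group") <- NULL
  v
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  v <- expr_values(x)
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  pg <- attr(x, "probe_group")
  expr_matrix(v[i, j, drop = FALSE], state = attr(x, "state"),
              probe_group = if (!is.null(pg)) pg[i])
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, state: %s\n",
              nrow(x), ncol(x), attr(x, "state")))
  if (!is.null(attr(x, "probe_group")))
    cat(sprintf("  %d probe rows mapping to %d miRNAs\n",
                nrow(x), length(unique(attr(x, "probe_group")))))
  v <- expr_values(x)
  print(v[seq_len(min(5, nrow(v))), seq_len(min(5, ncol(v))), drop = FALSE])
  if (nrow(v) > 5 || ncol(v) > 5) cat("  ...\n")
  invisible(x)
}
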
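#' Read and write the pipeline's plain-text file formats
#'
#' Expression matrices travel as tab-separated text with a first column
#' `miRNA` (probe id), a `probe_group` column naming the miRNA each
#' replicate probe collapses to, and one column per sample. Annotations
#' are CSV (or TSV) with the fixed columns `sample_id`, `cohort`
#' (`control`/`case`), `history` (0/1), `group` (1-4), `age`, `gender`
#' (`f`/`m`), `smoking` (`never`/`past`/`present`), `packyears`;
#' additional clinical columns pass through untouched. Category sets use
#' the standard GMT format (name, description, then members, all
#' tab-separated). All writers round-trip losslessly through the
#' corresponding readers.
#'
#' @param path File path.
#' @return `read_expression_tsv()` returns a raw [expr_matrix()];
#'   `read_annotation()` a data frame; `read_gmt()` a named list of
#'   member vectors (with a `descriptions` attribute); `read_truth()` a
#'   data frame with `mirna_id` and `signed_d`. Writers return the path
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("miRNA", "probe_group") %in% names(df)))
    stop("expression file must have 'miRNA' and 'probe_group' columns: ",
         path, call. = FALSE)
  sample_cols <- names(df)[!names(df) %in% c("miRNA", "probe_group")]
  dup <- unique(sample_cols[duplicated(sample_cols)])
  if (length(dup) > 0)
    stop("duplicated sample column(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$miRNA))
    stop("duplicated probe identifier(s) in ", path, ": ",
         paste(utils::head(unique(df$miRNA[duplicated(df$miRNA)]), 5),
               collapse = ", "), call. = FALSE)
  v <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(v))
    stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(v) <- df$miRNA
  expr_matrix(v, state = "raw", probe_group = df$probe_group)
}

#' @rdname pipeline_io
#' @param mat A raw [expr_matrix()] with probe groups.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "expr_matrix"))
  pg <- probe_groups(mat)
  if (is.null(pg)) pg <- rownames(mat)
  v <- expr_values(mat)
  df <- data.frame(miRNA = rownames(v), probe_group = unname(pg),
                   v, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

annotation_required_cols <- c("sample_id", "cohort", "history", "group",
                              "age", "gender", "smoking", "packyears")

#' @rdname pipeline_io
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(annotation_required_cols, names(df))
  if (length(missing_cols) > 0)
    stop("annotation file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id(s) in ", path, call. = FALSE)
  bad <- function(col, allowed)
    any(!is.na(df[[col]]) & !df[[col]] %in% allowed)
  if (bad("cohort", c("control", "case")))
    stop("annotation 'cohort' must be 'control' or 'case'", call. = FALSE)
  if (bad("gender", c("f", "m")))
    stop("annotation 'gender' must be 'f' or 'm'", call. = FALSE)
  if (bad("smoking", c("never", "past", "present")))
    stop("annotation 'smoking' must be never/past/present", call. = FALSE)
  if (bad("group", 1:4))
    stop("annotation 'group' must be in 1..4", call. = FALSE)
  df
}

#' @rdname pipeline_io
#' @param annotation Annotation data frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.csv(annotation, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("malformed GMT line %d in %s: %d field(s), need >= 3",
                 which(nf < 3L)[1], path, min(nf)), call. = FALSE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicated category name(s) in ", path, call. = FALSE)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' @rdname pipeline_io
#' @param sets Named list of member id vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @param truth Data frame with `mirna_id` and `signed_d`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
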
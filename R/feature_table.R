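#' Construct a feature table
#'
#' A feature table is a samples-by-taxa numeric matrix of non-negative values
#' with unique sample ids (rownames), unique taxonomy-string column labels and
#' a `space_tag` describing the value space: raw `counts`, `relative`
#' abundances (rows sum to 1), or `log_normalized` values produced by
#' [normalize_table()].
#'
#' @param values Numeric matrix, samples in rows, taxa in columns; rownames are
#'   sample ids and colnames taxonomy strings.
#' @param space_tag One of `"counts"`, `"relative"`, `"log_normalized"`.
#' @return A `feature_table` object.
#' @export
#' @examples
#' m <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("k__Bacteria;p__A", "k__Bacteria;p__B")))
#' feature_table(m, "relative")
feature_table <- function(values, space_tag = c("counts", "relative", "log_normalized")) {
  space_tag <- match.arg(space_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ft <- structure(values, space_tag = space_tag, class = c("feature_table", "matrix", "array"))
  validate_feature_table(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d taxa [%s]\n",
              nrow(x), ncol(x), space_tag(x)))
  invisible(x)
}

#' Value space of a feature table
#' @param ft A `feature_table`.
#' @return The space tag string.
#' @export
space_tag <- function(ft) attr(ft, "space_tag")

#' Validate a feature table
#'
#' Checks id/taxon uniqueness, non-negativity (counts/relative) and row-sum
#' closure (relative, tolerance 1e-6), and that every column label parses as a
#' taxonomy string.
#'
#' @param ft A `feature_table`.
#' @return `ft`, invisibly unchanged, or an error describing the violation.
#' @export
validate_feature_table <- function(ft) {
  if (is.null(rownames(ft)) || is.null(colnames(ft)))
    stop("feature table must have sample ids (rownames) and taxa (colnames)", call. = FALSE)
  dup <- rownames(ft)[duplicated(rownames(ft))]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  dup <- colnames(ft)[duplicated(colnames(ft))]
  if (length(dup))
    stop("duplicated taxa: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  tag <- space_tag(ft)
  if (tag %in% c("counts", "relative") && any(ft < 0))
    stop("negative values in ", tag, " feature table", call. = FALSE)
  if (identical(tag, "relative")) {
    rs <- rowSums(ft)
    off <- which(abs(rs - 1) > 1e-6)
    if (length(off))
      stop("relative rows not summing to 1: ", paste(rownames(ft)[off], collapse = ", "),
           call. = FALSE)
  }
  parse_taxonomy(colnames(ft))  # errors listing offending labels
  invisible(ft)
}

.subset_ft <- function(ft, i = NULL, j = NULL) {
  tag <- space_tag(ft)
  m <- unclass(ft)
  if (!is.null(i)) m <- m[i, , drop = FALSE]
  if (!is.null(j)) m <- m[, j, drop = FALSE]
  structure(m, space_tag = tag, class = c("feature_table", "matrix", "array"))
}

#' Close rows to relative abundance
#'
#' Divides each row by its total. Counts and relative tables are accepted;
#' log-normalized tables are rejected (closure is meaningless in log space).
#'
#' @param ft A `feature_table` in counts or relative space.
#' @return A `feature_table` with `space_tag = "relative"`.
#' @export
as_relative <- function(ft) {
  if (identical(space_tag(ft), "log_normalized"))
    stop("cannot close a log-normalized table to relative abundance", call. = FALSE)
  rs <- rowSums(ft)
  zero <- which(rs <= 0)
  if (length(zero))
    stop("all-zero sample row(s): ", paste(rownames(ft)[zero], collapse = ", "), call. = FALSE)
  feature_table(unclass(ft) / rs, "relative")
}

#' Read a feature table from disk
#'
#' Reads a TSV (samples in rows or taxa in rows) or a BIOM-JSON file into a
#' validated [feature_table()]. The value space is auto-detected from row sums:
#' rows all within 1e-6 of 1 are tagged `relative`, anything else `counts`.
#'
#' @param path File path.
#' @param dialect One of `"tsv_samples_by_taxa"` (default), `"tsv_taxa_by_samples"`,
#'   `"biom_json"`. BIOM reading requires the `biomformat` package.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path,
                               dialect = c("tsv_samples_by_taxa", "tsv_taxa_by_samples",
                                           "biom_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (identical(dialect, "biom_json")) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))  # biom is taxa x samples
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(m) <- ids
    if (identical(dialect, "tsv_taxa_by_samples")) m <- t(m)
  }
  if (any(!is.finite(m))) stop("non-finite values in feature table: ", path, call. = FALSE)
  if (any(m < 0)) stop("negative values in feature table: ", path, call. = FALSE)
  rs <- rowSums(m)
  tag <- if (all(abs(rs - 1) <= 1e-6)) "relative" else "counts"
  feature_table(m, tag)
}

#' Write a feature table as TSV
#'
#' Samples in rows, first column `sample_id`, one column per taxon. Values are
#' written at full precision so read-write-read round-trips are exact.
#'
#' @param ft A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(sample_id = rownames(ft), unclass(ft), check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Align feature tables onto the union taxon axis
#'
#' All tables are expanded to the lexicographically sorted union of their taxa;
#' taxa absent from a table are zero-filled. Zero padding does not change the
#' row sums of relative tables, so tables are not re-closed by default.
#'
#' @param tables List of `feature_table`s sharing one `space_tag`.
#' @param reclose If `TRUE`, re-close relative tables after padding (a no-op
#'   for genuine zero padding; provided for tables arriving slightly off
#'   closure).
#' @return List of aligned `feature_table`s in the input order.
#' @export
align_union <- function(tables, reclose = FALSE) {
  stopifnot(length(tables) >= 1L)
  tags <- vapply(tables, space_tag, character(1))
  if (length(unique(tags)) != 1L)
    stop("cannot align tables with conflicting space tags: ",
         paste(unique(tags), collapse = " vs "), call. = FALSE)
  axis <- sort(unique(unlist(lapply(tables, colnames))))
  lapply(tables, function(ft) {
    m <- matrix(0, nrow(ft), length(axis), dimnames = list(rownames(ft), axis))
    m[, colnames(ft)] <- unclass(ft)
    out <- structure(m, space_tag = space_tag(ft),
                     class = c("feature_table", "matrix", "array"))
    if (reclose && identical(space_tag(ft), "relative")) out <- as_relative(out)
    validate_feature_table(out)
    out
  })
}

#' Write a structured result to disk
#'
#' Structured results (lists of metrics, GA summaries) are written as JSON;
#' tabular results (data frames) as TSV. Output is bit-stable for fixed inputs.
#'
#' @param obj A list or data frame.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`; default chosen from the object class.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, format = if (is.data.frame(obj)) "tsv" else "json") {
  format <- match.arg(format, c("json", "tsv"))
  if (identical(format, "tsv")) {
    if (!is.data.frame(obj)) stop("TSV output requires a data frame", call. = FALSE)
    data.table::fwrite(obj, path, sep = "\t")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
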
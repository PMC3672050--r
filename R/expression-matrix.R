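#' Construct an expression matrix
#'
#' Container for a features-by-sampling-days expression table. Rows are
#' features (probes or transcripts), columns are sampling occasions in days
#' post irradiation, strictly increasing.
#'
#' @param values Numeric matrix, rows = features, columns = sampling days.
#' @param days Integer vector of days post irradiation, one per column,
#'   strictly increasing.
#' @param row_ids Feature identifiers; defaults to `rownames(values)`.
#' @param scale Either `"linear"` (processed signal) or `"log2"`.
#' @return An object of class `gw_expr`: a list with elements `values`
#'   (matrix with `row_ids` as rownames and `day_<d>` colnames), `days`
#'   and `scale`.
#' @export
expression_matrix <- function(values, days, row_ids = rownames(values),
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(row_ids)) row_ids <- paste0("f", seq_len(nrow(values)))
  days <- as.integer(days)
  if (length(days) != ncol(values))
    stop("length(days) must equal ncol(values)")
  if (ncol(values) < 3L)
    stop("an expression matrix needs at least 3 sampling days")
  if (any(diff(days) <= 0L))
    stop("sampling days must be strictly increasing")
  if (anyDuplicated(row_ids))
    stop("duplicated feature identifiers")
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  rownames(values) <- row_ids
  colnames(values) <- paste0("day_", days)
  structure(list(values = values, days = days, scale = scale),
            class = "gw_expr")
}

#' @export
print.gw_expr <- function(x, ...) {
  cat(sprintf("<gw_expr> %d features x %d days (pi day %d..%d), %s scale\n",
              nrow(x$values), length(x$days), min(x$days), max(x$days),
              x$scale))
  invisible(x)
}

#' @export
dim.gw_expr <- function(x) dim(x$values)

#' @export
as.matrix.gw_expr <- function(x, ...) x$values

#' Log-transform an expression matrix
#'
#' Converts a linear-scale matrix to `log2(value + 1)`. The +1 offset keeps
#' background-level signals finite and compresses their spread, which is the
#' standard transform for one-colour array intensities. A matrix already on
#' the log2 scale is returned unchanged.
#'
#' @param m A [expression_matrix()].
#' @return A `gw_expr` on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "gw_expr"))
  if (m$scale == "log2") return(m)
  if (any(m$values < 0))
    stop("negative values on the linear scale; cannot log-transform")
  expression_matrix(log2(m$values + 1), m$days, scale = "log2")
}

#' Read an expression table from TSV
#'
#' Expects a first column of feature identifiers and one column per sampling
#' day whose header matches `day_header_pattern` with the day number as the
#' first capture group. Day columns are sorted ascending on return.
#'
#' @param path Path to a tab-separated table.
#' @param day_header_pattern Regular expression with one capture group for
#'   the integer day; default `"^day_(\\d+)$"`.
#' @param scale Scale the stored values are on (`"linear"` or `"log2"`).
#' @return A [expression_matrix()].
#' @export
read_expression_table <- function(path, day_header_pattern = "^day_(\\d+)$",
                                  scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs id + day columns")
  headers <- colnames(tab)[-1L]
  hit <- grepl(day_header_pattern, headers)
  if (!any(hit)) stop("no day columns match ", day_header_pattern)
  day_cols <- headers[hit]
  days <- as.integer(sub(day_header_pattern, "\\1", day_cols))
  if (anyDuplicated(days))
    stop("duplicate day columns: ",
         paste(day_cols[duplicated(days)], collapse = ", "))
  if (length(days) < 3L)
    stop("fewer than 3 day columns")
  vals <- as.matrix(tab[, day_cols, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cells in day columns")
  ord <- order(days)
  m <- vals[, ord, drop = FALSE]
  rownames(m) <- as.character(tab[[1L]])
  expression_matrix(m, days[ord], scale = scale)
}

#' Write an expression table to TSV
#'
#' Writes a `feature_id` column plus one `day_<d>` column per sampling day,
#' at 6 significant digits (lossless round trip at that precision).
#'
#' @param m A [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  stopifnot(inherits(m, "gw_expr"))
  out <- data.frame(feature_id = rownames(m$values),
                    signif(m$values, 6L),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Two-column TSV (`probe_id`, `transcript_id`) mapping array probes to
#' systematic transcript identifiers. Many probes may map to one transcript;
#' a probe with more than one transcript is an error. Rows with a missing
#' transcript are dropped.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `probe_id` and `transcript_id`.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "transcript_id") %in% colnames(ann)))
    stop("annotation needs columns probe_id, transcript_id")
  ann <- ann[!is.na(ann$transcript_id) & nzchar(ann$transcript_id),
             c("probe_id", "transcript_id")]
  if (anyDuplicated(ann$probe_id))
    stop("a probe_id maps to more than one transcript_id")
  ann
}
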
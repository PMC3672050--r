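#' Quantile-normalize arrays against each other
#'
#' Forces every column (array) onto the identical value distribution: the
#' per-rank mean of the input columns. Ties within a column receive the mean
#' of the reference values at the ranks they occupy. Delegates to
#' [limma::normalizeQuantiles()], the normalization the field uses for
#' one-colour arrays.
#'
#' @param m A [expression_matrix()], or a plain numeric matrix with at
#'   least 2 columns.
#' @return Same type as the input, with quantile-normalized columns; rank
#'   order within each column is preserved.
#' @export
quantile_normalize <- function(m) {
  v <- if (inherits(m, "gw_expr")) m$values else as.matrix(m)
  if (ncol(v) < 2L) stop("quantile normalization needs at least 2 columns")
  if (!all(is.finite(v))) stop("non-finite expression values")
  norm <- if (nrow(v) == 1L) {
    matrix(mean(v), 1L, ncol(v))     # one rank: every column gets the mean
  } else {
    limma::normalizeQuantiles(v, ties = TRUE)
  }
  dimnames(norm) <- dimnames(v)
  if (!inherits(m, "gw_expr")) return(norm)
  expression_matrix(norm, m$days, scale = m$scale)
}

# group medians down columns; fast paths for the common small group sizes
.group_medians <- function(values, grp) {
  grp <- factor(grp, levels = unique(grp))
  sizes <- tabulate(grp)
  n_grp <- nlevels(grp)
  out <- matrix(NA_real_, n_grp, ncol(values),
                dimnames = list(levels(grp), colnames(values)))
  if (all(sizes == sizes[1L])) {
    s <- sizes[1L]
    ord <- order(as.integer(grp))
    v <- values[ord, , drop = FALSE]
    if (s == 1L) return(`dimnames<-`(v, dimnames(out)))
    if (s == 2L) {
      i <- seq(1L, nrow(v), by = 2L)
      return(`dimnames<-`((v[i, , drop = FALSE] + v[i + 1L, , drop = FALSE]) / 2,
                          dimnames(out)))
    }
    if (s == 3L) {
      i <- seq(1L, nrow(v), by = 3L)
      a <- v[i, , drop = FALSE]
      b <- v[i + 1L, , drop = FALSE]
      c_ <- v[i + 2L, , drop = FALSE]
      return(`dimnames<-`(a + b + c_ - pmax(a, b, c_) - pmin(a, b, c_),
                          dimnames(out)))
    }
  }
  idx <- split(seq_along(grp), grp)
  for (j in seq_len(ncol(values))) {
    col <- values[, j]
    out[, j] <- vapply(idx, function(i) stats::median(col[i]), numeric(1))
  }
  out
}

#' Collapse probe-level rows to transcript level by the median
#'
#' Each transcript's expression at a day is the median over its probes at
#' that day. Probes absent from the annotation are dropped (with a message
#' stating how many). The probe-level values and the probe-to-transcript
#' mapping are retained on the result, because the extreme-point dispersion
#' filter ([extreme_sd()]) needs the per-probe replicate structure.
#'
#' @param m Probe-level [expression_matrix()] (normalize first; the pipeline
#'   order is normalize at probe level, then collapse).
#' @param ann Probe annotation data.frame (`probe_id`, `transcript_id`), see
#'   [read_probe_annotation()].
#' @return A `gw_collapsed` object: a `gw_expr` at transcript level with
#'   additional elements `probe_values` (probe-level matrix, same scale),
#'   `probe_tx` (transcript per probe row) and `n_probes` (named counts).
#' @export
collapse_probes_median <- function(m, ann) {
  stopifnot(inherits(m, "gw_expr"))
  if (anyDuplicated(ann$probe_id))
    stop("a probe_id maps to more than one transcript_id")
  keep <- rownames(m$values) %in% ann$probe_id
  if (!any(keep))
    stop("no probes in the matrix are covered by the annotation")
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " unannotated probe(s) dropped")
  v <- m$values[keep, , drop = FALSE]
  tx <- ann$transcript_id[match(rownames(v), ann$probe_id)]
  med <- .group_medians(v, tx)
  out <- expression_matrix(med, m$days, scale = m$scale)
  out$probe_values <- v
  out$probe_tx <- tx
  out$n_probes <- table(factor(tx, levels = rownames(med)))
  class(out) <- c("gw_collapsed", class(out))
  out
}
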
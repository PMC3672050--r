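#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (unique gene symbols per set),
#'   with the descriptions as attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicated set names in GMT")
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description strings.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, de, genes)
    paste(c(nm, de, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Hypergeometric over-representation analysis of a gene list
#'
#' Tests each gene set for over-representation in a cluster's gene list
#' relative to a background universe (all genes represented on the array).
#' The p-value is the exact upper hypergeometric tail `P(X >= k)` for
#' observing `k` of the list's `n` genes inside a set of size `K` drawn from
#' a universe of size `N`. Reported per set: the count `k`, the percentage
#' `100 k / n` of the annotated list, the fold enrichment `(k/n) / (K/N)`,
#' and the Bonferroni-corrected p-value (multiplied by the number of sets
#' tested in this call, i.e. per category namespace when the collection is
#' one namespace). Significance cut-off: Bonferroni p <= 0.01.
#'
#' Genes in the list or the sets that are absent from the universe are
#' dropped (with a warning for the list). The EASE variant (the count
#' penalized by one, a conservative score some annotation servers use) is
#' available via `ease = TRUE`; the exact tail is the default.
#'
#' @param cluster_genes Character vector of gene symbols in the cluster.
#' @param sets Named list of gene sets ([read_gmt()]).
#' @param universe Character vector: every gene represented on the array.
#' @param ease Use the count-minus-one variant (default `FALSE`).
#' @param alpha Bonferroni significance cut-off (default 0.01).
#' @return A `gw_ora` data.frame sorted by p-value, one row per set:
#'   `set`, `count`, `list_size`, `set_size`, `universe_size`, `percent`,
#'   `fold_enrichment`, `p_value`, `bonferroni_p`, `significant`.
#' @export
hypergeom_ora <- function(cluster_genes, sets, universe, ease = FALSE,
                          alpha = 0.01) {
  uu <- unique(toupper(trimws(universe)))
  gg <- unique(toupper(trimws(cluster_genes)))
  outside <- setdiff(gg, uu)
  if (length(outside) > 0L) {
    warning(length(outside), " cluster gene(s) outside the universe dropped")
    gg <- intersect(gg, uu)
  }
  if (length(gg) == 0L) {
    warning("empty cluster gene list after intersecting with the universe")
    return(structure(data.frame(), class = c("gw_ora", "data.frame")))
  }
  N <- length(uu)
  n <- length(gg)
  n_sets <- length(sets)
  rows <- lapply(names(sets), function(nm) {
    ss <- intersect(unique(toupper(trimws(sets[[nm]]))), uu)
    K <- length(ss)
    k <- length(intersect(gg, ss))
    p <- if (K == 0L) 1 else {
      kk <- if (ease) k - 1L else k
      if (kk <= 0L) 1 else stats::phyper(kk - 1L, K, N - K, n,
                                         lower.tail = FALSE)
    }
    data.frame(set = nm, count = k, list_size = n, set_size = K,
               universe_size = N,
               percent = 100 * k / n,
               fold_enrichment = if (K == 0L) NA_real_ else (k / n) / (K / N),
               p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$bonferroni_p <- pmin(1, res$p_value * n_sets)
  res$significant <- res$bonferroni_p <= alpha
  res <- res[order(res$p_value, res$set), ]
  rownames(res) <- NULL
  class(res) <- c("gw_ora", class(res))
  res
}

#' @export
print.gw_ora <- function(x, ...) {
  cat(sprintf("<gw_ora> %d sets tested, %d significant (Bonferroni)\n",
              nrow(x), if (nrow(x)) sum(x$significant) else 0L))
  if (nrow(x)) print.data.frame(utils::head(x, 10L), digits = 3)
  invisible(x)
}
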
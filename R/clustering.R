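#' Z-scale expression profiles
#'
#' Centres and scales each row (transcript) to mean 0 and SD 1 across days,
#' making profiles comparable regardless of expression level.
#'
#' @param m A [expression_matrix()] or plain numeric matrix.
#' @return Numeric matrix of z-scaled profiles.
#' @export
z_scale_profiles <- function(m) {
  v <- if (inherits(m, "gw_expr")) m$values else as.matrix(m)
  s <- apply(v, 1L, stats::sd)
  if (any(s == 0)) stop("constant profiles cannot be z-scaled")
  (v - rowMeans(v)) / s
}

#' Correlation distance matrix
#'
#' Pairwise dissimilarity of expression profiles over the time series,
#' `d(i,j) = 1 - r(i,j)` with r the Pearson correlation: uncorrelated
#' profiles sit at 1 (the distances are centred around 1), identical
#' profiles at 0, opposite profiles at 2. Squared and r-squared variants
#' are available for sensitivity analysis.
#'
#' @param profiles Transcripts x days matrix (z-scaled or not; Pearson
#'   correlation is scale-free) or a `gw_expr`. Constant profiles are an
#'   error -- the selection step removes them.
#' @param method `"one_minus_r"` (default), `"one_minus_r_squared"`
#'   (`1 - r^2`) or `"squared"` (`(1 - r)^2`).
#' @return Symmetric non-negative matrix with zero diagonal, values in
#'   `[0, 2]`.
#' @export
correlation_distance <- function(profiles,
                                 method = c("one_minus_r",
                                            "one_minus_r_squared",
                                            "squared")) {
  method <- match.arg(method)
  v <- if (inherits(profiles, "gw_expr")) profiles$values
       else as.matrix(profiles)
  if (any(apply(v, 1L, stats::sd) == 0))
    stop("constant profile: filter before computing distances")
  r <- stats::cor(t(v))
  d <- switch(method,
              one_minus_r = 1 - r,
              one_minus_r_squared = 1 - r^2,
              squared = (1 - r)^2)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Partitioning around medoids on a precomputed distance matrix
#'
#' k-medoids clustering (BUILD initialization followed by SWAP passes until
#' no single medoid/non-medoid exchange lowers the total cost), delegated to
#' [cluster::pam()]. Deterministic given the distance matrix.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `gw_clusters`: list with `k`, `medoid_ids`, `labels` (named
#'   integer vector, transcript to cluster), `total_cost` (sum of distances
#'   to assigned medoids), `avg_silhouette` (`NA` for `k = 1`).
#' @export
pam_cluster <- function(d, k) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (k > n) stop("k cannot exceed the number of objects")
  if (k < 1L) stop("k must be at least 1")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k == n) {
    labels <- stats::setNames(seq_len(n), ids)
    return(structure(list(k = k, medoid_ids = ids, labels = labels,
                          total_cost = 0, avg_silhouette = NA_real_),
                     class = "gw_clusters"))
  }
  fit <- cluster::pam(stats::as.dist(dm), k = k, diss = TRUE)
  labels <- stats::setNames(as.integer(fit$clustering), ids)
  cost <- sum(dm[cbind(seq_len(n), fit$id.med[fit$clustering])])
  sil <- if (k > 1L) fit$silinfo$avg.width else NA_real_
  structure(list(k = k, medoid_ids = ids[fit$id.med], labels = labels,
                 total_cost = cost, avg_silhouette = sil),
            class = "gw_clusters")
}

#' @export
print.gw_clusters <- function(x, ...) {
  cat(sprintf("<gw_clusters> k = %d, total cost %.4f, sizes: %s\n",
              x$k, x$total_cost,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Per-cluster median z-scaled profiles
#'
#' Z-scales every transcript and takes, per cluster and per day, the median
#' z-value over the cluster members.
#'
#' @param m Transcript-level [expression_matrix()] (or matrix) covering the
#'   clustered transcripts.
#' @param labels Named integer vector (transcript to cluster index) as in
#'   [pam_cluster()].
#' @return Matrix, clusters x days, rownames the cluster indices.
#' @export
median_z_profiles <- function(m, labels) {
  v <- if (inherits(m, "gw_expr")) m$values else as.matrix(m)
  v <- v[names(labels), , drop = FALSE]
  z <- z_scale_profiles(v)
  ks <- sort(unique(labels))
  if (any(tabulate(labels, max(ks)) == 0L))
    stop("empty cluster")
  out <- t(vapply(ks, function(k) {
    apply(z[labels == k, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(z))))
  rownames(out) <- ks
  colnames(out) <- colnames(v)
  out
}

#' Choose the number of clusters separating the most unique profiles
#'
#' Runs PAM over a range of k and asks, for each k, whether every pair of
#' per-cluster median z-profiles is distinct: a k is admissible when all
#' pairwise Pearson correlations between cluster medians stay below
#' `rho_max` and every cluster reaches a minimal size (a singleton or
#' near-singleton is an outlier, not a separated expression pattern). The
#' largest admissible k is returned -- beyond it, clusters only split into
#' subclusters with near-identical patterns. If no k in the range is
#' admissible the function returns 2 with a warning.
#'
#' @param d Distance matrix over the selected transcripts
#'   ([correlation_distance()]).
#' @param m Matching transcript-level expression (for the median profiles).
#' @param k_range Candidate cluster counts (default `2:10`).
#' @param rho_max Maximum allowed correlation between two cluster median
#'   profiles before they count as duplicates (default 0.8).
#' @param min_size Minimum members a cluster needs to count as a separated
#'   transcript cluster; default `max(2, ceiling(0.005 n))`.
#' @return The chosen k (integer), with a data.frame of per-k diagnostics
#'   (`k`, `admissible`, `max_rho`, `min_cluster_size`, `avg_silhouette`)
#'   attached as attribute `diagnostics`.
#' @export
choose_k <- function(d, m, k_range = 2:10, rho_max = 0.8, min_size = NULL) {
  n <- nrow(as.matrix(d))
  if (is.null(min_size)) min_size <- max(2L, ceiling(0.005 * n))
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(k_range) == 0L) stop("empty k range")
  diag_df <- data.frame(k = k_range, admissible = NA, max_rho = NA_real_,
                        min_cluster_size = NA_integer_,
                        avg_silhouette = NA_real_)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cl <- pam_cluster(d, k)
    prof <- median_z_profiles(m, cl$labels)
    rho <- stats::cor(t(prof))
    max_rho <- max(rho[upper.tri(rho)])
    smallest <- min(tabulate(cl$labels, k))
    diag_df$max_rho[i] <- max_rho
    diag_df$min_cluster_size[i] <- smallest
    diag_df$admissible[i] <- max_rho < rho_max && smallest >= min_size
    diag_df$avg_silhouette[i] <- cl$avg_silhouette
  }
  adm <- diag_df$k[diag_df$admissible]
  if (length(adm) == 0L) {
    warning("no k in the range separates unique clusters; returning 2")
    best <- 2L
  } else {
    best <- max(adm)
  }
  attr(best, "diagnostics") <- diag_df
  best
}

#' Write cluster labels to TSV
#'
#' @param cl A `gw_clusters`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(cl, path) {
  utils::write.table(data.frame(transcript_id = names(cl$labels),
                                cluster = as.integer(cl$labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
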
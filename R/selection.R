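#' Selection configuration
#'
#' Parameters for the enrichment-score transcript selection: the number of
#' time-point shuffles behind the permutation null, the FDR cut-off, the
#' extreme-point dispersion cut-off, and the seed.
#'
#' @param n_permutations Number of shuffled-time-point recomputations of the
#'   score (default 10).
#' @param fdr_threshold FDR cut-off in percent (default 30).
#' @param sd_threshold Extreme-point dispersion cut-off in percent of the
#'   collapsed value (default 15).
#' @param rng_seed Integer seed for the shuffles.
#' @param per_transcript If `TRUE`, each transcript is shuffled with its own
#'   independent orderings; the default shares one ordering per permutation
#'   across all transcripts, preserving cross-transcript correlation in the
#'   null.
#' @return A list of class `gw_selcfg`.
#' @export
selection_config <- function(n_permutations = 10L, fdr_threshold = 30,
                             sd_threshold = 15, rng_seed = 1L,
                             per_transcript = FALSE) {
  stopifnot(n_permutations >= 1L,
            fdr_threshold > 0, fdr_threshold <= 100,
            sd_threshold > 0, sd_threshold <= 100)
  structure(list(n_permutations = as.integer(n_permutations),
                 fdr_threshold = fdr_threshold,
                 sd_threshold = sd_threshold,
                 rng_seed = as.integer(rng_seed),
                 per_transcript = isTRUE(per_transcript)),
            class = "gw_selcfg")
}

#' Enrichment score of a single expression profile
#'
#' The per-transcript smoothness statistic: the sum of absolute differences
#' between neighbouring time points divided by the sum of squared deviations
#' from the profile mean,
#' \deqn{ES = \frac{\sum_{i=1}^{n-1} |GE_i - GE_{i+1}|}{\sum_{i=1}^{n} (GE_i - \overline{GE})^2}.}
#' Low values mark profiles with large overall change but small change
#' between neighbouring days -- the signature of a depletion/recovery wave
#' moving through the tissue, as opposed to measurement noise. A constant
#' profile (zero denominator) returns `Inf` and is never selectable.
#'
#' @param profile Numeric vector of length >= 3, ordered by sampling day.
#' @return A non-negative number, or `Inf` for a constant profile.
#' @export
enrichment_score <- function(profile) {
  if (length(profile) < 3L) stop("profile needs at least 3 time points")
  if (!all(is.finite(profile))) stop("profile values must be finite")
  den <- sum((profile - mean(profile))^2)
  if (den == 0) return(Inf)
  sum(abs(diff(profile))) / den
}

# row-wise ES for a transcripts x days matrix
.es_rows <- function(v) {
  n <- ncol(v)
  num <- rowSums(abs(v[, -1L, drop = FALSE] - v[, -n, drop = FALSE]))
  den <- rowSums((v - rowMeans(v))^2)
  ifelse(den == 0, Inf, num / den)
}

#' Permutation null for the enrichment score
#'
#' Recomputes every transcript's enrichment score under
#' `cfg$n_permutations` random orderings of the sampling days. By default
#' one shared ordering per permutation is applied to all transcripts. The
#' squared-deviation denominator is order-invariant, so only the neighbour
#' differences change under shuffling.
#'
#' @param m Transcript-level [expression_matrix()] (collapsed).
#' @param cfg A [selection_config()].
#' @return Matrix of null scores, transcripts x permutations, with the
#'   orderings used attached as attribute `orderings` (shared mode only).
#' @export
permutation_null <- function(m, cfg = selection_config()) {
  stopifnot(inherits(m, "gw_expr"))
  v <- m$values
  n <- ncol(v)
  with_seed(cfg$rng_seed, {
    if (cfg$per_transcript) {
      null <- vapply(seq_len(cfg$n_permutations), function(p) {
        shuffled <- t(apply(v, 1L, function(x) x[sample.int(n)]))
        .es_rows(shuffled)
      }, numeric(nrow(v)))
      dimnames(null) <- list(rownames(v), NULL)
      null
    } else {
      ords <- replicate(cfg$n_permutations, sample.int(n))
      null <- apply(ords, 2L, function(o) .es_rows(v[, o, drop = FALSE]))
      dimnames(null) <- list(rownames(v), NULL)
      attr(null, "orderings") <- ords
      null
    }
  })
}

#' Permutation-FDR q-values for observed enrichment scores
#'
#' For a threshold t (selection keeps scores <= t) the raw plug-in FDR is
#' the null exceedance count scaled to one permutation, divided by the
#' observed count:
#' `FDR(t) = [(1/P) * #(null ES <= t)] / max(1, #(observed ES <= t))`.
#' The reported q-value is the cumulative minimum of the raw FDR taken from
#' the largest observed score downward, clipped to `[0, 1]`, so q is
#' monotone non-decreasing in the score.
#'
#' @param observed Numeric vector of observed scores (`Inf` allowed).
#' @param null Null score collection from [permutation_null()]: a matrix
#'   (transcripts x permutations) or a vector with `n_permutations` given.
#' @param n_permutations Number of permutations `null` came from; taken from
#'   `ncol(null)` when `null` is a matrix.
#' @return Numeric vector of q-values in `[0, 1]`, aligned with `observed`.
#' @export
fdr_curve <- function(observed, null, n_permutations = NULL) {
  if (is.matrix(null)) {
    if (is.null(n_permutations)) n_permutations <- ncol(null)
    null <- as.vector(null)
  }
  if (length(null) == 0L) stop("empty null collection")
  if (is.null(n_permutations))
    stop("n_permutations required when null is a vector")
  nv <- sort(null)                      # Inf sorts last
  o <- order(observed)
  n_null_le <- findInterval(observed[o], nv)
  n_obs_le <- rank(observed, ties.method = "max")[o]
  raw <- pmin(1, (n_null_le / n_permutations) / pmax(1, n_obs_le))
  q <- rev(cummin(rev(raw)))
  out <- numeric(length(observed))
  out[o] <- q
  names(out) <- names(observed)
  out
}

#' Dispersion of the most extreme expression value
#'
#' Finds the day at which the collapsed profile deviates most from its mean
#' (the most extreme expression value of the time series) and returns the
#' probe-level sample standard deviation at that day as a percentage of the
#' absolute collapsed value there. A transcript measured by a single probe
#' has no measurable dispersion and returns 0; a zero collapsed value at the
#' extreme day returns `Inf` (fails any filter). This coefficient of
#' variation at the profile's extreme point flags transcripts whose apparent
#' signal rests on discordant probes -- the typical false positives of a
#' smoothness statistic (single-day spikes, background-level probes).
#'
#' @param profile Collapsed (transcript-level) profile, ordered by day.
#' @param probe_values Matrix of that transcript's probe-level values,
#'   probes x days, same day order.
#' @return Dispersion percentage (non-negative, possibly `Inf`).
#' @export
extreme_sd <- function(profile, probe_values) {
  probe_values <- rbind(probe_values)
  if (ncol(probe_values) != length(profile))
    stop("probe_values must have one column per day")
  j <- which.max(abs(profile - mean(profile)))
  if (nrow(probe_values) < 2L) return(0)
  if (profile[j] == 0) return(Inf)
  100 * stats::sd(probe_values[, j]) / abs(profile[j])
}

# vectorized over a gw_collapsed object
.extreme_sd_all <- function(m) {
  v <- m$values
  dev <- abs(v - rowMeans(v))
  j <- max.col(dev, ties.method = "first")
  pv <- m$probe_values
  idx <- split(seq_along(m$probe_tx),
               factor(m$probe_tx, levels = rownames(v)))
  vapply(seq_len(nrow(v)), function(i) {
    rows <- idx[[i]]
    if (length(rows) < 2L) return(0)
    cj <- v[i, j[i]]
    if (cj == 0) return(Inf)
    100 * stats::sd(pv[rows, j[i]]) / abs(cj)
  }, numeric(1))
}

#' Select transcripts tracking cellularity
#'
#' Runs the full smoothness selection on a collapsed matrix: observed
#' enrichment scores, the seeded permutation null, cumulative-minimum FDR
#' q-values, and the extreme-point dispersion filter. A transcript is
#' selected when its q-value is at most `fdr_threshold` percent, its
#' extreme-point dispersion is at most `sd_threshold` percent, and its score
#' is finite. Deterministic given `cfg$rng_seed`.
#'
#' @param m A `gw_collapsed` matrix from [collapse_probes_median()] (log2
#'   scale recommended; see [log2_transform()]).
#' @param cfg A [selection_config()].
#' @return A `gw_selection`: data.frame with columns `transcript_id`, `es`,
#'   `q_value`, `extreme_sd_pct`, `selected`, with the configuration and the
#'   input matrix attached as attributes.
#' @export
select_transcripts <- function(m, cfg = selection_config()) {
  stopifnot(inherits(m, "gw_collapsed"))
  es <- .es_rows(m$values)
  null <- permutation_null(m, cfg)
  q <- fdr_curve(es, null)
  sdp <- .extreme_sd_all(m)
  sel <- is.finite(es) & q <= cfg$fdr_threshold / 100 &
    sdp <= cfg$sd_threshold
  res <- data.frame(transcript_id = rownames(m$values),
                    es = es, q_value = q, extreme_sd_pct = sdp,
                    selected = sel,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "config") <- cfg
  attr(res, "matrix") <- m
  class(res) <- c("gw_selection", class(res))
  res
}

#' @export
print.gw_selection <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<gw_selection> %d/%d transcripts selected (FDR <= %g%%, extreme SD <= %g%%, %d permutations)\n",
    sum(x$selected), nrow(x), cfg$fdr_threshold, cfg$sd_threshold,
    cfg$n_permutations))
  invisible(x)
}

#' @export
summary.gw_selection <- function(object, ...) {
  fin <- is.finite(object$es)
  cat("Enrichment-score selection\n")
  cat(sprintf("  transcripts: %d (%d with constant profile)\n",
              nrow(object), sum(!fin)))
  cat(sprintf("  selected:    %d\n", sum(object$selected)))
  cat(sprintf("  ES (finite): median %.3f, range %.3f..%.3f\n",
              stats::median(object$es[fin]), min(object$es[fin]),
              max(object$es[fin])))
  invisible(object)
}

#' Write a selection result to TSV
#'
#' @param x A `gw_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("transcript_id", "es", "q_value",
                                          "extreme_sd_pct", "selected")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
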
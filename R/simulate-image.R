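#' Simulate a stained-section image with known areas
#'
#' Draws red disks (Leydig-cell stain) of the requested physical areas onto
#' a blue tissue field with a white background margin at the top of the
#' canvas. Pixel colours are sampled from the configured class swatch
#' distributions, so the image exercises the Bayesian pixel classifier
#' under its own model. Returned ground-truth areas are the exact
#' rasterized pixel counts times the calibration, not the requested
#' nominal areas.
#'
#' @param blob_areas_um2 Numeric vector of nominal red blob areas in um^2
#'   (may be empty).
#' @param background_fraction Fraction of image height that is white
#'   background (default 0.15).
#' @param cfg A [quant_config()] (calibration and swatches).
#' @param rng_seed Seed for blob placement and pixel colours.
#' @param width,height Canvas size in pixels (default 200 x 200).
#' @return List with `image` (RGB array) and `truth`: per-blob areas
#'   (`blob_areas_um2`), totals `red_um2`, `blue_um2`, `background_um2`,
#'   and the ground-truth `ratio` red/blue.
#' @export
simulate_ihc_image <- function(blob_areas_um2, background_fraction = 0.15,
                               cfg, rng_seed = 1L,
                               width = 200L, height = 200L) {
  stopifnot(inherits(cfg, "gw_quantcfg"),
            background_fraction >= 0, background_fraction < 1)
  h <- as.integer(height); w <- as.integer(width)
  bg_rows <- as.integer(round(h * background_fraction))
  lab <- matrix(2L, h, w)                       # blue tissue
  if (bg_rows > 0L) lab[seq_len(bg_rows), ] <- 3L
  radii <- sqrt(blob_areas_um2 / (cfg$um2_per_pixel * pi))
  blob_px <- integer(length(radii))
  with_seed(rng_seed, {
    if (length(radii) > 0L) {
      centers <- matrix(NA_real_, length(radii), 2L)
      for (b in order(radii, decreasing = TRUE)) {
        r <- radii[b]
        rmin <- bg_rows + ceiling(r) + 2L
        if (rmin > h - ceiling(r) - 1L || 2 * r + 2 > w)
          stop("blob of ", blob_areas_um2[b],
               " um^2 does not fit the tissue region")
        ok <- FALSE
        for (try in seq_len(2000L)) {
          ci <- stats::runif(1, rmin, h - ceiling(r) - 1L)
          cj <- stats::runif(1, ceiling(r) + 2L, w - ceiling(r) - 1L)
          sep <- TRUE
          for (b2 in seq_len(length(radii))) {
            if (b2 == b || is.na(centers[b2, 1L])) next
            if (sqrt(sum((c(ci, cj) - centers[b2, ])^2)) <
                radii[b2] + r + 2) { sep <- FALSE; break }
          }
          if (sep) { centers[b, ] <- c(ci, cj); ok <- TRUE; break }
        }
        if (!ok) stop("cannot place ", length(radii),
                      " non-overlapping blobs on this canvas")
      }
      ri <- row(lab); cj <- col(lab)
      for (b in seq_along(radii)) {
        inside <- (ri - centers[b, 1L])^2 + (cj - centers[b, 2L])^2 <=
          radii[b]^2
        blob_px[b] <- sum(inside)
        lab[inside] <- 1L
      }
    }
    # sample colours from the class swatch Gaussians
    img <- array(0, c(h, w, 3L))
    classes <- c("red", "blue", "background")
    for (ci in 1:3) {
      sw <- cfg$class_swatches[[classes[ci]]]
      mu <- colMeans(sw)
      sg <- pmax(apply(sw, 2L, stats::sd), 0.005)
      n_px <- sum(lab == ci)
      if (n_px == 0L) next
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[lab == ci] <- pmin(pmax(
          stats::rnorm(n_px, mu[ch], sg[ch]), 0), 1)
        img[, , ch] <- plane
      }
    }
    counts <- tabulate(lab, 3L)
    truth <- list(blob_areas_um2 = blob_px * cfg$um2_per_pixel,
                  red_um2 = counts[1L] * cfg$um2_per_pixel,
                  blue_um2 = counts[2L] * cfg$um2_per_pixel,
                  background_um2 = counts[3L] * cfg$um2_per_pixel,
                  ratio = if (counts[2L] > 0)
                    counts[1L] / counts[2L] else NA_real_,
                  labels = lab)
    list(image = img, truth = truth)
  })
}
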
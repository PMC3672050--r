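#' Quantification configuration for stained-section images
#'
#' Physical calibration and classifier settings for the red (Hsd3b-stained
#' Leydig cells) versus blue (haematoxylin-counterstained other tissue)
#' versus white (background) area measurement.
#'
#' @param um2_per_pixel Physical pixel area in square micrometres (> 0).
#' @param min_red_area_um2 Connected red areas strictly smaller than this
#'   are re-assigned to blue (default 20).
#' @param connectivity Pixel connectivity for red components: 8 (default,
#'   includes diagonals) or 4.
#' @param class_swatches Named list (`red`, `blue`, `background`) of
#'   RGB training-pixel matrices (rows = pixels, 3 columns, values in
#'   `[0, 1]`), at least 10 pixels each; defaults to [default_swatches()].
#' @return A list of class `gw_quantcfg`.
#' @export
quant_config <- function(um2_per_pixel, min_red_area_um2 = 20,
                         connectivity = 8L,
                         class_swatches = default_swatches()) {
  stopifnot(um2_per_pixel > 0, min_red_area_um2 >= 0,
            connectivity %in% c(4L, 8L))
  need <- c("red", "blue", "background")
  if (!all(need %in% names(class_swatches)))
    stop("class_swatches needs entries red, blue, background")
  for (nm in need) {
    sw <- class_swatches[[nm]]
    if (!is.matrix(sw) || ncol(sw) != 3L || nrow(sw) < 10L)
      stop("swatch '", nm, "' must be a >=10 x 3 RGB matrix")
  }
  structure(list(um2_per_pixel = um2_per_pixel,
                 min_red_area_um2 = min_red_area_um2,
                 connectivity = as.integer(connectivity),
                 class_swatches = class_swatches[need]),
            class = "gw_quantcfg")
}

#' Default colour swatches for AEC red, haematoxylin blue and background
#'
#' Deterministic Gaussian samples around typical chromogen colours:
#' AEC-developed red stain, Meyer's haematoxylin blue, and near-white
#' background.
#'
#' @param n Pixels per class (default 60).
#' @return Named list of three `n x 3` RGB matrices with values in
#'   `[0, 1]`.
#' @export
default_swatches <- function(n = 60L) {
  means <- list(red = c(0.72, 0.20, 0.22),
                blue = c(0.30, 0.34, 0.66),
                background = c(0.96, 0.95, 0.93))
  sds <- list(red = c(0.06, 0.05, 0.05),
              blue = c(0.05, 0.05, 0.06),
              background = c(0.02, 0.02, 0.02))
  with_seed(20130528L, {
    out <- lapply(names(means), function(nm) {
      m <- matrix(stats::rnorm(n * 3L, rep(means[[nm]], each = n),
                               rep(sds[[nm]], each = n)), n, 3L)
      pmin(pmax(m, 0), 1)
    })
    names(out) <- names(means)
    out
  })
}

#' Read a section image
#'
#' Reads an RGB raster from PNG (or TIFF when the tiff package is
#' installed) into an `h x w x 3` array with values in `[0, 1]`. An alpha
#' channel, if present, is dropped; greyscale images are an error.
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`).
#' @return Numeric array `h x w x 3`.
#' @export
read_section_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L)
    stop("need an RGB image")
  img[, , 1:3, drop = FALSE]
}

#' Classify section pixels into red stain, blue tissue and background
#'
#' Bayesian colour classification: per class, an independent Gaussian model
#' per RGB channel is fitted to the training swatches; each pixel gets the
#' maximum-posterior label under equal class priors.
#'
#' @param image RGB array `h x w x 3` with values in `[0, 1]`
#'   ([read_section_image()]).
#' @param cfg A [quant_config()].
#' @return A `gw_pixmap`: list with `labels` (integer matrix `h x w`,
#'   levels `red`, `blue`, `background`), `levels`, and `um2_per_pixel`.
#' @export
classify_pixels <- function(image, cfg) {
  stopifnot(inherits(cfg, "gw_quantcfg"))
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stop("image must be h x w x 3")
  classes <- names(cfg$class_swatches)
  px <- matrix(image, ncol = 3L)          # (h*w) x 3
  ll <- matrix(0, nrow(px), length(classes))
  for (ci in seq_along(classes)) {
    sw <- cfg$class_swatches[[ci]]
    mu <- colMeans(sw)
    sg <- pmax(apply(sw, 2L, stats::sd), 0.005)   # variance floor
    for (ch in 1:3)
      ll[, ci] <- ll[, ci] + stats::dnorm(px[, ch], mu[ch], sg[ch],
                                          log = TRUE)
  }
  lab <- max.col(ll, ties.method = "first")
  structure(list(labels = matrix(lab, d[1L], d[2L]),
                 levels = classes,
                 um2_per_pixel = cfg$um2_per_pixel),
            class = "gw_pixmap")
}

# connected-component labelling of a logical mask by iterative minimum-label
# flooding (vectorized shifts); connectivity 4 or 8
.label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  cur <- matrix(Inf, h, w)
  cur[mask] <- which(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, h, w)
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  repeat {
    nb <- cur
    for (o in offs) nb <- pmin(nb, shift(cur, o[1L], o[2L]))
    nb[!mask] <- Inf
    new <- pmin(cur, nb)
    if (identical(new, cur)) break
    cur <- new
  }
  comp <- matrix(0L, h, w)
  if (any(mask)) {
    ids <- cur[mask]
    comp[mask] <- as.integer(factor(ids, levels = sort(unique(ids))))
  }
  comp
}

#' Re-assign small red components to blue
#'
#' Every connected red component (4- or 8-connectivity per the
#' configuration) whose physical area is strictly smaller than
#' `min_red_area_um2` is re-labelled blue; red components at or above the
#' cut-off, and all blue/background pixels, are untouched. The operation is
#' idempotent.
#'
#' @param pcm A `gw_pixmap` from [classify_pixels()].
#' @param cfg The [quant_config()] (for the area cut-off and connectivity).
#' @return The filtered `gw_pixmap`.
#' @export
filter_small_components <- function(pcm, cfg) {
  stopifnot(inherits(pcm, "gw_pixmap"), inherits(cfg, "gw_quantcfg"))
  red <- which(pcm$levels == "red")
  blue <- which(pcm$levels == "blue")
  comp <- .label_components(pcm$labels == red, cfg$connectivity)
  if (max(comp) == 0L) return(pcm)
  areas <- tabulate(comp[comp > 0L]) * pcm$um2_per_pixel
  small <- which(areas < cfg$min_red_area_um2)
  if (length(small) > 0L)
    pcm$labels[comp %in% small] <- blue
  pcm
}

#' Class areas of a pixel map in square micrometres
#'
#' @param pcm A `gw_pixmap`.
#' @return Named numeric vector of areas (um^2) per class.
#' @export
class_areas <- function(pcm) {
  stopifnot(inherits(pcm, "gw_pixmap"))
  counts <- tabulate(pcm$labels, length(pcm$levels))
  stats::setNames(counts * pcm$um2_per_pixel, pcm$levels)
}

#' Ratio of red to blue stained area
#'
#' The amount of Leydig cells relative to other testicular cells: red area
#' divided by blue area, background excluded from both terms. Apply
#' [filter_small_components()] first.
#'
#' @param pcm A (filtered) `gw_pixmap`.
#' @return Non-negative number.
#' @export
red_blue_ratio <- function(pcm) {
  a <- class_areas(pcm)
  if (a[["blue"]] == 0) stop("no blue (tissue) area in the image")
  unname(a[["red"]] / a[["blue"]])
}

#' Write a label map as a PNG overlay
#'
#' Renders the classified map with a pure red / blue / white palette,
#' mirroring the in-silico colour assignment applied to the stained
#' sections.
#'
#' @param pcm A `gw_pixmap`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(pcm, path) {
  pal <- rbind(red = c(1, 0, 0), blue = c(0, 0, 1),
               background = c(1, 1, 1))[pcm$levels, , drop = FALSE]
  h <- nrow(pcm$labels); w <- ncol(pcm$labels)
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(pal[pcm$labels, ch], h, w)
  png::writePNG(img, path)
  invisible(path)
}

#' Quantify Leydig-cell staining in one section image
#'
#' Convenience wrapper: classify pixels, filter sub-threshold red
#' components, and measure areas and the red/blue ratio.
#'
#' @param image RGB array or image path.
#' @param cfg A [quant_config()].
#' @return A list: `areas_um2` (named vector), `ratio`, and the filtered
#'   `pixmap`.
#' @export
quantify_section <- function(image, cfg) {
  if (is.character(image)) image <- read_section_image(image)
  pcm <- filter_small_components(classify_pixels(image, cfg), cfg)
  list(areas_um2 = class_areas(pcm), ratio = red_blue_ratio(pcm),
       pixmap = pcm)
}
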
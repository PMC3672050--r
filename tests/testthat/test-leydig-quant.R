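# build a pixel map by hand: label matrix with 1=red, 2=blue, 3=background
pixmap <- function(labels, um2_per_pixel = 1) {
  structure(list(labels = labels, levels = c("red", "blue", "background"),
                 um2_per_pixel = um2_per_pixel),
            class = "gw_pixmap")
}

test_that("pixel classification recovers the swatch classes", {
  cfg <- quant_config(um2_per_pixel = 1)
  sw <- cfg$class_swatches
  img <- array(0, c(1, 3, 3))
  img[1, 1, ] <- colMeans(sw$red)
  img[1, 2, ] <- colMeans(sw$blue)
  img[1, 3, ] <- c(1, 1, 1)                    # pure white
  pcm <- classify_pixels(img, cfg)
  expect_equal(as.vector(pcm$labels), c(1L, 2L, 3L))

  sim <- simulate_ihc_image(c(120, 60), cfg = cfg, rng_seed = 3L)
  pcm2 <- classify_pixels(sim$image, cfg)
  expect_gte(mean(pcm2$labels == sim$truth$labels), 0.99)

  cfg_bad <- cfg
  cfg_bad$class_swatches$red <- NULL
  expect_error(quant_config(1, class_swatches = cfg_bad$class_swatches),
               "red")
})

test_that("the small-component filter applies a strict 20 um^2 rule", {
  # 199 pixels at 0.1 um^2 = 19.9 um^2 -> re-assigned to blue
  lab <- matrix(2L, 40, 40)
  lab[2:20, 2:12] <- 1L                        # 19 x 11 = 209 px
  lab[2:11, 12] <- 2L                          # carve down to 199 px
  expect_equal(sum(lab == 1L), 199L)
  cfg <- quant_config(um2_per_pixel = 0.1, min_red_area_um2 = 20)
  f <- filter_small_components(pixmap(lab, 0.1), cfg)
  expect_equal(class_areas(f)[["red"]], 0)

  # exactly 20.0 um^2 (200 px) sits on the boundary and is retained
  lab2 <- matrix(2L, 40, 40)
  lab2[2:21, 2:11] <- 1L                       # 20 x 10 = 200 px
  f2 <- filter_small_components(pixmap(lab2, 0.1), cfg)
  expect_equal(class_areas(f2)[["red"]], 20)

  # no red: identity
  lab3 <- matrix(2L, 10, 10)
  expect_identical(filter_small_components(pixmap(lab3, 0.1), cfg)$labels,
                   lab3)
})

test_that("filtering is idempotent and conserves total area", {
  set.seed(6)
  lab <- matrix(sample(1:3, 900, replace = TRUE, prob = c(.15, .6, .25)),
                30, 30)
  cfg <- quant_config(um2_per_pixel = 2, min_red_area_um2 = 20)
  p0 <- pixmap(lab, 2)
  p1 <- filter_small_components(p0, cfg)
  p2 <- filter_small_components(p1, cfg)
  expect_identical(p1$labels, p2$labels)
  total <- 900 * 2
  expect_equal(sum(class_areas(p0)), total)
  expect_equal(sum(class_areas(p1)), total)
  # background is never relabelled and red never grows
  expect_equal(sum(p1$labels == 3L), sum(lab == 3L))
  expect_lte(sum(p1$labels == 1L), sum(lab == 1L))
})

test_that("connectivity decides whether diagonal red pixels form one blob", {
  lab <- matrix(2L, 8, 8)
  lab[3, 3] <- 1L
  lab[4, 4] <- 1L                              # diagonal neighbours
  # 8-connectivity: one 30 um^2 component, kept
  cfg8 <- quant_config(um2_per_pixel = 15, min_red_area_um2 = 20,
                       connectivity = 8)
  expect_equal(class_areas(filter_small_components(pixmap(lab, 15),
                                                   cfg8))[["red"]], 30)
  # 4-connectivity: two 15 um^2 singletons, both removed
  cfg4 <- quant_config(um2_per_pixel = 15, min_red_area_um2 = 20,
                       connectivity = 4)
  expect_equal(class_areas(filter_small_components(pixmap(lab, 15),
                                                   cfg4))[["red"]], 0)
})

test_that("the red/blue ratio excludes background and needs tissue", {
  lab <- matrix(2L, 40, 30)                    # all blue
  expect_equal(red_blue_ratio(pixmap(lab)), 0)
  lab[1:10, 1:10] <- 1L                        # 100 red px
  lab[31:40, ] <- 3L                           # background, excluded
  p <- pixmap(lab, 1)
  expect_equal(class_areas(p)[["red"]], 100)
  expect_equal(red_blue_ratio(p), 100 / (1200 - 100 - 300))
  lab_bg <- matrix(3L, 5, 5)
  expect_error(red_blue_ratio(pixmap(lab_bg)), "no blue")
})

test_that("a constructed 1:9 scene yields the 0.1111 ratio", {
  lab <- matrix(2L, 25, 40)                    # 1000 px tissue
  lab[3:12, 3:12] <- 1L                        # 100 px red
  expect_equal(red_blue_ratio(pixmap(lab, 1)), 1 / 9, tolerance = 1e-12)
})

test_that("removing a sub-threshold blob shifts the ratio by its area", {
  lab <- matrix(2L, 30, 30)
  lab[2:11, 2:11] <- 1L                        # 100 px blob (kept)
  lab[20:21, 20:25] <- 1L                      # 12 px blob (< 20 um^2)
  cfg <- quant_config(um2_per_pixel = 1, min_red_area_um2 = 20)
  p0 <- pixmap(lab, 1)
  p1 <- filter_small_components(p0, cfg)
  a0 <- class_areas(p0); a1 <- class_areas(p1)
  expect_equal(a0[["red"]] - a1[["red"]], 12)
  expect_equal(a1[["blue"]] - a0[["blue"]], 12)
  expect_equal(red_blue_ratio(p0), 112 / 788)
  expect_equal(red_blue_ratio(p1), 100 / 800)
})

test_that("the ratio is invariant to resolution rescaling", {
  lab <- matrix(2L, 20, 20)
  lab[5:10, 5:12] <- 1L
  r1 <- red_blue_ratio(pixmap(lab, 4))
  lab2 <- lab[rep(1:20, each = 2), rep(1:20, each = 2)]   # 2x upsampling
  r2 <- red_blue_ratio(pixmap(lab2, 1))
  expect_equal(r1, r2)
  expect_equal(class_areas(pixmap(lab, 4))[["red"]],
               class_areas(pixmap(lab2, 1))[["red"]])
})

test_that("label maps round-trip through PNG rendering", {
  lab <- matrix(2L, 6, 6)
  lab[2:3, 2:3] <- 1L
  lab[5, ] <- 3L
  tf <- withr::local_tempfile(fileext = ".png")
  write_label_map(pixmap(lab, 1), tf)
  img <- read_section_image(tf)
  cfg <- quant_config(um2_per_pixel = 1)
  back <- classify_pixels(img, cfg)
  expect_equal(back$labels, lab)
})
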
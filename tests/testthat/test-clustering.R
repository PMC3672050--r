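test_that("correlation distance matches hand-computed cases", {
  p <- rbind(a = c(1, 2, 1, 2), b = c(1, 2, 1, 2), c = -c(1, 2, 1, 2),
             d = c(1, 1, 2, 2))
  d <- correlation_distance(p)
  expect_equal(d["a", "b"], 0)          # identical: r = 1
  expect_equal(d["a", "c"], 2)          # negation: r = -1
  expect_equal(d["a", "d"], 1)          # orthogonal patterns: r = 0
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 2))
  expect_error(correlation_distance(rbind(c(1, 1, 1, 1), c(1, 2, 3, 4))),
               "constant")
})

test_that("PAM handles the degenerate and hand-checkable cases", {
  x <- c(0, 1, 10)
  D <- as.matrix(dist(x))
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  # k = 1: candidate costs 11, 10, 19 -> medoid is the middle point
  cl <- pam_cluster(D, 1)
  expect_equal(cl$medoid_ids, "b")
  expect_equal(cl$total_cost, 10)
  # k = n: every point its own medoid at zero cost
  cl3 <- pam_cluster(D, 3)
  expect_equal(cl3$total_cost, 0)
  expect_equal(length(unique(cl3$labels)), 3L)
  expect_error(pam_cluster(D, 4), "exceed")
})

test_that("PAM equals exhaustive medoid search on separated data (n <= 8)", {
  all_centers <- cbind(c(0, 30, 60), c(0, 40, 0))
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(2:3, 1)
    n <- sample((2 * k):8, 1)
    centers <- all_centers[seq_len(k), , drop = FALSE]
    grp <- c(seq_len(k), sample(k, n - k, replace = TRUE))
    pts <- centers[grp, ] + matrix(rnorm(n * 2, sd = 0.3), n)
    D <- as.matrix(dist(pts))
    cl <- pam_cluster(D, k)
    expect_equal(cl$total_cost, brute_force_pam_cost(D, k),
                 tolerance = 1e-10)
    # the separated groups are recovered exactly
    expect_equal(length(unique(cl$labels)), k)
    expect_true(all(tapply(grp, cl$labels, function(g)
      length(unique(g))) == 1L))
  }
})

test_that("two well-separated archetype groups are reproduced at k = 2", {
  cfg <- sim_config(
    archetypes = list(
      archetype_spec("spermatocytes", day = 17, width_days = 3,
                     amp_log2 = -3, n = 30L),
      archetype_spec("somatic", day = 21, width_days = 6,
                     amp_log2 = 2.6, n = 25L)),
    n_noise_transcripts = 0L, rng_seed = 5L)
  res <- run_chain(cfg, normalize = FALSE)
  z <- z_scale_profiles(res$collapsed)
  d <- correlation_distance(z)
  cl <- pam_cluster(d, 2)
  truth <- res$sim$truth$population[match(names(cl$labels),
                                          res$sim$truth$transcript_id)]
  expect_equal(length(unique(paste(truth, cl$labels))), 2L)
})

test_that("median z-profiles obey the membership contracts", {
  set.seed(8)
  v <- matrix(rnorm(4 * 6), 4)
  v[2, ] <- -v[1, ]
  m <- expr_mat(v, days = c(3, 7, 10, 14, 17, 21))
  z <- z_scale_profiles(m)
  # single-member cluster: that member's z-profile
  labels <- stats::setNames(c(1L, 1L, 2L, 3L), rownames(m$values))
  prof <- median_z_profiles(m, labels)
  expect_equal(unname(prof["2", ]), unname(z["t3", ]))
  # two members x and -x: exact cancellation
  expect_equal(unname(prof["1", ]), rep(0, 6))
  labels_gap <- stats::setNames(c(1L, 1L, 3L, 3L), rownames(m$values))
  expect_error(median_z_profiles(m, labels_gap), "empty cluster")
})

test_that("noise-free archetype clusters return the z-scaled archetype", {
  cfg <- sim_config(
    archetypes = list(archetype_spec("spermatocytes", day = 17,
                                     width_days = 3, amp_log2 = -3,
                                     n = 8L)),
    n_noise_transcripts = 0L, probe_noise_sd_log2 = 0,
    amp_jitter = 0, rng_seed = 1L)
  sim <- simulate_expression(cfg)
  # log2 of the noiseless linear signal recovers base + amp * shape exactly
  col <- collapse_probes_median(
    expression_matrix(log2(sim$probes$values), sim$probes$days,
                      scale = "log2"),
    sim$annotation)
  days <- cfg$sampling_days
  shape <- exp(-(days - 17)^2 / (2 * 9))
  zshape <- (shape - mean(shape)) / stats::sd(shape)
  labels <- stats::setNames(rep(1L, nrow(col$values)),
                            rownames(col$values))
  prof <- median_z_profiles(col, labels)
  expect_equal(unname(prof["1", ]), unname(-zshape), tolerance = 1e-9)
})

test_that("choose_k finds the planted number of distinct patterns", {
  # two archetypes -> 2
  cfg2 <- sim_config(
    archetypes = list(
      archetype_spec("spermatocytes", day = 17, width_days = 3,
                     amp_log2 = -3, n = 25L),
      archetype_spec("somatic", day = 21, width_days = 6,
                     amp_log2 = 2.6, n = 25L)),
    n_noise_transcripts = 0L, rng_seed = 3L)
  res2 <- run_chain(cfg2, normalize = FALSE)
  sub2 <- expression_matrix(res2$collapsed$values, res2$collapsed$days,
                            scale = "log2")
  d2 <- correlation_distance(z_scale_profiles(sub2))
  expect_equal(as.integer(choose_k(d2, sub2, k_range = 2:6)), 2L)

  # a single archetype: every split is a duplicate pattern -> 2 + warning
  cfg1 <- sim_config(
    archetypes = list(archetype_spec("spermatocytes", day = 17,
                                     width_days = 3, amp_log2 = -3,
                                     n = 40L)),
    n_noise_transcripts = 0L, rng_seed = 3L)
  res1 <- run_chain(cfg1, normalize = FALSE)
  sub1 <- expression_matrix(res1$collapsed$values, res1$collapsed$days,
                            scale = "log2")
  d1 <- correlation_distance(z_scale_profiles(sub1))
  expect_warning(k1 <- choose_k(d1, sub1, k_range = 2:5), "no k")
  expect_equal(as.integer(k1), 2L)
})

test_that("five archetypes are recovered as five clusters at small scale", {
  res <- run_chain(small_sim_config(seed = 7L))
  picked <- res$selection$transcript_id[res$selection$selected]
  sub <- expression_matrix(res$collapsed$values[picked, , drop = FALSE],
                           res$collapsed$days, scale = "log2")
  d <- correlation_distance(z_scale_profiles(sub))
  k <- choose_k(d, sub)
  expect_equal(as.integer(k), 5L)
  cl <- pam_cluster(d, 5L)
  truth <- res$sim$truth$population[match(names(cl$labels),
                                          res$sim$truth$transcript_id)]
  # every planted population maps to exactly one cluster
  for (p in setdiff(unique(truth), "noise"))
    expect_equal(length(unique(cl$labels[truth == p])), 1L)
})
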
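test_that("enrichment score matches hand-computed values", {
  expect_identical(enrichment_score(c(5, 5, 5, 5)), Inf)
  # |1|+|1|+|1| = 3 over 2.25+0.25+0.25+2.25 = 5
  expect_equal(enrichment_score(c(0, 1, 2, 3)), 0.6)
  # 3 over 4 * 0.25 = 1
  expect_equal(enrichment_score(c(0, 1, 0, 1)), 3.0)
  expect_error(enrichment_score(c(1, 2)), "at least 3")
  expect_error(enrichment_score(c(1, 2, NA)), "finite")
})

test_that("enrichment score is affine-equivariant: ES(c*x + b) = ES(x)/|c|", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(17)
    c0 <- runif(1, -5, 5)
    if (abs(c0) < 0.1) c0 <- 0.5
    b <- rnorm(1, sd = 10)
    expect_equal(enrichment_score(c0 * x + b),
                 enrichment_score(x) / abs(c0), tolerance = 1e-12)
  }
})

test_that("the ES denominator is permutation-invariant (exhaustive n = 4)", {
  x <- c(0.3, 1.7, -2.2, 0.9)
  perms <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
    perms[[length(perms) + 1]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  dens <- vapply(perms, function(p) sum((x[p] - mean(x))^2), numeric(1))
  expect_equal(length(perms), 24L)
  expect_true(all(abs(dens - dens[1]) < 1e-12))
  # while the numerator (hence ES) does change under some orderings
  ess <- vapply(perms, function(p) enrichment_score(x[p]), numeric(1))
  expect_gt(max(ess) - min(ess), 0)
})

test_that("sampled permutation null is drawn from the exhaustive null", {
  # n = 3 profile (0,1,2): the six orderings give ES 1.0 (monotone, twice)
  # or 1.5 (middle value at an end, four times)
  x <- c(0, 1, 2)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  exhaustive <- sort(vapply(perms, function(p) enrichment_score(x[p]),
                            numeric(1)))
  expect_equal(exhaustive, c(1, 1, 1.5, 1.5, 1.5, 1.5))

  m <- expr_mat(rbind(x, c(4, 4, 4)), days = c(3, 7, 10))
  null <- permutation_null(m, selection_config(n_permutations = 60L,
                                               rng_seed = 9L))
  expect_true(all(null[1, ] %in% c(1, 1.5)))
  expect_true(all(c(1, 1.5) %in% null[1, ]))
  # constant profile: order-invariant, all null values infinite
  expect_true(all(is.infinite(null[2, ])))
})

test_that("shared-ordering null applies one ordering to all transcripts", {
  set.seed(3)
  m <- expr_mat(matrix(rnorm(5 * 6), 5), days = c(3, 7, 10, 14, 17, 21))
  cfg <- selection_config(n_permutations = 4L, rng_seed = 2L)
  null <- permutation_null(m, cfg)
  ords <- attr(null, "orderings")
  for (p in 1:4) for (i in 1:5)
    expect_equal(unname(null[i, p]),
                 enrichment_score(m$values[i, ords[, p]]))
})

test_that("q-values follow the plug-in FDR with cumulative-minimum smoothing", {
  # hand oracle: raw FDR 0/1, 1/2, 3/3 -> q = 0, 0.5, 1
  q <- fdr_curve(c(0.1, 0.2, 0.9), c(0.15, 0.8, 0.85), n_permutations = 1L)
  expect_equal(q, c(0, 0.5, 1))
  # every null above every observation: no null exceedances anywhere
  q2 <- fdr_curve(c(0.1, 0.2, 0.3), matrix(5 + runif(9), 3))
  expect_equal(q2, c(0, 0, 0), ignore_attr = TRUE)
  # saturated null: the observations are their own null
  obs <- c(0.4, 1.2, 2.2, 3.1)
  expect_equal(fdr_curve(obs, obs, n_permutations = 1L), rep(1, 4))
  expect_error(fdr_curve(obs, numeric(0), n_permutations = 1L), "empty")
})

test_that("q-values are monotone non-decreasing in the score", {
  set.seed(21)
  for (i in 1:10) {
    obs <- rexp(200)
    null <- matrix(rexp(200 * 5), 200)
    q <- fdr_curve(obs, null)
    expect_true(all(diff(q[order(obs)]) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("extreme-point dispersion is the probe CV at the extreme day", {
  profile <- c(1, 1, 10)
  probes <- rbind(c(1, 1, 9), c(1, 1, 10), c(1, 1, 11))
  expect_equal(extreme_sd(profile, probes), 10)        # SD 1 of 10
  probes2 <- rbind(c(1, 1, 8), c(1, 1, 10), c(1, 1, 12))
  expect_equal(extreme_sd(profile, probes2), 20)       # SD 2, fails 15%
  expect_equal(extreme_sd(profile, matrix(c(1, 1, 10), 1)), 0)  # 1 probe
  profile0 <- c(5, 5, 0)
  expect_identical(extreme_sd(profile0, rbind(c(5, 5, -1), c(5, 5, 1))),
                   Inf)
})

test_that("selection keeps planted archetypes and rejects pure noise", {
  # background-only matrix: the observed scores are their own null
  noise_cfg <- sim_config(
    archetypes = list(), n_noise_transcripts = 400L, rng_seed = 42L)
  res <- run_chain(noise_cfg)
  expect_equal(sum(res$selection$selected), 0L)

  # planted-only matrix: the shuffled null dominates every observed score
  planted_cfg <- small_sim_config(seed = 42L, n_noise = 0L)
  res2 <- run_chain(planted_cfg, normalize = FALSE)
  expect_true(all(res2$selection$selected))
})

test_that("selection on planted plus noise recovers the planting", {
  res <- run_chain(small_sim_config(seed = 42L))
  truth <- res$sim$truth[match(res$selection$transcript_id,
                               res$sim$truth$transcript_id), ]
  planted <- truth$population != "noise"
  # every planted transcript is kept, background leakage is marginal
  expect_true(all(res$selection$selected[planted]))
  expect_lt(sum(res$selection$selected[!planted]), 0.01 * sum(!planted))
  expect_true(all(res$selection$q_value >= 0 & res$selection$q_value <= 1))
  # determinism contract
  res2 <- run_chain(small_sim_config(seed = 42L))
  expect_identical(res$selection$es, res2$selection$es)
  expect_identical(res$selection$selected, res2$selection$selected)
})
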
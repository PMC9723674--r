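test_that("tree and trait simulation is deterministic and conservatism-tunable", {
  a <- simulate_tree_traits(50, seed = 1)
  b <- simulate_tree_traits(50, seed = 1)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$traits, b$traits)
  expect_error(simulate_tree_traits(3), "at least 4")
  expect_error(simulate_tree_traits(10, conservatism = 0), "conservatism")

  # full conservatism: trait distance correlates with phylogeny
  # (first-class Mantel signal); near-zero conservatism: mostly not
  sim <- simulate_tree_traits(50, seed = 1, conservatism = 1)
  pd <- patristic_distances(sim$tree)
  res <- mantel_correlogram(sim$traits[rownames(pd)], pd, n_classes = 5,
                            n_perm = 199, seed = 2)
  expect_lt(res$p[1], 0.05)

  hits <- 0L
  for (s in 1:10) {
    w <- simulate_tree_traits(50, seed = s + 100, conservatism = 0.02)
    pdw <- patristic_distances(w$tree)
    rw <- mantel_correlogram(w$traits[rownames(pdw)], pdw, n_classes = 5,
                             n_perm = 199, seed = s)
    if (rw$p[1] < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})

test_that("drift sites are plain multinomial draws from the pool", {
  # chi-squared goodness of fit against J * p, small-expectation OTUs lumped
  n_sig <- 0L
  n_tests <- 0L
  for (s in 1:50) {
    sim <- simulate_tree_traits(50, seed = s)
    set.seed(s + 900)
    pool <- lognormal_pool(50)
    comm <- simulate_community(sim, regime_spec("drift", J = 5000), 2,
                               seed = s + 1800, pool = pool)
    expected <- 5000 * pool
    lump <- expected < 5
    for (site in 1:2) {
      obs <- comm[site, !lump]
      ex <- expected[!lump]
      if (any(lump)) {
        obs <- c(obs, sum(comm[site, lump]))
        ex <- c(ex, sum(expected[lump]))
      }
      stat <- sum((obs - ex)^2 / ex)
      p <- stats::pchisq(stat, length(ex) - 1, lower.tail = FALSE)
      n_tests <- n_tests + 1L
      if (p < 0.01) n_sig <- n_sig + 1L
    }
  }
  expect_gte(1 - n_sig / n_tests, 0.95)
})

test_that("vanishing selection width concentrates each site on one OTU", {
  sim <- simulate_tree_traits(30, seed = 4)
  spec <- regime_spec("selection_homogeneous", sigma_sel = 1e-4,
                      e_site = 0.5, e_jitter = 0, site_noise_sd = 0)
  comm <- simulate_community(sim, spec, 4, seed = 5)
  winner <- names(which.min(abs(sim$traits - 0.5)))
  for (s in 1:4) expect_equal(unname(comm[s, winner]), 1000L)
})

test_that("complete homogenizing dispersal makes all sites identical", {
  sim <- simulate_tree_traits(40, seed = 6)
  spec <- regime_spec("homogenizing_dispersal", m = 1)
  comm <- simulate_community(sim, spec, 5, seed = 7)
  for (s in 2:5) expect_identical(comm[s, ], comm[1, ])
  bc <- as.matrix(vegan::vegdist(comm, "bray"))
  expect_true(all(bc == 0))
  expect_true(all(rowSums(comm) == 1000))  # totals preserved by rounding
})

test_that("community simulation is seed-reproducible and validated", {
  sim <- simulate_tree_traits(30, seed = 8)
  a <- simulate_community(sim, regime_spec("dispersal_limited"), 6, seed = 9)
  b <- simulate_community(sim, regime_spec("dispersal_limited"), 6, seed = 9)
  expect_identical(a, b)
  expect_error(regime_spec("drift", J = 0), "at least 1")
  expect_error(regime_spec("blorp"), "arg")
})

test_that("predictor sets share variance as configured", {
  md <- simulate_metadata()
  # shared_fraction 0 (and no disturbance shift): sets nearly uncorrelated
  r0 <- sapply(1:20, function(s) {
    p <- simulate_predictors(md, shared_fraction = 0, seed = s,
                             disturbance_effect = 0)
    mean(abs(stats::cor(p$soil, log(p$vegetation))))
  })
  expect_lt(stats::median(r0), 0.2)

  # shared_fraction 1: both sets are transforms of the same latent factors,
  # so soil columns are (nearly) linear in the vegetation latents
  p1 <- simulate_predictors(md, shared_fraction = 1, seed = 3,
                            disturbance_effect = 0, noise_sd = 0)
  r1 <- sapply(1:20, function(s) {
    p <- simulate_predictors(md, shared_fraction = 1, seed = s,
                             disturbance_effect = 0)
    mean(abs(stats::cor(p$soil, log(p$vegetation))))
  })
  expect_gt(stats::median(r1), stats::median(r0) + 0.2)
  fit <- stats::lm(p1$soil[, 1] ~ log(p1$vegetation[, 1:2]))
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.99)

  a <- simulate_predictors(md, 0.5, seed = 11)
  b <- simulate_predictors(md, 0.5, seed = 11)
  expect_identical(a, b)
})

test_that("full dataset generation is a pure function of (config, seed)", {
  a <- simulate_dataset(seed = 5, S = 40, J = 200)
  b <- simulate_dataset(seed = 5, S = 40, J = 200)
  expect_identical(a$comm, b$comm)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$soil, b$soil)

  expect_equal(dim(a$comm), c(48, 40))
  expect_equal(nrow(a$metadata), 48)
  expect_equal(length(unique(a$metadata$watershed)), 8)
  expect_equal(sort(as.integer(table(a$metadata$history))), c(24L, 24L))
  # regimes cover every watershed; disturbed ones carry selection
  expect_setequal(names(a$truth$regimes), unique(a$metadata$watershed))
  dist_ws <- unique(a$metadata$watershed[a$metadata$history == "disturbed"])
  expect_true(all(grepl("^selection", a$truth$regimes[dist_ws])))
})

test_that("written datasets round-trip through the file readers", {
  ds <- simulate_dataset(seed = 2, S = 30, J = 100)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  tree <- read_tree(file.path(dir, "tree.nwk"))
  comm <- read_community(file.path(dir, "community.tsv"))
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  soil <- read_predictors(file.path(dir, "soil.tsv"))
  expect_setequal(tree$tip.label, colnames(ds$comm))
  expect_equal(unname(comm), unname(ds$comm), ignore_attr = TRUE)
  expect_equal(md$sample_id, ds$metadata$sample_id)
  expect_equal(unname(soil), unname(ds$soil), tolerance = 1e-12)
})

test_that("stronger filtering raises the selection call rate monotonically", {
  # selection share of pairs per sigma_sel level, betaNTI only (RC set to 0
  # cannot create or destroy selection labels)
  sel_rate <- function(sigma, seed) {
    sim <- simulate_tree_traits(100, seed = seed * 2 + 1)
    set.seed(seed + 500)
    pool <- lognormal_pool(100)
    comm <- simulate_community(sim,
                               regime_spec("selection_homogeneous",
                                           sigma_sel = sigma),
                               8, seed = seed + 1000, pool = pool)
    b <- suppressWarnings(bnti(comm, sim$tree, n_reps = 99,
                               seed = seed + 2000))
    calls <- suppressMessages(
      classify_processes(b$bnti, b$bnti * 0))
    # blocks where every pair is degenerate carry no call information
    if (nrow(calls) == 0L) NA_real_ else
      mean(grepl("selection", calls$process))
  }
  levels <- c(0.15, 0.6, 2.5)
  means <- vapply(levels, function(sg)
    mean(vapply(1:10, function(s) sel_rate(sg, s), numeric(1)),
         na.rm = TRUE), numeric(1))
  expect_gt(means[1], means[2] - 0.02)
  expect_gt(means[2], means[3] - 0.02)
  expect_gt(means[1], means[3] + 0.1)
})
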
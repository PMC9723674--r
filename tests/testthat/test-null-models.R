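test_that("beta-MNTD matches hand computations on the toy tree", {
  tree <- toy_tree()
  D <- patristic_distances(tree)[c("A", "B", "C"), c("A", "B", "C")]

  # identical communities: every minimum is 0
  expect_equal(beta_mntd(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5), D), 0)
  # singletons: the patristic distance itself
  expect_equal(beta_mntd(c(1, 0, 0), c(0, 1, 0), D), 2)
  # {A} vs {B:0.5, C:0.5}: 0.5*[1*2 + 0.5*2 + 0.5*2] = 2
  expect_equal(beta_mntd(c(1, 0, 0), c(0, 0.5, 0.5), D), 2)

  expect_error(beta_mntd(c(0, 0, 0), c(1, 0, 0), D), "empty|sum to 1")
})

test_that("beta-MNTD matrix agrees with an independent slow oracle", {
  set.seed(7)
  tree <- ape::rphylo(12, birth = 1, death = 0)
  tree$tip.label <- sprintf("t%02d", 1:12)
  comm <- small_comm(tree, n_samples = 5, J = 40, seed = 2)
  f <- relative_abundance(comm)
  D <- patristic_distances(tree)[colnames(comm), colnames(comm)]
  got <- beta_mntd_matrix(comm, tree)
  for (a in 1:4) for (b in (a + 1):5)
    expect_equal(got[a, b], oracle_beta_mntd(f[a, ], f[b, ], D),
                 tolerance = 1e-12)
  expect_equal(got, t(got))
})

test_that("beta-MNTD matrix agrees with picante::comdistnt", {
  skip_if_not_installed("picante")
  set.seed(3)
  tree <- ape::rphylo(20, birth = 1, death = 0)
  tree$tip.label <- sprintf("t%02d", 1:20)
  comm <- small_comm(tree, n_samples = 6, J = 100, seed = 4)
  D <- patristic_distances(tree)[colnames(comm), colnames(comm)]
  mine <- beta_mntd_matrix(comm, tree)
  ref <- as.matrix(picante::comdistnt(comm, D, abundance.weighted = TRUE))
  expect_equal(unname(mine), unname(ref[rownames(mine), colnames(mine)]),
               tolerance = 1e-10)
})

test_that("requires at least 3 taxa for phylogenetic turnover", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  comm <- matrix(c(1L, 1L, 1L, 1L), 2, 2,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_error(beta_mntd_matrix(comm, tree), "at least 3 taxa")
})

test_that("sampled betaNTI null matches the exhaustive tip-permutation null", {
  # 4-tip tree: all 4! = 24 permutations enumerable with the slow oracle
  tree <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:0.5):2);")
  D <- patristic_distances(tree)[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
  comm <- matrix(c(5L, 3L, 0L, 1L,
                   0L, 2L, 6L, 2L), 2, 4, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  f <- relative_abundance(comm)

  perms <- all_perms(4)
  exhaustive <- apply(perms, 1, function(p)
    oracle_beta_mntd(f[1, ], f[2, ], D[p, p]))
  exact_mean <- mean(exhaustive)
  exact_sd <- sd(exhaustive)

  res <- bnti(comm, tree, n_reps = 999, seed = 11, keep_null = TRUE)
  sampled <- res$null[1, ]
  expect_equal(mean(sampled), exact_mean,
               tolerance = 2 * exact_sd / sqrt(999) / exact_mean + 1e-12)
  expect_lt(abs(sd(sampled) - exact_sd) / exact_sd, 0.10)
  # observed statistic standardized consistently
  expect_equal(res$bnti[2, 1],
               (res$beta_mntd_obs[2, 1] - mean(sampled)) / sd(sampled))
})

test_that("star phylogeny degenerates the null and yields NaN betaNTI", {
  tree <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  comm <- matrix(c(3L, 1L, 0L, 0L,
                   0L, 0L, 2L, 2L), 2, 4, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  expect_warning(res <- bnti(comm, tree, n_reps = 99, seed = 1),
                 "degenerate null")
  expect_true(is.nan(res$bnti[2, 1]))
})

test_that("betaNTI is symmetric, masked on the diagonal, and reproducible", {
  set.seed(5)
  tree <- ape::rphylo(15, birth = 1, death = 0)
  tree$tip.label <- sprintf("t%02d", 1:15)
  comm <- small_comm(tree, n_samples = 5, J = 60, seed = 6)
  r1 <- bnti(comm, tree, n_reps = 99, seed = 42)
  r2 <- bnti(comm, tree, n_reps = 99, seed = 42)
  expect_identical(r1$bnti, r2$bnti)           # bit-reproducible
  expect_equal(r1$bnti, t(r1$bnti))
  expect_true(all(is.na(diag(r1$bnti))))
  expect_error(bnti(comm, tree, n_reps = 50), "at least 99")
})

test_that("data generated by the null itself is rarely called selection", {
  # held-out null replicates standardized against the rest of the ensemble
  # are draws from the null treated as observed
  set.seed(9)
  tree <- ape::rphylo(30, birth = 1, death = 0)
  tree$tip.label <- sprintf("t%02d", 1:30)
  comm <- small_comm(tree, n_samples = 10, J = 200, seed = 10)
  res <- bnti(comm, tree, n_reps = 999, seed = 13, keep_null = TRUE)

  n_draws <- 200
  obs <- res$null[, seq_len(n_draws), drop = FALSE]
  ref <- res$null[, -seq_len(n_draws), drop = FALSE]
  z <- (obs - rowMeans(ref)) / apply(ref, 1, sd)
  expect_gte(mean(abs(z) <= 2), 0.90)
})

test_that("Bray-Curtis follows its closed form", {
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(bray_curtis(c(5, 0, 0), c(0, 2, 3)), 1)
  expect_equal(bray_curtis(c(6, 0, 2), c(2, 2, 0)), 2 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "empty")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("RC-Bray hits its exact extremes", {
  # identical pair in a rich table: observed BC = 0 below every null -> -1;
  # disjoint pair: observed BC = 1 above every null -> +1
  set.seed(21)
  base <- t(stats::rmultinom(4, 600, prob = runif(30) + 0.5))
  comm <- rbind(base[1, ], base[1, ],                      # identical pair
                c(rep(40L, 15), rep(0L, 15)),              # disjoint pair
                c(rep(0L, 15), rep(40L, 15)),
                base[2:4, ])
  dimnames(comm) <- list(sprintf("s%d", 1:7), sprintf("o%02d", 1:30))
  storage.mode(comm) <- "integer"
  res <- rc_bray(comm, n_reps = 199, seed = 3)
  expect_equal(res$rc["s1", "s2"], -1)
  expect_equal(res$rc["s3", "s4"], 1)
  expect_true(all(res$rc >= -1 & res$rc <= 1))
  expect_equal(res$rc, t(res$rc))

  # single-OTU pool: every null equals the observed dissimilarity -> 0
  one <- matrix(c(10L, 30L), 2, 1, dimnames = list(c("a", "b"), "o1"))
  expect_equal(rc_bray(one, n_reps = 99, seed = 1)$rc["a", "b"], 0)
})

test_that("RC-Bray is seed-reproducible and rejects non-count input", {
  set.seed(31)
  comm <- small_comm(ape::rphylo(10, 1, 0), n_samples = 5, J = 80, seed = 32)
  colnames(comm) <- sprintf("o%02d", 1:10)
  r1 <- rc_bray(comm, n_reps = 99, seed = 5)
  r2 <- rc_bray(comm, n_reps = 99, seed = 5)
  expect_identical(r1$rc, r2$rc)
  expect_error(rc_bray(comm / rowSums(comm), n_reps = 99), "integer counts")
})
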
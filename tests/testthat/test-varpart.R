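test_that("PCoA response reconstructs Euclidean geometry", {
  set.seed(1)
  Z <- matrix(rnorm(20 * 3), 20, 3)
  D <- as.matrix(dist(Z))
  rownames(D) <- colnames(D) <- sprintf("s%02d", 1:20)
  Y <- bnti_to_response(D)
  expect_equal(as.matrix(dist(Y)), D, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(attr(Y, "shift"), 0)          # already non-negative: no shift
  expect_equal(attr(Y, "negative_mass"), 0)

  # constant positive off-diagonal: simplex with n-1 equal eigenvalues
  C <- matrix(3, 6, 6); diag(C) <- 0
  rownames(C) <- colnames(C) <- letters[1:6]
  Yc <- bnti_to_response(C)
  eig <- attr(Yc, "eig")
  expect_equal(sum(eig > 1e-8), 5)
  expect_lt(diff(range(eig[eig > 1e-8])) / max(eig), 1e-8)

  # negative entries are shifted so the off-diagonal minimum becomes 0
  B <- as.matrix(dist(rnorm(8))) - 2
  diag(B) <- 0
  rownames(B) <- colnames(B) <- letters[1:8]
  Yb <- bnti_to_response(B)
  shifted <- B + attr(Yb, "shift")
  expect_equal(min(shifted[lower.tri(shifted)]), 0)

  Z0 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_error(bnti_to_response(Z0), "degenerate response")
})

test_that("adjusted R2 follows the Ezekiel form and its monotonicities", {
  expect_equal(adjusted_r2(1, 30, 4), 1)
  expect_equal(adjusted_r2(0.4, 30, 0), 0.4)         # m = 0: identity
  expect_equal(adjusted_r2(0.5, 10, 2), 1 - 0.5 * 9 / 7)
  expect_error(adjusted_r2(0.5, 5, 4), "n > m")
  r2s <- seq(0.1, 0.9, by = 0.2)
  expect_true(all(diff(vapply(r2s, adjusted_r2, numeric(1),
                              n = 20, m = 3)) > 0))
  ms <- 1:6
  expect_true(all(diff(vapply(ms, function(m) adjusted_r2(0.5, 20, m),
                              numeric(1))) < 0))
})

test_that("dbRDA matches classical RDA on Euclidean responses", {
  set.seed(4)
  n <- 30
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("s%02d", 1:n), c("x1", "x2", "x3")))
  coords <- cbind(X %*% c(1, -0.5, 0.2), rnorm(n), rnorm(n))
  D <- as.matrix(dist(coords))
  rownames(D) <- colnames(D) <- rownames(X)
  Y <- bnti_to_response(D)
  fit <- db_rda(Y, X, n_perm = 0)

  ref <- vegan::rda(coords ~ X)               # independent classical oracle
  expect_equal(fit$r2, unname(vegan::RsquareAdj(ref)$r.squared),
               tolerance = 1e-10)
  expect_equal(fit$adj_r2, unname(vegan::RsquareAdj(ref)$adj.r.squared),
               tolerance = 1e-10)
  expect_equal(fit$r2, sum(fit$eig) / sum(scale(Y, scale = FALSE)^2),
               tolerance = 1e-10)
})

test_that("dbRDA permutation tests behave at the extremes", {
  set.seed(6)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(NULL, c("a", "b")))
  # noiseless linear response: perfect fit, minimal p
  Y <- cbind(X %*% c(2, 1), X %*% c(-1, 3))
  fit <- db_rda(Y, X, n_perm = 99, seed = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$p_global, 1 / 100)

  # orthogonal (independent) predictors: small adjusted R2, large p
  stats_ortho <- t(sapply(1:20, function(s) {
    set.seed(s)
    Yr <- matrix(rnorm(n * 2), n, 2)
    Xr <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    f <- db_rda(Yr, Xr, n_perm = 99, seed = s)
    c(adj = f$adj_r2, p = f$p_global)
  }))
  expect_lte(stats::median(stats_ortho[, "adj"]), 0.05)
  expect_gt(stats::median(stats_ortho[, "p"]), 0.1)
})

test_that("aliased and constant predictors are dropped with a warning", {
  set.seed(7)
  n <- 20
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  X <- cbind(X, x3 = X[, "x1"] + X[, "x2"], cst = 1)
  Y <- matrix(rnorm(n * 2), n, 2)
  expect_warning(expect_warning(fit <- db_rda(Y, X, n_perm = 0),
                                "constant"), "aliased")
  expect_equal(fit$rank, 2L)
})

test_that("variation-partitioning arithmetic is exact", {
  fr <- varpart_fractions(0.24, 0.33, 0.38)
  expect_equal(unname(fr["unique_1"] + fr["shared"] + fr["unique_2"]), 0.38,
               tolerance = 1e-10)
  expect_equal(unname(fr["residual"]), 1 - 0.38)

  # identical predictor sets: no unique fractions, everything shared
  set.seed(8)
  n <- 25
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("v1", "v2")))
  Y <- cbind(X %*% c(1, 1) + rnorm(n), rnorm(n))
  X2 <- X; colnames(X2) <- c("w1", "w2")
  vp <- suppressWarnings(two_set_varpart(Y, X, X2, n_perm = 0))
  expect_equal(vp$fractions[["unique_1"]], 0, tolerance = 1e-10)
  expect_equal(vp$fractions[["unique_2"]], 0, tolerance = 1e-10)
  expect_equal(vp$fractions[["shared"]], vp$fits$soil$adj_r2,
               tolerance = 1e-10)
})

test_that("two-set varpart on betaNTI-like input produces the full table", {
  set.seed(9)
  ds <- simulate_dataset(seed = 9, S = 40, J = 200)
  b <- suppressWarnings(bnti(ds$comm, ds$tree, n_reps = 99, seed = 2))
  m <- b$bnti
  diag(m) <- 0
  m[!is.finite(m)] <- 0
  vp <- two_set_varpart(m, ds$soil, ds$vegetation, n_perm = 99, seed = 3)
  expect_equal(vp$table$partition,
               c("Soil", "Vegetation", "Soil + Vegetation",
                 "Soil | Vegetation", "Vegetation | Soil",
                 "Soil ∩ Vegetation", "Residuals"))
  fr <- vp$fractions
  T_ <- vp$fits$both$adj_r2
  expect_equal(unname(fr["unique_1"] + fr["shared"] + fr["unique_2"]), T_,
               tolerance = 1e-10)
  expect_equal(vp$table$adj_r2[7], 1 - T_)
  expect_true(is.na(vp$table$p[6]))           # shared fraction untestable
  expect_true(all(vp$table$p[1:5] >= 1 / 100, na.rm = TRUE))

  vp2 <- two_set_varpart(m, ds$soil, ds$vegetation, n_perm = 99, seed = 3)
  expect_identical(vp$table, vp2$table)       # seed-reproducible
})

test_that("per-variable tests flag a planted signal and hold type I error", {
  set.seed(10)
  n <- 48
  flags_signal <- 0L
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    Y <- cbind(X[, 1] * 2 + rnorm(n, sd = 0.5), rnorm(n))
    f <- db_rda(Y, X, n_perm = 99, seed = s)
    if (f$p_variables[["v1"]] < 0.05) flags_signal <- flags_signal + 1L
  }
  expect_gte(flags_signal, 18L)

  false_flags <- integer(20)
  for (s in 1:20) {
    set.seed(s + 100)
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    Y <- matrix(rnorm(n * 2), n, 2)
    f <- db_rda(Y, X, n_perm = 99, seed = s)
    false_flags[s] <- sum(f$p_variables < 0.05)
  }
  # mean flagged ~ 6 * 0.05 = 0.3 per run; binomial band over 120 tests
  rate <- sum(false_flags) / (20 * 6)
  expect_lt(abs(rate - 0.05), 2.5 * sqrt(0.05 * 0.95 / 120) + 0.01)
})
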
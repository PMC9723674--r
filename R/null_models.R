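#' Beta mean nearest taxon distance between two communities
#'
#' Abundance-weighted mean patristic distance from each taxon in one
#' community to its nearest relative in the other:
#' \deqn{\beta MNTD = \frac{1}{2}\left[\sum_{i \in A} f_i^A \min_{j \in B}
#'   D_{ij} + \sum_{j \in B} f_j^B \min_{i \in A} D_{ij}\right]}
#' Taxa shared by both communities contribute zero to their own minimum.
#'
#' @param f_a,f_b Relative-abundance vectors over the same taxon set,
#'   each summing to 1.
#' @param D Patristic distance matrix (symmetric, zero diagonal) over the
#'   same taxa, in the same order.
#' @return A non-negative scalar.
#' @export
beta_mntd <- function(f_a, f_b, D) {
  S <- length(f_a)
  if (length(f_b) != S || nrow(D) != S || ncol(D) != S)
    stop("abundance vectors and distance matrix must agree in length")
  if (sum(f_a) == 0 || sum(f_b) == 0) stop("empty community")
  if (abs(sum(f_a) - 1) > 1e-8 || abs(sum(f_b) - 1) > 1e-8)
    stop("abundance vectors must sum to 1")
  F <- rbind(f_a, f_b)
  m <- cpp_pair_mntd(unname(D), unname(F), seq_len(S) - 1L)
  m[1L, 2L]
}

#' Pairwise beta-MNTD matrix for a community table
#'
#' @param comm Sample x OTU matrix (counts or relative abundances).
#' @param tree Tree whose tips exactly match `colnames(comm)` (see
#'   [harmonize()]).
#' @param weighted Abundance-weighted (default)? If `FALSE`, every taxon
#'   present in a sample gets equal weight.
#' @return Symmetric sample x sample matrix of beta-MNTD values.
#' @export
beta_mntd_matrix <- function(comm, tree, weighted = TRUE) {
  D <- align_distances(comm, tree)
  F <- mntd_weights(comm, weighted)
  out <- cpp_pair_mntd(unname(D), unname(F), seq_len(ncol(comm)) - 1L)
  dimnames(out) <- list(rownames(comm), rownames(comm))
  out
}

#' @keywords internal
align_distances <- function(comm, tree) {
  validate_tree(tree)
  if (ncol(comm) < 3L)
    stop("phylogenetic turnover needs at least 3 taxa")
  if (!setequal(tree$tip.label, colnames(comm)))
    stop("tree tips and table OTUs differ; run harmonize() first")
  stats::cophenetic(tree)[colnames(comm), colnames(comm)]
}

#' @keywords internal
mntd_weights <- function(comm, weighted) {
  if (weighted) relative_abundance(comm)
  else {
    P <- (comm > 0) * 1
    P / rowSums(P)
  }
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardizes observed beta-MNTD against a null distribution generated by
#' shuffling taxa across the tips of the phylogeny (regional-scale taxa
#' shuffle): each null replicate applies one random permutation of tip
#' labels — shared by all sample pairs — and recomputes beta-MNTD with
#' abundances untouched. The index is
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \bar{\beta MNTD}_{null}) / sd(\beta MNTD_{null})}
#' Values below -2 indicate less phylogenetic turnover than expected
#' (homogeneous selection), above +2 more than expected (variable
#' selection); the diagonal is undefined and masked as `NA`.
#'
#' @param comm Sample x OTU matrix; OTUs must match the tree tips.
#' @param tree Harmonized [ape::phylo].
#' @param n_reps Null replicates, at least 99. Default 999.
#' @param seed Integer seed for the permutations.
#' @param weighted Abundance-weighted beta-MNTD (default `TRUE`).
#' @param keep_null Return the full null ensemble (pairs x replicates)?
#' @return An object of class `bnti_result`: list with `bnti` (sample x
#'   sample matrix, `NA` diagonal, `NaN` where the null sd is 0),
#'   `beta_mntd_obs`, `null_mean`, `null_sd`, and optionally `null` (a
#'   lower-triangle-pairs x replicates matrix).
#' @export
bnti <- function(comm, tree, n_reps = 999L, seed = NULL, weighted = TRUE,
                 keep_null = FALSE) {
  if (n_reps < 99L) stop("n_reps must be at least 99")
  D <- align_distances(comm, tree)
  F <- mntd_weights(comm, weighted)
  S <- ncol(comm)
  n <- nrow(comm)
  if (!is.null(seed)) set.seed(seed)

  obs <- cpp_pair_mntd(unname(D), unname(F), seq_len(S) - 1L)
  lower <- lower.tri(obs)
  sum_x <- matrix(0, n, n)
  sum_x2 <- matrix(0, n, n)
  null_store <- if (keep_null) matrix(NA_real_, sum(lower), n_reps) else NULL
  for (r in seq_len(n_reps)) {
    perm <- sample.int(S) - 1L
    nul <- cpp_pair_mntd(unname(D), unname(F), perm)
    sum_x <- sum_x + nul
    sum_x2 <- sum_x2 + nul * nul
    if (keep_null) null_store[, r] <- nul[lower]
  }
  mu <- sum_x / n_reps
  va <- (sum_x2 - n_reps * mu^2) / (n_reps - 1)
  sdv <- sqrt(pmax(va, 0))
  z <- (obs - mu) / sdv
  z[!is.finite(z)] <- NaN
  diag(z) <- NA_real_
  if (any(sdv[lower] == 0))
    warning("degenerate null (sd = 0) for ", sum(sdv[lower] == 0),
            " pair(s); betaNTI reported as NaN")
  dimnames(z) <- dimnames(obs) <- dimnames(mu) <- dimnames(sdv) <-
    list(rownames(comm), rownames(comm))
  structure(list(bnti = z, beta_mntd_obs = obs, null_mean = mu,
                 null_sd = sdv, n_reps = n_reps, null = null_store),
            class = "bnti_result")
}

#' @export
print.bnti_result <- function(x, ...) {
  v <- x$bnti[lower.tri(x$bnti)]
  cat("betaNTI over", length(v), "sample pairs (", x$n_reps, "null replicates )\n")
  cat(sprintf("  range %.2f .. %.2f; |betaNTI| > 2 for %d pair(s)\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              sum(abs(v) > 2, na.rm = TRUE)))
  invisible(x)
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' \eqn{BC = 1 - 2 \sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)}.
#'
#' @param x,y Non-negative count vectors of equal length, not both empty.
#' @return A value in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both communities are empty")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Raup-Crick null on Bray-Curtis dissimilarity (RC-Bray)
#'
#' For each sample pair, compares the observed Bray-Curtis dissimilarity
#' with a null distribution in which both samples are probabilistically
#' reassembled from the regional pool: a sample of richness k draws k
#' distinct OTUs with probability proportional to occupancy (number of
#' samples in which the OTU occurs), then allocates its observed total
#' count among the drawn OTUs by a multinomial with probabilities
#' proportional to dataset-wide relative abundance. The two samples of a
#' pair are reassembled independently. The statistic is
#' \deqn{RC = 2\left[(n_{<} + 0.5\, n_{=})/n_{reps} - 0.5\right] \in [-1, 1]}
#' where \eqn{n_<} and \eqn{n_=} count null values below and equal to the
#' observed one (equality after rounding to 12 decimals). Values above
#' +0.95 among phylogenetically null pairs indicate dispersal limitation
#' (+ drift), below -0.95 homogenizing dispersal.
#'
#' @param comm Sample x OTU matrix of counts (not proportions).
#' @param n_reps Null replicates, at least 99. Default 999.
#' @param seed Integer seed.
#' @return Object of class `rcbray_result`: list with `rc` (sample x
#'   sample matrix in \[-1, 1\], zero diagonal), `bray_obs`, `n_reps`.
#' @export
rc_bray <- function(comm, n_reps = 999L, seed = NULL) {
  if (n_reps < 99L) stop("n_reps must be at least 99")
  if (isTRUE(attr(comm, "relative")) || any(comm %% 1 != 0))
    stop("rc_bray needs integer counts, not relative abundances")
  n <- nrow(comm)
  S <- ncol(comm)
  occ <- colSums(comm > 0)
  if (all(occ == 0)) stop("empty table")
  p_reg <- colSums(comm) / sum(comm)
  rich <- rowSums(comm > 0)
  tot <- rowSums(comm)
  if (any(rich > sum(occ > 0)))
    stop("sample richness exceeds regional pool size")
  if (!is.null(seed)) set.seed(seed)

  obs <- as.matrix(vegan::vegdist(comm, method = "bray"))
  obs_r <- round(obs, 12)
  n_lt <- matrix(0L, n, n)
  n_eq <- matrix(0L, n, n)
  pool <- which(occ > 0)
  null_comm <- matrix(0, n, S)
  for (r in seq_len(n_reps)) {
    null_comm[] <- 0
    for (s in seq_len(n)) {
      chosen <- if (length(pool) == 1L) pool else
        pool[sample.int(length(pool), rich[s], prob = occ[pool])]
      pr <- p_reg[chosen]
      null_comm[s, chosen] <- stats::rmultinom(1L, tot[s], pr / sum(pr))
    }
    bc <- round(as.matrix(vegan::vegdist(null_comm, method = "bray")), 12)
    n_lt <- n_lt + (bc < obs_r)
    n_eq <- n_eq + (bc == obs_r)
  }
  rc <- 2 * ((n_lt + 0.5 * n_eq) / n_reps - 0.5)
  diag(rc) <- 0
  dimnames(rc) <- dimnames(obs) <- list(rownames(comm), rownames(comm))
  structure(list(rc = rc, bray_obs = obs, n_reps = n_reps),
            class = "rcbray_result")
}

#' @export
print.rcbray_result <- function(x, ...) {
  v <- x$rc[lower.tri(x$rc)]
  cat("RC-Bray over", length(v), "sample pairs (", x$n_reps, "null replicates )\n")
  cat(sprintf("  range %.3f .. %.3f; |RC| > 0.95 for %d pair(s)\n",
              min(v), max(v), sum(abs(v) > 0.95)))
  invisible(x)
}

#' Long-format view of a pairwise sample statistic
#'
#' @param mat Symmetric sample x sample matrix.
#' @param value_name Column name for the statistic.
#' @return data.frame with columns `sample_i`, `sample_j`, `value_name`,
#'   one row per unordered pair.
#' @export
pairs_long <- function(mat, value_name = "value") {
  idx <- which(lower.tri(mat), arr.ind = TRUE)
  out <- data.frame(sample_i = rownames(mat)[idx[, "row"]],
                    sample_j = colnames(mat)[idx[, "col"]],
                    value = mat[idx], stringsAsFactors = FALSE)
  names(out)[3L] <- value_name
  out
}
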
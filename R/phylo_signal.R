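#' Abundance-weighted niche value per OTU
#'
#' The niche value of OTU i for an environmental variable is its
#' abundance-weighted mean across samples,
#' \eqn{\nu_i = \sum_s f_{i,s} e_s / \sum_s f_{i,s}}, with f the
#' within-sample relative abundances. OTUs absent everywhere are excluded
#' with a message. By convexity every niche value lies within the observed
#' range of the variable.
#'
#' @param comm Sample x OTU matrix.
#' @param env Numeric vector of the environmental variable, aligned to the
#'   samples (named or in row order).
#' @return Named numeric vector over the OTUs with nonzero abundance.
#' @export
niche_values <- function(comm, env) {
  if (length(env) != nrow(comm))
    stop("env must have one value per sample")
  if (!is.null(names(env))) {
    if (!setequal(names(env), rownames(comm)))
      stop("env names do not match sample names")
    env <- env[rownames(comm)]
  }
  f <- relative_abundance(comm)
  wsum <- colSums(f)
  absent <- wsum == 0
  if (any(absent)) {
    message("excluding ", sum(absent), " OTU(s) absent from every sample")
    f <- f[, !absent, drop = FALSE]
    wsum <- wsum[!absent]
  }
  colSums(f * env) / wsum
}

#' Mantel correlogram of niche distance against phylogenetic distance
#'
#' Tests, per phylogenetic-distance class, whether closely related OTUs
#' have more similar niche values than expected by chance — the assumption
#' that justifies reading betaNTI as evidence of selection. Distance
#' classes are equal-frequency (quantile) bins of the patristic
#' distances. Within class k the statistic is the Mantel correlation
#' between the niche-distance matrix and the in-class indicator matrix,
#' signed so that positive r at short distances means phylogenetic signal
#' (the correlogram convention). The permutation null simultaneously
#' permutes rows and columns of the niche-distance matrix; p-values are
#' two-sided with progressive Holm correction across classes (class k is
#' corrected for the k tests up to and including it).
#'
#' @param niche_dist OTU x OTU niche distance matrix (or a numeric vector
#'   of niche values, from which absolute differences are taken).
#' @param phylo_dist OTU x OTU patristic distance matrix, same ordering.
#' @param n_classes Number of distance classes (>= 2), default 10.
#' @param n_perm Permutations, default 999.
#' @param seed Integer seed.
#' @return Object of class `mantel_correlogram`: data.frame with columns
#'   `class`, `lower`, `upper`, `n_pairs`, `r`, `p`, `p_corrected`.
#'   Degenerate (constant) niche distances yield `NA` statistics.
#' @export
mantel_correlogram <- function(niche_dist, phylo_dist, n_classes = 10L,
                               n_perm = 999L, seed = NULL) {
  if (n_classes < 2L) stop("n_classes must be at least 2")
  if (is.null(dim(niche_dist)))
    niche_dist <- as.matrix(stats::dist(niche_dist))
  niche_dist <- as.matrix(niche_dist)
  phylo_dist <- as.matrix(phylo_dist)
  S <- nrow(phylo_dist)
  if (!all(dim(niche_dist) == S))
    stop("matrices must cover the same OTUs in the same order")
  low <- lower.tri(phylo_dist)
  pd <- phylo_dist[low]
  breaks <- unique(stats::quantile(pd, probs = seq(0, 1, length.out = n_classes + 1)))
  if (length(breaks) < 3L) stop("phylogenetic distances too degenerate for classes")
  cls <- cut(pd, breaks = breaks, include.lowest = TRUE)
  k_eff <- nlevels(cls)
  members <- lapply(seq_len(k_eff), function(k) as.numeric(cls == levels(cls)[k]))

  nd <- niche_dist[low]
  degenerate <- stats::sd(nd) == 0
  if (!is.null(seed)) set.seed(seed)
  r_obs <- rep(NA_real_, k_eff)
  p <- rep(NA_real_, k_eff)
  if (!degenerate) {
    r_obs <- vapply(members, function(m) -stats::cor(nd, m), numeric(1))
    exceed <- rep(1L, k_eff)  # observed counts as one permutation
    for (i in seq_len(n_perm)) {
      ord <- sample.int(S)
      ndp <- niche_dist[ord, ord][low]
      rp <- vapply(members, function(m) -stats::cor(ndp, m), numeric(1))
      exceed <- exceed + (abs(rp) >= abs(r_obs))
    }
    p <- exceed / (n_perm + 1)
  } else {
    warning("constant niche distances; Mantel r undefined")
  }
  p_corr <- vapply(seq_len(k_eff),
                   function(k) stats::p.adjust(p[seq_len(k)], "holm")[k],
                   numeric(1))
  out <- data.frame(class = seq_len(k_eff),
                    lower = breaks[-length(breaks)][seq_len(k_eff)],
                    upper = breaks[-1L][seq_len(k_eff)],
                    n_pairs = vapply(members, sum, numeric(1)),
                    r = r_obs, p = p, p_corrected = p_corr)
  class(out) <- c("mantel_correlogram", "data.frame")
  attr(out, "n_perm") <- n_perm
  out
}

#' @export
print.mantel_correlogram <- function(x, ...) {
  cat("Mantel correlogram (", attr(x, "n_perm"),
      "permutations, progressive Holm correction )\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Phylogenetic-signal check across environmental variables
#'
#' Convenience wrapper: computes niche values and a Mantel correlogram for
#' every column of a predictor matrix.
#'
#' @param comm Sample x OTU matrix.
#' @param tree Harmonized tree.
#' @param env Predictor matrix, samples x variables.
#' @param n_classes,n_perm,seed Passed to [mantel_correlogram()].
#' @return Named list of `mantel_correlogram` objects, one per variable.
#' @export
phylo_signal_check <- function(comm, tree, env, n_classes = 10L,
                               n_perm = 999L, seed = NULL) {
  D <- align_distances(comm, tree)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(colnames(env), function(v) {
    nv <- niche_values(comm, env[rownames(comm), v])
    mantel_correlogram(nv, D[names(nv), names(nv)],
                       n_classes = n_classes, n_perm = n_perm)
  })
  names(out) <- colnames(env)
  out
}
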
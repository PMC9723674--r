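#' Principal-coordinate representation of a betaNTI matrix
#'
#' betaNTI matrices can hold negative entries, so before ordination the
#' matrix is shifted to non-negative dissimilarities by subtracting the
#' (negative) global off-diagonal minimum; already non-negative matrices
#' are left untouched. The diagonal is set to zero and a principal
#' coordinate decomposition is computed; axes with positive eigenvalues
#' are retained and the absolute mass of negative eigenvalues is reported.
#' A Lingoes correction (adding a constant to all squared off-diagonal
#' dissimilarities so the matrix becomes Euclidean) is available instead
#' of dropping negative axes.
#'
#' @param mat Symmetric sample x sample matrix (diagonal ignored).
#' @param correction `"none"` (drop negative axes, default) or
#'   `"lingoes"`.
#' @return Matrix of coordinates (samples x retained axes) with attributes
#'   `eig` (all eigenvalues), `negative_mass` (sum of |negative
#'   eigenvalues|), and `shift` (the additive constant applied).
#' @export
bnti_to_response <- function(mat, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  mat <- as.matrix(mat)
  if (!isSymmetric(unname(mat), tol = 1e-8))
    stop("matrix must be symmetric")
  n <- nrow(mat)
  off <- mat[lower.tri(mat)]
  if (anyNA(off)) stop("off-diagonal entries must be finite")
  shift <- -min(0, min(off))
  d <- mat + shift
  diag(d) <- 0

  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  if (!is.finite(tol) || max(e$values) <= 0 || sum(e$values[e$values > 0]) < 1e-12)
    stop("degenerate response: betaNTI matrix has no variation")

  if (correction == "lingoes") {
    neg <- e$values[e$values < -tol]
    if (length(neg) > 0L) {
      cstar <- -min(neg)
      d2 <- d^2 + 2 * cstar
      diag(d2) <- 0
      B <- J %*% (-0.5 * d2) %*% J
      e <- eigen((B + t(B)) / 2, symmetric = TRUE)
      tol <- max(abs(e$values)) * 1e-8
    }
  }
  keep <- e$values > tol
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(coords) <- rownames(mat)
  attr(coords, "eig") <- e$values
  attr(coords, "negative_mass") <- sum(abs(e$values[e$values < -tol]))
  attr(coords, "shift") <- shift
  coords
}

#' Adjusted R-squared (Ezekiel correction)
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - m - 1)}.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param m Number of explanatory variables (model rank).
#' @return Adjusted R-squared (may be negative).
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (n <= m + 1) stop("need n > m + 1 for the adjustment")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' @keywords internal
standardize_predictors <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "numeric"
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant predictor column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(X)
}

# explained sum of squares of Y projected on the column space held in `qrX`
#' @keywords internal
explained_ss <- function(qrX, Y) {
  if (is.null(qrX)) return(0)
  sum(qr.fitted(qrX, Y)^2)
}

#' Distance-based redundancy analysis
#'
#' Least-squares projection of principal coordinates on a predictor
#' matrix. The coordinates come from [bnti_to_response()] (or any other
#' PCoA), so this is the constrained-ordination significance machinery
#' behind the variation-partitioning table: global permutation test by
#' permuting response rows, and a marginal permutation test per variable
#' (each variable against the model containing all other variables, with
#' residuals of the reduced model permuted).
#'
#' @param Y Response coordinates (samples x axes), centered.
#' @param X Predictor matrix or data.frame (numeric columns); columns are
#'   z-score standardized. Aliased (linearly dependent) columns are
#'   dropped with a warning.
#' @param n_perm Permutations for the tests, default 999. `0` skips them.
#' @param seed Integer seed.
#' @param condition Optional predictor matrix to partial out: the fit and
#'   tests then concern X given `condition` (partial dbRDA), and the
#'   reported `r2`/`adj_r2` are the semipartial fractions of total
#'   variation.
#' @return Object of class `db_rda`: list with `r2`, `adj_r2`, `eig`
#'   (canonical eigenvalues), `p_global`, `p_variables`, `n`, `rank`,
#'   `aliased`.
#' @export
db_rda <- function(Y, X, n_perm = 999L, seed = NULL, condition = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  X <- standardize_predictors(X)
  if (nrow(X) != n) stop("predictors must align with response rows")

  Z <- if (!is.null(condition)) standardize_predictors(condition) else NULL
  full_mat <- cbind(X, Z)
  qr_full <- qr(full_mat)
  if (qr_full$rank < ncol(full_mat)) {
    keep_idx <- qr_full$pivot[seq_len(qr_full$rank)]
    aliased <- colnames(full_mat)[-keep_idx]
    aliased <- intersect(aliased, colnames(X))
    if (length(aliased) > 0L) {
      warning("dropping aliased predictor(s): ", paste(aliased, collapse = ", "))
      X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
      full_mat <- cbind(X, Z)
      qr_full <- qr(full_mat)
    }
  } else aliased <- character(0)
  m_x <- qr(X)$rank
  m_full <- qr_full$rank
  if (n <= m_full + 1) stop("need more samples than predictors + 1")

  ss_tot <- sum(Yc^2)
  qr_z <- if (!is.null(Z)) qr(Z) else NULL
  ss_full <- explained_ss(qr_full, Yc)
  ss_cond <- explained_ss(qr_z, Yc)
  ss_x <- ss_full - ss_cond           # variation attributable to X (given Z)
  r2 <- ss_x / ss_tot

  # semipartial adjustment: adjR2(X|Z) = adjR2(full) - adjR2(Z)
  adj <- if (is.null(Z)) adjusted_r2(r2, n, m_x)
         else adjusted_r2(ss_full / ss_tot, n, m_full) -
              adjusted_r2(ss_cond / ss_tot, n, qr_z$rank)

  fit_x <- qr.fitted(qr_full, Yc) - if (is.null(Z)) 0 else qr.fitted(qr_z, Yc)
  eig <- svd(fit_x, nu = 0, nv = 0)$d^2
  eig <- eig[eig > max(eig, 0) * 1e-10]

  p_global <- NA_real_
  p_vars <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    # global test: permute residuals of the conditioning model (free
    # permutation of Y rows when there is no condition)
    fit_c <- if (is.null(Z)) matrix(0, n, ncol(Yc)) else qr.fitted(qr_z, Yc)
    res_c <- Yc - fit_c
    stat_obs <- pseudo_f(ss_x, ss_tot - ss_full, m_x, n - m_full - 1)
    hits <- 1L
    for (i in seq_len(n_perm)) {
      Yp <- fit_c + res_c[sample.int(n), , drop = FALSE]
      ssf <- explained_ss(qr_full, Yp)
      ssc <- explained_ss(qr_z, Yp)
      if (pseudo_f(ssf - ssc, sum(scale(Yp, scale = FALSE)^2) - ssf,
                   m_x, n - m_full - 1) >= stat_obs) hits <- hits + 1L
    }
    p_global <- hits / (n_perm + 1)

    # marginal test per variable: reduced model = all other variables (+ Z)
    for (j in seq_len(ncol(X))) {
      red_mat <- cbind(X[, -j, drop = FALSE], Z)
      qr_red <- if (ncol(red_mat) > 0L) qr(red_mat) else NULL
      m_red <- if (is.null(qr_red)) 0L else qr_red$rank
      ss_red <- explained_ss(qr_red, Yc)
      stat_obs <- pseudo_f(ss_full - ss_red, ss_tot - ss_full,
                           m_full - m_red, n - m_full - 1)
      fit_r <- if (is.null(qr_red)) matrix(0, n, ncol(Yc))
               else qr.fitted(qr_red, Yc)
      res_r <- Yc - fit_r
      hits <- 1L
      for (i in seq_len(n_perm)) {
        Yp <- fit_r + res_r[sample.int(n), , drop = FALSE]
        ssf <- explained_ss(qr_full, Yp)
        ssr <- explained_ss(qr_red, Yp)
        totp <- sum(scale(Yp, scale = FALSE)^2)
        if (pseudo_f(ssf - ssr, totp - ssf, m_full - m_red,
                     n - m_full - 1) >= stat_obs) hits <- hits + 1L
      }
      p_vars[j] <- hits / (n_perm + 1)
    }
  }
  structure(list(r2 = r2, adj_r2 = adj, eig = eig, p_global = p_global,
                 p_variables = p_vars, n = n, rank = m_x,
                 aliased = aliased, conditioned = !is.null(Z)),
            class = "db_rda")
}

#' @keywords internal
pseudo_f <- function(ss_effect, ss_resid, df_effect, df_resid) {
  if (df_effect <= 0) return(-Inf)
  if (ss_resid <= 0) return(Inf)
  (ss_effect / df_effect) / (ss_resid / df_resid)
}

#' @export
print.db_rda <- function(x, ...) {
  cat(if (x$conditioned) "Partial distance-based RDA\n"
      else "Distance-based RDA\n")
  cat(sprintf("  R2 = %.4f, adj. R2 = %.4f (n = %d, rank = %d)\n",
              x$r2, x$adj_r2, x$n, x$rank))
  if (!is.na(x$p_global)) cat(sprintf("  global permutation p = %.4g\n", x$p_global))
  sig <- names(x$p_variables)[!is.na(x$p_variables) & x$p_variables < 0.05]
  if (length(sig) > 0L)
    cat("  significant variables (p < 0.05):", paste(sig, collapse = ", "), "\n")
  invisible(x)
}

#' Variation-partitioning fraction arithmetic for two predictor sets
#'
#' Given adjusted R-squared values for set 1 alone (A), set 2 alone (C)
#' and both together (T), the unique, shared and residual fractions are
#' `a = T - C`, `c = T - A`, `b = A + C - T`, `residual = 1 - T`.
#' `a + b + c = T` holds identically.
#'
#' @param adj_1,adj_2,adj_both Adjusted R-squared of each marginal model
#'   and of the combined model.
#' @return Named numeric vector: `unique_1`, `shared`, `unique_2`,
#'   `residual`.
#' @export
varpart_fractions <- function(adj_1, adj_2, adj_both) {
  c(unique_1 = adj_both - adj_2,
    shared = adj_1 + adj_2 - adj_both,
    unique_2 = adj_both - adj_1,
    residual = 1 - adj_both)
}

#' Two-set variation partitioning of a betaNTI matrix
#'
#' Partitions the variation of a betaNTI response (after
#' [bnti_to_response()]) into the fraction uniquely explained by soil
#' variables, the fraction uniquely explained by vegetation composition,
#' their shared overlap, and the residual, in adjusted R-squared units.
#' Marginal and combined models are tested by dbRDA permutation tests;
#' each unique fraction is tested by partial dbRDA conditioning on the
#' other set. The shared fraction cannot be tested. Per-variable
#' significance mirrors the marginal permutation tests of each fitted
#' model.
#'
#' @param Y Response coordinates from [bnti_to_response()] (or a betaNTI
#'   matrix, which is converted).
#' @param X_soil,X_veg Predictor matrices aligned to the response samples.
#' @param n_perm Permutations, default 999.
#' @param seed Integer seed.
#' @param hellinger_veg Hellinger-transform the vegetation abundances
#'   (square root of row-normalized proportions) before standardizing?
#'   Default `FALSE`.
#' @return Object of class `varpart_result`: a data.frame `table` with
#'   rows Soil, Vegetation, Soil + Vegetation, Soil | Vegetation,
#'   Vegetation | Soil, Soil &#8745; Vegetation, Residuals (adjusted R2,
#'   p-value, significant variables) plus the underlying `db_rda` fits.
#' @export
two_set_varpart <- function(Y, X_soil, X_veg, n_perm = 999L, seed = NULL,
                            hellinger_veg = FALSE) {
  if (is.null(attr(Y, "eig")) && isSymmetric(unname(as.matrix(Y)), tol = 1e-8) &&
      nrow(as.matrix(Y)) == ncol(as.matrix(Y)))
    Y <- bnti_to_response(Y)
  if (hellinger_veg) {
    rs <- rowSums(X_veg)
    if (any(rs <= 0)) stop("Hellinger transform needs positive row totals")
    X_veg <- sqrt(X_veg / rs)
  }
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 5L)
  fit_soil <- db_rda(Y, X_soil, n_perm, seeds[1L])
  fit_veg <- db_rda(Y, X_veg, n_perm, seeds[2L])
  fit_both <- db_rda(Y, cbind(X_soil, X_veg), n_perm, seeds[3L])
  fit_soil_given <- db_rda(Y, X_soil, n_perm, seeds[4L], condition = X_veg)
  fit_veg_given <- db_rda(Y, X_veg, n_perm, seeds[5L], condition = X_soil)

  fr <- varpart_fractions(fit_soil$adj_r2, fit_veg$adj_r2, fit_both$adj_r2)
  sig <- function(fit) {
    v <- names(fit$p_variables)[!is.na(fit$p_variables) & fit$p_variables < 0.05]
    if (length(v) == 0L) "" else paste(v, collapse = ", ")
  }
  tab <- data.frame(
    partition = c("Soil", "Vegetation", "Soil + Vegetation",
                  "Soil | Vegetation", "Vegetation | Soil",
                  "Soil ∩ Vegetation", "Residuals"),
    adj_r2 = c(fit_soil$adj_r2, fit_veg$adj_r2, fit_both$adj_r2,
               fr[["unique_1"]], fr[["unique_2"]], fr[["shared"]],
               fr[["residual"]]),
    p = c(fit_soil$p_global, fit_veg$p_global, fit_both$p_global,
          fit_soil_given$p_global, fit_veg_given$p_global, NA, NA),
    significant_variables = c(sig(fit_soil), sig(fit_veg), sig(fit_both),
                              sig(fit_soil_given), sig(fit_veg_given),
                              "", ""),
    stringsAsFactors = FALSE)
  structure(list(table = tab, fractions = fr,
                 fits = list(soil = fit_soil, vegetation = fit_veg,
                             both = fit_both, soil_given_veg = fit_soil_given,
                             veg_given_soil = fit_veg_given)),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("Two-set variation partitioning of betaNTI (adjusted R2)\n")
  tab <- x$table
  tab$adj_r2 <- round(tab$adj_r2, 3)
  print.data.frame(tab, row.names = FALSE)
  cat("(the shared fraction cannot be tested)\n")
  invisible(x)
}
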
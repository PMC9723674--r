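PROCESS_LABELS <- c("homogeneous_selection", "variable_selection",
                    "homogenizing_dispersal", "dispersal_limitation_drift",
                    "drift")

#' Classify a sample pair into an assembly process
#'
#' Two-step decision used throughout the null-model framework:
#' betaNTI below -2 is homogeneous selection, above +2 variable selection;
#' pairs within the null band (|betaNTI| <= 2) are split by RC-Bray into
#' homogenizing dispersal (RC < -0.95), dispersal limitation + drift
#' (RC > +0.95), and drift alone otherwise. Boundary values fall on the
#' neutral/drift side (strict inequalities for the extreme labels).
#'
#' @param bnti_val Finite betaNTI value(s).
#' @param rc_val RC-Bray value(s); only consulted when |betaNTI| is within
#'   the threshold.
#' @param bnti_thresh,rc_thresh Thresholds, default 2 and 0.95.
#' @return Character vector of process labels.
#' @export
classify_pair <- function(bnti_val, rc_val, bnti_thresh = 2, rc_thresh = 0.95) {
  n <- length(bnti_val)
  if (length(rc_val) != n) stop("bnti_val and rc_val must have equal length")
  out <- rep(NA_character_, n)
  out[bnti_val < -bnti_thresh] <- "homogeneous_selection"
  out[bnti_val > bnti_thresh] <- "variable_selection"
  neutral <- is.na(out) & is.finite(bnti_val)
  out[neutral & rc_val < -rc_thresh] <- "homogenizing_dispersal"
  out[neutral & rc_val > rc_thresh] <- "dispersal_limitation_drift"
  out[neutral & is.na(out)] <- "drift"
  out
}

#' Classify all sample pairs of a betaNTI / RC-Bray matrix pair
#'
#' Pairs whose betaNTI is `NaN` (degenerate null) are excluded with a
#' logged count.
#'
#' @param bnti_mat Symmetric betaNTI matrix (masked diagonal).
#' @param rc_mat Symmetric RC-Bray matrix, same samples.
#' @param bnti_thresh,rc_thresh See [classify_pair()].
#' @return data.frame: `sample_i`, `sample_j`, `bnti`, `rc`, `process`.
#' @export
classify_processes <- function(bnti_mat, rc_mat, bnti_thresh = 2,
                               rc_thresh = 0.95) {
  if (!identical(rownames(bnti_mat), rownames(rc_mat)))
    stop("betaNTI and RC-Bray matrices must cover the same samples")
  b <- pairs_long(bnti_mat, "bnti")
  r <- pairs_long(rc_mat, "rc")
  calls <- data.frame(b, rc = r$rc, stringsAsFactors = FALSE)
  bad <- !is.finite(calls$bnti)
  if (any(bad)) {
    message("excluding ", sum(bad), " pair(s) with undefined betaNTI")
    calls <- calls[!bad, , drop = FALSE]
  }
  calls$process <- classify_pair(calls$bnti, calls$rc, bnti_thresh, rc_thresh)
  calls
}

#' Per-group proportions of assembly processes
#'
#' Under `within_class` scope a pair belongs to a history class iff both
#' samples carry that class; cross-class pairs are excluded. Under
#' `within_watershed` the group is the watershed, pairs spanning
#' watersheds are excluded.
#'
#' @param calls data.frame from [classify_processes()].
#' @param metadata Sample metadata (see [read_metadata()]).
#' @param scope `"within_class"` (default) or `"within_watershed"`.
#' @return data.frame with columns `group`, `process`, `count`, `n_pairs`,
#'   `proportion`; proportions sum to 1 within each group.
#' @export
group_proportions <- function(calls, metadata,
                              scope = c("within_class", "within_watershed")) {
  scope <- match.arg(scope)
  validate_metadata(metadata)
  key <- if (scope == "within_class") "history" else "watershed"
  grp <- metadata[[key]][match(calls$sample_i, metadata$sample_id)]
  grp_j <- metadata[[key]][match(calls$sample_j, metadata$sample_id)]
  if (anyNA(grp) || anyNA(grp_j))
    stop("sample(s) in calls missing from metadata")
  keep <- grp == grp_j
  if (!any(keep)) stop("no within-group pairs under scope '", scope, "'")
  calls <- calls[keep, , drop = FALSE]
  grp <- grp[keep]
  out <- do.call(rbind, lapply(split(calls$process, grp), function(p) {
    counts <- table(factor(p, levels = PROCESS_LABELS))
    data.frame(process = names(counts), count = as.integer(counts),
               n_pairs = length(p),
               proportion = as.integer(counts) / length(p),
               stringsAsFactors = FALSE)
  }))
  out <- data.frame(group = rep(names(split(calls$process, grp)),
                                each = length(PROCESS_LABELS)),
                    out, row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Two-proportion Z-test
#'
#' Pooled-variance z statistic for the difference of two binomial
#' proportions,
#' \eqn{z = (k_1/n_1 - k_2/n_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p = (k_1 + k_2)/(n_1 + n_2)}; two-sided p-value from the
#' normal distribution. If the pooled proportion is 0 or 1 the statistic is
#' undefined; `z = NA`, `p = 1` is returned with a warning.
#'
#' @param k1,n1,k2,n2 Successes and trials in each group.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`
#'   (direction of group 1 minus group 2).
#' @return List with `z`, `p`, `estimate` (the two proportions),
#'   `alternative`.
#' @export
proportion_ztest <- function(k1, n1, k2, n2,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n and n >= 1 in both groups")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  if (pool == 0 || pool == 1) {
    warning("pooled proportion is ", pool, "; z undefined")
    return(list(z = NA_real_, p = 1, estimate = c(p1 = p1, p2 = p2),
                alternative = alternative))
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(z = z, p = p, estimate = c(p1 = p1, p2 = p2),
       alternative = alternative)
}

#' Compare process proportions between two groups
#'
#' Runs a two-proportion Z-test per process label, plus a pooled
#' "selection_overall" comparison (homogeneous + variable selection
#' combined). Pairwise comparisons are treated as independent observations;
#' this inflates effective sample size (pairs share samples) and is the
#' framework's convention, not a corrected inference.
#'
#' @param props Output of [group_proportions()] with exactly two groups.
#' @param group1,group2 Group identifiers; defaults to the two groups
#'   present (alphabetical).
#' @return data.frame: `process`, per-group proportions, `z`, `p`.
#' @export
compare_proportions <- function(props, group1 = NULL, group2 = NULL) {
  groups <- sort(unique(props$group))
  if (is.null(group1)) group1 <- groups[1L]
  if (is.null(group2)) group2 <- groups[2L]
  if (!all(c(group1, group2) %in% groups)) stop("group not found")
  g1 <- props[props$group == group1, ]
  g2 <- props[props$group == group2, ]
  rows <- lapply(PROCESS_LABELS, function(lab) {
    a <- g1[g1$process == lab, ]
    b <- g2[g2$process == lab, ]
    zt <- suppressWarnings(
      proportion_ztest(a$count, a$n_pairs, b$count, b$n_pairs))
    data.frame(process = lab, prop1 = a$proportion, prop2 = b$proportion,
               z = zt$z, p = zt$p, stringsAsFactors = FALSE)
  })
  sel1 <- sum(g1$count[g1$process %in% c("homogeneous_selection",
                                         "variable_selection")])
  sel2 <- sum(g2$count[g2$process %in% c("homogeneous_selection",
                                         "variable_selection")])
  zt <- suppressWarnings(
    proportion_ztest(sel1, g1$n_pairs[1L], sel2, g2$n_pairs[1L]))
  rows <- c(rows, list(data.frame(process = "selection_overall",
                                  prop1 = sel1 / g1$n_pairs[1L],
                                  prop2 = sel2 / g2$n_pairs[1L],
                                  z = zt$z, p = zt$p,
                                  stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(group1, group2)
  out
}

#' Kruskal-Wallis comparison of betaNTI distributions
#'
#' Rank-based test for a location difference between two or more betaNTI
#' distributions (e.g., bacteria vs. fungi), with the standard tie
#' correction and a chi-squared reference distribution. If every value is
#' tied across all groups, `H = 0, p = 1` by convention.
#'
#' @param groups Named list of two or more numeric vectors.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations in total")
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
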
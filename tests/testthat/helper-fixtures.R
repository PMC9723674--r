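# Shared fixtures and independent oracles, built in code at test time.

# three-tip toy tree used throughout: d(B,C) = 1, d(A,B) = d(A,C) = 2
toy_tree <- function() ape::read.tree(text = "(A:1,(B:0.5,C:0.5):0.5);")

# slow, independent beta-MNTD oracle (plain R loops; never touches the
# package's C++ path)
oracle_beta_mntd <- function(f_a, f_b, D) {
  A <- which(f_a > 0)
  B <- which(f_b > 0)
  term_a <- sum(vapply(A, function(i) f_a[i] * min(D[i, B]), numeric(1)))
  term_b <- sum(vapply(B, function(j) f_b[j] * min(D[j, A]), numeric(1)))
  0.5 * (term_a + term_b)
}

# all permutations of 1..n (n small), for exhaustive-null oracles
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# small community fixture over a given tree's tips; per-sample lognormal
# weights keep the table sparse so taxon sets differ between samples
small_comm <- function(tree, n_samples = 4L, J = 50L, seed = 1L) {
  set.seed(seed)
  S <- length(tree$tip.label)
  m <- t(vapply(seq_len(n_samples), function(s)
    stats::rmultinom(1L, J, exp(stats::rnorm(S, sd = 1.5)))[, 1L],
    integer(S)))
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)), tree$tip.label)
  m
}

# write a matrix/data.frame to a temp TSV and return the path
tmp_tsv <- function(df, id_header = "id") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  m <- as.matrix(df)
  out <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(out)[1L] <- id_header
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# per-regime process-call fractions on a fresh synthetic block
regime_call_fractions <- function(regime, seed, n_sites = 12L, reps = 299L,
                                  S = 200L, ...) {
  sim <- simulate_tree_traits(S, seed = seed * 2 + 1)
  set.seed(seed + 5000)
  pool <- lognormal_pool(S)
  comm <- simulate_community(sim, regime_spec(regime, ...), n_sites,
                             seed = seed + 10000, pool = pool)
  b <- suppressWarnings(bnti(comm, sim$tree, n_reps = reps,
                             seed = seed + 20000))
  r <- rc_bray(comm, n_reps = reps, seed = seed + 30000)
  calls <- suppressMessages(classify_processes(b$bnti, r$rc))
  labs <- c("homogeneous_selection", "variable_selection",
            "homogenizing_dispersal", "dispersal_limitation_drift", "drift")
  # fractions over classified pairs; NA when every pair was excluded
  # (degenerate betaNTI null)
  if (nrow(calls) == 0L) return(setNames(rep(NA_real_, 5L), labs))
  vapply(labs, function(l) mean(calls$process == l), numeric(1))
}
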
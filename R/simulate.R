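ASSEMBLY_REGIMES <- c("selection_homogeneous", "selection_variable",
                      "dispersal_limited", "homogenizing_dispersal", "drift")

#' Specify an assembly regime for community simulation
#'
#' Bundles the knobs of one generative regime. `sigma_sel` is the width of
#' the Gaussian environmental filter in standardized trait units (small =
#' strong filtering); `m` is the migration/mixing rate; `e_site` the site
#' environmental optimum (trait units); `J` the local community size in
#' individuals.
#'
#' @param regime One of `selection_homogeneous`, `selection_variable`,
#'   `dispersal_limited`, `homogenizing_dispersal`, `drift`.
#' @param sigma_sel Selection width, > 0. Defaults: 0.15 for
#'   `selection_homogeneous` (a strict filter around one optimum), 0.5
#'   for `selection_variable`.
#' @param m Migration rate in \[0, 1\]. Defaults: 0.05 for
#'   `dispersal_limited`, 0.95 for `homogenizing_dispersal`, ignored
#'   otherwise unless given.
#' @param e_site Environmental optimum in trait units.
#'   `selection_variable` spreads site optima around it. The default
#'   (`NULL`) is 0 for `selection_variable` and, for
#'   `selection_homogeneous`, the maximum of the realized tip traits: an
#'   optimum at the trait extreme selects the extreme clades and
#'   produces the phylogenetic clustering that defines the regime, where
#'   an optimum at the trait center would admit taxa from all over the
#'   tree.
#' @param e_spread Half-range of site optima under `selection_variable`,
#'   in trait units. Default 2.
#' @param e_jitter Per-site jitter (sd, trait units) around the shared
#'   optimum under `selection_homogeneous`: micro-heterogeneity that
#'   makes different sites favor different members of the selected
#'   clade. Default 0.2.
#' @param site_noise_sd Log-sd of per-site multiplicative availability
#'   noise on the pool weights in the two selection regimes — local
#'   compositional drift layered under the filter, giving the
#'   within-clade taxon replacement among sites that real filtered
#'   communities show. Default 2; ignored by the neutral regimes (the
#'   drift regime is pure multinomial sampling by construction).
#' @param J Individuals per site, >= 1. Default 1000.
#' @param window Fraction of the 1-D taxon axis available to each site
#'   under `dispersal_limited`. Default 0.25.
#' @return A `regime_spec` list.
#' @export
regime_spec <- function(regime, sigma_sel = NULL, m = NULL, e_site = NULL,
                        e_spread = 2, e_jitter = 0.2, site_noise_sd = 2,
                        J = 1000L, window = 0.25) {
  regime <- match.arg(regime, ASSEMBLY_REGIMES)
  if (is.null(m))
    m <- switch(regime, dispersal_limited = 0.05,
                homogenizing_dispersal = 0.95, 0)
  if (is.null(sigma_sel))
    sigma_sel <- if (regime == "selection_homogeneous") 0.15 else 0.5
  if (sigma_sel <= 0) stop("sigma_sel must be > 0")
  if (m < 0 || m > 1) stop("m must be in [0, 1]")
  if (e_jitter < 0 || site_noise_sd < 0)
    stop("e_jitter and site_noise_sd must be non-negative")
  if (J < 1) stop("J must be at least 1")
  if (window <= 0 || window > 1) stop("window must be in (0, 1]")
  structure(list(regime = regime, sigma_sel = sigma_sel, m = m,
                 e_site = e_site, e_spread = e_spread, e_jitter = e_jitter,
                 site_noise_sd = site_noise_sd, J = as.integer(J),
                 window = window),
            class = "regime_spec")
}

#' Simulate a phylogeny with a conserved niche trait
#'
#' Pure-birth tree on S tips (via [ape::rphylo()]) with a niche trait
#' evolved by Brownian motion along the branches. The trait is blended
#' with independent normal noise, `t = w * BM + (1 - w) * noise` with both
#' components standardized, so `conservatism` (w) is a single knob for the
#' strength of phylogenetic signal; the blend is re-standardized to mean 0,
#' sd 1.
#'
#' @param S Number of tips, >= 4. Default 200.
#' @param seed Integer seed.
#' @param conservatism Trait-phylogeny coupling in (0, 1\]. Default 1 (a
#'   fully conserved trait, the framework's working assumption).
#' @return List with `tree` (tips `OTU0001`, ...) and `traits` (named
#'   numeric vector).
#' @export
simulate_tree_traits <- function(S = 200L, seed = NULL, conservatism = 1) {
  if (S < 4L) stop("need at least 4 tips")
  if (conservatism <= 0 || conservatism > 1)
    stop("conservatism must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(S, birth = 1, death = 0)
  tree$tip.label <- sprintf("OTU%04d", seq_len(S))
  bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  noise <- stats::rnorm(S)
  z <- function(x) (x - mean(x)) / stats::sd(x)
  traits <- conservatism * z(bm) + (1 - conservatism) * z(noise)
  traits <- z(traits)
  names(traits) <- tree$tip.label
  list(tree = tree, traits = traits)
}

#' Regional pool relative abundances
#'
#' Lognormal rank-abundance curve: realistic unevenness matters for the
#' occupancy/abundance weighting of the RC-Bray null.
#'
#' @param S Number of taxa.
#' @param log_sd Log-scale standard deviation, default 1.
#' @return Relative-abundance vector summing to 1.
#' @export
lognormal_pool <- function(S, log_sd = 1) {
  p <- exp(stats::rnorm(S, sd = log_sd))
  p / sum(p)
}

# largest-remainder rounding to integers preserving the total
#' @keywords internal
round_preserve_total <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' Simulate a community table under a known assembly regime
#'
#' Each site draws `J` individuals by multinomial sampling from the
#' regional pool, with weights set by the regime:
#' \itemize{
#'   \item selection regimes: \eqn{w_i \propto p_i \exp(-(t_i - e_s)^2 /
#'     (2\sigma_{sel}^2))} — a Gaussian filter of the niche trait around
#'     the site optimum; `selection_homogeneous` shares one optimum
#'     across sites, `selection_variable` spreads optima across sites;
#'   \item drift: \eqn{w_i \propto p_i} (neutral sampling);
#'   \item dispersal_limited: taxa carry random 1-D positions and each
#'     site only samples taxa within a window around its own position,
#'     mixed with the full pool at low migration rate m;
#'   \item homogenizing_dispersal: a neutral local draw is mixed with the
#'     regional mean composition at rate m (m = 1 makes all sites
#'     identical).
#' }
#'
#' @param sim Output of [simulate_tree_traits()] (list with `tree`,
#'   `traits`).
#' @param spec A [regime_spec()].
#' @param n_sites Number of sites to generate.
#' @param seed Integer seed.
#' @param pool Optional regional relative-abundance vector (defaults to a
#'   fresh [lognormal_pool()] draw).
#' @param site_names Optional sample identifiers.
#' @return Sample x OTU integer count matrix.
#' @export
simulate_community <- function(sim, spec, n_sites, seed = NULL, pool = NULL,
                               site_names = NULL) {
  if (!inherits(spec, "regime_spec")) stop("spec must be a regime_spec")
  if (n_sites < 1L) stop("need at least one site")
  traits <- sim$traits
  S <- length(traits)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- lognormal_pool(S, log_sd = 1)
  if (length(pool) != S || any(pool < 0) || sum(pool) == 0)
    stop("invalid regional pool")
  pool <- pool / sum(pool)
  J <- spec$J

  e_site <- spec$e_site %||% switch(spec$regime,
    selection_homogeneous = max(traits),
    0)
  e_sites <- switch(spec$regime,
    selection_variable = e_site +
      seq(-spec$e_spread, spec$e_spread, length.out = n_sites),
    selection_homogeneous = e_site + stats::rnorm(n_sites, 0, spec$e_jitter),
    rep(e_site, n_sites))

  if (spec$regime == "dispersal_limited") {
    taxon_pos <- stats::runif(S)
    site_pos <- stats::runif(n_sites)
  }

  comm <- matrix(0L, n_sites, S,
                 dimnames = list(site_names %||% sprintf("site%02d", seq_len(n_sites)),
                                 names(traits)))
  for (s in seq_len(n_sites)) {
    w <- switch(spec$regime,
      selection_homogeneous = ,
      selection_variable = {
        d2 <- (traits - e_sites[s])^2
        avail <- if (spec$site_noise_sd > 0)
          exp(stats::rnorm(S, 0, spec$site_noise_sd)) else 1
        # subtract the best match so the filter survives sigma_sel -> 0
        pool * avail * exp(-(d2 - min(d2)) / (2 * spec$sigma_sel^2))
      },
      drift = ,
      homogenizing_dispersal = pool,
      dispersal_limited = {
        half <- spec$window / 2
        dist1d <- abs(taxon_pos - site_pos[s])
        dist1d <- pmin(dist1d, 1 - dist1d)  # wrap-around axis, no edge effects
        local <- ifelse(dist1d <= half, pool, 0)
        if (sum(local) == 0) local <- pool  # empty window: fall back to pool
        (1 - spec$m) * local / sum(local) + spec$m * pool
      })
    if (sum(w) == 0) stop("empty sampling pool at site ", s)
    counts <- as.integer(stats::rmultinom(1L, J, w / sum(w)))
    if (spec$regime == "homogenizing_dispersal" && spec$m > 0)
      counts <- round_preserve_total((1 - spec$m) * counts + spec$m * J * pool, J)
    comm[s, ] <- counts
  }
  empty <- rowSums(comm) == 0
  if (any(empty)) stop("simulation produced empty site(s)")
  comm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired-watershed sample metadata
#'
#' Eight watersheds of six plots each, arranged in four
#' reference/disturbed pairs — the sampling design the generator
#' emulates.
#'
#' @param n_pairs Number of reference/disturbed watershed pairs. Default 4.
#' @param plots_per_watershed Plots per watershed. Default 6.
#' @return data.frame with columns `sample_id`, `watershed`, `history`,
#'   `pair`, `plot`.
#' @export
simulate_metadata <- function(n_pairs = 4L, plots_per_watershed = 6L) {
  ws <- sprintf("WS%d", seq_len(2L * n_pairs))
  history <- rep(c("reference", "disturbed"), n_pairs)
  pair <- rep(sprintf("P%d", seq_len(n_pairs)), each = 2L)
  md <- do.call(rbind, lapply(seq_along(ws), function(i) {
    data.frame(sample_id = sprintf("%s_plot%d", ws[i],
                                   seq_len(plots_per_watershed)),
               watershed = ws[i], history = history[i], pair = pair[i],
               plot = seq_len(plots_per_watershed),
               stringsAsFactors = FALSE)
  }))
  rownames(md) <- NULL
  md
}

SOIL_VARIABLES <- c("total_N", "extractable_N", "extractable_CN",
                    "microbial_biomass_C", "pH", "moisture")
VEG_SPECIES <- c("Q_rubra", "P_strobus", "B_lenta", "L_tulipifera",
                 "R_maximum", "Carya_spp", "A_rubrum", "T_canadensis")

#' Simulate soil and vegetation predictor matrices
#'
#' Both predictor sets are linear read-outs of latent per-sample factors:
#' a shared block and one private block per set, mixed so the expected
#' fraction of each set's systematic variance that is common to both sets
#' equals `shared_fraction`. Historical disturbance shifts the latent
#' means, so predictors co-vary with the assembly regime assigned to each
#' watershed. Soil variables are Gaussian in lab-like units; vegetation
#' columns are non-negative lognormal abundances per species.
#'
#' @param metadata Sample metadata (see [simulate_metadata()]).
#' @param shared_fraction In \[0, 1\]: 0 = independent sets, 1 = both sets
#'   are transforms of the same latent factors. Default 0.5.
#' @param seed Integer seed.
#' @param disturbance_effect Latent mean shift for disturbed samples, in
#'   latent sd units. Default 1.
#' @param noise_sd Measurement noise sd on each variable. Default 0.3.
#' @return List with `soil` and `vegetation` matrices (samples x
#'   variables, rownames = sample ids).
#' @export
simulate_predictors <- function(metadata, shared_fraction = 0.5, seed = NULL,
                                disturbance_effect = 1, noise_sd = 0.3) {
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(metadata)
  q <- 2L  # latent factors per block
  shift <- ifelse(metadata$history == "disturbed", disturbance_effect, 0)
  latent <- function() matrix(stats::rnorm(n * q), n, q) + shift
  z_shared <- latent()
  z_soil <- latent()
  z_veg <- latent()
  mix <- function(private) sqrt(shared_fraction) * z_shared +
    sqrt(1 - shared_fraction) * private

  readout <- function(z, vars) {
    L <- matrix(stats::rnorm(q * length(vars)), q, length(vars))
    out <- z %*% L + matrix(stats::rnorm(n * length(vars), sd = noise_sd),
                            n, length(vars))
    dimnames(out) <- list(metadata$sample_id, vars)
    out
  }
  soil <- readout(mix(z_soil), SOIL_VARIABLES)
  veg <- exp(readout(mix(z_veg), VEG_SPECIES) * 0.5)
  list(soil = soil, vegetation = veg)
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' One call produces everything the pipeline consumes: a phylogeny with a
#' conserved niche trait, a community table over the paired-watershed
#' design with one assembly regime per watershed, sample metadata, soil
#' and vegetation predictor matrices, and the truth labels. The whole
#' dataset is a pure function of (configuration, seed).
#'
#' The default regime map ties disturbance history to selection —
#' disturbed watersheds assemble under environmental filtering
#' (homogeneous or variable selection), reference watersheds under
#' dispersal limitation or drift — so downstream process inference has a
#' known signal to recover.
#'
#' @param seed Master integer seed.
#' @param S Regional pool size (OTUs). Default 200.
#' @param J Individuals per site. Default 1000.
#' @param conservatism Trait-phylogeny coupling. Default 1.
#' @param shared_fraction Shared predictor variance. Default 0.5.
#' @param regimes Optional named character vector, watershed id -> regime;
#'   defaults to the map described above.
#' @param n_pairs,plots_per_watershed Design size. Defaults 4 and 6 (48
#'   samples).
#' @param sigma_sel Selection width for the selection regimes; `NULL`
#'   (default) uses the per-regime defaults of [regime_spec()].
#' @return List with `tree`, `comm`, `metadata`, `soil`, `vegetation`,
#'   `truth` (list: `regimes`, `traits`, `pool`).
#' @export
simulate_dataset <- function(seed = 1L, S = 200L, J = 1000L,
                             conservatism = 1, shared_fraction = 0.5,
                             regimes = NULL, n_pairs = 4L,
                             plots_per_watershed = 6L, sigma_sel = NULL) {
  md <- simulate_metadata(n_pairs, plots_per_watershed)
  ws <- unique(md$watershed)
  if (is.null(regimes)) {
    ref_cycle <- c("dispersal_limited", "drift")
    dis_cycle <- c("selection_homogeneous", "selection_variable")
    regimes <- character(length(ws))
    names(regimes) <- ws
    is_ref <- md$history[match(ws, md$watershed)] == "reference"
    regimes[is_ref] <- rep_len(ref_cycle, sum(is_ref))
    regimes[!is_ref] <- rep_len(dis_cycle, sum(!is_ref))
  }
  if (!setequal(names(regimes), ws)) stop("regimes must name every watershed")

  base_seed <- as.integer(seed) %% 1000000L
  sim <- simulate_tree_traits(S, seed = base_seed * 2L + 1L,
                              conservatism = conservatism)
  set.seed(base_seed * 2L + 2L)
  pool <- lognormal_pool(S, log_sd = 1)

  comm <- do.call(rbind, lapply(seq_along(ws), function(i) {
    rows <- md$watershed == ws[i]
    simulate_community(sim, regime_spec(regimes[[ws[i]]], sigma_sel = sigma_sel,
                                        J = J),
                       n_sites = sum(rows),
                       seed = base_seed * 100L + i,
                       pool = pool,
                       site_names = md$sample_id[rows])
  }))
  comm <- comm[md$sample_id, , drop = FALSE]
  pred <- simulate_predictors(md, shared_fraction,
                              seed = base_seed * 2L + 3L)
  list(tree = sim$tree, comm = comm, metadata = md,
       soil = pred$soil, vegetation = pred$vegetation,
       truth = list(regimes = regimes, traits = sim$traits, pool = pool))
}

#' Write a synthetic dataset to a directory of TSV/newick files
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_community(dataset$comm, file.path(dir, "community.tsv"))
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(dataset$soil, file.path(dir, "soil.tsv"), "sample_id")
  write_matrix_tsv(dataset$vegetation, file.path(dir, "vegetation.tsv"),
                   "sample_id")
  truth <- data.frame(watershed = names(dataset$truth$regimes),
                      regime = unname(dataset$truth$regimes),
                      stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth_regimes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  traits <- data.frame(otu = names(dataset$truth$traits),
                       trait = unname(dataset$truth$traits))
  utils::write.table(traits, file.path(dir, "truth_traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
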
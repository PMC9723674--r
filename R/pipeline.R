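#' Default pipeline configuration
#'
#' The configuration drives every stage of the analysis; all randomness is
#' seeded from the single master `seed`. With a `simulate` block the
#' pipeline generates its own dataset; with an `inputs` block it reads
#' tree/table/metadata/predictor files instead.
#'
#' @return Nested list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "ecoassembly_out",
    simulate = list(S = 200L, J = 1000L, conservatism = 0.8,
                    shared_fraction = 0.5, sigma_sel = 0.5,
                    n_pairs = 4L, plots_per_watershed = 6L),
    inputs = NULL,
    bnti = list(reps = 999L, weighted = TRUE),
    rcbray = list(reps = 999L),
    classify = list(bnti_thresh = 2, rc_thresh = 0.95,
                    scope = "within_class"),
    signal = list(n_classes = 10L, n_perm = 999L, variables = NULL),
    varpart = list(n_perm = 999L, hellinger_veg = FALSE)
  )
}

CONFIG_SCHEMA <- list(
  seed = "integer", outdir = "character",
  simulate = list(S = "integer", J = "integer", conservatism = "numeric",
                  shared_fraction = "numeric", sigma_sel = "numeric",
                  n_pairs = "integer", plots_per_watershed = "integer"),
  inputs = list(tree = "character", table = "character",
                metadata = "character", soil = "character",
                vegetation = "character"),
  bnti = list(reps = "integer", weighted = "logical"),
  rcbray = list(reps = "integer"),
  classify = list(bnti_thresh = "numeric", rc_thresh = "numeric",
                  scope = "character"),
  signal = list(n_classes = "integer", n_perm = "integer",
                variables = "character"),
  varpart = list(n_perm = "integer", hellinger_veg = "logical")
)

#' Validate a pipeline configuration
#'
#' Schema-checks a configuration list or YAML file: unknown keys are
#' rejected (with a closest-match suggestion), types are checked, and all
#' problems are reported at once.
#'
#' @param config A configuration list, or the path to a YAML file.
#' @return `TRUE` if valid, otherwise a character vector of error
#'   messages (invisibly `FALSE`-like; check with `isTRUE()`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) return("config file not found")
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) e)
    if (inherits(config, "error"))
      return(paste("could not parse config:", conditionMessage(config)))
  }
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))

  check_keys <- function(x, schema, prefix = "") {
    unknown <- setdiff(names(x), names(schema))
    for (k in unknown) {
      d <- utils::adist(k, names(schema))
      hint <- if (min(d) <= 2) paste0(" (did you mean '",
                                      names(schema)[which.min(d)], "'?)") else ""
      note("unknown key '", prefix, k, "'", hint)
    }
    for (k in intersect(names(x), names(schema))) {
      if (is.list(schema[[k]])) {
        if (!is.null(x[[k]])) {
          if (!is.list(x[[k]])) note("'", prefix, k, "' must be a block")
          else check_keys(x[[k]], schema[[k]], paste0(prefix, k, "."))
        }
      } else if (!is.null(x[[k]])) {
        ok <- switch(schema[[k]],
                     integer = is.numeric(x[[k]]) && all(x[[k]] %% 1 == 0),
                     numeric = is.numeric(x[[k]]),
                     logical = is.logical(x[[k]]),
                     character = is.character(x[[k]]))
        if (!ok) note("'", prefix, k, "' must be of type ", schema[[k]])
      }
    }
  }
  check_keys(config, CONFIG_SCHEMA)

  reps_of <- function(block) config[[block]]$reps
  for (b in c("bnti", "rcbray"))
    if (!is.null(reps_of(b)) && is.numeric(reps_of(b)) && reps_of(b) < 99)
      note("'", b, ".reps' must be >= 99")
  if (!is.null(config$signal$n_classes) &&
      is.numeric(config$signal$n_classes) && config$signal$n_classes < 2)
    note("'signal.n_classes' must be >= 2")
  if (is.null(config$simulate) && is.null(config$inputs))
    note("config needs either a 'simulate' or an 'inputs' block")
  if (!is.null(config$inputs))
    for (k in c("tree", "table", "metadata", "soil", "vegetation"))
      if (is.null(config$inputs[[k]]))
        note("'inputs.", k, "' is required when inputs are given")

  if (length(errs) == 0L) TRUE else errs
}

# per-stage seeds derived deterministically from the master seed
#' @keywords internal
stage_seeds <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  setNames(sample.int(2^31 - 1, 6L),
           c("simulate", "bnti", "rcbray", "signal", "varpart", "extra"))
}

#' Run the full assembly-process analysis
#'
#' Orchestrates simulate/load, phylogenetic-signal check, betaNTI,
#' RC-Bray, process classification and group comparisons, and two-set
#' variation partitioning. All stage outputs are written as TSV under the
#' configured output directory, together with a machine-readable
#' `manifest.json` (configuration, derived seeds, package version). A
#' failing stage aborts with the stage name and leaves a `FAILED` marker
#' next to the partial outputs.
#'
#' @param config Configuration list or YAML path; see [default_config()].
#'   Partial configurations are filled in from the defaults.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(default_config(), config,
                       keep.null = TRUE)
  ok <- validate_config(config)
  if (!isTRUE(ok)) stop("invalid config:\n  ", paste(ok, collapse = "\n  "))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  mark_failed <- function(stage, e) {
    writeLines(paste("FAILED at stage:", stage, "--", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) mark_failed(name, e))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  data <- stage("data", {
    if (!is.null(config$inputs)) {
      tree <- read_tree(config$inputs$tree)
      comm <- read_community(config$inputs$table)
      h <- harmonize(tree, comm)
      list(tree = h$tree, comm = h$comm,
           metadata = read_metadata(config$inputs$metadata),
           soil = read_predictors(config$inputs$soil),
           vegetation = read_predictors(config$inputs$vegetation))
    } else {
      sc <- config$simulate
      ds <- simulate_dataset(seed = seeds[["simulate"]], S = sc$S, J = sc$J,
                             conservatism = sc$conservatism,
                             shared_fraction = sc$shared_fraction,
                             sigma_sel = sc$sigma_sel, n_pairs = sc$n_pairs,
                             plots_per_watershed = sc$plots_per_watershed)
      write_dataset(ds, file.path(outdir, "synthetic_data"))
      ds
    }
  })

  signal <- stage("signal", {
    vars <- config$signal$variables %||% colnames(data$soil)
    res <- phylo_signal_check(data$comm, data$tree,
                              data$soil[, vars, drop = FALSE],
                              n_classes = config$signal$n_classes,
                              n_perm = config$signal$n_perm,
                              seed = seeds[["signal"]])
    for (v in names(res))
      utils::write.table(as.data.frame(res[[v]]),
                         file.path(outdir, paste0("signal_", v, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  bnti_res <- stage("bnti", {
    r <- bnti(data$comm, data$tree, n_reps = config$bnti$reps,
              seed = seeds[["bnti"]], weighted = config$bnti$weighted)
    write_matrix_tsv(r$bnti, file.path(outdir, "bnti.tsv"), "sample_id")
    utils::write.table(pairs_long(r$bnti, "bnti"),
                       file.path(outdir, "bnti_long.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    r
  })

  rc_res <- stage("rcbray", {
    r <- rc_bray(data$comm, n_reps = config$rcbray$reps,
                 seed = seeds[["rcbray"]])
    write_matrix_tsv(r$rc, file.path(outdir, "rcbray.tsv"), "sample_id")
    utils::write.table(pairs_long(r$rc, "rc"),
                       file.path(outdir, "rcbray_long.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    r
  })

  inference <- stage("classify", {
    calls <- classify_processes(bnti_res$bnti, rc_res$rc,
                                bnti_thresh = config$classify$bnti_thresh,
                                rc_thresh = config$classify$rc_thresh)
    props <- group_proportions(calls, data$metadata,
                               scope = config$classify$scope)
    comp <- compare_proportions(props)
    grp <- data$metadata$history[match(rownames(bnti_res$bnti),
                                       data$metadata$sample_id)]
    calls_grp_i <- data$metadata$history[match(calls$sample_i,
                                               data$metadata$sample_id)]
    calls_grp_j <- data$metadata$history[match(calls$sample_j,
                                               data$metadata$sample_id)]
    within <- calls_grp_i == calls_grp_j
    kw <- kruskal_wallis(split(calls$bnti[within], calls_grp_i[within]))
    utils::write.table(calls, file.path(outdir, "process_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(props, file.path(outdir, "process_proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comp, file.path(outdir, "process_comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(H = kw$H, df = kw$df, p = kw$p),
                       file.path(outdir, "kruskal_wallis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(calls = calls, proportions = props, comparisons = comp,
         kruskal = kw)
  })

  vp <- stage("varpart", {
    Y <- bnti_to_response(finite_bnti(bnti_res$bnti))
    ids <- rownames(Y)
    v <- two_set_varpart(Y, data$soil[ids, , drop = FALSE],
                         data$vegetation[ids, , drop = FALSE],
                         n_perm = config$varpart$n_perm,
                         seed = seeds[["varpart"]],
                         hellinger_veg = config$varpart$hellinger_veg)
    utils::write.table(v$table, file.path(outdir, "varpart.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    v
  })

  stage("manifest", {
    manifest <- list(config = config, seeds = as.list(seeds),
                     package_version = as.character(utils::packageVersion("ecoassembly")),
                     n_samples = nrow(data$comm), n_otus = ncol(data$comm))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  })

  invisible(list(data = data, signal = signal, bnti = bnti_res,
                 rcbray = rc_res, inference = inference, varpart = vp,
                 seeds = seeds, outdir = outdir))
}

# replace NaN betaNTI entries by 0 so the ordination keeps all samples;
# degenerate pairs are rare and logged upstream
#' @keywords internal
finite_bnti <- function(m) {
  diag(m) <- 0
  bad <- !is.finite(m)
  if (any(bad)) {
    message("replacing ", sum(bad) / 2, " undefined betaNTI pair(s) by 0 ",
            "for ordination")
    m[bad] <- 0
  }
  m
}

#' Command-line entry point
#'
#' Backs the `inst/scripts/ecoassembly` Rscript. Subcommands: `simulate`,
#' `signal`, `bnti`, `rcbray`, `classify`, `varpart`, `run-all`,
#' `validate`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit code (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ecoassembly <subcommand> [options]",
    "  simulate  --seed INT --outdir DIR [--otus INT --individuals INT]",
    "  run-all   [--config FILE] [--seed INT] [--outdir DIR]",
    "  validate  --config FILE",
    "  bnti      --tree FILE --table FILE --outdir DIR [--reps INT --seed INT --unweighted]",
    "  rcbray    --table FILE --outdir DIR [--reps INT --seed INT]",
    "  classify  --bnti FILE --rcbray FILE --metadata FILE --outdir DIR",
    "  signal    --tree FILE --table FILE --soil FILE --outdir DIR [--seed INT]",
    "  varpart   --bnti FILE --soil FILE --vegetation FILE --outdir DIR [--seed INT]",
    sep = "\n")
  if (length(args) == 0L) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- parse_cli_flags(args[-1L])
  get <- function(key, default = NULL) opts[[key]] %||% default
  num <- function(key, default = NULL) {
    v <- get(key); if (is.null(v)) default else as.numeric(v)
  }
  outdir <- get("outdir", ".")

  status <- switch(cmd,
    "simulate" = {
      ds <- simulate_dataset(seed = num("seed", 1),
                             S = num("otus", 200),
                             J = num("individuals", 1000))
      write_dataset(ds, outdir)
      message("synthetic dataset written to ", outdir)
      0L
    },
    "run-all" = {
      cfg <- if (!is.null(get("config"))) yaml::read_yaml(get("config"))
             else default_config()
      if (!is.null(get("seed"))) cfg$seed <- as.integer(num("seed"))
      if (!is.null(get("outdir"))) cfg$outdir <- outdir
      run_pipeline(cfg)
      0L
    },
    "validate" = {
      ok <- validate_config(get("config"))
      if (isTRUE(ok)) { message("config OK"); 0L }
      else { message(paste(ok, collapse = "\n")); 1L }
    },
    "bnti" = {
      h <- harmonize(read_tree(get("tree")), read_community(get("table")))
      r <- bnti(h$comm, h$tree, n_reps = num("reps", 999),
                seed = num("seed", 1),
                weighted = is.null(opts[["unweighted"]]))
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_matrix_tsv(r$bnti, file.path(outdir, "bnti.tsv"), "sample_id")
      utils::write.table(pairs_long(r$bnti, "bnti"),
                         file.path(outdir, "bnti_long.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      0L
    },
    "rcbray" = {
      r <- rc_bray(read_community(get("table")), n_reps = num("reps", 999),
                   seed = num("seed", 1))
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_matrix_tsv(r$rc, file.path(outdir, "rcbray.tsv"), "sample_id")
      utils::write.table(pairs_long(r$rc, "rc"),
                         file.path(outdir, "rcbray_long.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      0L
    },
    "classify" = {
      bm <- as.matrix(utils::read.delim(get("bnti"), row.names = 1L,
                                        check.names = FALSE))
      rm_ <- as.matrix(utils::read.delim(get("rcbray"), row.names = 1L,
                                         check.names = FALSE))
      calls <- classify_processes(bm, rm_)
      md <- read_metadata(get("metadata"))
      props <- group_proportions(calls, md)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(calls, file.path(outdir, "process_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(props, file.path(outdir, "process_proportions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(compare_proportions(props),
                         file.path(outdir, "process_comparisons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      0L
    },
    "signal" = {
      h <- harmonize(read_tree(get("tree")), read_community(get("table")))
      res <- phylo_signal_check(h$comm, h$tree, read_predictors(get("soil")),
                                seed = num("seed", 1))
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      for (v in names(res))
        utils::write.table(as.data.frame(res[[v]]),
                           file.path(outdir, paste0("signal_", v, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      0L
    },
    "varpart" = {
      bm <- as.matrix(utils::read.delim(get("bnti"), row.names = 1L,
                                        check.names = FALSE))
      v <- two_set_varpart(finite_bnti(bm), read_predictors(get("soil")),
                           read_predictors(get("vegetation")),
                           seed = num("seed", 1))
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(v$table, file.path(outdir, "varpart.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      0L
    },
    { cat(usage, "\n"); 1L })
  invisible(status)
}

#' @keywords internal
parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
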
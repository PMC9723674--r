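#' Read a phylogenetic tree from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' turnover statistics rely on: unique tip labels and a branch length on
#' every edge. Zero-length branches are legal and preserved.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  validate_tree(tree)
  tree
}

#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L)
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  bad <- which(is.na(tree$edge.length))
  if (length(bad) > 0L) {
    child <- tree$edge[bad[1L], 2L]
    lab <- if (child <= length(tree$tip.label)) tree$tip.label[child]
           else paste0("internal node ", child)
    stop("missing branch length on edge to ", lab)
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) present")
  invisible(tree)
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree An [ape::phylo] object.
#' @return A symmetric zero-diagonal matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  stats::cophenetic(tree)
}

#' Read a sample-by-OTU community table
#'
#' Reads a tab-delimited table (header row, first column = identifier) of
#' non-negative counts. Either orientation is accepted; the result is always
#' samples as rows and OTUs as columns. Real-valued tables whose rows sum to
#' approximately one are treated as relative abundances and kept as given,
#' with a notice.
#'
#' @param path Path to a TSV file.
#' @param orientation `"samples_as_rows"` (default) or `"otus_as_rows"`.
#' @return A numeric matrix, samples x OTUs, with dimnames.
#' @export
read_community <- function(path,
                           orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("community table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  if (orientation == "otus_as_rows") m <- t(m)
  storage.mode(m) <- "numeric"
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing cell at (%s, %s)",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  validate_community(m)
}

#' @keywords internal
validate_community <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community matrix must carry sample and OTU names")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative count at (%s, %s)",
                 rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("empty sample(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  # real-valued rows summing to ~1 are relative abundances, not counts
  if (all(abs(tot - 1) < 1e-6) && any(m %% 1 != 0)) {
    message("table appears to hold relative abundances; keeping as given")
    attr(m, "relative") <- TRUE
    return(m)
  }
  if (any(m %% 1 != 0))
    stop("non-integer counts present (and rows do not sum to 1)")
  attr(m, "relative") <- FALSE
  m
}

#' Write a community table to TSV
#'
#' @param comm Sample x OTU matrix.
#' @param path Output path.
#' @param orientation Orientation to write in; round-trips with
#'   [read_community()].
#' @export
write_community <- function(comm, path,
                            orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "otus_as_rows") t(comm) else comm
  id <- if (orientation == "otus_as_rows") "otu_id" else "sample_id"
  write_matrix_tsv(m, path, id_header = id)
}

#' @keywords internal
write_matrix_tsv <- function(m, path, id_header = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects tab-delimited columns `sample_id`, `watershed`, `history`
#' (`reference` or `disturbed`) and `pair` (reference-disturbed watershed
#' pairing).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' @keywords internal
validate_metadata <- function(md) {
  need <- c("sample_id", "watershed", "history", "pair")
  miss <- setdiff(need, colnames(md))
  if (length(miss) > 0L)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(md$history), c("reference", "disturbed"))
  if (length(bad) > 0L)
    stop("history must be 'reference' or 'disturbed'; found: ",
         paste(bad, collapse = ", "))
  md
}

#' Read an environmental or vegetation predictor matrix
#'
#' Tab-delimited, header row, first column = sample id, remaining columns
#' numeric. Missing values are an error unless `impute = TRUE`, in which
#' case each missing cell is replaced by its column median.
#'
#' @param path Path to a TSV file.
#' @param impute Impute missing values by column medians? Default `FALSE`
#'   (fail loudly: silent imputation corrupts variation partitioning).
#' @return A numeric matrix, samples x variables.
#' @export
read_predictors <- function(path, impute = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "numeric"
  if (anyNA(m)) {
    if (!impute) {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing predictor value at (%s, %s); use impute = TRUE for column-median imputation",
                   rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
    }
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
    }
    message("imputed ", sum(is.na(raw)), " missing value(s) by column median")
  }
  m
}

#' Harmonize a tree and a community table
#'
#' Prunes the tree to, and subsets the table to, the intersection of tip
#' labels and OTU identifiers. OTUs without a tip (unplaced OTUs are routine
#' in ITS/16S tables) are dropped with a report rather than an error.
#'
#' @param tree An [ape::phylo] object.
#' @param comm Sample x OTU matrix.
#' @return A list with elements `tree`, `comm`, `dropped_tips`,
#'   `dropped_otus`.
#' @export
harmonize <- function(tree, comm) {
  validate_tree(tree)
  shared <- intersect(tree$tip.label, colnames(comm))
  if (length(shared) == 0L)
    stop("tree tips and community OTUs share no identifiers")
  dropped_tips <- setdiff(tree$tip.label, shared)
  dropped_otus <- setdiff(colnames(comm), shared)
  if (length(dropped_tips) > 0L)
    message("dropping ", length(dropped_tips), " tree tip(s) absent from table")
  if (length(dropped_otus) > 0L)
    message("dropping ", length(dropped_otus), " OTU(s) absent from tree")
  tree2 <- if (length(dropped_tips) > 0L) ape::keep.tip(tree, shared) else tree
  comm2 <- comm[, tree2$tip.label, drop = FALSE]
  tot <- rowSums(comm2)
  if (any(tot == 0))
    stop("harmonization left empty sample(s): ",
         paste(rownames(comm2)[tot == 0], collapse = ", "))
  list(tree = tree2, comm = comm2,
       dropped_tips = dropped_tips, dropped_otus = dropped_otus)
}

#' Relative abundances of a community table
#'
#' @param comm Sample x OTU matrix of counts (or relative abundances, which
#'   pass through unchanged up to renormalization).
#' @return Matrix of the same shape; every row sums to 1.
#' @export
relative_abundance <- function(comm) {
  tot <- rowSums(comm)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(rownames(comm)[tot == 0], collapse = ", "))
  comm / tot
}
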
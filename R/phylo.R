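#' Read a sample of time-calibrated trees
#'
#' Reads one or more rooted, possibly non-ultrametric trees from a Newick or
#' NEXUS file and optionally prunes each tree down to a set of analysis taxa
#' (e.g. dropping outgroups and taxa without trait data). Pruning merges the
#' two edges at any resulting degree-2 node by summing their lengths, so
#' root-to-tip path lengths of retained taxa are preserved.
#'
#' @param path path to a Newick (one tree per line) or NEXUS file; the format
#'   is detected from the file header.
#' @param keep optional character vector of tip labels to retain. Must be a
#'   subset of the tip labels of every tree in the file. Labels are matched
#'   exactly after trimming surrounding whitespace.
#' @return a list of `phylo` objects (class `multiPhylo`), each rooted with
#'   non-negative branch lengths in the units of the input file (Myr for
#'   time-calibrated trees).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((a:1,b:1):2,c:3);", tf)
#' trees <- read_trees(tf, keep = c("a", "c"))
#' trees[[1]]$tip.label
#' @export
read_trees <- function(path, keep = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  trees <- if (startsWith(first, "#NEXUS")) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(trees, "phylo")) trees <- c(trees)      # promote to multiPhylo
  if (length(trees) == 0L) stop("no trees parsed from ", path)
  trees <- lapply(trees, function(tr) {
    tr$tip.label <- trimws(tr$tip.label)
    validate_tree(tr)
    if (!is.null(keep)) {
      keep <- trimws(keep)
      missing <- setdiff(keep, tr$tip.label)
      if (length(missing) > 0L)
        stop("requested tips absent from a tree: ", paste(missing, collapse = ", "))
      tr <- prune_tips(tr, keep)
    }
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

#' Prune a tree to a set of tips, preserving root-to-tip path lengths
#'
#' Drops all tips outside `keep`, merging the two edges at any resulting
#' degree-2 node by summing their lengths. When the kept tips' most recent
#' common ancestor lies below the original root, the root-to-MRCA stem is
#' retained as the tree's `root.edge`, so every kept tip's distance from the
#' original root is preserved (and [phylo_cov()] accounts for it).
#'
#' @param tree a rooted `phylo`.
#' @param keep character vector of tip labels to retain.
#' @return the pruned `phylo`.
#' @export
prune_tips <- function(tree, keep) {
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0L)
    stop("requested tips absent from a tree: ",
         paste(missing, collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)
  stem <- 0
  if (length(keep) > 1L) {
    mrca <- ape::getMRCA(tree, keep)
    stem <- ape::node.depth.edgelength(tree)[mrca]
  }
  old_root <- tree$root.edge %||% 0
  out <- ape::keep.tip(tree, keep)
  if (stem + old_root > 0) out$root.edge <- stem + old_root
  out
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  invisible(tree)
}

#' Phylogenetic shared-path covariance matrix
#'
#' Computes the species-by-species phylogenetic variance-covariance matrix of
#' a rooted tree: entry (i, j) is the root-to-MRCA(i, j) path length and the
#' diagonal holds each tip's root-to-tip depth. Fossil (non-ultrametric) trees
#' are handled without modification; polytomies are treated as hard.
#'
#' By default the matrix is rescaled by the mean of its diagonal so that the
#' average tip depth is 1. This makes the phylogenetic variance component
#' comparable across trees of different total depths, and makes the
#' heritability computed by [heritability()] well defined for non-ultrametric
#' trees where tip depths differ. The factor used is retained in
#' `scale_factor` so the matrix in original Myr^2 units is
#' `scale_factor * as.matrix(x)`.
#'
#' @param tree a rooted `phylo` object with non-negative branch lengths.
#' @param rescale divide the matrix by the mean of its diagonal (default TRUE).
#' @return an object of class `phylo_cov`: a list with elements `labels`
#'   (species names, in matrix order), `V` (the covariance matrix), and
#'   `scale_factor` (the mean tip depth divided out; 1 when `rescale = FALSE`).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):2,c:3);")
#' phylo_cov(tr, rescale = FALSE)$V
#' @export
phylo_cov <- function(tree, rescale = TRUE) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2L) stop("need at least 2 tips")
  V <- ape::vcv(tree)
  # a root edge (e.g. the stem retained by pruning) is shared by every tip
  if (!is.null(tree$root.edge) && tree$root.edge > 0)
    V <- V + tree$root.edge
  sf <- 1
  if (rescale) {
    sf <- mean(diag(V))
    V <- V / sf
  }
  structure(list(labels = rownames(V), V = V, scale_factor = sf),
            class = "phylo_cov")
}

#' @export
as.matrix.phylo_cov <- function(x, ...) x$V

#' @export
print.phylo_cov <- function(x, ...) {
  cat("Phylogenetic shared-path covariance:", length(x$labels), "species",
      sprintf("(mean tip depth divided out: %.4g)\n", x$scale_factor))
  print(x$V, ...)
  invisible(x)
}

#' Export a phylogenetic covariance matrix as labelled CSV
#'
#' @param cov a `phylo_cov` object.
#' @param path output CSV path; species labels are written as the first column
#'   and as the header row.
#' @return `path`, invisibly.
#' @export
write_phylo_cov <- function(cov, path) {
  stopifnot(inherits(cov, "phylo_cov"))
  df <- data.frame(species = cov$labels, cov$V, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Root-to-tip node counts
#'
#' Counts, for every tip, the number of internal nodes on the path from the
#' root to that tip, counting the root and excluding the tip itself. The
#' log10 of the count is the speciation-rate proxy used as the cladogenesis
#' covariate in model M3: tips subtended by more splitting events carry larger
#' counts regardless of branch lengths.
#'
#' @param tree a rooted `phylo` object.
#' @return a data.frame with columns `species`, `count`, `log10_count`.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):2,c:3);")
#' node_counts(tr)
#' @export
node_counts <- function(tree) {
  validate_tree(tree)
  paths <- ape::nodepath(tree)   # root -> tip node sequences, per tip
  cnt <- vapply(paths, function(p) length(p) - 1L, integer(1))
  data.frame(species = tree$tip.label, count = cnt,
             log10_count = log10(cnt), stringsAsFactors = FALSE)
}
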
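# Phylogeny handling: Newick I/O, pruning, and among-species covariance
# under a Pagel's-lambda transform. Tree parsing and pruning are delegated
# to ape; the covariance contracts (and the lambda transform, which acts
# on the matrix) are owned here.

.normalize_labels <- function(x) gsub("[ _]+", "_", trimws(x))

#' Read a phylogeny from Newick
#'
#' Wraps [ape::read.tree()] with the validity checks the downstream
#' analyses rely on: unique tip labels, branch lengths present, finite
#' and non-negative.
#'
#' @param source A file path or a Newick string.
#' @return An [ape::phylo] object.
#' @export
read_phylogeny <- function(source) {
  tr <- if (file.exists(source)) ape::read.tree(source)
        else ape::read.tree(text = source)
  if (is.null(tr)) stop("failed to parse Newick input")
  validate_phylogeny(tr)
}

#' Validate a phylogeny for comparative analyses
#'
#' @param tree An `ape::phylo` object.
#' @return The tree, invisibly unchanged, or an error.
#' @export
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  tree
}

#' Write a phylogeny to Newick
#'
#' @param tree An `ape::phylo` object.
#' @param path Optional file path; if `NULL`, the Newick string is
#'   returned.
#' @return The path (invisibly) or the Newick string.
#' @export
write_phylogeny <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Prune a phylogeny to a set of species
#'
#' Induced subtree on `keep`: dropped tips removed, degree-2 nodes
#' collapsed with branch lengths summed, so root-to-tip path lengths of
#' retained tips are unchanged. Label matching is exact after
#' normalising whitespace/underscores on both sides.
#'
#' @param tree An `ape::phylo` object.
#' @param keep Character vector of tip labels to retain.
#' @return The pruned `ape::phylo`.
#' @export
prune_phylogeny <- function(tree, keep) {
  validate_phylogeny(tree)
  if (!length(keep)) stop("cannot prune to an empty tip set")
  tipn <- .normalize_labels(tree$tip.label)
  keepn <- .normalize_labels(keep)
  missing <- keep[!keepn %in% tipn]
  if (length(missing))
    stop(errorCondition(
      paste0("species not in tree: ", paste(missing, collapse = ", ")),
      class = c("squamorph_taxa_mismatch", "error", "condition")))
  ape::keep.tip(tree, tree$tip.label[tipn %in% keepn])
}

#' Report the overlap between a trait table and a tree
#'
#' @param species Character vector of species in the data.
#' @param tree An `ape::phylo` object.
#' @return List with `matched`, `data_only`, `tree_only` character
#'   vectors and a preformatted `text` report.
#' @export
taxa_overlap_report <- function(species, tree) {
  sn <- .normalize_labels(species)
  tn <- .normalize_labels(tree$tip.label)
  matched <- species[sn %in% tn]
  data_only <- species[!sn %in% tn]
  tree_only <- tree$tip.label[!tn %in% sn]
  txt <- c(sprintf("taxa overlap: %d matched, %d in data only, %d in tree only",
                   length(matched), length(data_only), length(tree_only)),
           if (length(data_only)) paste0("  data only: ", paste(data_only, collapse = ", ")),
           if (length(tree_only)) paste0("  tree only: ", paste(tree_only, collapse = ", ")))
  list(matched = matched, data_only = data_only, tree_only = tree_only,
       text = paste(txt, collapse = "\n"))
}

#' Phylogenetic variance-covariance structure
#'
#' `V[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`
#' (the Brownian-motion trait covariance up to a rate constant);
#' `V[i, i]` is the root-to-tip distance. The returned object records the
#' lambda already applied (1 for an untransformed tree).
#'
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @return An object of class `phylo_cov`: list with `taxa`, `V`,
#'   `lambda`.
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  # ape stores unrooted binary trees as a basal trichotomy; a wider basal
  # polytomy is taken as a genuine (star-like) rooted topology
  root <- length(tree$tip.label) + 1L
  if (!ape::is.rooted(tree) && sum(tree$edge[, 1] == root) == 3L &&
      length(tree$tip.label) > 3L)
    stop("tree must be rooted to define a phylogenetic covariance")
  V <- ape::vcv(tree)
  structure(list(taxa = rownames(V), V = V, lambda = 1),
            class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat(sprintf("<phylo_cov> %d taxa, lambda = %g, depth range [%g, %g]\n",
              length(x$taxa), x$lambda, min(diag(x$V)), max(diag(x$V))))
  invisible(x)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies all off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` returns the Brownian covariance, `lambda = 0`
#' a star phylogeny (independent species).
#'
#' @param cov A `phylo_cov` object (or plain covariance matrix).
#' @param lambda Scalar in `[0, 1]`.
#' @return A `phylo_cov` with the transform applied; `lambda` recorded is
#'   the product of successive transforms.
#' @export
lambda_transform <- function(cov, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  if (is.matrix(cov)) cov <- structure(list(taxa = rownames(cov), V = cov,
                                            lambda = 1), class = "phylo_cov")
  V <- cov$V
  d <- diag(V)
  V <- lambda * V
  diag(V) <- d
  structure(list(taxa = cov$taxa, V = V, lambda = cov$lambda * lambda),
            class = "phylo_cov")
}

# V(lambda) as a plain matrix from a base (lambda = 1) covariance
.lambda_V <- function(V, lambda) {
  d <- diag(V)
  W <- lambda * V
  diag(W) <- d
  W
}
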
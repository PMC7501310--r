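#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Branch lengths are required because all downstream analyses rest on
#' cophenetic (tip-to-tip path) distances; polytomies and zero-length edges
#' are allowed.
#'
#' @param path Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("tree has missing branch lengths; tip-to-tip distances are undefined")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  tr
}

#' Intersect a community table with a phylogeny
#'
#' Keeps only taxa present in both the table and the tree, aligning the
#' table's row order to the pruned tree's tip order. Dropped counts are
#' reported with a warning.
#'
#' @param table A `comm_table`.
#' @param tree A rooted `phylo` with branch lengths.
#' @return `list(table=, tree=)` on the common taxon set.
#' @export
match_taxa <- function(table, tree) {
  validate_tree(tree)
  common <- intersect(rownames(table), tree$tip.label)
  if (length(common) == 0) stop("no taxa shared between table and tree")
  drop_tab <- nrow(table) - length(common)
  drop_tree <- length(tree$tip.label) - length(common)
  if (drop_tab > 0 || drop_tree > 0)
    warning(sprintf("dropping %d taxa from table and %d tips from tree",
                    drop_tab, drop_tree))
  tree2 <- ape::keep.tip(tree, common)
  m <- unclass(table)[tree2$tip.label, , drop = FALSE]
  cs <- colSums(m)
  if (any(cs == 0))
    stop("sample(s) left empty after taxon matching: ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  # dropped taxa break the unit column sums, so the result is never
  # flagged relative; re-normalise with to_relative() if needed
  list(table = community_table(m, is_relative = FALSE), tree = tree2)
}

#' Cophenetic distance matrix of a phylogeny
#'
#' d(i, j) is the sum of branch lengths on the path between tips i and j;
#' this matrix carries all phylogenetic information used by the binning and
#' null-model machinery.
#'
#' @param tree A `phylo` with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal, tips as dimnames.
#' @export
cophenetic_distances <- function(tree) {
  validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}
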
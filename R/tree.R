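#' Patristic (cophenetic) distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric species x species matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(tree) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Insert a taxon at its most derived consensus clade (MDCC)
#'
#' Grafts a phylogenetically uncertain taxon onto the crown node of the
#' clade spanned by `mdcc_tips`. The new terminal branch length equals the
#' depth of that clade (mean crown-to-tip distance), so on an ultrametric
#' tree the inserted tip sits level with the clade's existing tips and all
#' original pairwise distances are preserved.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param taxon name of the tip to insert (must be absent from the tree).
#' @param mdcc_tips character vector of existing tip labels whose most
#'   recent common ancestor defines the clade; the set must be
#'   monophyletic (it must contain every descendant tip of that ancestor).
#' @return the enlarged `phylo` tree (tip count + 1).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' tr2 <- add_taxon_at_mdcc(tr, "X", c("A", "B"))
#' ape::cophenetic.phylo(tr2)["X", "A"]  # 2: level with A and B
#' @export
add_taxon_at_mdcc <- function(tree, taxon, mdcc_tips) {
  tree <- validate_tree(tree)
  taxon <- canonical_ids(taxon)
  mdcc_tips <- canonical_ids(mdcc_tips)
  if (taxon %in% tree$tip.label) {
    stop("taxon already present in tree: ", taxon)
  }
  missing <- setdiff(mdcc_tips, tree$tip.label)
  if (length(missing)) {
    stop("MDCC tips absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(mdcc_tips) == 1L) {
    # degenerate clade: attach as sister to the single tip at mid-branch
    node <- match(mdcc_tips, tree$tip.label)
    edge <- which(tree$edge[, 2] == node)
    len <- tree$edge.length[edge] / 2
    return(phytools::bind.tip(tree, taxon, edge.length = len,
                              where = node, position = len))
  }
  node <- ape::getMRCA(tree, mdcc_tips)
  desc <- tree$tip.label[tip_descendants(tree, node)]
  extra <- setdiff(desc, mdcc_tips)
  if (length(extra)) {
    stop("MDCC tip set is not monophyletic; clade also contains: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  depths <- ape::node.depth.edgelength(tree)
  tipn <- match(mdcc_tips, tree$tip.label)
  clade_depth <- mean(depths[tipn] - depths[node])
  phytools::bind.tip(tree, taxon, edge.length = clade_depth, where = node)
}

# tip indices descending from an internal node
tip_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tip_descendants, tree = tree))
}
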
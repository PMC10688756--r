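#' Phylogeny-weighted species composition (P matrix)
#'
#' Smooths the incidence matrix by phylogenetic similarity: with patristic
#' distances `D`, species similarity is `S = 1 - D / max(D)` (diagonal 1),
#' the raw weighted composition is `incidence %*% S`, and each row is
#' divided by its sum so rows are compositional (sum to one).
#'
#' @param cm a [community_matrix()].
#' @param tree rooted `phylo` with branch lengths covering `cm` species.
#' @return sites x species matrix with non-negative entries and unit row
#'   sums.
#' @export
phylo_weighted_composition <- function(cm, tree) {
  stopifnot(inherits(cm, "community_matrix"))
  d <- cophenetic_matrix(tree)
  missing <- setdiff(cm$species_ids, rownames(d))
  if (length(missing)) {
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  }
  d <- d[cm$species_ids, cm$species_ids]
  dmax <- max(d)
  if (dmax <= 0) stop("all patristic distances are zero; tree is degenerate")
  s <- 1 - d / dmax
  raw <- cm$incidence %*% s
  p <- raw / rowSums(raw)
  dimnames(p) <- dimnames(cm$incidence)
  p
}

#' Principal coordinates of phylogenetic structure (PCPS)
#'
#' Ordination of the phylogeny-weighted species composition: pairwise
#' Bray-Curtis dissimilarities among P-matrix rows, square-root
#' transformed, then principal coordinates via [pcoa_axes()]. The leading
#' axis captures the deepest phylogenetic gradients across sites.
#'
#' @param cm a [community_matrix()].
#' @param tree rooted `phylo` with branch lengths covering `cm` species.
#' @param sqrt_transform apply the square-root transform to the
#'   dissimilarities (default `TRUE`, which makes Bray-Curtis nearly
#'   Euclidean).
#' @param correction eigenvalue correction passed to [pcoa_axes()].
#' @return a `pcoa_result` whose `scores` columns are renamed `PCPS1`,
#'   `PCPS2`, ... and which carries the P matrix in attribute `"P"`.
#' @export
pcps <- function(cm, tree, sqrt_transform = TRUE,
                 correction = c("none", "cailliez")) {
  stopifnot(inherits(cm, "community_matrix"))
  if (nrow(cm$incidence) < 3L) stop("PCPS needs at least 3 sites")
  p <- phylo_weighted_composition(cm, tree)
  d <- vegan::vegdist(p, method = "bray")
  if (sqrt_transform) d <- sqrt(d)
  res <- pcoa_axes(d, correction = match.arg(correction))
  colnames(res$scores) <- paste0("PCPS", seq_len(ncol(res$scores)))
  attr(res, "P") <- p
  res
}
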
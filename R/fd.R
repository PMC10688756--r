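#' Functional dendrogram from a species feature matrix
#'
#' Hierarchical clustering (UPGMA by default) of Euclidean distances among
#' species feature vectors, returned as a rooted ultrametric `phylo` tree.
#' Cophenetic distances on the returned tree equal the clustering merge
#' heights (each node sits at half the merge height, so tip-to-tip path
#' lengths reproduce the heights).
#'
#' @param features numeric species x feature matrix (e.g. PVR-controlled
#'   traits from [trait_pvr_residuals()]); no missing values.
#' @param distance distance metric; only `"euclidean"` is supported.
#' @param linkage clustering linkage; `"upgma"` (average) is the default.
#' @return ultrametric `phylo` of class `c("functional_dendrogram",
#'   "phylo")` with the species as tips.
#' @export
functional_dendrogram <- function(features, distance = c("euclidean"),
                                  linkage = c("upgma")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least two species")
  if (anyNA(features)) stop("features contain NA; impute traits first")
  if (is.null(rownames(features))) stop("features must have species names")
  d <- stats::dist(features, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  dend <- ape::as.phylo(hc)
  class(dend) <- c("functional_dendrogram", "phylo")
  dend
}

#' Petchey-Gaston functional diversity (dendrogram branch-length sum)
#'
#' For each site, the total branch length of the dendrogram subtree
#' spanning the site's species, including the path to the dendrogram root
#' (root-inclusive, as in Faith's PD). A single-species site therefore
#' scores its tip-to-root length, and the full species pool scores the
#' total tree length.
#'
#' @param dend dendrogram (`phylo`) whose tips cover the community species.
#' @param cm a [community_matrix()].
#' @return data.frame with columns `site_id`, `fd` and `richness`.
#' @export
fd_petchey_gaston <- function(dend, cm) {
  stopifnot(inherits(cm, "community_matrix"))
  if (any(rowSums(cm$incidence) == 0L)) stop("empty sites are not allowed")
  fd <- fd_from_incidence(cm$incidence, dendrogram_paths(dend, cm$species_ids))
  data.frame(site_id = cm$site_ids, fd = fd,
             richness = rowSums(cm$incidence),
             stringsAsFactors = FALSE)
}

#' SES of functional diversity under the taxa-label null model
#'
#' Null replicates permute the species labels on the dendrogram tips
#' (equivalently, permute the species -> tip assignment), keeping both the
#' dendrogram shape and the incidence matrix fixed, and recompute FD per
#' site. Negative SES indicates functional clustering, positive SES
#' functional overdispersion.
#'
#' @param dend dendrogram (`phylo`) whose tips cover the community species.
#' @param cm a [community_matrix()].
#' @param n_null number of label permutations (default 999).
#' @param seed integer seed.
#' @return a [ses_result()] with statistic `"fd"`.
#' @export
ses_fd <- function(dend, cm, n_null = 999L, seed = 1L) {
  stopifnot(inherits(cm, "community_matrix"))
  n_null <- as.integer(n_null)
  if (n_null < 1L) stop("n_null must be >= 1")
  paths <- dendrogram_paths(dend, cm$species_ids)
  inc <- Matrix::Matrix(cm$incidence, sparse = TRUE)
  obs <- fd_from_incidence(inc, paths)
  n_sp <- length(cm$species_ids)
  nulls <- matrix(0, nrow(cm$incidence), n_null)
  withr_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(n_sp)
      nulls[, r] <- fd_from_incidence(
        inc, list(tip_edge = paths$tip_edge[perm, , drop = FALSE],
                  lengths = paths$lengths))
    }
  })
  ses_result(cm$site_ids, obs,
             null_mean = rowMeans(nulls),
             null_sd = apply(nulls, 1L, stats::sd),
             n_replicates = n_null, seed = seed, statistic = "fd")
}

# tip x edge incidence (1 where the edge lies on the tip's root path),
# aligned to the given species order, plus edge lengths
dendrogram_paths <- function(dend, species_ids) {
  stopifnot(inherits(dend, "phylo"))
  missing <- setdiff(species_ids, dend$tip.label)
  if (length(missing)) {
    stop("dendrogram lacks species: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  n_tip <- length(dend$tip.label)
  n_edge <- nrow(dend$edge)
  # accumulate tips under each edge by walking edges child-first
  below <- vector("list", n_tip + dend$Nnode)
  for (i in ape::postorder(dend)) {
    child <- dend$edge[i, 2]
    if (child <= n_tip) {
      below[[child]] <- child
    }
    parent <- dend$edge[i, 1]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  ii <- integer(0); jj <- integer(0)
  for (e in seq_len(n_edge)) {
    tips <- below[[dend$edge[e, 2]]]
    ii <- c(ii, tips)
    jj <- c(jj, rep.int(e, length(tips)))
  }
  tip_edge <- Matrix::sparseMatrix(i = ii, j = jj,
                                   dims = c(n_tip, n_edge))
  rownames(tip_edge) <- dend$tip.label
  list(tip_edge = tip_edge[species_ids, , drop = FALSE],
       lengths = dend$edge.length)
}

fd_from_incidence <- function(inc, paths) {
  hits <- (inc %*% paths$tip_edge) > 0
  drop(as.matrix(hits %*% paths$lengths))
}
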
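#' Community incidence matrix with site coordinates
#'
#' Bundles a sites x species presence/absence matrix with per-site
#' geographic coordinates. This is the central community container used by
#' the null models, the phylogeny-weighted ordination and the functional
#' diversity calculations.
#'
#' Site and species identifiers must be unique; names are canonicalised by
#' trimming whitespace and replacing internal spaces with underscores so
#' they can be matched against Newick tip labels.
#'
#' @param incidence numeric or logical matrix (sites x species), entries 0/1.
#' @param coords two-column matrix or data.frame of (longitude, latitude)
#'   in decimal degrees, one row per site.
#' @param site_ids,species_ids optional character vectors; defaults taken
#'   from `dimnames(incidence)`.
#' @return an object of class `community_matrix` with elements `incidence`
#'   (integer matrix with dimnames), `coords` (matrix with columns
#'   `lon`, `lat`), `site_ids` and `species_ids`.
#' @examples
#' inc <- matrix(c(1, 1, 0, 1, 1, 1), 2, 3,
#'               dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' cm <- community_matrix(inc, cbind(lon = c(-50, -51), lat = c(-20, -21)))
#' cm
#' @export
community_matrix <- function(incidence, coords, site_ids = NULL,
                             species_ids = NULL) {
  incidence <- as.matrix(incidence)
  if (is.logical(incidence)) storage.mode(incidence) <- "integer"
  if (is.null(site_ids)) site_ids <- rownames(incidence)
  if (is.null(species_ids)) species_ids <- colnames(incidence)
  if (is.null(site_ids) || is.null(species_ids)) {
    stop("site and species identifiers are required (dimnames or arguments)")
  }
  site_ids <- canonical_ids(site_ids)
  species_ids <- canonical_ids(species_ids)
  if (anyDuplicated(site_ids)) {
    stop("duplicate site ids: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  }
  if (anyDuplicated(species_ids)) {
    stop("duplicate species ids: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  }
  if (!all(incidence %in% c(0L, 1L))) {
    stop("incidence entries must be 0 or 1")
  }
  storage.mode(incidence) <- "integer"
  dimnames(incidence) <- list(site_ids, species_ids)

  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns (lon, lat)")
  if (nrow(coords) != nrow(incidence)) {
    stop("coords must have one row per site")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (any(coords[, 2] <= -90 | coords[, 2] >= 90) ||
      any(coords[, 1] <= -180 | coords[, 1] >= 180)) {
    stop("coordinates outside (-180, 180) longitude / (-90, 90) latitude")
  }
  colnames(coords) <- c("lon", "lat")
  rownames(coords) <- site_ids

  structure(
    list(incidence = incidence, coords = coords,
         site_ids = site_ids, species_ids = species_ids),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("Community matrix: ", nrow(x$incidence), " sites x ",
      ncol(x$incidence), " species\n", sep = "")
  rich <- rowSums(x$incidence)
  cat("  richness: ", min(rich), "-", max(rich),
      " (mean ", round(mean(rich), 2), ")\n", sep = "")
  cat("  occupancy fill: ",
      round(100 * mean(x$incidence), 2), "%\n", sep = "")
  invisible(x)
}

#' Site richness of a community matrix
#' @param cm a [community_matrix()].
#' @return named integer vector of per-site species counts.
#' @export
site_richness <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  rowSums(cm$incidence)
}

# trim whitespace, collapse internal spaces to underscores (Newick style)
canonical_ids <- function(x) {
  x <- trimws(as.character(x))
  gsub("[ ]+", "_", x)
}

#' Drop sites failing the coordinate and minimum-richness filters
#'
#' Sites with missing/non-finite coordinates or with fewer than
#' `min_richness` species are removed. The filter is idempotent.
#'
#' @param incidence sites x species 0/1 matrix.
#' @param coords two-column coordinate matrix aligned to `incidence` rows;
#'   rows with non-finite values mark a site for removal.
#' @param min_richness minimum number of species a site must hold
#'   (default 2: single-species records are not communities).
#' @return list with the filtered `incidence`, `coords` and `dropped`
#'   (character vector of removed site ids).
#' @export
filter_sites <- function(incidence, coords, min_richness = 2L) {
  incidence <- as.matrix(incidence)
  coords <- as.matrix(coords)
  ok_coord <- apply(coords, 1L, function(r) all(is.finite(r))) &
    coords[, 2] > -90 & coords[, 2] < 90 &
    coords[, 1] > -180 & coords[, 1] < 180
  ok_rich <- rowSums(incidence, na.rm = TRUE) >= min_richness
  keep <- ok_coord & ok_rich
  list(incidence = incidence[keep, , drop = FALSE],
       coords = coords[keep, , drop = FALSE],
       dropped = rownames(incidence)[!keep])
}
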
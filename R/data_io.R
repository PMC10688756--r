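#' Read a community incidence table
#'
#' Accepts either a wide table (one row per site: site id, longitude,
#' latitude, then one 0/1 column per species) or a long table with columns
#' `site`, `lon`, `lat`, `species` (one row per occurrence record). The
#' format of the file is inferred from its extension (`.csv` or `.xlsx`;
#' XLSX requires the readxl package).
#'
#' Sites with missing or out-of-range coordinates and sites with fewer
#' than two species are dropped, and the number of dropped sites is
#' reported via a message and the `"dropped_sites"` attribute.
#'
#' @param path path to a CSV or XLSX file.
#' @param layout `"auto"` (default), `"wide"` or `"long"`.
#' @param sheet sheet index or name for XLSX input.
#' @return a [community_matrix()] with attribute `dropped_sites`.
#' @export
read_community_table <- function(path, layout = c("auto", "wide", "long"),
                                 sheet = 1L) {
  layout <- match.arg(layout)
  df <- read_table_file(path, sheet = sheet)
  names(df) <- tolower(names(df))
  coord_names <- resolve_coord_names(names(df))
  if (is.null(coord_names)) {
    stop("community table lacks coordinate columns ",
         "(expected longitude/latitude, lon/lat or x/y)")
  }
  site_col <- intersect(c("site", "site_id", "id", "locality"), names(df))[1]
  if (is.na(site_col)) site_col <- names(df)[1]
  if (layout == "auto") {
    layout <- if ("species" %in% names(df)) "long" else "wide"
  }

  if (layout == "long") {
    key <- paste(df[[site_col]], df$species, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop("duplicate (site, species) records: ",
           paste(gsub("\r", " / ", utils::head(dup, 5L)), collapse = "; "))
    }
    sites <- unique(as.character(df[[site_col]]))
    species <- sort(unique(canonical_ids(df$species)))
    inc <- matrix(0L, length(sites), length(species),
                  dimnames = list(sites, species))
    inc[cbind(match(as.character(df[[site_col]]), sites),
              match(canonical_ids(df$species), species))] <- 1L
    coords <- do.call(rbind, lapply(sites, function(s) {
      i <- match(s, as.character(df[[site_col]]))
      c(df[[coord_names[1]]][i], df[[coord_names[2]]][i])
    }))
  } else {
    sites <- as.character(df[[site_col]])
    coords <- cbind(df[[coord_names[1]]], df[[coord_names[2]]])
    sp_cols <- setdiff(names(df), c(site_col, coord_names))
    inc <- as.matrix(df[sp_cols])
    inc[is.na(inc)] <- 0
    if (!all(inc %in% c(0, 1))) stop("wide table species entries must be 0/1")
    storage.mode(inc) <- "integer"
    dimnames(inc) <- list(sites, sp_cols)
  }
  rownames(coords) <- rownames(inc)

  filt <- filter_sites(inc, coords)
  if (length(filt$dropped)) {
    message(length(filt$dropped),
            " site(s) dropped (coordinate or single-species filter)")
  }
  cm <- community_matrix(filt$incidence, filt$coords)
  attr(cm, "dropped_sites") <- filt$dropped
  cm
}

#' Read a species trait table
#'
#' Expects one row per species with a `species` column, the categorical
#' traits `oviposition_type` (aquatic/terrestrial), `development_type`
#' (larval/direct), `juvenile_habitat` (terrestrial/aquatic/semiterrestrial)
#' and `oviposition_site` (seven site categories), and the continuous
#' traits `body_length`, `head_width` and `tibia_length` in millimetres
#' (missing values allowed for the continuous traits only).
#'
#' @param path path to a CSV or XLSX file.
#' @param sheet sheet index or name for XLSX input.
#' @return data.frame with canonical species ids as row names.
#' @export
read_trait_table <- function(path, sheet = 1L) {
  df <- read_table_file(path, sheet = sheet)
  names(df) <- tolower(names(df))
  sp_col <- intersect(c("species", "species_id", "id"), names(df))[1]
  if (is.na(sp_col)) sp_col <- names(df)[1]
  rownames(df) <- canonical_ids(df[[sp_col]])
  df[[sp_col]] <- NULL
  validate_trait_table(df)
}

trait_levels <- list(
  oviposition_type = c("aquatic", "terrestrial"),
  development_type = c("larval", "direct"),
  juvenile_habitat = c("terrestrial", "aquatic", "semiterrestrial"),
  oviposition_site = c("water_or_submersed_substrate", "bubble_nest",
                       "foam_nest", "female_back", "ground_rock_burrow",
                       "arboreal", "carried_by_adult")
)

continuous_traits <- c("body_length", "head_width", "tibia_length")

#' Validate a trait table against the fixed trait vocabulary
#'
#' @param tt data.frame with species as row names.
#' @return the validated data.frame (categorical columns as factors with
#'   the canonical level sets).
#' @export
validate_trait_table <- function(tt) {
  if (anyDuplicated(rownames(tt))) stop("duplicate species in trait table")
  for (tr in names(trait_levels)) {
    if (!tr %in% names(tt)) next
    v <- as.character(tt[[tr]])
    if (tr == "development_type" && anyNA(v)) {
      stop("development_type may not be missing")
    }
    bad <- setdiff(stats::na.omit(unique(v)), trait_levels[[tr]])
    if (length(bad)) {
      stop("invalid ", tr, " level(s): ", paste(bad, collapse = ", "))
    }
    tt[[tr]] <- factor(v, levels = trait_levels[[tr]])
  }
  if (!"development_type" %in% names(tt)) {
    stop("trait table must contain development_type")
  }
  for (tr in intersect(continuous_traits, names(tt))) {
    v <- as.numeric(tt[[tr]])
    if (any(v[!is.na(v)] <= 0)) stop(tr, " must be strictly positive")
    tt[[tr]] <- v
  }
  tt
}

#' Read a site x environment table
#'
#' @param path path to a CSV or XLSX file with a site id column and one
#'   numeric column per environmental variable (e.g. BIO4, BIO12, ET0,
#'   slope).
#' @param sheet sheet index or name for XLSX input.
#' @return data.frame of environmental variables, sites as row names.
#' @export
read_env_table <- function(path, sheet = 1L) {
  df <- read_table_file(path, sheet = sheet)
  site_col <- intersect(c("site", "site_id", "id"), tolower(names(df)))[1]
  if (is.na(site_col)) site_col <- tolower(names(df))[1]
  i <- match(site_col, tolower(names(df)))
  rownames(df) <- canonical_ids(df[[i]])
  df <- df[-i]
  num <- vapply(df, is.numeric, logical(1))
  df <- df[num]
  if (!all(vapply(df, function(v) all(is.finite(v)), logical(1)))) {
    stop("environmental values must be finite")
  }
  df
}

#' Read a rooted, branch-lengthed phylogenetic tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contract needed
#' downstream: the tree must be rooted and carry branch lengths.
#' Polytomies are preserved.
#'
#' @param path path to a Newick file.
#' @return an [ape::read.tree()] `phylo` object with canonicalised tip
#'   labels.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree)
}

validate_tree <- function(tree, allow_basal_polytomy = TRUE) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; a branch-lengthed tree is required")
  }
  # ape calls a tree with a basal polytomy unrooted; we accept it (a
  # rooted consensus tree or a star tree is a legitimate input)
  if (!ape::is.rooted(tree) && !allow_basal_polytomy) {
    stop("tree is unrooted; a rooted tree is required")
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree$tip.label <- canonical_ids(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Align community, trait, tree and environment inputs
#'
#' Restricts species to the intersection of the community matrix, the
#' trait table and the tree tips, and sites to the intersection of the
#' community matrix and the environment table, putting everything in a
#' single consistent order. Sites left with fewer than two species after
#' the species restriction are dropped as well.
#'
#' @param cm a [community_matrix()].
#' @param tt trait table (data.frame, species as row names), or `NULL`.
#' @param tree a `phylo` tree, or `NULL`.
#' @param env environment table (data.frame, sites as row names), or `NULL`.
#' @return list with the aligned `cm`, `tt`, `tree`, `env` and a `dropped`
#'   list reporting the ids removed from each input.
#' @export
align_inputs <- function(cm, tt = NULL, tree = NULL, env = NULL) {
  stopifnot(inherits(cm, "community_matrix"))
  species <- cm$species_ids
  if (!is.null(tt)) species <- intersect(species, rownames(tt))
  if (!is.null(tree)) species <- intersect(species, tree$tip.label)
  sites <- cm$site_ids
  if (!is.null(env)) sites <- intersect(sites, rownames(env))
  if (length(species) == 0L) stop("no species shared across inputs")
  if (length(sites) == 0L) stop("no sites shared across inputs")

  dropped <- list(
    species_cm = setdiff(cm$species_ids, species),
    species_tt = if (is.null(tt)) character() else
      setdiff(rownames(tt), species),
    species_tree = if (is.null(tree)) character() else
      setdiff(tree$tip.label, species),
    sites_cm = setdiff(cm$site_ids, sites),
    sites_env = if (is.null(env)) character() else
      setdiff(rownames(env), sites)
  )

  inc <- cm$incidence[sites, species, drop = FALSE]
  coords <- cm$coords[sites, , drop = FALSE]
  keep <- rowSums(inc) >= 2L
  dropped$sites_richness <- rownames(inc)[!keep]
  inc <- inc[keep, , drop = FALSE]
  coords <- coords[keep, , drop = FALSE]

  out <- list(
    cm = community_matrix(inc, coords),
    tt = if (is.null(tt)) NULL else tt[species, , drop = FALSE],
    tree = if (is.null(tree)) NULL else
      ape::keep.tip(tree, species),
    env = if (is.null(env)) NULL else
      env[rownames(inc), , drop = FALSE],
    dropped = dropped
  )
  out
}

# shared CSV/XLSX reader; the canonical on-disk format is CSV
read_table_file <- function(path, sheet = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package; convert to CSV")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

resolve_coord_names <- function(nms) {
  for (pair in list(c("lon", "lat"), c("longitude", "latitude"),
                    c("long", "lat"), c("x", "y"))) {
    if (all(pair %in% nms)) return(pair)
  }
  NULL
}
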
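#' Standardized effect size result container
#'
#' @param site_ids site identifiers.
#' @param observed per-site observed statistic.
#' @param null_mean,null_sd moments of the null distribution.
#' @param n_replicates number of null replicates.
#' @param seed RNG seed used.
#' @param statistic short label of the statistic ("prop_dd", "fd", ...).
#' @return data.frame of class `ses_result` with columns `site_id`,
#'   `observed`, `null_mean`, `null_sd`, `ses` and `defined`. Where the
#'   null standard deviation is zero the SES is `NaN` and `defined` is
#'   `FALSE` (no zero is fabricated).
#' @export
ses_result <- function(site_ids, observed, null_mean, null_sd,
                       n_replicates, seed = NA_integer_,
                       statistic = "statistic") {
  stopifnot(length(observed) == length(site_ids),
            length(null_mean) == length(site_ids),
            length(null_sd) == length(site_ids),
            n_replicates >= 1L, all(null_sd >= 0 | is.na(null_sd)))
  defined <- is.finite(null_sd) & null_sd > 0
  ses <- ifelse(defined, (observed - null_mean) / null_sd, NaN)
  out <- data.frame(site_id = site_ids, observed = observed,
                    null_mean = null_mean, null_sd = null_sd,
                    ses = ses, defined = defined,
                    stringsAsFactors = FALSE)
  attr(out, "n_replicates") <- as.integer(n_replicates)
  attr(out, "seed") <- seed
  attr(out, "statistic") <- statistic
  class(out) <- c("ses_result", "data.frame")
  out
}

#' @export
print.ses_result <- function(x, ...) {
  cat("Standardized effect sizes (", attr(x, "statistic"), "), ",
      nrow(x), " sites, ", attr(x, "n_replicates"),
      " null replicates\n", sep = "")
  ok <- x$defined
  if (any(ok)) {
    cat("  SES: mean ", round(mean(x$ses[ok]), 3),
        ", sd ", round(stats::sd(x$ses[ok]), 3), sep = "")
  }
  if (any(!ok)) cat("  (", sum(!ok), " undefined)", sep = "")
  cat("\n")
  invisible(x)
}

#' Observed proportion of direct-developing species per site
#'
#' @param cm a [community_matrix()].
#' @param dev logical or 0/1 vector over `cm$species_ids` (`TRUE`/1 =
#'   direct development), or a factor/character vector with levels
#'   `larval`/`direct`. Must be named or aligned to the species order.
#' @return named numeric vector in `[0, 1]`, one value per site.
#' @export
observed_dd_proportion <- function(cm, dev) {
  stopifnot(inherits(cm, "community_matrix"))
  dev <- as_dev01(dev, cm$species_ids)
  rich <- rowSums(cm$incidence)
  if (any(rich < 1L)) stop("sites with zero species are not allowed")
  drop(cm$incidence %*% dev) / rich
}

#' Composition-controlled SES of the direct-development proportion
#'
#' Null model: the species -> development-type map (the D matrix) is
#' permuted across the entire regional pool, keeping the incidence matrix
#' fixed, and the per-site proportion of direct developers is recomputed
#' for each of `n_null` permutations. Species columns are put in a
#' canonical (sorted) order before permutations are drawn, so the result
#' does not depend on input column order.
#'
#' @param cm a [community_matrix()].
#' @param dev development vector as in [observed_dd_proportion()].
#' @param n_null number of null permutations (default 999).
#' @param seed integer seed for the single RNG stream.
#' @return a [ses_result()] with statistic `"prop_dd"`.
#' @export
ses_dd_proportion <- function(cm, dev, n_null = 999L, seed = 1L) {
  stopifnot(inherits(cm, "community_matrix"))
  n_null <- as.integer(n_null)
  if (n_null < 1L) stop("n_null must be >= 1")
  ord <- order(cm$species_ids)
  inc <- cm$incidence[, ord, drop = FALSE]
  dev <- as_dev01(dev, cm$species_ids)[ord]
  n_sp <- length(dev)
  rich <- rowSums(inc)
  obs <- drop(inc %*% dev) / rich

  withr_seed(seed, {
    perms <- matrix(0, n_sp, n_null)
    for (r in seq_len(n_null)) perms[, r] <- dev[sample.int(n_sp)]
  })
  null_props <- (inc %*% perms) / rich
  ses_result(cm$site_ids, obs,
             null_mean = rowMeans(null_props),
             null_sd = apply(null_props, 1L, stats::sd),
             n_replicates = n_null, seed = seed, statistic = "prop_dd")
}

#' Descriptive summary of direct development across communities
#'
#' The community-level quantities usually reported first for such a data
#' set: counts of communities and species, how many species develop
#' directly, how many communities contain at least one of them, the
#' richness distribution, and the observed direct-development proportion.
#'
#' @param cm a [community_matrix()].
#' @param dev development vector as in [observed_dd_proportion()].
#' @return list with `n_communities`, `n_species`, `n_dd_species`,
#'   `n_communities_with_dd`, `richness_mean`, `richness_sd`,
#'   `prop_dd_mean_pct`, `prop_dd_sd_pct`, `richness_min`,
#'   `richness_max` and `max_dd_richness` (largest per-site count of
#'   direct developers).
#' @export
community_summary <- function(cm, dev) {
  stopifnot(inherits(cm, "community_matrix"))
  dev <- as_dev01(dev, cm$species_ids)
  rich <- rowSums(cm$incidence)
  dd_rich <- drop(cm$incidence %*% dev)
  prop <- dd_rich / rich
  list(n_communities = nrow(cm$incidence),
       n_species = ncol(cm$incidence),
       n_dd_species = sum(dev),
       n_communities_with_dd = sum(dd_rich > 0),
       richness_mean = mean(rich),
       richness_sd = stats::sd(rich),
       richness_min = min(rich),
       richness_max = max(rich),
       prop_dd_mean_pct = 100 * mean(prop),
       prop_dd_sd_pct = 100 * stats::sd(prop),
       max_dd_richness = max(dd_rich))
}

# coerce the development trait to a named 0/1 vector aligned to species
as_dev01 <- function(dev, species_ids) {
  if (is.factor(dev) || is.character(dev)) {
    v <- as.character(dev)
    bad <- setdiff(unique(v), c("larval", "direct"))
    if (length(bad)) stop("unknown development levels: ",
                          paste(bad, collapse = ", "))
    out <- as.integer(v == "direct")
  } else {
    out <- as.integer(as.logical(dev))
  }
  if (anyNA(out)) stop("development vector contains missing values")
  if (!is.null(names(dev))) {
    names(out) <- canonical_ids(names(dev))
    missing <- setdiff(species_ids, names(out))
    if (length(missing)) {
      stop("development vector lacks species: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    out <- out[species_ids]
  } else if (length(out) != length(species_ids)) {
    stop("development vector not aligned to community species")
  } else {
    names(out) <- species_ids
  }
  out
}

# evaluate expr under a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
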
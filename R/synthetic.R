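#' Scenario configuration for the synthetic-data generator
#'
#' Defaults emulate the Atlantic Forest anuran study system: 766
#' communities drawn from a pool of 464 species of which 49 (about 10.6%)
#' are direct developers concentrated in 3 lineages, head width and tibia
#' length missing for roughly 30% of species, spatially autocorrelated
#' standardized environmental gradients, and a causal path structure in
#' which climate and topography drive phylogenetic composition, functional
#' diversity and the direct-development proportion (standardized
#' coefficients for ET0, BIO4 and SES.FD on the proportion: -0.45, -0.30
#' and +0.23).
#'
#' @param n_species species-pool size.
#' @param n_sites number of communities.
#' @param birth,death birth-death rates for the tree simulation.
#' @param dd_fraction target fraction of direct developers in the pool.
#' @param dd_clade_count number of lineages holding the direct developers.
#' @param trait_missing named completely-at-random missingness fraction
#'   per continuous trait.
#' @param rho_env spatial range (decimal degrees) of the environmental
#'   gradients.
#' @param rho_err spatial range of the structural-equation errors.
#' @param env_cor pairwise correlation among the three climate variables
#'   (slope is independent).
#' @param richness_target expected number of species per site.
#' @param niche_breadth breadth of the Gaussian niche on the composition
#'   gradient (in SD units of the gradient).
#' @param dd_site_effect strength with which the latent
#'   direct-development propensity raises occurrence of direct developers.
#' @param dd_rarity additive logit penalty making direct developers rarer
#'   than the average species.
#' @param paths true standardized path coefficients: named list with
#'   elements `PCPS1`, `SES.FD` (each over the four environment
#'   variables) and `prop_dd` (over environment plus `PCPS1`, `SES.FD`).
#' @param lon_range,lat_range rectangle from which site coordinates are
#'   drawn uniformly.
#' @param seed integer seed used by [simulate_scenario()].
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 464L,
                            n_sites = 766L,
                            birth = 1,
                            death = 0.5,
                            dd_fraction = 49 / 464,
                            dd_clade_count = 3L,
                            trait_missing = c(body_length = 0,
                                              head_width = 0.30,
                                              tibia_length = 0.31),
                            rho_env = 2.5,
                            rho_err = 1,
                            env_cor = 0.15,
                            richness_target = 13.5,
                            niche_breadth = 1.2,
                            dd_site_effect = 1.0,
                            dd_rarity = -1.2,
                            paths = list(
                              PCPS1 = c(BIO4 = 0.25, BIO12 = 0.15,
                                        ET0 = -0.25, slope = 0.10),
                              SES.FD = c(BIO4 = -0.15, BIO12 = 0.20,
                                         ET0 = -0.20, slope = 0.10),
                              prop_dd = c(BIO4 = -0.30, BIO12 = 0,
                                          ET0 = -0.45, slope = 0.10,
                                          PCPS1 = -0.10, SES.FD = 0.23)),
                            lon_range = c(-55, -35),
                            lat_range = c(-30, -5),
                            seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_species < 3L) stop("n_species must be >= 3")
  if (cfg$n_sites < 10L) stop("n_sites must be >= 10")
  if (!(dd_fraction > 0 && dd_fraction < 1)) {
    stop("dd_fraction must be in (0, 1)")
  }
  if (birth <= 0 || death < 0) stop("rates must be positive")
  class(cfg) <- "scenario_config"
  cfg
}

#' Simulate a birth-death phylogeny conditioned on tip count
#'
#' @param n_species number of extant tips.
#' @param birth,death per-lineage rates.
#' @param seed integer seed.
#' @return ultrametric `phylo` with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_species, birth = 1, death = 0.5, seed = 1L) {
  if (n_species < 3L) stop("n_species must be >= 3")
  if (death >= birth) stop("death rate must be below birth rate")
  tree <- withr_seed(seed, ape::rphylo(n_species, birth = birth,
                                       death = death, fossils = FALSE))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Assign direct development to a few clades
#'
#' Chooses `dd_clade_count` disjoint clades whose combined tip count is as
#' close as possible to `dd_fraction * n` and marks their tips as direct
#' developers, mimicking the phylogenetic concentration of the trait.
#'
#' @param tree `phylo` tree.
#' @param dd_fraction target fraction of direct-developing tips.
#' @param dd_clade_count number of clades to mark.
#' @param seed integer seed.
#' @return named factor (`larval`/`direct`) over the tips, with
#'   attributes `"clades"` (list of tip sets) and `"realized_fraction"`.
#'   Errors if no clade combination lands within +/-50% of the target.
#' @export
assign_direct_development <- function(tree, dd_fraction = 0.1,
                                      dd_clade_count = 3L, seed = 1L) {
  n <- length(tree$tip.label)
  target <- max(1L, round(dd_fraction * n))
  n_tip <- n
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  tipsets <- lapply(internal, function(nd) tip_descendants(tree, nd))
  sizes <- lengths(tipsets)

  pick <- withr_seed(seed, {
    chosen <- list()
    used <- integer(0)
    remaining <- target
    for (k in seq_len(dd_clade_count)) {
      want <- max(1L, round(remaining / (dd_clade_count - k + 1L)))
      ok <- which(sizes <= remaining - (dd_clade_count - k) &
                    sizes < n_tip &
                    !vapply(tipsets, function(s) any(s %in% used),
                            logical(1)))
      if (!length(ok)) break
      score <- abs(sizes[ok] - want)
      cand <- ok[score <= min(score) + 1L]
      sel <- cand[sample.int(length(cand), 1L)]
      chosen[[k]] <- tipsets[[sel]]
      used <- c(used, tipsets[[sel]])
      remaining <- remaining - sizes[sel]
      if (remaining <= 0L) break
    }
    chosen
  })
  marked <- unique(unlist(pick))
  realized <- length(marked) / n
  if (abs(realized - dd_fraction) > 0.5 * dd_fraction) {
    stop("no clade combination within 50% of the target fraction (",
         "realized ", signif(realized, 3), ")")
  }
  dev <- factor(rep("larval", n), levels = c("larval", "direct"))
  dev[marked] <- "direct"
  names(dev) <- tree$tip.label
  attr(dev, "clades") <- lapply(pick, function(s) tree$tip.label[s])
  attr(dev, "realized_fraction") <- realized
  dev
}

#' Simulate spatially autocorrelated environmental gradients
#'
#' Site coordinates are uniform in a rectangle; each variable is a draw
#' from a Gaussian process with exponential covariance `exp(-d /
#' rho_env)`, the three climate variables mutually correlated by
#' `env_cor`, and every column z-scored.
#'
#' @param n_sites number of sites.
#' @param rho_env spatial range in coordinate units.
#' @param env_cor correlation among BIO4, BIO12 and ET0.
#' @param lon_range,lat_range sampling rectangle.
#' @param seed integer seed.
#' @return list with `env` (data.frame: BIO4, BIO12, ET0, slope) and
#'   `coords` (matrix with columns lon, lat).
#' @export
simulate_env <- function(n_sites, rho_env = 2.5, env_cor = 0.15,
                         lon_range = c(-55, -35), lat_range = c(-30, -5),
                         seed = 1L) {
  if (n_sites < 10L) stop("n_sites must be >= 10")
  withr_seed(seed, {
    coords <- cbind(lon = stats::runif(n_sites, lon_range[1], lon_range[2]),
                    lat = stats::runif(n_sites, lat_range[1], lat_range[2]))
    gp <- gp_chol(coords, rho_env)
    z <- gp %*% matrix(stats::rnorm(n_sites * 4L), n_sites, 4L)
    cmat <- diag(4)
    cmat[1:3, 1:3] <- env_cor
    diag(cmat) <- 1
    vars <- z %*% chol(cmat)
    env <- as.data.frame(scale(vars))
    names(env) <- c("BIO4", "BIO12", "ET0", "slope")
    rownames(env) <- sprintf("site%04d", seq_len(n_sites))
    rownames(coords) <- rownames(env)
    list(env = env, coords = coords)
  })
}

# lower-triangular factor of the exponential-covariance GP (with jitter)
gp_chol <- function(coords, rho) {
  d <- as.matrix(stats::dist(coords))
  v <- exp(-d / rho)
  ch <- tryCatch(chol(v), error = function(e) {
    chol(v + diag(1e-8, nrow(v)))
  })
  t(ch)
}

#' Simulate correlated continuous traits under Brownian motion
#'
#' Multivariate Brownian motion on the tree (log-millimetre scale,
#' exponentiated so values are strictly positive), with completely at
#' random missingness per trait.
#'
#' @param tree `phylo` tree.
#' @param trait_missing named missingness fractions for `body_length`,
#'   `head_width`, `tibia_length`.
#' @param seed integer seed.
#' @return list with `traits` (data.frame in mm, `NA` where masked) and
#'   `truth` (the complete matrix before masking).
#' @export
simulate_traits_bm <- function(tree,
                               trait_missing = c(body_length = 0,
                                                 head_width = 0.30,
                                                 tibia_length = 0.31),
                               seed = 1L) {
  n <- length(tree$tip.label)
  cmat <- ape::vcv(tree)
  cmat <- cmat / max(diag(cmat))
  # evolutionary covariance of (log body, log head, log tibia)
  rmat <- matrix(c(0.30, 0.22, 0.20,
                   0.22, 0.25, 0.16,
                   0.20, 0.16, 0.28), 3, 3)
  mu <- c(body_length = log(40), head_width = log(14),
          tibia_length = log(18))
  withr_seed(seed, {
    z <- matrix(stats::rnorm(n * 3L), n, 3L)
    logy <- outer(rep(1, n), mu) + t(chol(cmat)) %*% z %*% chol(rmat)
    y <- exp(logy)
    dimnames(y) <- list(rownames(cmat), names(mu))
    y <- y[tree$tip.label, ]
    masked <- as.data.frame(y)
    for (tr in names(trait_missing)) {
      frac <- trait_missing[[tr]]
      if (frac > 0) {
        hide <- sample.int(n, round(frac * n))
        masked[hide, tr] <- NA_real_
      }
    }
    list(traits = masked, truth = y)
  })
}

#' Assemble communities with a known causal structure
#'
#' Each species carries a phylogenetically conserved niche position on a
#' latent composition gradient; each site's gradient value and latent
#' direct-development propensity come from the scenario's structural
#' equations. Occurrence probability is a logistic Gaussian-niche model
#' plus a direct-development term, the intercept calibrated so expected
#' richness matches `richness_target`. Sites left with fewer than two
#' species are redrawn (up to 100 times each).
#'
#' @param tree `phylo` over the species pool.
#' @param dev development factor from [assign_direct_development()].
#' @param gradient per-site latent composition gradient (standardized).
#' @param dd_propensity per-site latent direct-development propensity
#'   (standardized).
#' @param coords site coordinate matrix.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return a [community_matrix()] with attribute `"niche_positions"`.
#' @export
assemble_communities <- function(tree, dev, gradient, dd_propensity,
                                 coords, config, seed = 1L) {
  n_sp <- length(tree$tip.label)
  n_site <- length(gradient)
  withr_seed(seed, {
    # phylogenetically conserved niche positions (BM, standardized)
    cmat <- ape::vcv(tree)
    cmat <- cmat / max(diag(cmat))
    u <- drop(t(chol(cmat)) %*% stats::rnorm(n_sp))
    u <- (u - mean(u)) / stats::sd(u)
    names(u) <- rownames(cmat)
    u <- u[tree$tip.label]

    is_dd <- as.integer(dev[tree$tip.label] == "direct")
    eta0 <- -outer(gradient, u, `-`)^2 / (2 * config$niche_breadth^2) +
      outer(rep(1, n_site), is_dd * config$dd_rarity) +
      config$dd_site_effect * outer(dd_propensity, is_dd)
    # calibrate intercept for the target expected richness
    target <- config$richness_target
    f <- function(a) mean(stats::plogis(a + eta0)) * n_sp - target
    a <- stats::uniroot(f, c(-30, 30))$root
    prob <- stats::plogis(a + eta0)

    inc <- matrix(stats::rbinom(length(prob), 1L, prob),
                  n_site, n_sp)
    for (i in seq_len(n_site)) {
      tries <- 0L
      while (sum(inc[i, ]) < 2L) {
        tries <- tries + 1L
        if (tries > 100L) stop("could not draw a site with >= 2 species")
        inc[i, ] <- stats::rbinom(n_sp, 1L, prob[i, ])
      }
    }
    dimnames(inc) <- list(rownames(coords), tree$tip.label)
    cm <- community_matrix(inc, coords)
    attr(cm, "niche_positions") <- u
    cm
  })
}

#' Simulate a complete study scenario
#'
#' Generates, in order: a birth-death tree, the clade-concentrated
#' development trait, Brownian continuous traits with missingness,
#' spatially autocorrelated environments, the latent endogenous variables
#' (`PCPS1`, `SES.FD`, `prop_dd`) from the configured structural
#' equations with spatially correlated errors, and a community matrix
#' assembled from the latent gradient and propensity. The site-level
#' table with known path coefficients is returned alongside the raw
#' inputs so both single stages and the full pipeline can be verified.
#'
#' @param config a [scenario_config()].
#' @return list of class `scenario` with `tree`, `dev`, `traits`,
#'   `trait_truth`, `env`, `coords`, `cm`, `site_table` (data.frame:
#'   BIO4, BIO12, ET0, slope, PCPS1, SES.FD, prop_dd) and `truth`
#'   (true path coefficients, error SDs, clade assignments).
#' @export
simulate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- as.integer(config$seed)
  tree <- simulate_tree(config$n_species, config$birth, config$death,
                        seed = seed)
  dev <- assign_direct_development(tree, config$dd_fraction,
                                   config$dd_clade_count, seed = seed + 1L)
  tr <- simulate_traits_bm(tree, config$trait_missing, seed = seed + 2L)
  # categorical traits consistent with the development mode
  cat_traits <- withr_seed(seed + 3L, {
    n <- length(dev)
    direct <- dev == "direct"
    data.frame(
      oviposition_type = factor(
        ifelse(direct, "terrestrial",
               sample(c("aquatic", "terrestrial"), n, TRUE, c(0.8, 0.2))),
        levels = trait_levels$oviposition_type),
      development_type = dev,
      juvenile_habitat = factor(
        ifelse(direct, "terrestrial",
               sample(c("aquatic", "semiterrestrial"), n, TRUE,
                      c(0.7, 0.3))),
        levels = trait_levels$juvenile_habitat),
      oviposition_site = factor(
        ifelse(direct, "ground_rock_burrow",
               sample(c("water_or_submersed_substrate", "foam_nest",
                        "bubble_nest", "arboreal"), n, TRUE,
                      c(0.55, 0.2, 0.1, 0.15))),
        levels = trait_levels$oviposition_site),
      row.names = names(dev), stringsAsFactors = FALSE)
  })
  traits <- cbind(cat_traits, tr$traits[rownames(cat_traits), ])

  envs <- simulate_env(config$n_sites, config$rho_env, config$env_cor,
                       config$lon_range, config$lat_range,
                       seed = seed + 4L)
  env <- envs$env
  coords <- envs$coords

  # structural equations on standardized variables
  st <- withr_seed(seed + 5L, {
    gp <- gp_chol(coords, config$rho_err)
    draw_err <- function(sd_err) {
      drop(gp %*% stats::rnorm(nrow(coords))) * sd_err
    }
    x <- as.matrix(env)
    lin <- function(beta, preds) drop(preds %*% beta)
    sd_resid <- function(eta) {
      v <- stats::var(eta)
      if (v >= 0.95) stop("path coefficients leave no residual variance")
      sqrt(1 - v)
    }
    b1 <- config$paths$PCPS1
    eta1 <- lin(b1[colnames(x)], x)
    pcps1 <- eta1 + draw_err(sd_resid(eta1))
    b2 <- config$paths$SES.FD
    eta2 <- lin(b2[colnames(x)], x)
    sesfd <- eta2 + draw_err(sd_resid(eta2))
    b3 <- config$paths$prop_dd
    preds <- cbind(x, PCPS1 = pcps1, SES.FD = sesfd)
    eta3 <- lin(b3[colnames(preds)], preds)
    dd <- eta3 + draw_err(sd_resid(eta3))
    data.frame(env, PCPS1 = pcps1, SES.FD = sesfd, prop_dd = dd,
               row.names = rownames(env))
  })

  cm <- assemble_communities(tree, dev, st$PCPS1, st$prop_dd, coords,
                             config, seed = seed + 6L)

  structure(
    list(tree = tree, dev = dev, traits = traits,
         trait_truth = tr$truth, env = env, coords = coords,
         cm = cm, site_table = st,
         truth = list(paths = config$paths,
                      dd_clades = attr(dev, "clades"),
                      dd_fraction = attr(dev, "realized_fraction"),
                      config = config)),
    class = "scenario"
  )
}

#' Path model of the study's causal diagram
#'
#' Four abiotic variables (BIO4, BIO12, ET0, slope) affect phylogenetic
#' composition (PCPS1), functional diversity (SES.FD) and the
#' direct-development proportion (`prop_dd`) directly; PCPS1 and SES.FD
#' also affect `prop_dd`; PCPS1 and SES.FD share no edge, which yields a
#' single d-separation claim (df = 2).
#'
#' @return a [path_model()].
#' @export
dd_path_model <- function() {
  env <- c("BIO4", "BIO12", "ET0", "slope")
  path_model(c(
    paste(env, "-> PCPS1"),
    paste(env, "-> SES.FD"),
    paste(env, "-> prop_dd"),
    "PCPS1 -> prop_dd",
    "SES.FD -> prop_dd"
  ))
}
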
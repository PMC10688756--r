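#' Write a simulated scenario as the four standard input files
#'
#' Writes `community.csv` (long site/species records with coordinates),
#' `traits.csv`, `env.csv`, `tree.nwk` and `truth.json` into a directory,
#' in the formats the readers in this package consume.
#'
#' @param scenario result of [simulate_scenario()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- scenario$cm
  idx <- which(cm$incidence == 1L, arr.ind = TRUE)
  long <- data.frame(
    site = cm$site_ids[idx[, 1]],
    lon = cm$coords[idx[, 1], "lon"],
    lat = cm$coords[idx[, 1], "lat"],
    species = cm$species_ids[idx[, 2]],
    stringsAsFactors = FALSE)
  utils::write.csv(long[order(long$site, long$species), ],
                   file.path(dir, "community.csv"), row.names = FALSE)
  tt <- cbind(species = rownames(scenario$traits), scenario$traits)
  utils::write.csv(tt, file.path(dir, "traits.csv"), row.names = FALSE)
  env <- cbind(site = rownames(scenario$env), scenario$env)
  utils::write.csv(env, file.path(dir, "env.csv"), row.names = FALSE)
  ape::write.tree(scenario$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(paths = scenario$truth$paths,
         dd_fraction = scenario$truth$dd_fraction,
         dd_clades = scenario$truth$dd_clades),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages: read and align the four inputs; composition-controlled SES of
#' the direct-development proportion; PCPS ordination; PVR eigenvectors;
#' Brownian-motion imputation of missing continuous traits; PVR-controlled
#' functional dendrogram; SES of functional diversity; assembly of the
#' standardized site table; spatial-GLS piecewise SEM over the declared
#' DAG. All result tables are written as CSV, the SEM report and a
#' machine-readable log (inputs, seed, replicate counts, dropped ids) as
#' JSON.
#'
#' @param config path to a YAML file, or an equivalent named list, with
#'   entries `community`, `traits`, `tree`, `env` (file paths),
#'   `n_null` (replicates, default 999), `seed`, `variance_fraction`
#'   (PVR, default 0.95), `dag` (character vector of `"a -> b"` edges;
#'   default the study DAG of [dd_path_model()]) and `dd_variable`
#'   (`"ses"`, the default, or `"observed"`: which form of the
#'   direct-development proportion enters the SEM).
#' @param out_dir directory for result files.
#' @return invisibly, a list with the aligned inputs and every stage
#'   result (`ses_dd`, `pcps`, `pvr`, `traits_imputed`, `dendrogram`,
#'   `ses_fd`, `site_table`, `sem`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("community", "traits", "tree", "env")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys)) {
    stop("config lacks entries: ", paste(missing_keys, collapse = ", "))
  }
  n_null <- as.integer(config$n_null %||% 999L)
  if (n_null < 1L) stop("n_null must be >= 1 (null models are undefined)")
  seed <- as.integer(config$seed %||% 1L)
  vf <- config$variance_fraction %||% 0.95
  dd_variable <- config$dd_variable %||% "ses"
  dag <- if (is.null(config$dag)) dd_path_model() else
    path_model(config$dag)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cm <- stage("read_community", read_community_table(config$community))
  tt <- stage("read_traits", read_trait_table(config$traits))
  tree <- stage("read_tree", read_tree(config$tree))
  env <- stage("read_env", read_env_table(config$env))

  # optional PUT insertion: taxon -> character vector of MDCC tips
  if (!is.null(config$put)) {
    for (taxon in names(config$put)) {
      tree <- stage("put_insertion",
                    add_taxon_at_mdcc(tree, taxon,
                                      unlist(config$put[[taxon]])))
    }
  }
  al <- stage("align", align_inputs(cm, tt, tree, env))

  dev <- al$tt$development_type
  names(dev) <- rownames(al$tt)
  sesdd <- stage("ses_dd",
                 ses_dd_proportion(al$cm, dev, n_null = n_null,
                                   seed = seed))
  ord <- stage("pcps", pcps(al$cm, al$tree))
  pvr <- stage("pvr", pvr_eigenvectors(al$tree, variance_fraction = vf))

  cont <- intersect(continuous_traits, names(al$tt))
  imputed <- stage("impute",
                   impute_traits_bm(al$tree, al$tt[cont]))
  full_traits <- al$tt
  full_traits[cont] <- as.data.frame(unclass(imputed))[cont]
  feats <- stage("pvr_residuals",
                 trait_pvr_residuals(full_traits, pvr))
  dend <- stage("dendrogram", functional_dendrogram(feats))
  sesfd <- stage("ses_fd",
                 ses_fd(dend, al$cm, n_null = n_null, seed = seed + 1L))

  site_table <- data.frame(
    al$env[al$cm$site_ids, , drop = FALSE],
    PCPS1 = ord$scores[al$cm$site_ids, "PCPS1"],
    SES.FD = sesfd$ses,
    prop_dd = if (dd_variable == "observed") sesdd$observed else sesdd$ses,
    row.names = al$cm$site_ids, check.names = FALSE)
  usable <- stats::complete.cases(site_table) &
    apply(site_table, 1L, function(r) all(is.finite(r)))
  sem <- stage("sem",
               fit_piecewise_sem(dag, site_table[usable, , drop = FALSE],
                                 coords = al$cm$coords[usable, ,
                                                       drop = FALSE]))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wr(as.data.frame(sesdd), "ses_dd.csv")
  wr(data.frame(site_id = rownames(ord$scores),
                ord$scores[, seq_len(min(10L, ncol(ord$scores))),
                           drop = FALSE], check.names = FALSE),
     "pcps_scores.csv")
  wr(data.frame(axis = seq_along(ord$eigenvalues),
                eigenvalue = ord$eigenvalues), "pcps_eigenvalues.csv")
  wr(as.data.frame(sesfd), "ses_fd.csv")
  wr(cbind(site_id = rownames(site_table), site_table), "site_table.csv")
  wr(sem$paths, "sem_paths.csv")
  ape::write.tree(dend, file.path(out_dir, "dendrogram.nwk"))
  jsonlite::write_json(
    list(seed = seed, n_null = n_null, variance_fraction = vf,
         dd_variable = dd_variable,
         n_sites = nrow(al$cm$incidence),
         n_species = ncol(al$cm$incidence),
         dropped = al$dropped,
         pvr_axes = ncol(pvr),
         sem = list(fisher_c = sem$fisher_c, df = sem$df,
                    p_value = sem$p_value, valid = sem$valid,
                    r_squared = as.list(sem$r_squared))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  invisible(list(aligned = al, ses_dd = sesdd, pcps = ord, pvr = pvr,
                 traits_imputed = imputed, dendrogram = dend,
                 ses_fd = sesfd, site_table = site_table, sem = sem))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
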
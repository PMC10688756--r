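#' Directed acyclic path model
#'
#' Defines the causal structure for a piecewise structural equation model
#' as an edge list. Each endogenous variable (one with at least one
#' parent) will be fit as one spatial GLS submodel whose predictors are
#' exactly its parents.
#'
#' @param edges two-column matrix or data.frame (`from`, `to`) of directed
#'   edges, or a character vector of `"a -> b"` strings.
#' @return object of class `path_model` with `nodes`, `edges`,
#'   `parents` (named list), `exogenous`, `endogenous` and a topological
#'   order.
#' @examples
#' pm <- path_model(c("ET0 -> DD", "BIO4 -> DD", "ET0 -> FD", "FD -> DD"))
#' pm
#' @export
path_model <- function(edges) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("edges must look like 'a -> b'")
    edges <- data.frame(from = trimws(vapply(parts, `[`, "", 1L)),
                        to = trimws(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(paste(edges$from, edges$to))) {
    stop("duplicate edges")
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  nodes <- unique(c(edges$from, edges$to))
  order <- topological_order(nodes, edges)  # errors on cycles
  parents <- lapply(nodes, function(v) edges$from[edges$to == v])
  names(parents) <- nodes
  endo <- nodes[lengths(parents) > 0L]
  structure(
    list(nodes = nodes, edges = edges, parents = parents,
         exogenous = setdiff(nodes, endo), endogenous = endo,
         topological_order = order),
    class = "path_model"
  )
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model: ", length(x$nodes), " variables, ",
      nrow(x$edges), " paths\n", sep = "")
  cat("  exogenous:  ", paste(x$exogenous, collapse = ", "), "\n", sep = "")
  cat("  endogenous: ", paste(x$endogenous, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Kahn's algorithm; stops on cycles
topological_order <- function(nodes, edges) {
  indeg <- vapply(nodes, function(v) sum(edges$to == v), integer(1))
  order <- character(0)
  avail <- nodes[indeg == 0L]
  indeg <- stats::setNames(indeg, nodes)
  edges_left <- edges
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, v)
    out <- edges_left$to[edges_left$from == v]
    edges_left <- edges_left[edges_left$from != v, , drop = FALSE]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(order) != length(nodes)) stop("path model contains a cycle")
  order
}

#' d-separation basis set of a path model
#'
#' One conditional-independence claim per non-adjacent pair of variables:
#' `x _||_ y | parents(x) U parents(y)`, directed so the variable later in
#' the topological order is the response of the test. Pairs of exogenous
#' variables are excluded (they are treated as freely correlated).
#'
#' @param pm a [path_model()].
#' @return data.frame with columns `x` (tested predictor), `y` (response),
#'   and `conditioning` (comma-separated set); zero rows for a saturated
#'   model.
#' @export
basis_set <- function(pm) {
  stopifnot(inherits(pm, "path_model"))
  ord <- pm$topological_order
  adj <- paste(pm$edges$from, pm$edges$to)
  claims <- list()
  n <- length(ord)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- ord[i]; b <- ord[j]
      if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
      if (a %in% pm$exogenous && b %in% pm$exogenous) next
      cond <- setdiff(union(pm$parents[[a]], pm$parents[[b]]), c(a, b))
      claims[[length(claims) + 1L]] <- data.frame(
        x = a, y = b, conditioning = paste(cond, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(claims)) {
    return(data.frame(x = character(), y = character(),
                      conditioning = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, claims)
}

#' Fisher's C from independence-claim p-values
#'
#' `C = -2 * sum(log(p_i))` compared to a chi-squared distribution with
#' `2k` degrees of freedom.
#'
#' @param claim_pvalues numeric vector of p-values in `(0, 1]`.
#' @return list with `C`, `df` and `p_value`. An empty claim set yields
#'   `C = 0`, `df = 0`, `p = 1` (saturated model).
#' @export
fishers_c <- function(claim_pvalues) {
  if (!length(claim_pvalues)) return(list(C = 0, df = 0L, p_value = 1))
  if (any(claim_pvalues <= 0)) {
    stop("claim p-value of 0: Fisher's C diverges; ",
         "report the failing claim directly")
  }
  if (any(claim_pvalues > 1)) stop("p-values must lie in (0, 1]")
  cc <- -2 * sum(log(claim_pvalues))
  df <- 2L * length(claim_pvalues)
  list(C = cc, df = df,
       p_value = stats::pchisq(cc, df = df, lower.tail = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' Each endogenous variable is fit as one [gls_exponential()] submodel on
#' its parents. The d-separation basis set of the DAG is tested by adding
#' the claim's independent variable to the response's submodel and taking
#' the p-value of its coefficient; the claim p-values combine into
#' Fisher's C. Standardized path coefficients are `beta * sd(x) / sd(y)`
#' (equal to raw coefficients when the data are z-scored), and each
#' endogenous variable's R-squared is the squared Pearson correlation of
#' fitted versus observed values.
#'
#' @param pm a [path_model()].
#' @param data data.frame containing every model variable.
#' @param coords two-column (lon, lat) matrix, one row per row of `data`;
#'   required for the exponential correlation structure.
#' @param correlation `"exponential"` (default) or `"none"` (ordinary
#'   least squares path analysis).
#' @param standardize z-score all model variables before fitting
#'   (default `TRUE`).
#' @return object of class `piecewise_sem`: list with `paths` (per-edge
#'   standardized coefficient, SE, p), `r_squared` (per endogenous
#'   variable), `claims` (basis set with p-values), `fisher_c`, `df`,
#'   `p_value`, `valid` (`p_value > 0.05`) and the fitted submodels.
#' @export
fit_piecewise_sem <- function(pm, data, coords = NULL,
                              correlation = c("exponential", "none"),
                              standardize = TRUE) {
  stopifnot(inherits(pm, "path_model"))
  correlation <- match.arg(correlation)
  missing_vars <- setdiff(pm$nodes, names(data))
  if (length(missing_vars)) {
    stop("variables absent from data: ",
         paste(missing_vars, collapse = ", "))
  }
  data <- as.data.frame(data)[pm$nodes]
  sds <- vapply(data, stats::sd, numeric(1))
  if (standardize) data <- standardize(data)

  fit_node <- function(y, extra = character(0)) {
    rhs <- c(pm$parents[[y]], extra)
    f <- stats::reformulate(rhs, response = y)
    fit <- tryCatch(
      gls_exponential(f, data, coords, correlation = correlation),
      error = function(e) stop("submodel for '", y, "' failed: ",
                               conditionMessage(e)))
    fit
  }

  submodels <- lapply(pm$endogenous, fit_node)
  names(submodels) <- pm$endogenous

  paths <- pm$edges
  paths$coefficient <- NA_real_
  paths$se <- NA_real_
  paths$p_value <- NA_real_
  for (i in seq_len(nrow(paths))) {
    fit <- submodels[[paths$to[i]]]
    ct <- fit$coef_table
    j <- match(paths$from[i], rownames(ct))
    scale_xy <- if (standardize) 1 else sds[paths$from[i]] / sds[paths$to[i]]
    paths$coefficient[i] <- ct[j, "Estimate"] * scale_xy
    paths$se[i] <- ct[j, "Std. Error"] * scale_xy
    paths$p_value[i] <- ct[j, "Pr(>|t|)"]
  }

  r2 <- vapply(submodels, function(f) {
    stats::cor(f$fitted, f$y)^2
  }, numeric(1))

  claims <- basis_set(pm)
  if (nrow(claims)) {
    claims$p_value <- NA_real_
    for (i in seq_len(nrow(claims))) {
      fit <- fit_node(claims$y[i], extra = claims$x[i])
      claims$p_value[i] <- fit$coef_table[claims$x[i], "Pr(>|t|)"]
    }
  }
  fc <- fishers_c(claims$p_value)

  structure(
    list(paths = paths, r_squared = r2, claims = claims,
         fisher_c = fc$C, df = fc$df, p_value = fc$p_value,
         valid = fc$p_value > 0.05,
         submodels = submodels, model = pm,
         correlation = correlation, n = nrow(data)),
    class = "piecewise_sem"
  )
}

#' @export
print.piecewise_sem <- function(x, digits = 3, ...) {
  cat("Piecewise SEM (", x$correlation, " errors), n = ", x$n,
      "\n\n", sep = "")
  cat("Paths (standardized coefficients):\n")
  pt <- x$paths
  pt$coefficient <- round(pt$coefficient, digits)
  pt$se <- round(pt$se, digits)
  pt$p_value <- signif(pt$p_value, digits)
  print(pt, row.names = FALSE)
  cat("\nR-squared:\n")
  print(round(x$r_squared, digits))
  if (nrow(x$claims)) {
    cat("\nIndependence claims:\n")
    cl <- x$claims
    cl$p_value <- signif(cl$p_value, digits)
    print(cl, row.names = FALSE)
  } else {
    cat("\nSaturated model: no independence claims.\n")
  }
  cat("\nFisher's C = ", round(x$fisher_c, digits), ", df = ", x$df,
      ", p = ", round(x$p_value, digits),
      if (x$valid) "  (model consistent with data)" else
        "  (model rejected at alpha = 0.05)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.piecewise_sem <- function(object, ...) object

#' @export
coef.piecewise_sem <- function(object, ...) {
  stats::setNames(object$paths$coefficient,
                  paste(object$paths$from, "->", object$paths$to))
}
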
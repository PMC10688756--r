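#' Z-score columns of a numeric table
#'
#' Centres each column to mean 0 and scales to SD 1 (divisor `n - 1`).
#'
#' @param x numeric vector, matrix or data.frame.
#' @return object of the same shape with standardized columns.
#' @export
standardize <- function(x) {
  if (is.vector(x) && is.numeric(x)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("constant column cannot be standardized")
    return((x - mean(x)) / s)
  }
  out <- x
  for (j in seq_len(ncol(out))) {
    v <- out[[j]]
    if (!is.numeric(v)) next
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("constant column cannot be standardized: ", colnames(out)[j])
    }
    out[[j]] <- (v - mean(v)) / s
  }
  out
}

#' Generalized least squares with exponential spatial correlation
#'
#' Fits `y = X beta + e` with `cov(e_i, e_j) = sigma^2 exp(-d_ij / rho)`,
#' where `d_ij` is the planar Euclidean distance between sites `i` and `j`
#' on their (longitude, latitude) coordinates. Estimation is maximum
#' likelihood: the range `rho` is profiled over a log-spaced grid and the
#' bracketing interval refined by golden-section search; at each `rho` the
#' fixed effects have the closed form `(X' V^-1 X)^-1 X' V^-1 y`. No
#' nugget term is used. With `correlation = "none"` the model reduces to
#' ordinary least squares (still fit by ML).
#'
#' @param formula model formula.
#' @param data data.frame holding the model variables.
#' @param coords two-column matrix of site (lon, lat), one row per
#'   observation of `data`.
#' @param correlation `"exponential"` (default) or `"none"`.
#' @param rho optional fixed range; skips estimation of `rho`.
#' @param n_grid number of grid points for the profile search.
#' @return object of class `spatial_gls` with coefficients, standard
#'   errors, t and p values, `rho`, `logLik`, `AIC` (counting the fixed
#'   effects plus `sigma^2` and, for the exponential model, `rho`),
#'   fitted values and raw residuals.
#' @seealso [aic_table()], [morans_i()]
#' @export
gls_exponential <- function(formula, data, coords,
                            correlation = c("exponential", "none"),
                            rho = NULL, n_grid = 12L) {
  correlation <- match.arg(correlation)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(x)
  if (qr(x)$rank < p) stop("singular model matrix")
  if (correlation == "exponential") {
    coords <- as.matrix(coords)
    if (nrow(coords) != n) stop("coords must match the number of rows")
    if (n <= p + 2L) stop("need n > p + 2 observations")
    dmat <- as.matrix(stats::dist(coords))
    ridge <- if (any(dmat[upper.tri(dmat)] == 0)) 1e-10 else 0
    profile <- function(log_rho) {
      gls_profile_ll(exp(log_rho), y, x, dmat, ridge)$ll
    }
    if (is.null(rho)) {
      dpos <- dmat[upper.tri(dmat)]
      dpos <- dpos[dpos > 0]
      lo <- log(max(min(dpos) / 4, max(dpos) * 1e-4))
      hi <- log(max(dpos) * 4)
      grid <- seq(lo, hi, length.out = n_grid)
      ll_grid <- vapply(grid, profile, numeric(1))
      i <- which.max(ll_grid)
      bracket <- c(grid[max(1L, i - 1L)], grid[min(n_grid, i + 1L)])
      opt <- stats::optimize(profile, interval = bracket, maximum = TRUE,
                             tol = 1e-8)
      if (opt$objective < ll_grid[i]) {
        opt <- list(maximum = grid[i], objective = ll_grid[i])
      }
      rho <- exp(opt$maximum)
      ll_grid_max <- max(ll_grid)
    } else {
      if (rho <= 0) stop("rho must be positive")
      ll_grid_max <- -Inf
    }
    fit <- gls_profile_ll(rho, y, x, dmat, ridge)
    npar <- p + 2L
  } else {
    fit <- gls_profile_ll(NULL, y, x, NULL, 0)
    rho <- NA_real_
    ll_grid_max <- -Inf
    npar <- p + 1L
  }

  se <- sqrt(diag(fit$cov_beta))
  tval <- fit$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coefs <- cbind(Estimate = fit$beta, `Std. Error` = se,
                 `t value` = tval, `Pr(>|t|)` = pval)
  rownames(coefs) <- colnames(x)
  structure(
    list(coefficients = fit$beta, coef_table = coefs, rho = rho,
         sigma2 = fit$sigma2, logLik = fit$ll,
         grid_logLik_max = ll_grid_max,
         AIC = -2 * fit$ll + 2 * npar, npar = npar,
         fitted = drop(x %*% fit$beta),
         residuals = y - drop(x %*% fit$beta),
         y = y, x = x, n = n, formula = formula,
         correlation = correlation,
         coords = if (correlation == "exponential") coords else NULL,
         call = match.call()),
    class = "spatial_gls"
  )
}

# ML profile: beta, sigma2 and log-likelihood at a given range
gls_profile_ll <- function(rho, y, x, dmat, ridge) {
  n <- length(y)
  if (is.null(rho)) {
    ch <- NULL
    xs <- x
    ys <- y
    logdet <- 0
  } else {
    v <- exp(-dmat / rho)
    if (ridge > 0) v <- v + diag(ridge, n)
    ch <- tryCatch(chol(v), error = function(e) chol(v + diag(1e-8, n)))
    xs <- backsolve(ch, x, transpose = TRUE)
    ys <- backsolve(ch, y, transpose = TRUE)
    logdet <- 2 * sum(log(diag(ch)))
  }
  xtx <- crossprod(xs)
  beta <- drop(solve(xtx, crossprod(xs, ys)))
  names(beta) <- colnames(x)
  r <- ys - xs %*% beta
  sigma2 <- sum(r^2) / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(beta = beta, sigma2 = sigma2, ll = ll,
       cov_beta = sigma2 * solve(xtx))
}

#' @export
print.spatial_gls <- function(x, ...) {
  cat("Spatial GLS (", x$correlation, " correlation), n = ", x$n,
      "\n", sep = "")
  if (x$correlation == "exponential") {
    cat("  range rho = ", signif(x$rho, 4), "\n", sep = "")
  }
  cat("  logLik = ", round(x$logLik, 3), ", AIC = ",
      round(x$AIC, 3), "\n\nCoefficients:\n", sep = "")
  stats::printCoefmat(x$coef_table, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
summary.spatial_gls <- function(object, ...) {
  object
}

#' @export
coef.spatial_gls <- function(object, ...) object$coefficients

#' @export
fitted.spatial_gls <- function(object, ...) object$fitted

#' @export
residuals.spatial_gls <- function(object, ...) object$residuals

#' @export
logLik.spatial_gls <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
AIC.spatial_gls <- function(object, ..., k = 2) object$AIC

#' @export
predict.spatial_gls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- stats::model.matrix(stats::delete.response(
    stats::terms(object$formula)), newdata)
  drop(x %*% object$coefficients)
}

#' Moran's I with inverse-distance weights and a permutation test
#'
#' Weights are inverse pairwise distances with zero diagonal, row
#' normalized so each site's weights sum to one (the convention of
#' `ape::Moran.I`).
#'
#' @param residuals numeric vector (e.g. GLS residuals).
#' @param coords two-column coordinate matrix.
#' @param n_perm number of permutations for the p-value (default 999).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `observed`, `expected` (`-1/(n-1)`), `p_value` and
#'   `n_perm`.
#' @export
morans_i <- function(residuals, coords, n_perm = 999L, seed = 1L,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(residuals)
  if (n < 10L) stop("Moran's I needs at least 10 observations")
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  w <- 1 / d
  diag(w) <- 0
  w[!is.finite(w)] <- 0
  rs <- rowSums(w)
  w[rs > 0, ] <- w[rs > 0, ] / rs[rs > 0]
  s0 <- sum(w)
  if (s0 <= 0) stop("all spatial weights are zero")
  istat <- function(z) {
    zc <- z - mean(z)
    (n / s0) * drop(crossprod(zc, w %*% zc)) / sum(zc^2)
  }
  obs <- istat(residuals)
  perms <- numeric(n_perm)
  withr_seed(seed, {
    for (r in seq_len(n_perm)) perms[r] <- istat(residuals[sample.int(n)])
  })
  p_gr <- (1 + sum(perms >= obs)) / (n_perm + 1)
  p_ls <- (1 + sum(perms <= obs)) / (n_perm + 1)
  p <- switch(alternative,
              greater = p_gr, less = p_ls,
              two.sided = min(1, 2 * min(p_gr, p_ls)))
  list(observed = obs, expected = -1 / (n - 1), p_value = p,
       n_perm = n_perm)
}

#' AIC model-selection table
#'
#' @param fits named list of fitted models with an `AIC()` method, all fit
#'   to the same response vector.
#' @return data.frame sorted by AIC with `dAIC` and Akaike `weight`
#'   columns.
#' @export
aic_table <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  ys <- lapply(fits, function(f) {
    if (inherits(f, "spatial_gls")) f$y else stats::model.response(
      stats::model.frame(f))
  })
  for (i in seq_along(ys)[-1]) {
    if (length(ys[[i]]) != length(ys[[1]]) ||
        any(ys[[i]] != ys[[1]])) {
      stop("all models must be fit to the same response")
    }
  }
  aics <- vapply(fits, function(f) stats::AIC(f), numeric(1))
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  out <- data.frame(model = nm, AIC = aics, dAIC = delta,
                    weight = w / sum(w), stringsAsFactors = FALSE)
  out[order(out$AIC), , drop = FALSE]
}
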
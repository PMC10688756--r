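#' Phylogenetic eigenvectors (PVR)
#'
#' Principal coordinates of the patristic distance matrix among species.
#' The leading eigenvectors summarise phylogenetic structure; regressing
#' traits on them (see [trait_pvr_residuals()]) removes phylogenetic
#' autocorrelation.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param variance_fraction keep the smallest number of axes whose
#'   cumulative fraction of positive-eigenvalue variation reaches this
#'   value (default 0.95).
#' @return species x k matrix of axis scores with attributes
#'   `"fraction_of_variation"` (per retained axis), `"cumulative"` and
#'   `"n_positive"` (number of positive axes available).
#' @export
pvr_eigenvectors <- function(tree, variance_fraction = 0.95) {
  if (!(variance_fraction > 0 && variance_fraction <= 1)) {
    stop("variance_fraction must be in (0, 1]")
  }
  d <- cophenetic_matrix(tree)
  if (max(d) <= 0) stop("all species are identical (zero distances)")
  res <- pcoa_axes(stats::as.dist(d))
  cum <- cumsum(res$fraction_of_variation)
  k <- which(cum >= variance_fraction - 1e-12)[1]
  if (is.na(k)) k <- length(cum)
  scores <- res$scores[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PVR", seq_len(k))
  attr(scores, "fraction_of_variation") <-
    res$fraction_of_variation[seq_len(k)]
  attr(scores, "cumulative") <- cum[seq_len(k)]
  attr(scores, "n_positive") <- length(res$fraction_of_variation)
  scores
}

#' Impute missing continuous traits under multivariate Brownian motion
#'
#' Models the continuous traits jointly as multivariate Brownian motion on
#' the tree: across species and traits the tip values are distributed as
#' `vec(Y) ~ N(mu (x) 1, R (x) C)`, where `C` is the shared branch-length
#' matrix of the tree and `R` the evolutionary trait covariance. Root
#' means and `R` are estimated by EM over the missing entries (maximum
#' likelihood); missing values are replaced by their conditional
#' expectations given the observed values. Observed entries are returned
#' unchanged; categorical traits are never touched.
#'
#' @param tree rooted `phylo` with branch lengths; tips must cover the
#'   trait rows.
#' @param traits data.frame or matrix of continuous traits (species as row
#'   names), `NA` for missing.
#' @param tol convergence tolerance on the observed-data log-likelihood
#'   (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @return numeric matrix of completed traits with attributes `"R"`
#'   (estimated trait covariance), `"mu"` (root means), `"loglik"` and
#'   `"iterations"`.
#' @export
impute_traits_bm <- function(tree, traits, tol = 1e-6, max_iter = 500L) {
  tree <- validate_tree(tree)
  y <- as.matrix(traits)
  storage.mode(y) <- "double"
  if (is.null(rownames(y))) stop("traits must have species row names")
  rownames(y) <- canonical_ids(rownames(y))
  missing_sp <- setdiff(rownames(y), tree$tip.label)
  if (length(missing_sp)) {
    stop("species absent from tree: ",
         paste(utils::head(missing_sp, 5L), collapse = ", "))
  }
  if (any(colSums(!is.na(y)) == 0L)) {
    stop("each trait needs at least one observed value")
  }
  if (!anyNA(y)) {
    attr(y, "R") <- NULL
    return(y)
  }

  n <- nrow(y)
  p <- ncol(y)
  ctree <- ape::keep.tip(tree, rownames(y))
  cmat <- ape::vcv(ctree)[rownames(y), rownames(y)]
  if (min(eigen(cmat, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    cmat <- cmat + diag(1e-8 * mean(diag(cmat)), n)
  }
  cinv <- solve(cmat)
  one <- rep(1, n)
  c1 <- drop(cinv %*% one)
  s11 <- sum(c1)

  miss <- is.na(y)
  obs_idx <- which(!as.vector(miss))
  mis_idx <- which(as.vector(miss))
  yobs <- as.vector(y)[obs_idx]

  # initial estimates from per-trait observed data (phylogenetic GLS means)
  mu <- numeric(p)
  for (j in seq_len(p)) {
    o <- !miss[, j]
    mu[j] <- mean(y[o, j])
  }
  rmat <- stats::cov(y, use = "pairwise.complete.obs")
  rmat[!is.finite(rmat)] <- 0
  if (min(eigen(rmat, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
    rmat <- rmat + diag(max(diag(rmat)) * 0.05 + 1e-8, p)
  }

  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sigma <- kronecker(rmat, cmat)
    mvec <- rep(mu, each = n)
    soo <- sigma[obs_idx, obs_idx]
    smo <- sigma[mis_idx, obs_idx, drop = FALSE]
    smm <- sigma[mis_idx, mis_idx, drop = FALSE]
    ch <- tryCatch(chol(soo), error = function(e) NULL)
    if (is.null(ch)) {
      soo <- soo + diag(1e-8 * mean(diag(soo)), nrow(soo))
      ch <- chol(soo)
    }
    resid_obs <- yobs - mvec[obs_idx]
    alpha <- backsolve(ch, forwardsolve(t(ch), resid_obs))
    ll <- -0.5 * (length(obs_idx) * log(2 * pi) +
                    2 * sum(log(diag(ch))) + sum(resid_obs * alpha))

    # E-step: conditional mean / covariance of missing entries
    cond_mean <- mvec[mis_idx] + drop(smo %*% alpha)
    w <- backsolve(ch, forwardsolve(t(ch), t(smo)))
    cond_cov <- smm - smo %*% w

    yhat <- as.vector(y)
    yhat[mis_idx] <- cond_mean
    yfull <- matrix(yhat, n, p, dimnames = dimnames(y))

    # M-step: GLS root means and trait covariance with trace correction
    mu <- drop(crossprod(yfull, c1)) / s11
    centred <- yfull - outer(one, mu)
    rnew <- crossprod(centred, cinv %*% centred)
    # add E[(Ym - E Ym)(Yk - E Yk)'] contributions: tr(Cinv * cov block)
    for (j in seq_len(p)) {
      mj <- which(miss[, j])
      if (!length(mj)) next
      rows_j <- match((j - 1L) * n + mj, mis_idx)
      for (k in seq_len(p)) {
        mk <- which(miss[, k])
        if (!length(mk)) next
        cols_k <- match((k - 1L) * n + mk, mis_idx)
        block <- cond_cov[rows_j, cols_k, drop = FALSE]
        rnew[j, k] <- rnew[j, k] +
          sum(cinv[mj, mk, drop = FALSE] * block)
      }
    }
    rnew <- (rnew + t(rnew)) / (2 * n)
    rmat <- rnew

    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    if (iter >= max_iter) {
      stop("Brownian-motion EM did not converge after ", max_iter,
           " iterations (last log-likelihood change ",
           signif(ll - ll_old, 3), ")")
    }
    ll_old <- ll
  }

  out <- y
  out[miss] <- yfull[miss]
  attr(out, "R") <- rmat
  attr(out, "mu") <- mu
  attr(out, "loglik") <- ll
  attr(out, "iterations") <- iter
  out
}

#' Remove phylogenetic structure from traits via eigenvector regression
#'
#' Regresses each trait column on the retained phylogenetic eigenvectors
#' and returns the residuals. Categorical columns are one-hot encoded
#' before regression.
#'
#' @param traits data.frame or matrix over species (row names); no missing
#'   values (impute first).
#' @param pvr_axes species x k eigenvector matrix from
#'   [pvr_eigenvectors()].
#' @return numeric species x feature matrix of residuals.
#' @export
trait_pvr_residuals <- function(traits, pvr_axes) {
  x <- trait_feature_matrix(traits)
  pvr_axes <- as.matrix(pvr_axes)
  if (!setequal(rownames(x), rownames(pvr_axes))) {
    stop("traits and eigenvectors cover different species")
  }
  pvr_axes <- pvr_axes[rownames(x), , drop = FALSE]
  if (ncol(pvr_axes) >= nrow(x)) {
    stop("saturated regression: as many eigenvectors as species")
  }
  if (anyNA(x)) stop("traits contain missing values; impute first")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, pvr_axes), x)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(x)
  res
}

#' One-hot encode a mixed trait table into a numeric feature matrix
#'
#' Categorical columns become one 0/1 indicator per level scaled to unit
#' range; numeric columns are kept and scaled to zero mean / unit SD so no
#' single trait dominates Euclidean distances.
#'
#' @param traits data.frame or matrix with species row names.
#' @param scale_numeric z-score numeric columns (default TRUE).
#' @return numeric matrix, species x features.
#' @export
trait_feature_matrix <- function(traits, scale_numeric = TRUE) {
  if (is.matrix(traits)) {
    x <- traits
    storage.mode(x) <- "double"
  } else {
    stopifnot(is.data.frame(traits))
    cols <- list()
    for (nm in names(traits)) {
      v <- traits[[nm]]
      if (is.numeric(v)) {
        cols[[nm]] <- matrix(v, dimnames = list(NULL, nm))
      } else {
        f <- factor(v)
        m <- stats::model.matrix(~ f - 1)
        colnames(m) <- paste(nm, levels(f), sep = ".")
        cols[[nm]] <- m
      }
    }
    x <- do.call(cbind, cols)
    rownames(x) <- rownames(traits)
  }
  if (scale_numeric) {
    sds <- apply(x, 2L, stats::sd)
    keep_scale <- is.finite(sds) & sds > 0
    x[, keep_scale] <- scale(x[, keep_scale, drop = FALSE])
  }
  x
}
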
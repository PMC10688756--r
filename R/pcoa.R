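#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering of the squared distances, eigendecomposition,
#' and axis scores scaled by the square root of the eigenvalue. Negative
#' eigenvalues (possible for semi-metric dissimilarities such as
#' Bray-Curtis) are reported but excluded from the variance decomposition:
#' `fraction_of_variation[i] = lambda_i / sum(lambda_positive)`. No
#' Cailliez/Lingoes correction is applied by default; set
#' `correction = "cailliez"` to add the constant that removes negative
#' eigenvalues.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return object of class `pcoa_result`: list with `eigenvalues`
#'   (descending), `scores` (objects x positive axes, columns `PCoA1`,
#'   ...), `fraction_of_variation` (over positive axes),
#'   `negative_eigenvalues` (the negative part, if any) and `correction`.
#' @export
pcoa_axes <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  n <- nrow(d)
  if (n < 2L) stop("need at least two objects")
  if (correction == "cailliez") d <- cailliez_constant(d)
  # Gower centering: B = -1/2 * J D^2 J
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  b <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  lambda <- eig$values
  tol <- max(abs(lambda)) * 1e-10
  pos <- which(lambda > tol)
  if (!length(pos)) stop("no positive eigenvalues: objects are coincident")
  scores <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lambda[pos]), length(pos))
  colnames(scores) <- paste0("PCoA", seq_along(pos))
  rownames(scores) <- rownames(d)
  structure(
    list(eigenvalues = lambda,
         scores = scores,
         fraction_of_variation = lambda[pos] / sum(lambda[pos]),
         negative_eigenvalues = lambda[lambda < -tol],
         correction = correction),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat("Principal coordinates: ", nrow(x$scores), " objects, ",
      k, " positive axes\n", sep = "")
  show <- utils::head(x$fraction_of_variation, 5L)
  cat("  variation: ",
      paste0(round(100 * show, 2), "%", collapse = ", "),
      if (k > 5L) ", ..." else "", "\n", sep = "")
  if (length(x$negative_eigenvalues)) {
    cat("  ", length(x$negative_eigenvalues),
        " negative eigenvalue(s), min ",
        signif(min(x$negative_eigenvalues), 3), "\n", sep = "")
  }
  invisible(x)
}

# additive constant of Cailliez (1983): smallest c s.t. d + c is Euclidean
cailliez_constant <- function(d) {
  n <- nrow(d)
  del1 <- -0.5 * d^2
  del2 <- -0.5 * d
  center <- function(a) {
    rm_ <- rowMeans(a)
    a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
  }
  top <- cbind(matrix(0, n, n), 2 * center(del1))
  bot <- cbind(-diag(n), -4 * center(del2))
  cc <- max(Re(eigen(rbind(top, bot), only.values = TRUE)$values))
  d2 <- d + cc
  diag(d2) <- 0
  d2
}
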
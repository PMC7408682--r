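#' @keywords internal
new_pcor_network <- function(weights, labels, selected_penalty, ebic_gamma,
                             ebic_value, n_samples, grid = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  dimnames(weights) <- list(labels, labels)
  structure(
    list(
      labels = labels, weights = weights,
      selected_penalty = selected_penalty, ebic_gamma = ebic_gamma,
      ebic_value = ebic_value, n_samples = n_samples, grid = grid
    ),
    class = "pcor_network"
  )
}

#' @export
print.pcor_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf(
    "Partial-correlation network: %d nodes, %d edges\n", length(x$labels), ne
  ))
  if (!is.na(x$selected_penalty)) {
    cat(sprintf(
      "  graphical lasso penalty %.4g selected by EBIC (gamma = %g): %.2f\n",
      x$selected_penalty, x$ebic_gamma, x$ebic_value
    ))
  }
  if (ne > 0) {
    amax <- which(abs(x$weights) == max(abs(x$weights)), arr.ind = TRUE)[1, ]
    cat(sprintf(
      "  strongest edge: %s ~ %s (%.2f)\n",
      x$labels[amax[1]], x$labels[amax[2]], x$weights[amax[1], amax[2]]
    ))
  }
  invisible(x)
}

.check_pcor_matrix <- function(pcor) {
  stopifnot(is.matrix(pcor), nrow(pcor) == ncol(pcor))
  if (max(abs(pcor - t(pcor))) > 1e-8) stop("pcor matrix must be symmetric")
  if (any(diag(pcor) != 0)) stop("pcor matrix must have a zero diagonal")
  if (any(abs(pcor) >= 1)) stop("pcor entries must lie in (-1, 1)")
  invisible(pcor)
}

#' Covariance matrix of a latent Gaussian with a given partial-correlation
#' structure
#'
#' Inverts the partial-correlation parameterization: builds the precision
#' matrix with unit diagonal and off-diagonal entries \eqn{-\rho_{ij}},
#' and returns its inverse. The partial correlations of the returned
#' covariance matrix equal the input exactly, so the round trip
#' `partial_correlations(latent_pcor_to_covariance(P)) == P` holds whenever
#' the implied precision matrix is positive definite. If it is not, the
#' diagonal is inflated just enough to restore positive definiteness (with a
#' warning); the round trip then recovers a proportionally shrunken matrix.
#'
#' @param pcor Symmetric matrix of partial correlations in (-1, 1) with zero
#'   diagonal (a `pcor_network` is also accepted).
#' @param min_eigenvalue Smallest acceptable eigenvalue of the precision
#'   matrix before diagonal inflation kicks in.
#' @return Covariance matrix of the same dimension.
#' @seealso [partial_correlations()]
#' @export
#' @examples
#' p <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
#' cov2cor(latent_pcor_to_covariance(p))[1, 2]  # 0.5: with p = 2,
#' # the partial correlation is the marginal correlation
latent_pcor_to_covariance <- function(pcor, min_eigenvalue = 1e-8) {
  if (inherits(pcor, "pcor_network")) pcor <- pcor$weights
  .check_pcor_matrix(pcor)
  p <- nrow(pcor)
  omega <- diag(p) - pcor
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  lam_min <- min(ev)
  if (lam_min < min_eigenvalue) {
    bump <- min_eigenvalue - lam_min
    warning(sprintf(
      "precision matrix implied by pcor is not positive definite (min eigenvalue %.3g); inflating diagonal by %.3g",
      lam_min, bump
    ))
    omega <- omega + diag(bump, p)
    ev2 <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev2) < min_eigenvalue / 2) {
      stop("precision matrix still not positive definite after diagonal inflation")
    }
  }
  sigma <- solve(omega)
  dimnames(sigma) <- dimnames(pcor)
  (sigma + t(sigma)) / 2
}

#' Partial correlations from a covariance matrix or data
#'
#' Computes \eqn{\rho_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\omega_{jj}}}
#' from the precision matrix \eqn{\Omega = \Sigma^{-1}}.
#'
#' @param x Covariance (or correlation) matrix, or a numeric data matrix /
#'   data.frame with observations in rows (in which case its sample
#'   covariance is used).
#' @return Symmetric matrix of partial correlations with zero diagonal.
#' @export
partial_correlations <- function(x) {
  x <- as.matrix(x)
  sigma <- if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-10) x else stats::cov(x)
  omega <- solve(sigma)
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  diag(pc) <- 0
  dimnames(pc) <- dimnames(sigma)
  (pc + t(pc)) / 2
}

#' Partial correlations from a precision matrix
#'
#' @param omega Positive-definite precision matrix.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
precision_to_pcor <- function(omega) {
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  diag(pc) <- 0
  (pc + t(pc)) / 2
}
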
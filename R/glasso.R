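#' Extended Bayesian information criterion for a Gaussian graphical model
#'
#' EBIC = -2 loglik + E log n + 4 E gamma log p, where E is the number of
#' edges (nonzero upper-triangle entries of the precision matrix). gamma = 0
#' reduces to the ordinary BIC.
#'
#' @param loglik Gaussian log-likelihood of the fitted precision matrix.
#' @param n Number of observations.
#' @param p Number of variables (nodes).
#' @param n_edges Number of nonzero off-diagonal edges (upper triangle).
#' @param gamma EBIC edge-penalty weight, >= 0.
#' @return The EBIC value (scalar).
#' @export
#' @examples
#' ebic(-100, n = 100, p = 16, n_edges = 10, gamma = 0.5)  # ~300.51
ebic <- function(loglik, n, p, n_edges, gamma = 0.5) {
  stopifnot(n >= 0, p >= 0, n_edges >= 0, gamma >= 0)
  -2 * loglik + n_edges * log(n) + 4 * n_edges * gamma * log(p)
}

# Gaussian log-likelihood of precision matrix theta at sample covariance S
# (profile over the mean; includes the 2*pi constant).
.ggm_loglik <- function(theta, s, n) {
  p <- ncol(s)
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  (n / 2) * (as.numeric(ld$modulus) - sum(s * theta)) - (n * p / 2) * log(2 * pi)
}

#' Graphical lasso at a single penalty
#'
#' Block-coordinate-descent graphical lasso (Friedman-Hastie-Tibshirani):
#' estimates a sparse precision matrix by L1-penalized Gaussian
#' log-likelihood maximization. Lasso soft-thresholding zeroes weak partial
#' correlations exactly.
#'
#' @param s Sample covariance (or correlation) matrix.
#' @param rho Nonnegative L1 penalty. At `rho = 0` the estimate is the plain
#'   inverse of `s`, which must then be nonsingular.
#' @param tol Convergence tolerance on the average absolute change of the
#'   working covariance, relative to the average absolute off-diagonal of `s`.
#' @param maxit Maximum outer sweeps.
#' @return List with `theta` (precision), `w` (estimated covariance),
#'   `pcor` (partial correlations, exact zeros preserved), `rho`, `n_iter`.
#' @export
graphical_lasso <- function(s, rho, tol = 1e-7, maxit = 500) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s), rho >= 0)
  p <- ncol(s)
  if (rho == 0) {
    theta <- tryCatch(solve(s), error = function(e) {
      stop("sample covariance is singular at zero penalty; use a positive penalty")
    })
    theta <- (theta + t(theta)) / 2
    return(list(
      theta = theta, w = s, pcor = precision_to_pcor(theta),
      rho = rho, n_iter = 0L
    ))
  }
  w <- s
  diag(w) <- diag(s) + rho
  beta <- matrix(0, p - 1, p) # lasso coefficients per column, warm-started
  off_scale <- mean(abs(s[upper.tri(s)]))
  if (off_scale == 0) off_scale <- 1
  n_iter <- 0L
  for (it in seq_len(maxit)) {
    w_old <- w
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      w11 <- w[idx, idx, drop = FALSE]
      s12 <- s[idx, j]
      b <- beta[, j]
      # coordinate descent for: min 0.5 b'W11 b - s12'b + rho ||b||_1
      for (inner in seq_len(200)) {
        b_old <- b
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(w11[k, ] * b) + w11[k, k] * b[k]
          b[k] <- sign(r) * max(abs(r) - rho, 0) / w11[k, k]
        }
        if (max(abs(b - b_old)) < tol * off_scale) break
      }
      beta[, j] <- b
      w12 <- drop(w11 %*% b)
      w[idx, j] <- w12
      w[j, idx] <- w12
    }
    n_iter <- it
    if (mean(abs(w - w_old)) < tol * off_scale) break
  }
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    b <- beta[, j]
    theta_jj <- 1 / (w[j, j] - sum(w[idx, j] * b))
    theta[j, j] <- theta_jj
    theta[idx, j] <- -b * theta_jj
  }
  # exact zeros are symmetric by the lasso structure; average for stability
  zero <- (theta == 0) & (t(theta) == 0)
  theta <- (theta + t(theta)) / 2
  theta[zero] <- 0
  pc <- precision_to_pcor(theta)
  pc[zero] <- 0
  list(theta = theta, w = w, pcor = pc, rho = rho, n_iter = n_iter)
}

#' Estimate the food-group partial-correlation network
#'
#' Fits graphical-lasso Gaussian graphical models over a grid of penalties on
#' the column-standardized data and returns the network minimizing the
#' extended BIC (default gamma = 0.5). Edge weights are regularized partial
#' correlations; entries shrunk to zero by the penalty are exact zeros.
#'
#' @param intakes Numeric matrix or data.frame, observations in rows,
#'   variables (food groups) in columns. Must be complete, with more rows
#'   than columns and positive column variances.
#' @param gamma EBIC edge-penalty weight (default 0.5).
#' @param penalty_grid Optional vector of positive penalties. Default: 100
#'   log-spaced values from the maximum absolute off-diagonal sample
#'   correlation down to 1% of it.
#' @param n_penalties Grid size when `penalty_grid` is NULL.
#' @param standardize Standardize columns first (partial correlations are
#'   scale-free, so this only conditions the optimization).
#' @return A `pcor_network` with the selected penalty, the EBIC value and the
#'   full `$grid` (penalty, edges, loglik, ebic per candidate).
#' @export
estimate_ggm <- function(intakes, gamma = 0.5, penalty_grid = NULL,
                         n_penalties = 100, standardize = TRUE) {
  x <- as.matrix(intakes)
  if (anyNA(x)) stop("intakes must not contain missing values")
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("need more observations than food groups")
  if (any(apply(x, 2, stats::var) <= 0)) {
    stop("every column must have positive variance")
  }
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  s <- if (standardize) stats::cor(x) else stats::cov(x)
  if (is.null(penalty_grid)) {
    rho_max <- max(abs(s[upper.tri(s)]))
    penalty_grid <- exp(seq(log(rho_max), log(0.01 * rho_max),
                            length.out = n_penalties))
  }
  if (any(penalty_grid < 0)) stop("penalties must be nonnegative")
  if (any(penalty_grid == 0) && inherits(try(solve(s), silent = TRUE), "try-error")) {
    warning("singular covariance: dropping the zero penalty from the grid")
    penalty_grid <- penalty_grid[penalty_grid > 0]
  }
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)
  grid <- data.frame(
    penalty = penalty_grid, n_edges = NA_integer_,
    loglik = NA_real_, ebic = NA_real_
  )
  best <- NULL
  for (i in seq_along(penalty_grid)) {
    fit <- graphical_lasso(s, penalty_grid[i])
    ne <- sum(fit$pcor[upper.tri(fit$pcor)] != 0)
    ll <- .ggm_loglik(fit$theta, s, n)
    crit <- ebic(ll, n, p, ne, gamma)
    grid$n_edges[i] <- ne
    grid$loglik[i] <- ll
    grid$ebic[i] <- crit
    if (is.null(best) || crit < best$ebic) {
      best <- list(fit = fit, ebic = crit, penalty = penalty_grid[i])
    }
  }
  new_pcor_network(
    best$fit$pcor, labels,
    selected_penalty = best$penalty, ebic_gamma = gamma,
    ebic_value = best$ebic, n_samples = n, grid = grid
  )
}
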
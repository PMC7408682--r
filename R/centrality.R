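#' Eigenvector centrality of the food-group network
#'
#' Node weights proportional to the leading eigenvector of the edge-weight
#' matrix, computed by shifted power iteration and scaled so the maximum
#' centrality is exactly 1. Isolated nodes receive 0.
#'
#' The network has negative partial-correlation edges, so a convention is
#' needed. The default (`weights = "signed"`) iterates on the signed weight
#' matrix and returns the algebraically leading eigenvector, which reproduces
#' the published node weights of the reference network (including the
#' identity of the maximal node); `weights = "absolute"` iterates on
#' \eqn{|w_{ij}|} (the classical nonnegative convention).
#'
#' @param network A `pcor_network`, or a symmetric numeric matrix of edge
#'   weights with zero diagonal.
#' @param weights `"signed"` (default) or `"absolute"`.
#' @param tol Convergence tolerance: max-norm difference between successive
#'   normalized iterates.
#' @param maxit Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return Object of class `centrality_weights`: list with `labels` and
#'   `weight` (named vector, max exactly 1).
#' @export
#' @examples
#' cw <- eigenvector_centrality(reference_network())
#' round(cw$weight[c("Seasonings", "Vegetables")], 2)
eigenvector_centrality <- function(network,
                                   weights = c("signed", "absolute"),
                                   tol = 1e-10, maxit = 100000) {
  weights <- match.arg(weights)
  w <- if (inherits(network, "pcor_network")) network$weights else as.matrix(network)
  stopifnot(nrow(w) == ncol(w))
  if (max(abs(w - t(w))) > 1e-10) stop("edge-weight matrix must be symmetric")
  labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(w)))
  if (all(w == 0)) stop("network has no edges: eigenvector centrality undefined")
  a <- if (weights == "absolute") abs(w) else w
  p <- nrow(a)
  # shift by the max absolute row sum so the algebraically largest eigenvalue
  # dominates in magnitude and power iteration converges to its eigenvector
  shift <- max(rowSums(abs(a)))
  v <- rep(1 / sqrt(p), p)
  converged <- FALSE
  residual <- NA_real_
  for (it in seq_len(maxit)) {
    av <- drop(a %*% v) + shift * v
    nv <- sqrt(sum(av^2))
    if (nv == 0) stop("power iteration collapsed to the zero vector")
    v_new <- av / nv
    residual <- max(abs(v_new - v))
    v <- v_new
    if (residual < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "power iteration did not converge in %d iterations (residual %.3g)",
      maxit, residual
    ))
  }
  # orient so the dominant component is positive, then max-normalize
  v <- v * sign(v[which.max(abs(v))])
  v[abs(v) < tol * 10] <- 0
  cw <- v / max(v)
  structure(
    list(labels = labels, weight = stats::setNames(cw, labels),
         convention = weights),
    class = "centrality_weights"
  )
}

#' @export
print.centrality_weights <- function(x, ...) {
  cat(sprintf("Eigenvector centrality weights (%s edge weights):\n",
              x$convention))
  print(round(sort(x$weight, decreasing = TRUE), 3))
  invisible(x)
}

#' Dietary intake score
#'
#' Per-subject weighted sum of food-group intakes (g/day), weighted by the
#' max-normalized eigenvector centralities of the dietary network. With all
#' weights 1 this is the total daily intake over the 16 groups.
#'
#' @param intake Numeric vector of one subject's intakes, or a matrix /
#'   data.frame (subjects in rows) whose column names match the weight
#'   labels (either display labels or `intake_<key>` cohort columns).
#' @param weights A `centrality_weights` object, or a named numeric vector.
#' @return Numeric vector of scores (g/day), one per subject.
#' @export
dietary_score <- function(intake, weights) {
  w <- if (inherits(weights, "centrality_weights")) weights$weight else weights
  if (is.null(names(w))) stop("weights must be named by food group")
  x <- if (is.null(dim(intake))) {
    matrix(intake, nrow = 1, dimnames = list(NULL, names(intake)))
  } else {
    as.matrix(intake)
  }
  cols <- colnames(x)
  if (is.null(cols)) {
    if (ncol(x) != length(w)) stop("unnamed intake must match weight length")
    cols <- names(w)
    colnames(x) <- cols
  }
  # accept cohort-style intake_<key> column names
  if (!all(names(w) %in% cols)) {
    fg <- food_groups()
    alt <- paste0("intake_", fg$key[match(names(w), fg$label)])
    if (all(alt %in% cols)) {
      x <- x[, alt, drop = FALSE]
      colnames(x) <- names(w)
      cols <- names(w)
    } else {
      stop("intake columns do not match the weight labels")
    }
  }
  x <- x[, names(w), drop = FALSE]
  if (any(x < 0)) stop("intakes must be nonnegative")
  drop(x %*% w)
}

#' Tertile eating-behavior classes
#'
#' Cuts dietary scores at the empirical 1/3 and 2/3 quantiles into light,
#' normal and heavy eating behavior. The lower class is closed on the
#' cutpoint (score <= q1/3 is light), so ties at a cutpoint all fall in the
#' lower class.
#'
#' @param scores Numeric vector of dietary scores, length >= 3, not all
#'   identical.
#' @return Factor with ordered levels `light`, `normal`, `heavy`.
#' @export
#' @examples
#' table(tertile_classes(1:9))
tertile_classes <- function(scores) {
  if (length(scores) < 3) stop("need at least 3 subjects for tertiles")
  if (anyNA(scores)) stop("scores must be complete")
  q <- stats::quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
  if (q[1] == q[2] || min(scores) == max(scores)) {
    stop("scores are too heavily tied for tertiles")
  }
  cls <- ifelse(scores <= q[1], "light", ifelse(scores <= q[2], "normal", "heavy"))
  factor(cls, levels = c("light", "normal", "heavy"))
}
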
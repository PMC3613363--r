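# The t-LSE probability model over node pairs.
#
# Node i carries a coordinate z_i in R^d and the model scores a pair by
# the margin  xi_ij = b - ||z_i - z_j||^2 ; the interaction probability
# is F_t(xi_ij) and the non-interaction probability F_t(-xi_ij).  The
# bias b is a single global squared-distance cutoff: pairs closer than
# sqrt(b) are more likely interacting than not.

#' Pair margins under an embedding
#'
#' @param coords n x d numeric matrix of node coordinates.
#' @param bias scalar bias `b` (squared-distance cutoff).
#' @param pairs m x 2 integer matrix of node-index pairs.
#' @return numeric vector of margins `b - ||z_i - z_j||^2`.
#' @export
pair_margin <- function(coords, bias, pairs) {
  bias - pair_sqdist(coords, pairs)
}

pair_sqdist <- function(coords, pairs) {
  d <- coords[pairs[, 1], , drop = FALSE] - coords[pairs[, 2], , drop = FALSE]
  unname(rowSums(d * d))
}

# Build the positive/negative pair set for a fit.
#
# Positives are the network's edges.  Negatives are either all non-edges
# (exact = TRUE) or a uniform sample of round(neg_ratio * |E|) of them,
# reweighted by (#non-edges / #sampled) so the sampled objective is an
# unbiased estimate of the full negative-log-likelihood.
make_pair_set <- function(net, neg_ratio = 5, exact = FALSE, seed = 1) {
  n <- n_nodes(net)
  m <- n_edges(net)
  n_non <- n * (n - 1) / 2 - m
  if (exact) {
    neg <- all_non_edges(net)
    w <- 1
  } else {
    count <- min(max(1, round(neg_ratio * m)), n_non)
    neg <- sample_non_edges(net, count, seed = seed)
    w <- if (count > 0) n_non / count else 1
  }
  structure(list(pos = net$edges, neg = neg, neg_weight = w),
            class = "pair_set")
}

#' The t-LSE negative log-likelihood
#'
#' Sum of t-logistic losses over positive pairs (at margin `xi`) and
#' negative pairs (at margin `-xi`), the latter weighted by the
#' `neg_weight` of the pair set (1 for the exact objective, the
#' inverse sampling fraction for sampled negatives).
#'
#' @inheritParams pair_margin
#' @param t loss parameter in `[1, 2)`.
#' @param pairs a pair set as built internally by [tlse()]: a list with
#'   `pos`, `neg` (index matrices) and `neg_weight`.
#' @return scalar objective value.
#' @export
tlse_objective <- function(coords, bias, t, pairs) {
  obj <- 0
  if (nrow(pairs$pos) > 0) {
    obj <- obj + sum(t_loss(pair_margin(coords, bias, pairs$pos), t))
  }
  if (nrow(pairs$neg) > 0) {
    obj <- obj + pairs$neg_weight *
      sum(t_loss(-pair_margin(coords, bias, pairs$neg), t))
  }
  obj
}

# objective, coordinate gradient and bias gradient in one pass
# (single normalizer solve over all sampled pairs)
eval_state <- function(coords, bias, t, pairs) {
  n <- nrow(coords)
  P <- rbind(pairs$pos, pairs$neg)
  np <- nrow(pairs$pos)
  nn <- nrow(pairs$neg)
  u <- pair_margin(coords, bias, P)
  y <- rep(c(1, -1), c(np, nn))
  wt <- rep(c(1, pairs$neg_weight), c(np, nn))
  lg <- t_loss_grad(y * u, t)
  obj <- sum(lg$loss * wt)
  W <- -2 * lg$dloss * y * wt
  db <- sum(lg$dloss * y * wt)
  diffs <- coords[P[, 1], , drop = FALSE] - coords[P[, 2], , drop = FALSE]
  grp <- c(P[, 1], P[, 2])
  acc <- rowsum(rbind(diffs * W, -diffs * W), group = grp)
  dZ <- matrix(0, n, ncol(coords))
  dZ[as.integer(rownames(acc)), ] <- acc
  rs <- rowsum(c(abs(W), abs(W)), group = grp)
  rowsum_abs <- numeric(n)
  rowsum_abs[as.integer(rownames(rs))] <- rs
  list(obj = obj, dZ = dZ, db = db,
       weights = list(pairs = P, w = W, y = y, rowsum_abs = rowsum_abs,
                      n_pos = np))
}

#' Gradient of the t-LSE objective
#'
#' Returns the gradient in the weighted-average (graph Laplacian) form:
#' each sampled pair `(i, j)` carries a mixing coefficient
#' `W_ij = -2 * loss'(y_ij * xi_ij) * y_ij * weight`, positive for edges
#' (attraction) and negative for non-edges (repulsion), and the
#' coordinate gradient row is `dZ_i = sum_j W_ij (z_i - z_j)`.  At a
#' stationary point with non-zero row sums each point is the weighted
#' average of its partners.
#'
#' @inheritParams tlse_objective
#' @return a list with `dZ` (n x d matrix), `db` (scalar), and
#'   `weights`: a list with the stacked pair matrix `pairs`, the mixing
#'   coefficients `w`, and `rowsum_abs` (per-node sum of |W| entries,
#'   used by the diagonal preconditioner).
#' @export
tlse_gradient <- function(coords, bias, t, pairs) {
  n <- nrow(coords)
  d <- ncol(coords)
  P <- rbind(pairs$pos, pairs$neg)
  np <- nrow(pairs$pos)
  nn <- nrow(pairs$neg)
  u <- pair_margin(coords, bias, P)
  y <- rep(c(1, -1), c(np, nn))
  wt <- rep(c(1, pairs$neg_weight), c(np, nn))
  lp <- t_dloss(y * u, t)              # loss'(y * xi), always < 0
  W <- -2 * lp * y * wt
  db <- sum(lp * y * wt)
  diffs <- coords[P[, 1], , drop = FALSE] - coords[P[, 2], , drop = FALSE]
  contrib <- rbind(diffs * W, -diffs * W)
  grp <- c(P[, 1], P[, 2])
  acc <- rowsum(contrib, group = grp)
  dZ <- matrix(0, n, d)
  dZ[as.integer(rownames(acc)), ] <- acc
  rs <- rowsum(c(abs(W), abs(W)), group = grp)
  rowsum_abs <- numeric(n)
  rowsum_abs[as.integer(rownames(rs))] <- rs
  list(dZ = dZ, db = db,
       weights = list(pairs = P, w = W, y = y, rowsum_abs = rowsum_abs,
                      n_pos = np))
}
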
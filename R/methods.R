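# S3 methods for fitted embeddings

#' @export
print.tlse <- function(x, ...) {
  cat(sprintf("t-LSE embedding (t = %g, d = %d)\n", x$t, x$dim))
  cat(sprintf("  network: %d nodes, %d edges\n",
              n_nodes(x$network), n_edges(x$network)))
  cat(sprintf("  objective: %.6g after %d iterations (%s)\n",
              x$objective, nrow(x$trace), x$reason))
  cat(sprintf("  bias (squared-distance cutoff): %.4g\n", x$bias))
  invisible(x)
}

#' Summarise a fitted t-LSE embedding
#'
#' Reports the fit trace, the training-edge margin distribution, the
#' fraction of edges classified as interacting at probability 1/2
#' (positive margin), and the rank-based AUC separating edges from the
#' fitted negative pairs.
#'
#' @param object a [tlse()] fit.
#' @param ... unused.
#' @return an object of class `summary.tlse`.
#' @export
summary.tlse <- function(object, ...) {
  mar_pos <- pair_margin(object$coords, object$bias, object$pairs$pos)
  d_pos <- sqrt(pair_sqdist(object$coords, object$pairs$pos))
  d_neg <- sqrt(pair_sqdist(object$coords, object$pairs$neg))
  structure(list(t = object$t, dim = object$dim,
                 n = n_nodes(object$network), m = n_edges(object$network),
                 objective = object$objective,
                 iterations = nrow(object$trace),
                 converged = object$converged, reason = object$reason,
                 bias = object$bias,
                 edge_margin = summary(mar_pos),
                 frac_edges_positive = mean(mar_pos > 0),
                 train_auc = rank_auc(d_pos, d_neg)),
            class = "summary.tlse")
}

#' @export
print.summary.tlse <- function(x, ...) {
  cat(sprintf("t-LSE embedding: n = %d, m = %d, d = %d, t = %g\n",
              x$n, x$m, x$dim, x$t))
  cat(sprintf("  objective %.6g after %d iterations (%s)\n",
              x$objective, x$iterations, x$reason))
  cat(sprintf("  bias: %.4g\n", x$bias))
  cat(sprintf("  edges with positive margin: %.1f%%\n",
              100 * x$frac_edges_positive))
  cat(sprintf("  training AUC (edges vs sampled non-edges): %.4f\n",
              x$train_auc))
  cat("  edge margins:\n")
  print(x$edge_margin)
  invisible(x)
}

#' Extract embedding coordinates
#'
#' @param object a fitted `tlse` or `mdsgeo` object.
#' @param ... unused.
#' @return the n x d coordinate matrix, with the bias attached as
#'   attribute `"bias"`.
#' @export
coef.tlse <- function(object, ...) {
  structure(object$coords, bias = object$bias)
}

#' Predict interaction scores for node pairs
#'
#' @param object a [tlse()] fit.
#' @param pairs two-column matrix of node labels (or integer indices);
#'   defaults to the training pairs.
#' @param type `"prob"` for the interaction probability `F_t(margin)`,
#'   `"margin"` for `b - distance^2`, `"distance"` for the embedding
#'   distance.
#' @param ... unused.
#' @return numeric vector, one value per pair.
#' @export
predict.tlse <- function(object, pairs = NULL,
                         type = c("prob", "margin", "distance"), ...) {
  type <- match.arg(type)
  idx <- resolve_pairs(object, pairs)
  d2 <- pair_sqdist(object$coords, idx)
  switch(type,
         distance = sqrt(d2),
         margin = object$bias - d2,
         prob = t_link(object$bias - d2, object$t)$p_pos)
}

resolve_pairs <- function(object, pairs) {
  if (is.null(pairs)) {
    return(rbind(object$pairs$pos, object$pairs$neg))
  }
  pairs <- as.matrix(pairs)
  if (is.character(pairs)) {
    idx <- matrix(match(pairs, rownames(object$coords)), ncol = 2)
    if (any(is.na(idx))) stop("unknown node label in `pairs`")
    idx
  } else {
    matrix(as.integer(pairs), ncol = 2)
  }
}

#' @export
fitted.tlse <- function(object, ...) {
  P <- rbind(object$pairs$pos, object$pairs$neg)
  p <- t_link(pair_margin(object$coords, object$bias, P), object$t)$p_pos
  data.frame(i = rownames(object$coords)[P[, 1]],
             j = rownames(object$coords)[P[, 2]],
             label = rep(c(1, -1), c(nrow(object$pairs$pos),
                                     nrow(object$pairs$neg))),
             prob = p)
}

#' Deviance-style residuals of a t-LSE fit
#'
#' `sign(y) * sqrt(2 * loss)` per training pair: large positive values
#' are edges the embedding keeps far apart (candidate false positives),
#' large negative values non-edges it pulls close.
#'
#' @param object a [tlse()] fit.
#' @param ... unused.
#' @return numeric vector over the training pairs (positives first).
#' @export
residuals.tlse <- function(object, ...) {
  u_pos <- pair_margin(object$coords, object$bias, object$pairs$pos)
  u_neg <- pair_margin(object$coords, object$bias, object$pairs$neg)
  c(sqrt(2 * t_loss(u_pos, object$t)),
    -sqrt(2 * t_loss(-u_neg, object$t)))
}

#' Plot an embedded network
#'
#' Scatter of the first two embedding coordinates with the network's
#' edges drawn between them (1-D embeddings are plotted against node
#' rank).
#'
#' @param x a fitted `tlse` or `mdsgeo` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tlse <- function(x, ...) {
  plot_embedding(x$coords, x$network,
                 main = sprintf("t-LSE (t = %g, d = %d)", x$t, x$dim), ...)
  invisible(x)
}

plot_embedding <- function(coords, net, main = "", ...) {
  Z <- if (ncol(coords) >= 2) coords[, 1:2] else
    cbind(coords[, 1], seq_len(nrow(coords)) / nrow(coords))
  graphics::plot(Z, xlab = "dim 1", ylab = if (ncol(coords) >= 2) "dim 2"
                 else "node rank", main = main, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.8), ...)
  if (n_edges(net) > 0) {
    graphics::segments(Z[net$edges[, 1], 1], Z[net$edges[, 1], 2],
                       Z[net$edges[, 2], 1], Z[net$edges[, 2], 2],
                       col = grDevices::adjustcolor("grey40", 0.3))
    graphics::points(Z, pch = 16,
                     col = grDevices::adjustcolor("steelblue", 0.8))
  }
}

#' Simulate networks from a fitted t-LSE model
#'
#' Draws each node pair independently with its fitted interaction
#' probability `F_t(b - distance^2)`.  Quadratic in the node count, so
#' only offered at desk scale.
#'
#' @param object a [tlse()] fit.
#' @param nsim number of networks to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` [ppi_network()] objects.
#' @export
simulate.tlse <- function(object, nsim = 1, seed = 1, ...) {
  n <- nrow(object$coords)
  if (n * (n - 1) / 2 > 5e6) stop("network too large to simulate all pairs")
  P <- t(utils::combn(n, 2))
  p <- t_link(pair_margin(object$coords, object$bias, P), object$t)$p_pos
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      keep <- stats::runif(length(p)) < p
      ppi_network(P[keep, , drop = FALSE], nodes = rownames(object$coords))
    })
  })
}
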
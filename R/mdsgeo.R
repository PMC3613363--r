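# MDS-GEO baseline: classical multidimensional scaling of the
# shortest-path (hop) distance matrix.

#' All-pairs shortest-path (hop) distance matrix
#'
#' @param net a connected [ppi_network()].
#' @param disconnected `"error"` (the default; split the network with
#'   [graph_components()] first) or `"impute"`, which replaces
#'   unreachable distances by the largest finite hop count plus one so
#'   that a single global embedding still exists (used by the
#'   noise-perturbation driver, where perturbed graphs can fragment).
#' @return symmetric integer matrix of hop counts with zero diagonal,
#'   node labels as dimnames.
#' @export
shortest_path_matrix <- function(net, disconnected = c("error", "impute")) {
  disconnected <- match.arg(disconnected)
  if (n_nodes(net) == 0) stop("empty network")
  D <- igraph::distances(as_igraph(net))
  if (any(is.infinite(D))) {
    if (disconnected == "error") {
      stop("network is disconnected; embed components separately ",
           "(see graph_components)")
    }
    finite_max <- max(D[is.finite(D)])
    D[is.infinite(D)] <- finite_max + 1
  }
  dimnames(D) <- list(net$nodes, net$nodes)
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distances, `B = -1/2 J (D o D) J` with
#' `J = I - 11'/n`, and embeds on the top-`d` eigenvectors scaled by the
#' square roots of their (positive) eigenvalues.  If fewer than `d`
#' eigenvalues are positive the remaining coordinates are zero.  The
#' sign of each eigenvector is fixed by making its largest-magnitude
#' entry positive, for reproducibility.
#'
#' @param D square symmetric distance matrix.
#' @param d embedding dimension.
#' @return n x d coordinate matrix with attribute `"eigenvalues"` (all
#'   `n` eigenvalues of the centred Gram matrix, decreasing).
#' @export
classical_mds <- function(D, d) {
  stopifnot(d >= 1, nrow(D) == ncol(D))
  n <- nrow(D)
  D2 <- D * D
  B <- -0.5 * (D2 - rowMeans(D2) -
                 rep(colMeans(D2), each = n) + mean(D2))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  Z <- matrix(0, n, d)
  k <- min(d, sum(e$values > 0))
  if (k > 0) {
    V <- e$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
    }
    Z[, seq_len(k)] <- V %*% diag(sqrt(e$values[seq_len(k)]), k)
  }
  rownames(Z) <- rownames(D)
  attr(Z, "eigenvalues") <- e$values
  Z
}

#' Fit the MDS-GEO baseline embedding
#'
#' Embeds a connected network by classical MDS of its hop-distance
#' matrix.  A bias (squared-distance cutoff) is chosen as the threshold
#' maximising Youden's J (sensitivity + specificity - 1) on the
#' training edges, so MDS-GEO fits expose the same margin/score
#' interface as [tlse()] fits.
#'
#' @inheritParams shortest_path_matrix
#' @param dim embedding dimension.
#' @return an object of class `mdsgeo` with `coords`, `bias`,
#'   `eigenvalues`, `dim`, `network`.
#' @examples
#' net <- gen_geometric(50, 2, 120, seed = 1)$net
#' fit <- mdsgeo(net, dim = 2)
#' fit
#' @export
mdsgeo <- function(net, dim = 2, disconnected = c("error", "impute")) {
  D <- shortest_path_matrix(net, disconnected = match.arg(disconnected))
  Z <- classical_mds(D, dim)
  ev <- attr(Z, "eigenvalues")
  attr(Z, "eigenvalues") <- NULL
  structure(list(coords = Z, bias = youden_bias(Z, net),
                 eigenvalues = ev, dim = dim, network = net),
            class = "mdsgeo")
}

# squared-distance cutoff maximising Youden's J on the training edges,
# with non-edges (all, or a deterministic cap) as negatives
youden_bias <- function(Z, net) {
  n <- nrow(Z)
  d2_pos <- pair_sqdist(Z, net$edges)
  neg <- if (n * (n - 1) / 2 <= 5e6) all_non_edges(net) else
    sample_non_edges(net, 10 * n_edges(net), seed = 1)
  d2_neg <- pair_sqdist(Z, neg)
  cand <- sort(unique(d2_pos))
  sens <- vapply(cand, function(th) mean(d2_pos <= th), numeric(1))
  spec <- vapply(cand, function(th) mean(d2_neg > th), numeric(1))
  cand[which.max(sens + spec - 1)]
}

#' @export
print.mdsgeo <- function(x, ...) {
  pos_ev <- sum(x$eigenvalues > 0)
  cat(sprintf("MDS-GEO embedding (d = %d)\n", x$dim))
  cat(sprintf("  network: %d nodes, %d edges\n",
              n_nodes(x$network), n_edges(x$network)))
  cat(sprintf("  positive eigenvalues: %d of %d; top-%d mass %.1f%%\n",
              pos_ev, length(x$eigenvalues), x$dim,
              100 * sum(pmax(x$eigenvalues, 0)[seq_len(x$dim)]) /
                sum(pmax(x$eigenvalues, 0))))
  cat(sprintf("  bias (squared-distance cutoff): %.4g\n", x$bias))
  invisible(x)
}

#' @export
coef.mdsgeo <- function(object, ...) {
  structure(object$coords, bias = object$bias)
}

#' Predict scores from an MDS-GEO embedding
#'
#' MDS-GEO has no probabilistic model, so `type = "prob"` is not
#' offered; distances and margins share the [tlse()] conventions.
#'
#' @param object an [mdsgeo()] fit.
#' @param pairs two-column matrix of node labels or indices; defaults
#'   to all pairs of the network's edges.
#' @param type `"distance"` or `"margin"`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.mdsgeo <- function(object, pairs = NULL,
                           type = c("distance", "margin"), ...) {
  type <- match.arg(type)
  idx <- if (is.null(pairs)) object$network$edges else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) {
      matrix(match(pairs, rownames(object$coords)), ncol = 2)
    } else matrix(as.integer(pairs), ncol = 2)
  }
  d2 <- pair_sqdist(object$coords, idx)
  switch(type, distance = sqrt(d2), margin = object$bias - d2)
}

#' @export
plot.mdsgeo <- function(x, ...) {
  plot_embedding(x$coords, x$network,
                 main = sprintf("MDS-GEO (d = %d)", x$dim), ...)
  invisible(x)
}
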
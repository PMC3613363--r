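# Random-graph null models used to benchmark the fit of network models
# to PPI data, plus the geometric generator that serves as synthetic
# ground truth and the noise-perturbation operator.
#
# Every generator is seed-deterministic, leaves the caller's RNG stream
# untouched, and emits a simple undirected ppi_net.

default_labels <- function(n) sprintf("v%d", seq_len(n))

#' Erdos-Renyi random graph G(n, m)
#'
#' Exactly `m` distinct edges chosen uniformly among all node pairs.
#' Uses only the node and edge counts of the network being modelled.
#'
#' @param n number of nodes.
#' @param m number of edges, at most `choose(n, 2)`.
#' @param seed integer seed.
#' @return a [ppi_network()].
#' @export
gen_er <- function(n, m, seed = 1) {
  total <- n * (n - 1) / 2
  if (m > total) stop("m exceeds the number of node pairs")
  ks <- with_seed(seed, sort(sample.int(total, m)))
  ppi_network(pair_unindex(ks, n), nodes = default_labels(n))
}

#' Degree-matched random graph by the stubs method (ER-DD)
#'
#' Each node of the reference network contributes as many "stubs"
#' (half-edges) as its degree; edges are created by repeatedly joining
#' two uniformly chosen stubs, rejecting self-loops and duplicate
#' edges, and decrementing the joined nodes' stub counts.  When no
#' legal join can be found (a configurable run of consecutive
#' rejections), the remaining stubs are discarded and reported via the
#' `"residual_stubs"` attribute, so the output degree sequence matches
#' the reference up to that residue.
#'
#' @param reference a [ppi_network()] whose degree sequence is matched.
#' @param seed integer seed.
#' @param max_reject consecutive rejected joins tolerated before
#'   declaring a dead end (default `1000 * |E|`).
#' @param retries stub pairing can dead-end with a few stranded stubs
#'   (the last stubs may only offer self-loops or duplicate edges,
#'   increasingly likely at higher density); the construction is
#'   restarted up to this many times until a residue-free pairing is
#'   found, which leaves the sampling distribution unchanged apart from
#'   conditioning on success.
#' @return a [ppi_network()] on the reference's nodes, with attributes
#'   `"residual_stubs"` (count of unplaceable stubs, usually 0) and
#'   `"attempts"`.
#' @export
gen_erdd <- function(reference, seed = 1, max_reject = NULL, retries = 10) {
  deg <- degrees(reference)
  n <- length(deg)
  if (sum(deg) == 0) stop("reference network has no edges")
  max_reject <- max_reject %||% (1000 * n_edges(reference))
  seeds <- derive_seeds(seed, retries + 1L)
  best <- NULL
  for (att in seq_len(retries + 1L)) {
    out <- with_seed(seeds[att], stub_match_once(deg, n, max_reject))
    if (is.null(best) ||
        attr(out, "residual_stubs") < attr(best, "residual_stubs")) {
      best <- out
      attr(best, "attempts") <- att
    }
    if (attr(best, "residual_stubs") == 0) break
  }
  best$nodes <- reference$nodes
  best
}

stub_match_once <- function(deg, n, max_reject) {
  stubs <- rep(seq_len(n), deg)
  seen <- new.env(hash = TRUE)
  ei <- integer(0); ej <- integer(0)
  rejects <- 0L
  while (length(stubs) >= 2 && rejects < max_reject) {
    pick <- sample.int(length(stubs), 2)
    a <- stubs[pick[1]]; b <- stubs[pick[2]]
    key <- paste0(min(a, b), ".", max(a, b))
    if (a == b || !is.null(seen[[key]])) {
      rejects <- rejects + 1L
      # cheap exact dead-end checks: all stubs on one node, or the
      # remaining distinct stub pairs all already joined
      if (rejects %% 1000L == 0L) {
        us <- unique(stubs)
        if (length(us) == 1L) break
        if (length(us) <= 6L) {
          cand <- utils::combn(sort(us), 2)
          legal <- !vapply(seq_len(ncol(cand)), function(k) {
            !is.null(seen[[paste0(cand[1, k], ".", cand[2, k])]])
          }, logical(1))
          if (!any(legal)) break
        }
      }
      next
    }
    seen[[key]] <- TRUE
    ei <- c(ei, min(a, b)); ej <- c(ej, max(a, b))
    stubs <- stubs[-pick]
    rejects <- 0L
  }
  out <- ppi_network(cbind(ei, ej), nodes = sprintf("s%d", seq_len(n)))
  attr(out, "residual_stubs") <- length(stubs)
  out
}

#' Scale-free network by Barabasi-Albert preferential attachment
#'
#' Growth with degree-proportional attachment.  The number of edges
#' added per arriving node is randomised between the floor and ceiling
#' of the per-node average needed so that the expected final edge count
#' equals `m_total` (matching the modelled network's node and edge
#' counts, as the protocol requires).
#'
#' @param n number of nodes (>= 3).
#' @param m_total target total edge count.
#' @param seed integer seed.
#' @return a [ppi_network()] with exactly `n` nodes and approximately
#'   `m_total` edges.
#' @export
gen_sf <- function(n, m_total, seed = 1) {
  if (n < 3) stop("gen_sf needs n >= 3")
  mbar <- m_total / n
  s <- max(2L, ceiling(mbar) + 1L)     # seed path: attachment targets exist
  if (s >= n) stop("m_total too large for preferential attachment on n nodes")
  target_per <- (m_total - (s - 1)) / (n - s)
  base <- max(0L, floor(target_per))
  frac <- target_per - base
  with_seed(seed, {
    deg <- numeric(n)
    ei <- seq_len(s - 1); ej <- 2:s     # path on the seed nodes
    deg[1:s] <- tabulate(c(ei, ej), nbins = n)[1:s]
    for (v in (s + 1):n) {
      k <- min(v - 1, base + (stats::runif(1) < frac))
      if (k > 0) {
        targets <- sample(v - 1, k, prob = deg[seq_len(v - 1)])
        ei <- c(ei, targets); ej <- c(ej, rep(v, k))
        deg[targets] <- deg[targets] + 1
        deg[v] <- deg[v] + k
      }
    }
    ppi_network(cbind(ei, ej), nodes = default_labels(n))
  })
}

#' Stickiness-index random graph
#'
#' Node `i` gets stickiness `theta_i = deg(i) / sqrt(sum(deg))` from the
#' reference degrees; each pair `(i, j)` is included independently with
#' probability `min(1, theta_i * theta_j)`, so expected degrees track
#' the reference for sparse graphs.  Probability clips at 1 are counted
#' in the `"clipped_pairs"` attribute.
#'
#' @inheritParams gen_erdd
#' @return a [ppi_network()] on the reference's nodes.
#' @export
gen_sticky <- function(reference, seed = 1) {
  deg <- degrees(reference)
  if (sum(deg) == 0) stop("reference network has no edges")
  n <- length(deg)
  theta <- deg / sqrt(sum(deg))
  P <- t(utils::combn(n, 2))
  p <- theta[P[, 1]] * theta[P[, 2]]
  clipped <- sum(p > 1)
  p <- pmin(p, 1)
  with_seed(seed, {
    keep <- stats::runif(length(p)) < p
    out <- ppi_network(P[keep, , drop = FALSE], nodes = reference$nodes)
    attr(out, "clipped_pairs") <- clipped
    out
  })
}

#' Geometric random graph with known ground-truth coordinates
#'
#' `n` points drawn uniformly in the unit `d_true`-cube; the
#' `m_target` closest pairs are connected (the connection radius is the
#' `m_target`-th smallest pairwise distance; ties broken by pair index).
#' This makes the geometric assumption exact — every edge's generating
#' distance is no larger than every non-edge's — so the generating
#' coordinates give a perfect-recovery oracle for embedding
#' experiments.
#'
#' @param n number of nodes.
#' @param d_true latent dimension.
#' @param m_target number of edges.
#' @param seed integer seed.
#' @return list with `net` (a [ppi_network()]), `coords` (the n x
#'   d_true generating coordinates, rownames = node labels) and
#'   `radius` (the realised connection radius).
#' @export
gen_geometric <- function(n, d_true = 2, m_target, seed = 1) {
  total <- n * (n - 1) / 2
  if (m_target > total) stop("m_target exceeds the number of node pairs")
  X <- with_seed(seed, matrix(stats::runif(n * d_true), n, d_true))
  dd <- as.vector(stats::dist(X))      # pair order (2,1),(3,1).. by column:
  P <- t(utils::combn(n, 2))           # combn order matches dist's ordering
  ord <- order(dd, seq_along(dd))
  keep <- ord[seq_len(m_target)]
  rownames(X) <- default_labels(n)
  list(net = ppi_network(P[keep, , drop = FALSE], nodes = rownames(X)),
       coords = X,
       radius = if (m_target > 0) max(dd[keep]) else 0)
}

#' Randomly rewire a fraction of a network's edges (noise model)
#'
#' Removes `floor(frac * |E|)` uniformly chosen edges and inserts the
#' same number of uniformly chosen non-edges, emulating the false
#' negatives and false positives of high-throughput interaction data.
#' The edge count and node set are conserved.
#'
#' @param net a [ppi_network()].
#' @param frac fraction of edges to rewire, in `[0, 1)`.
#' @param seed integer seed.
#' @return a perturbed [ppi_network()].
#' @export
perturb_network <- function(net, frac, seed = 1) {
  stopifnot(frac >= 0, frac < 1)
  k <- floor(frac * n_edges(net))
  if (k == 0) return(net)
  seeds <- derive_seeds(seed, 2)
  drop <- with_seed(seeds[1], sample.int(n_edges(net), k))
  ins <- sample_non_edges(net, k, seed = seeds[2])
  kept <- net$edges[-drop, , drop = FALSE]
  ppi_network(rbind(kept, ins), nodes = net$nodes)
}
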
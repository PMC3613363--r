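# Shared fixtures and independent oracles for the test-suite.
# Oracles are deliberately written from first principles (closed forms,
# brute-force enumeration) so they never share code with the paths they
# check.

net_triangle <- function() ppi_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
net_path3 <- function() ppi_network(cbind(c("a", "b"), c("b", "c")))

rand_net <- function(n, m, seed) gen_er(n, m, seed = seed)

# closed-form logistic loss and derivative (t = 1 oracle)
logistic_loss <- function(u) log1p(exp(-u))
logistic_dloss <- function(u) -1 / (1 + exp(u))

# brute-force AUC: explicit pairwise comparison, ties half
brute_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
  mean(cmp)
}

# independent full t-LSE objective at t = 1 via the logistic closed form
brute_logistic_objective <- function(Z, b, pairs) {
  marg <- function(P) {
    d <- Z[P[, 1], , drop = FALSE] - Z[P[, 2], , drop = FALSE]
    b - rowSums(d^2)
  }
  sum(logistic_loss(marg(pairs$pos))) +
    pairs$neg_weight * sum(logistic_loss(-marg(pairs$neg)))
}

# numerical gradient of a scalar function of a matrix, central differences
num_grad_mat <- function(f, X, h = 1e-6) {
  G <- X * 0
  for (k in seq_along(X)) {
    Xp <- X; Xp[k] <- X[k] + h
    Xm <- X; Xm[k] <- X[k] - h
    G[k] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

# ---- brute-force graphlet orbit oracle (independent of the package's
# ESU/classifier path): enumerate every node subset, test connectivity
# and classify with igraph isomorphism against reference graphlets.

# reference graphlets for orbits 0..14, as edge lists on 1..k
.oracle_graphlets <- list(
  list(size = 2, edges = rbind(c(1, 2)), orbits = c(0, 0)),
  list(size = 3, edges = rbind(c(1, 2), c(2, 3)), orbits = c(1, 2, 1)),
  list(size = 3, edges = rbind(c(1, 2), c(2, 3), c(1, 3)), orbits = c(3, 3, 3)),
  list(size = 4, edges = rbind(c(1, 2), c(2, 3), c(3, 4)),
       orbits = c(4, 5, 5, 4)),                                   # P4
  list(size = 4, edges = rbind(c(1, 2), c(1, 3), c(1, 4)),
       orbits = c(7, 6, 6, 6)),                                   # claw
  list(size = 4, edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)),
       orbits = c(8, 8, 8, 8)),                                   # C4
  list(size = 4, edges = rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4)),
       orbits = c(11, 10, 10, 9)),                                # paw
  list(size = 4, edges = rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(3, 4)),
       orbits = c(13, 12, 13, 12)),                               # diamond
  list(size = 4, edges = rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3),
                               c(2, 4), c(3, 4)),
       orbits = c(14, 14, 14, 14))                                # K4
)

oracle_orbit_counts <- function(net, max_size = 4) {
  n <- n_nodes(net)
  g <- as_igraph(net)
  counts <- matrix(0L, n, 15, dimnames = list(net$nodes, sprintf("o%d", 0:14)))
  refs <- lapply(.oracle_graphlets, function(gl) {
    igraph::graph_from_edgelist(gl$edges, directed = FALSE)
  })
  for (k in 2:max_size) {
    if (n < k) next
    subs <- utils::combn(n, k)
    for (ci in seq_len(ncol(subs))) {
      s <- subs[, ci]
      sg <- igraph::induced_subgraph(g, s)
      if (!igraph::is_connected(sg)) next
      for (gi in seq_along(.oracle_graphlets)) {
        gl <- .oracle_graphlets[[gi]]
        if (gl$size != k) next
        map <- igraph::isomorphic(sg, refs[[gi]])
        if (!map) next
        # find an explicit isomorphism to carry node orbits over
        perm <- find_iso(sg, refs[[gi]])
        counts[cbind(s, gl$orbits[perm] + 1L)] <-
          counts[cbind(s, gl$orbits[perm] + 1L)] + 1L
        break
      }
    }
  }
  counts
}

# explicit isomorphism by brute force over permutations (k <= 4 here)
find_iso <- function(g1, g2) {
  k <- igraph::vcount(g1)
  A1 <- as.matrix(igraph::as_adjacency_matrix(g1)) > 0
  A2 <- as.matrix(igraph::as_adjacency_matrix(g2)) > 0
  perms <- perms_of(k)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (all(A1 == A2[p, p])) return(p)  # node i of g1 maps to p[i] of g2
  }
  stop("no isomorphism found")
}

perms_of <- function(k) {
  g <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  g[apply(g, 1, function(r) length(unique(r)) == k), , drop = FALSE]
}
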
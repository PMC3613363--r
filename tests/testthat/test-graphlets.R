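# Orbit counting, GDD profiles and GDD agreement.

test_that("orbit counts match hand enumeration on K3 and P3", {
  k3 <- orbit_counts(net_triangle())
  expect_equal(unname(k3[, "o0"]), rep(2L, 3))
  expect_equal(unname(k3[, "o3"]), rep(1L, 3))
  expect_true(all(k3[, sprintf("o%d", c(1, 2, 4:14))] == 0))

  p3 <- orbit_counts(net_path3())
  expect_equal(p3[, "o1"], c(a = 1L, b = 0L, c = 1L))
  expect_equal(p3[, "o2"], c(a = 0L, b = 1L, c = 0L))
  expect_true(all(p3[, "o3"] == 0))
})

test_that("edgeless graphs have all-zero counts", {
  lone <- ppi_network(nodes = c("x", "y", "z"))
  expect_true(all(orbit_counts(lone) == 0))
})

test_that("orbit counts equal the brute-force induced-subgraph oracle", {
  # all connected graphs on <= 5 nodes via the igraph atlas, plus random
  # graphs on 6 and 7 nodes
  cases <- list()
  for (idx in 1:52) {  # atlas ids 1..52 cover all graphs on <= 5 nodes
    g <- igraph::graph_from_atlas(idx)
    if (igraph::vcount(g) < 2 || !igraph::is_connected(g)) next
    el <- igraph::as_edgelist(g)
    cases[[length(cases) + 1]] <-
      ppi_network(matrix(sprintf("n%d", el), ncol = 2),
                  nodes = sprintf("n%d", seq_len(igraph::vcount(g))))
  }
  set.seed(99)
  for (n in 6:7) {
    for (r in 1:6) {
      m <- sample(n:(n * (n - 1) / 2 - 1), 1)
      cases[[length(cases) + 1]] <- gen_er(n, m, seed = 1000 * n + r)
    }
  }
  for (net in cases) {
    expect_equal(orbit_counts(net, max_size = 4),
                 oracle_orbit_counts(net, max_size = 4))
  }
})

test_that("five-node orbits partition correctly against brute force", {
  # the atlas-derived table must produce 73 orbits total and count each
  # connected 5-subgraph exactly once per node
  net <- gen_er(9, 16, seed = 12)
  oc <- orbit_counts(net, max_size = 5)
  expect_equal(ncol(oc), 73L)
  expect_equal(oc[, 1:15], orbit_counts(net, max_size = 4))
  # total orbit touches per graphlet size: each connected induced
  # k-subgraph contributes exactly k touches across the size-k orbits
  g <- as_igraph(net)
  n5 <- 0
  subs <- utils::combn(9, 5)
  for (ci in seq_len(ncol(subs))) {
    if (igraph::is_connected(igraph::induced_subgraph(g, subs[, ci]))) {
      n5 <- n5 + 1
    }
  }
  expect_equal(sum(oc[, 16:73]), 5 * n5)
  # node-level cross-check: within-orbit degree symmetry — permuting the
  # node labels permutes rows
  perm <- sample(9)
  pnet <- ppi_network(cbind(perm[net$edges[, 1]], perm[net$edges[, 2]]),
                      nodes = sprintf("v%d", 1:9))
  poc <- orbit_counts(pnet, max_size = 5)
  expect_equal(unname(poc[perm, ]), unname(oc))
})

test_that("gdd profile normalises with the 1/k scaling", {
  k3 <- orbit_counts(net_triangle())
  prof <- gdd_profile(k3)
  # edge orbit: all three nodes touch it twice -> single bin at k = 2
  expect_equal(prof$o0, c("2" = 1))
  expect_equal(prof$o3, c("1" = 1))
  expect_length(prof$o5, 0)

  # doubling a network (disjoint union) leaves the profile unchanged
  two <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                           c("x", "y"), c("y", "z"), c("x", "z")))
  expect_equal(gdd_profile(orbit_counts(two))$o0, prof$o0)
  expect_equal(gdd_profile(orbit_counts(two))$o3, prof$o3)
})

test_that("gdd agreement is 1 on identical networks and in [0,1] generally", {
  net <- gen_er(15, 30, seed = 5)
  expect_equal(as.numeric(gdd_agreement(net, net)), 1)
  expect_equal(as.numeric(gdd_agreement(net, net, mean = "geometric")), 1)

  set.seed(21)
  for (r in 1:100) {
    a <- gen_er(12, sample(11:30, 1), seed = 2 * r)
    b <- gen_sf(12, sample(11:30, 1), seed = 2 * r + 1)
    ag <- as.numeric(gdd_agreement(a, b))
    expect_gte(ag, 0)
    expect_lte(ag, 1)
  }
})

test_that("agreement between K3 and P3 matches the hand computation", {
  # K3 profiles: o0 {2:1}, o3 {1:1};  P3: o0 {1: (2/1)/(2+1)... } computed
  # by hand: o0 has two nodes touching once (mass 2/1) and one node twice
  # (mass 1/2), normalised; o1 {1:1}, o2 {1:1}
  p_o0_k3 <- c(`1` = 0, `2` = 1)
  p_o0_p3 <- c(`1` = (2 / 1) / (2 / 1 + 1 / 2), `2` = (1 / 2) / (2 / 1 + 1 / 2))
  a_o0 <- 1 - sqrt(sum((p_o0_k3 - p_o0_p3)^2)) / sqrt(2)
  a_o1 <- 1 - 1 / sqrt(2)  # {1:1} vs empty: distance 1
  a_o2 <- a_o1
  a_o3 <- a_o1             # triangle orbit: K3 only
  expected <- mean(c(a_o0, a_o1, a_o2, a_o3))
  got <- gdd_agreement(net_triangle(), net_path3())
  expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  expect_equal(attr(got, "orbits_used"), 4L)
})

test_that("agreement is symmetric and relabelling-invariant", {
  a <- gen_er(14, 28, seed = 8)
  b <- gen_sf(14, 28, seed = 9)
  expect_equal(as.numeric(gdd_agreement(a, b)), as.numeric(gdd_agreement(b, a)))
  perm <- local({ set.seed(4); sample(14) })
  b2 <- ppi_network(cbind(perm[b$edges[, 1]], perm[b$edges[, 2]]),
                    nodes = sprintf("w%d", 1:14))
  expect_equal(as.numeric(gdd_agreement(a, b2)), as.numeric(gdd_agreement(a, b)))
})

test_that("model networks fit a geometric source at least as well as ER", {
  # scaled-down model-fit comparison: networks simulated from a fitted
  # embedding agree with the source better than size-matched ER graphs
  src <- graph_components(gen_geometric(80, 2, 240, seed = 3)$net)[[1]]
  fit <- tlse(src, dim = 2, t = 1.9, seed = 3,
              control = tlse_control(max_iter = 120))
  ag_fit <- vapply(1:3, function(s) {
    recon <- simulate(fit, seed = s)[[1]]
    as.numeric(gdd_agreement(src, recon))
  }, numeric(1))
  ag_er <- vapply(1:3, function(s) {
    as.numeric(gdd_agreement(src, gen_er(n_nodes(src), n_edges(src), seed = s)))
  }, numeric(1))
  expect_gte(mean(ag_fit), mean(ag_er))
})
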
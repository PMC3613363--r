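# Descent-direction contract, Wolfe line search and the alternating fit.

test_that("identity preconditioner returns the negative gradient", {
  inst_net <- rand_net(8, 14, seed = 3)
  pairs <- tlse:::make_pair_set(inst_net, neg_ratio = 3, seed = 4)
  set.seed(5)
  Z <- matrix(rnorm(16, sd = 0.5), 8, 2)
  st <- tlse:::eval_state(Z, 0.4, 1.9, pairs)
  dir <- search_direction(st, tlse_control(precond = "identity"))
  expect_equal(dir$D, -st$dZ)
  expect_equal(dir$dirderiv, -sum(st$dZ^2))
})

test_that("preconditioned directions are descent directions at random states", {
  net <- rand_net(10, 20, seed = 8)
  pairs <- tlse:::make_pair_set(net, neg_ratio = 3, seed = 9)
  set.seed(10)
  for (pc in c("diagonal", "sparse")) {
    ctrl <- tlse_control(precond = pc)
    for (rep in 1:100) {
      Z <- matrix(rnorm(20, sd = runif(1, 0.05, 2)), 10, 2)
      st <- tlse:::eval_state(Z, runif(1, 0.1, 2), 1.9, pairs)
      dir <- search_direction(st, ctrl)
      expect_lt(dir$dirderiv, 0)
    }
  }
})

test_that("zero gradient yields the zero direction", {
  st <- list(dZ = matrix(0, 4, 2),
             weights = list(pairs = rbind(c(1L, 2L)), w = 1,
                            rowsum_abs = rep(1, 4), n_pos = 1L))
  dir <- search_direction(st, tlse_control(precond = "diagonal"))
  expect_equal(dir$D, matrix(0, 4, 2))
  expect_equal(dir$dirderiv, 0)
})

test_that("line search solves the 1-D quadratic and honours Armijo", {
  phi <- function(eta) (eta - 1)^2
  dphi <- function(eta) 2 * (eta - 1)
  ctrl <- tlse_control()
  ls <- wolfe_line_search(phi, dphi(0), dphi, ctrl)
  expect_true(ls$wolfe)
  expect_gt(ls$step, 0)
  # both conditions hold at the accepted step
  expect_lte(phi(ls$step), phi(0) + ctrl$c1 * ls$step * dphi(0))
  expect_gte(dphi(ls$step), ctrl$c2 * dphi(0))
  expect_error(wolfe_line_search(phi, 0.5, dphi, ctrl), "descent direction")
})

test_that("accepted steps satisfy the Armijo inequality on random objectives", {
  set.seed(31)
  ctrl <- tlse_control()
  for (rep in 1:20) {
    a <- runif(1, 0.3, 4); c0 <- runif(1, -2, -0.1)
    phi <- function(eta) a * eta^2 + c0 * eta  # phi(0) = 0
    dphi <- function(eta) 2 * a * eta + c0
    ls <- wolfe_line_search(phi, c0, dphi, ctrl)
    expect_lte(phi(ls$step), 0 + ctrl$c1 * ls$step * c0 + 1e-12)
  }
})

test_that("fitting a triangle classifies all its edges as interactions", {
  fit <- tlse(net_triangle(), dim = 2, t = 1.9, seed = 2,
              control = tlse_control(max_iter = 200))
  margins <- predict(fit, fit$network$edges, type = "margin")
  expect_true(all(margins > 0))
  probs <- predict(fit, fit$network$edges, type = "prob")
  expect_true(all(probs > 0.5))
})

test_that("objective trace is non-increasing with negative directional derivatives", {
  for (tt in c(1, 1.9)) {
    net <- rand_net(20, 45, seed = 17)
    fit <- tlse(net, dim = 2, t = tt, seed = 6,
                control = tlse_control(max_iter = 60))
    expect_true(all(diff(fit$trace$objective) <= 1e-9))
    expect_true(all(fit$trace$dirderiv < 0))
    expect_true(all(fit$trace$step > 0))
  }
})

test_that("fits are deterministic given a seed", {
  net <- rand_net(15, 30, seed = 23)
  f1 <- tlse(net, dim = 2, seed = 99, control = tlse_control(max_iter = 25))
  f2 <- tlse(net, dim = 2, seed = 99, control = tlse_control(max_iter = 25))
  expect_identical(f1$coords, f2$coords)
  expect_identical(f1$bias, f2$bias)
  f3 <- tlse(net, dim = 2, seed = 100, control = tlse_control(max_iter = 25))
  expect_false(identical(f1$coords, f3$coords))
})

test_that("degenerate inputs are rejected", {
  expect_error(tlse(ppi_network(nodes = c("a", "b"))), "at least 2 nodes and 1 edge")
  expect_error(tlse(ppi_network()), "at least 2 nodes and 1 edge")
  two <- ppi_network(rbind(c("a", "b")))
  fit <- tlse(two, dim = 2, seed = 1, control = tlse_control(max_iter = 10))
  expect_equal(nrow(fit$coords), 2)
})

test_that("node relabelling permutes the embedding consistently", {
  # same deterministic inputs mapped through a permutation must give the
  # same pairwise-distance multiset
  net <- rand_net(12, 26, seed = 41)
  perm <- local({ set.seed(1); sample(12) })
  # permuted network: node i of net becomes position perm[i]
  pedges <- cbind(perm[net$edges[, 1]], perm[net$edges[, 2]])
  pnet <- ppi_network(pedges, nodes = sprintf("n%d", 1:12))
  set.seed(2)
  Z0 <- matrix(rnorm(24, sd = 0.1), 12, 2)
  negs <- tlse:::make_pair_set(net, neg_ratio = 3, seed = 7)$neg
  pnegs <- cbind(perm[negs[, 1]], perm[negs[, 2]])
  pnegs <- cbind(pmin(pnegs[, 1], pnegs[, 2]), pmax(pnegs[, 1], pnegs[, 2]))
  ctrl <- tlse_control(max_iter = 40)
  f <- tlse(net, dim = 2, seed = 1, control = ctrl,
            init_coords = Z0, neg_pairs = negs)
  fp <- tlse(pnet, dim = 2, seed = 1, control = ctrl,
             init_coords = Z0[order(perm), ], neg_pairs = pnegs)
  d <- sort(as.vector(dist(f$coords)))
  dp <- sort(as.vector(dist(fp$coords)))
  expect_equal(d, dp, tolerance = 1e-6)
})

test_that("t = 1 fit agrees with an independent logistic-loss embedder", {
  net <- rand_net(10, 22, seed = 55)
  pairs <- tlse:::make_pair_set(net, neg_ratio = 3, seed = 5)
  set.seed(3)
  Z0 <- matrix(rnorm(20, sd = 0.1), 10, 2)
  # gradients agree exactly at the initial state
  g_pkg <- tlse_gradient(Z0, 0.4, 1, pairs)
  marg <- function(Z, P, b)
    b - rowSums((Z[P[, 1], , drop = FALSE] - Z[P[, 2], , drop = FALSE])^2)
  oracle_grad <- function(Z, b) {
    G <- Z * 0
    for (k in seq_len(nrow(pairs$pos))) {
      e <- pairs$pos[k, ]
      u <- marg(Z, pairs$pos[k, , drop = FALSE], b)
      w <- -2 * logistic_dloss(u)
      G[e[1], ] <- G[e[1], ] + w * (Z[e[1], ] - Z[e[2], ])
      G[e[2], ] <- G[e[2], ] + w * (Z[e[2], ] - Z[e[1], ])
    }
    for (k in seq_len(nrow(pairs$neg))) {
      e <- pairs$neg[k, ]
      u <- -marg(Z, pairs$neg[k, , drop = FALSE], b)
      w <- 2 * logistic_dloss(u) * pairs$neg_weight
      G[e[1], ] <- G[e[1], ] + w * (Z[e[1], ] - Z[e[2], ])
      G[e[2], ] <- G[e[2], ] + w * (Z[e[2], ] - Z[e[1], ])
    }
    G
  }
  expect_equal(g_pkg$dZ, oracle_grad(Z0, 0.4), tolerance = 1e-10)
  # an independent plain gradient-descent embedder reaches a comparable
  # objective on the same fixed pair set
  fit <- tlse(net, dim = 2, t = 1, seed = 1, init_coords = Z0,
              neg_pairs = structure(pairs$neg, neg_weight = pairs$neg_weight),
              control = tlse_control(max_iter = 300))
  Z <- Z0; b <- 0.4
  obj <- function(Z, b) {
    sum(logistic_loss(marg(Z, pairs$pos, b))) +
      pairs$neg_weight * sum(logistic_loss(-marg(Z, pairs$neg, b)))
  }
  f_cur <- obj(Z, b)
  for (it in 1:2000) {
    G <- oracle_grad(Z, b)
    gb <- sum(-1 / (1 + exp(marg(Z, pairs$pos, b)))) +
      pairs$neg_weight * sum(1 / (1 + exp(-marg(Z, pairs$neg, b))))
    eta <- 0.05
    repeat {
      f_new <- obj(Z - eta * G, b - eta * gb)
      if (f_new <= f_cur || eta < 1e-12) break
      eta <- eta / 2
    }
    Z <- Z - eta * G; b <- b - eta * gb
    if (abs(f_cur - f_new) < 1e-10 * max(1, f_cur)) break
    f_cur <- f_new
  }
  expect_lt(abs(fit$objective - f_cur) / max(1, f_cur), 0.05)
})
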
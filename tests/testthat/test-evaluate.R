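# Scoring, ROC/AUC, densities, edge ranking and the noise driver.

test_that("pair scores are Euclidean distances", {
  Z <- rbind(a = c(0, 0), b = c(3, 4), c = c(1, 1))
  expect_equal(score_pairs(Z, rbind(c("a", "b"))), 5)
  expect_equal(score_pairs(Z, rbind(c(1, 1))), 0)
  # symmetry and triangle inequality on all three pairs
  d_ab <- score_pairs(Z, rbind(c(1, 2)))
  d_bc <- score_pairs(Z, rbind(c(2, 3)))
  d_ac <- score_pairs(Z, rbind(c(1, 3)))
  expect_equal(score_pairs(Z, rbind(c(2, 1))), d_ab)
  expect_lte(d_ac, d_ab + d_bc)
  # matches a naive per-pair computation
  set.seed(2)
  Zr <- matrix(rnorm(30), 10, 3)
  P <- t(utils::combn(10, 2))
  naive <- apply(P, 1, function(p) sqrt(sum((Zr[p[1], ] - Zr[p[2], ])^2)))
  expect_equal(score_pairs(Zr, P), naive, tolerance = 1e-12)
})

test_that("AUC equals the brute-force pairwise probability", {
  expect_equal(roc_auc(c(1, 3), c(2, 4))$auc, 0.75)
  expect_equal(roc_auc(1:5, 6:10)$auc, 1)           # perfect separation
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)  # identical -> ties
  set.seed(14)
  for (r in 1:25) {
    pos <- round(runif(sample(2:8, 1), 0, 4), 1)
    neg <- round(runif(sample(2:8, 1), 0, 4), 1)
    expect_equal(roc_auc(pos, neg)$auc, brute_auc(pos, neg))
  }
})

test_that("ROC sweep spans (0,0) to (1,1) monotonically with correct counts", {
  set.seed(8)
  pos <- rexp(40); neg <- rexp(60) + 0.5
  ev <- roc_auc(pos, neg)
  roc <- ev$roc
  expect_equal(roc$sensitivity[1], 0)
  expect_equal(1 - roc$specificity[1], 0)
  expect_equal(roc$sensitivity[nrow(roc)], 1)
  expect_equal(roc$specificity[nrow(roc)], 0)
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(1 - roc$specificity) >= 0))
  expect_true(all(roc$tp + roc$fn == 40))
  expect_true(all(roc$tn + roc$fp == 60))
  # definitions at one interior threshold
  th <- median(c(pos, neg))
  k <- max(which(roc$threshold <= th))
  expect_equal(roc$tp[k], sum(pos < roc$threshold[k]))
  expect_equal(roc$tn[k], sum(neg >= roc$threshold[k]))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  pos <- runif(30); neg <- runif(30) + 0.3
  a0 <- roc_auc(pos, neg)$auc
  expect_equal(roc_auc(log1p(pos), log1p(neg))$auc, a0)
  expect_equal(roc_auc(pos^3, neg^3)$auc, a0)
})

test_that("conditional densities integrate to one and separate a clean fit", {
  set.seed(9)
  cd <- conditional_densities(rnorm(200, 1), rnorm(300, 3))
  ig <- function(y) sum(diff(cd$grid) * (y[-1] + y[-length(y)]) / 2)
  expect_equal(ig(cd$pos_density), 1, tolerance = 1e-3)
  expect_equal(ig(cd$neg_density), 1, tolerance = 1e-3)

  # near-degenerate scores collapse to a sharp mode at the common value
  cd2 <- conditional_densities(rep(2, 50), rnorm(50, 5))
  expect_equal(cd2$grid[which.max(cd2$pos_density)], 2, tolerance = 0.05)
})

test_that("edge ranking orders by distance with lexicographic ties", {
  Z <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), d = c(1, 1))
  net <- ppi_network(rbind(c("a", "b"), c("c", "d"), c("a", "c"), c("b", "d")))
  rk <- rank_edges(Z, net)
  expect_equal(rk$distance, rep(1, 4))
  expect_equal(rk$from, c("a", "a", "b", "c"))  # ties: label order
  expect_equal(rank_edges(Z, net, top = 1)$rank, 1:4)
  expect_equal(nrow(rank_edges(Z, net, top = 0.5)), 2)
})

test_that("embedding distances separate edges from non-edges (density modes)", {
  g <- gen_geometric(120, 2, 480, seed = 11)
  comp <- graph_components(g$net)[[1]]
  fit <- tlse(comp, dim = 2, t = 1.9, seed = 11,
              control = tlse_control(max_iter = 120))
  pos <- predict(fit, comp$edges, type = "distance")
  neg <- predict(fit, all_non_edges(comp), type = "distance")
  cd <- conditional_densities(pos, neg)
  expect_lt(cd$grid[which.max(cd$pos_density)],
            cd$grid[which.max(cd$neg_density)])
})

test_that("planted false edges sink to the bottom of the reliability ranking", {
  g <- gen_geometric(100, 2, 400, seed = 21)
  ok <- 0
  for (s in 1:3) {
    pert <- perturb_network(g$net, 0.2, seed = s)
    injected <- setdiff(paste(pert$edges[, 1], pert$edges[, 2]),
                        paste(g$net$edges[, 1], g$net$edges[, 2]))
    fit <- tlse(pert, dim = 2, t = 1.9, seed = s,
                control = tlse_control(max_iter = 100))
    rk <- rank_edges(fit, pert)
    key <- paste(match(rk$from, pert$nodes), match(rk$to, pert$nodes))
    key <- paste(pmin(match(rk$from, pert$nodes), match(rk$to, pert$nodes)),
                 pmax(match(rk$from, pert$nodes), match(rk$to, pert$nodes)))
    m <- length(key); q <- ceiling(0.2 * m)
    frac_top <- mean(key[1:q] %in% injected)
    frac_bot <- mean(key[(m - q + 1):m] %in% injected)
    if (frac_bot > frac_top) ok <- ok + 1
  }
  expect_gte(ok, 2)  # holds in at least 2 of 3 replicates
})

test_that("noise experiment reproduces plain recovery at level zero", {
  g <- gen_geometric(60, 2, 180, seed = 31)
  ctrl <- tlse_control(max_iter = 60)
  tab <- noise_experiment(g$net, levels = 0, replicates = 1, dim = 2,
                          methods = "tlse_t1.9", seed = 31, control = ctrl)
  fit <- tlse(g$net, dim = 2, t = 1.9, seed = tlse:::derive_seeds(31, 2)[2],
              control = ctrl)
  auc <- tlse:::rank_auc(
    score_pairs(fit, g$net$edges),
    score_pairs(fit, all_non_edges(g$net)))
  expect_equal(tab$mean_auc, auc, tolerance = 1e-12)
  expect_true(is.na(tab$sd_auc) || tab$sd_auc == 0)
})

test_that("noise experiment has the level x method shape with finite stats", {
  g <- gen_geometric(50, 2, 120, seed = 41)
  ctrl <- tlse_control(max_iter = 30)
  tab <- noise_experiment(g$net, levels = c(0.05, 0.2), replicates = 2,
                          dim = 2, seed = 41, control = ctrl)
  expect_equal(nrow(tab), 2 * 3)
  expect_true(all(is.finite(tab$mean_auc)))
  expect_true(all(is.finite(tab$sd_auc)))
  expect_true(all(tab$mean_auc > 0 & tab$mean_auc <= 1))
  runs <- attr(tab, "runs")
  expect_equal(nrow(runs), 2 * 2 * 3)
})
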
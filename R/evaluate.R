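# Embedding-quality evaluation: distance scores, ROC/AUC, conditional
# densities, edge-reliability ranking and the noise-perturbation
# experiment driver.

#' Embedding distances for node pairs
#'
#' @param emb a fitted `tlse`/`mdsgeo` object, or a coordinate matrix
#'   with node labels as rownames.
#' @param pairs two-column matrix of node labels or integer indices.
#' @return numeric vector of Euclidean distances (lower = more likely
#'   interacting).
#' @export
score_pairs <- function(emb, pairs) {
  coords <- if (is.matrix(emb)) emb else emb$coords
  pairs <- as.matrix(pairs)
  idx <- if (is.character(pairs)) {
    matrix(match(pairs, rownames(coords)), ncol = 2)
  } else matrix(as.integer(pairs), ncol = 2)
  if (any(is.na(idx))) stop("unknown node in `pairs`")
  sqrt(pair_sqdist(coords, idx))
}

# rank-based AUC: probability that a positive scores LOWER than a
# negative, ties counted half
rank_auc <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[n_pos + seq_len(n_neg)]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve and AUC for distance scores
#'
#' Sensitivity (`TP/(TP+FN)`) and specificity (`TN/(TN+FP)`) over a
#' threshold sweep: a pair is predicted interacting when its distance
#' is below the threshold, and the sweep runs over all distinct scores
#' plus 0 and a final all-inclusive threshold, so the curve spans
#' (0,0) to (1,1).  The AUC is computed rank-based — the probability
#' that an interacting pair scores lower than a non-interacting one,
#' ties counted half — rather than from the sweep grid.
#'
#' @param pos_scores distances of interacting (edge) pairs.
#' @param neg_scores distances of non-interacting pairs.
#' @return an object of class `tlse_eval`: list with `roc`
#'   (data.frame: threshold, tp, fp, tn, fn, sensitivity, specificity),
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("both score vectors must be nonempty")
  }
  th <- c(0, sort(unique(c(pos_scores, neg_scores))), Inf)
  sp <- sort(pos_scores)
  sn <- sort(neg_scores)
  tp <- findInterval(th, sp, left.open = TRUE)  # # pos strictly below th
  fp <- findInterval(th, sn, left.open = TRUE)
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  roc <- data.frame(threshold = th, tp = tp, fp = fp,
                    tn = n_neg - fp, fn = n_pos - tp,
                    sensitivity = tp / n_pos,
                    specificity = (n_neg - fp) / n_neg)
  structure(list(roc = roc, auc = rank_auc(pos_scores, neg_scores),
                 n_pos = n_pos, n_neg = n_neg),
            class = "tlse_eval")
}

#' @export
print.tlse_eval <- function(x, ...) {
  cat(sprintf("ROC evaluation: %d interacting vs %d non-interacting pairs\n",
              x$n_pos, x$n_neg))
  cat(sprintf("  AUC (rank-based): %.4f\n", x$auc))
  j <- which.max(x$roc$sensitivity + x$roc$specificity - 1)
  cat(sprintf("  best Youden point: threshold %.4g, sens %.3f, spec %.3f\n",
              x$roc$threshold[j], x$roc$sensitivity[j], x$roc$specificity[j]))
  invisible(x)
}

#' Conditional distance densities p(Distance | Interaction) and
#' p(Distance | Non-interaction)
#'
#' Gaussian kernel density estimates on a shared grid, Silverman's
#' rule-of-thumb bandwidth, each renormalised to integrate to 1 on the
#' grid.
#'
#' @inheritParams roc_auc
#' @param bw bandwidth rule, any selector accepted by
#'   [stats::density()] (`"nrd0"`, Silverman's rule, is the default) or
#'   a numeric bandwidth.
#' @param n_grid number of grid points.
#' @return list with `grid`, `pos_density`, `neg_density`,
#'   `bw_pos`, `bw_neg`.
#' @export
conditional_densities <- function(pos_scores, neg_scores, bw = "nrd0",
                                  n_grid = 512) {
  if (length(pos_scores) < 2 || length(neg_scores) < 2) {
    stop("need at least 2 scores per class")
  }
  safe_bw <- function(x) {
    b <- if (is.numeric(bw)) bw else {
      tryCatch(stats::density(x, bw = bw, n = 2)$bw,
               error = function(e) NA_real_)
    }
    if (!is.finite(b) || b <= 0) b <- max(1e-3 * max(abs(x), 1), 1e-6)
    b
  }
  bw_p <- safe_bw(pos_scores)
  bw_n <- safe_bw(neg_scores)
  lo <- min(pos_scores, neg_scores) - 3 * max(bw_p, bw_n)
  hi <- max(pos_scores, neg_scores) + 3 * max(bw_p, bw_n)
  dp <- stats::density(pos_scores, bw = bw_p, from = lo, to = hi, n = n_grid)
  dn <- stats::density(neg_scores, bw = bw_n, from = lo, to = hi, n = n_grid)
  renorm <- function(y, x) y / trapz(x, y)
  list(grid = dp$x,
       pos_density = renorm(dp$y, dp$x),
       neg_density = renorm(dn$y, dn$x),
       bw_pos = bw_p, bw_n = bw_n)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Rank a network's edges by embedding distance (reliability ranking)
#'
#' Interactions are ordered from the most reliable (smallest embedding
#' distance) to the least; ties are broken lexicographically by node
#' labels.  Slicing the top `q` fraction gives the `q`-coverage
#' sub-network used in reliability assessment.
#'
#' @param emb a fitted `tlse`/`mdsgeo` object or coordinate matrix.
#' @param net the network whose edges are ranked.
#' @param top fraction of edges to keep, in `(0, 1]`.
#' @return data.frame with columns `from`, `to`, `distance`, `rank`.
#' @export
rank_edges <- function(emb, net, top = 1) {
  stopifnot(top > 0, top <= 1)
  lab <- cbind(net$nodes[net$edges[, 1]], net$nodes[net$edges[, 2]])
  d <- score_pairs(emb, lab)
  o <- order(d, lab[, 1], lab[, 2])
  k <- ceiling(top * length(o))
  out <- data.frame(from = lab[o, 1], to = lab[o, 2], distance = d[o],
                    rank = seq_along(o))[seq_len(k), ]
  rownames(out) <- NULL
  out
}

#' Noise-perturbation experiment (denoising protocol)
#'
#' For each noise level, generates `replicates` perturbed networks
#' (random edge deletions plus equally many random insertions), embeds
#' each with every requested method, and computes the AUC of the
#' embedding distances against the edges and non-edges of the
#' *original*, unperturbed network.
#'
#' @param net the clean reference [ppi_network()].
#' @param levels numeric vector of perturbation fractions.
#' @param replicates perturbed networks per level.
#' @param dim embedding dimension.
#' @param methods subset of `"tlse_t1.9"`, `"tlse_t1.0"`, `"mdsgeo"`.
#' @param seed master seed; every perturbation and fit derives from it.
#' @param control a [tlse_control()] for the t-LSE fits.
#' @param max_neg cap on evaluation non-edges; all non-edges are used
#'   when their count is below the cap, otherwise a seeded sample.
#' @return data.frame with one row per level x method: `level`,
#'   `method`, `mean_auc`, `sd_auc`, `replicates`; the per-run AUCs are
#'   attached as attribute `"runs"`.
#' @export
noise_experiment <- function(net, levels = c(0.05, 0.10, 0.25),
                             replicates = 5, dim = 2,
                             methods = c("tlse_t1.9", "tlse_t1.0", "mdsgeo"),
                             seed = 1, control = tlse_control(),
                             max_neg = 5e5) {
  methods <- match.arg(methods, several.ok = TRUE)
  n <- n_nodes(net)
  n_non <- n * (n - 1) / 2 - n_edges(net)
  eval_neg <- if (n_non <= max_neg) all_non_edges(net) else
    sample_non_edges(net, min(max_neg, 10 * n_edges(net)), seed = seed)
  pos <- net$edges
  seeds <- matrix(derive_seeds(seed, 2 * length(levels) * replicates),
                  nrow = 2)
  runs <- data.frame()
  col <- 0L
  for (lv in levels) {
    for (r in seq_len(replicates)) {
      col <- col + 1L
      pert <- perturb_network(net, lv, seed = seeds[1, col])
      for (mth in methods) {
        emb <- switch(mth,
          "tlse_t1.9" = tlse(pert, dim = dim, t = 1.9,
                             seed = seeds[2, col], control = control),
          "tlse_t1.0" = tlse(pert, dim = dim, t = 1.0,
                             seed = seeds[2, col], control = control),
          "mdsgeo" = mdsgeo(pert, dim = dim, disconnected = "impute"))
        auc <- rank_auc(sqrt(pair_sqdist(emb$coords, pos)),
                        sqrt(pair_sqdist(emb$coords, eval_neg)))
        runs <- rbind(runs, data.frame(level = lv, replicate = r,
                                       method = mth, auc = auc))
      }
    }
  }
  agg <- do.call(rbind, lapply(split(runs, list(runs$level, runs$method),
                                     drop = TRUE), function(g) {
    data.frame(level = g$level[1], method = g$method[1],
               mean_auc = mean(g$auc), sd_auc = stats::sd(g$auc),
               replicates = nrow(g))
  }))
  agg <- agg[order(agg$level, agg$method), ]
  rownames(agg) <- NULL
  attr(agg, "runs") <- runs
  agg
}
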
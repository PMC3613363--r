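#' Control parameters for [tlse()]
#'
#' @param max_iter maximum number of outer iterations (one bias update
#'   plus one coordinate step each).
#' @param tol relative objective-change convergence tolerance.
#' @param neg_ratio negative-sampling ratio: `round(neg_ratio * |E|)`
#'   non-edges enter the sampled objective.
#' @param exact_negatives if `TRUE`, use every non-edge (quadratic; only
#'   sensible up to a couple of thousand nodes).  The default `NULL`
#'   resolves automatically: exact when the network has at most 250000
#'   non-edges, sampled otherwise.
#' @param c1,c2 Wolfe line-search constants, `0 < c1 < c2 < 1`.
#' @param max_backtracks line-search iteration cap.
#' @param precond search-direction preconditioner: `"sparse"` (the
#'   default; the attractive-pair graph Laplacian plus a ridge, solved
#'   with a sparse factorisation — the analogue of solving the
#'   fixed-point linear system), `"diagonal"` (Jacobi from the absolute
#'   mixing coefficients; cheaper per step but takes far more steps), or
#'   `"identity"` (plain gradient descent direction).
#' @param damping ridge `lambda >= 0` added to the preconditioner.
#' @param init `"mdsgeo"` (the default: warm start from the
#'   classical-MDS baseline plus a small Gaussian jitter; the
#'   non-convex loss benefits greatly from a globally arranged start)
#'   or `"random"` (Gaussian, scale `init_scale`).
#' @param init_scale standard deviation of the random initialisation.
#' @param restarts number of random restarts; the fit with the best
#'   final objective is returned.
#' @return a list of class `tlse_control`.
#' @export
tlse_control <- function(max_iter = 500, tol = 1e-6,
                         neg_ratio = 5, exact_negatives = NULL,
                         c1 = 1e-4, c2 = 0.9, max_backtracks = 30,
                         precond = c("sparse", "diagonal", "identity"),
                         damping = 1e-4,
                         init = c("mdsgeo", "random"), init_scale = 0.1,
                         restarts = 1) {
  stopifnot(c1 > 0, c1 < c2, c2 < 1, tol > 0, max_iter >= 1, damping >= 0)
  structure(list(max_iter = max_iter, tol = tol, neg_ratio = neg_ratio,
                 exact_negatives = exact_negatives, c1 = c1, c2 = c2,
                 max_backtracks = max_backtracks,
                 precond = match.arg(precond), damping = damping,
                 init = match.arg(init), init_scale = init_scale,
                 restarts = restarts),
            class = "tlse_control")
}

#' Preconditioned descent direction for the coordinate update
#'
#' Solves `M D = -dZ` for a symmetric positive-definite `M` built from
#' the mixing coefficients, so that `<D, dZ> < 0` whenever `dZ != 0`.
#' With `precond = "diagonal"`, `M = diag(sum_j |W_ij| + lambda)`; with
#' `"sparse"`, `M` is the graph Laplacian of the attractive (positive
#' pair) weights plus `lambda I`, solved with a sparse Cholesky
#' factorisation.  If the computed direction fails the descent check it
#' falls back to `-dZ`.
#'
#' @param grad result of [tlse_gradient()].
#' @param control a [tlse_control()] list.
#' @return list with `D` (n x d matrix) and `dirderiv = <D, dZ>`.
#' @export
search_direction <- function(grad, control = tlse_control()) {
  dZ <- grad$dZ
  lambda <- control$damping
  if (control$precond == "identity") {
    D <- -dZ
  } else if (control$precond == "diagonal") {
    diag_m <- grad$weights$rowsum_abs + lambda
    if (all(diag_m == 0)) {
      warning("singular preconditioner with damping 0; using -gradient")
      D <- -dZ
    } else {
      diag_m[diag_m == 0] <- 1   # isolated rows: dZ is 0 there anyway
      D <- -dZ / diag_m
    }
  } else {  # sparse positive-pair Laplacian system
    n <- nrow(dZ)
    np <- grad$weights$n_pos
    if (lambda <= 0) {
      warning("sparse preconditioner needs damping > 0; raising to 1e-8")
      lambda <- 1e-8
    }
    if (np == 0) {
      D <- -dZ / lambda
    } else {
      P <- grad$weights$pairs[seq_len(np), , drop = FALSE]
      w <- grad$weights$w[seq_len(np)]
      L <- Matrix::sparseMatrix(
        i = c(P[, 1], P[, 2], P[, 1], P[, 2]),
        j = c(P[, 2], P[, 1], P[, 1], P[, 2]),
        x = c(-w, -w, w, w),
        dims = c(n, n))
      M <- L + Matrix::Diagonal(n, lambda)
      D <- as.matrix(Matrix::solve(M, -dZ))
    }
  }
  dd <- sum(D * dZ)
  if (!is.finite(dd) || dd >= 0) {
    if (sum(dZ * dZ) > 0) {
      D <- -dZ
      dd <- -sum(dZ * dZ)
    } else {
      D <- dZ * 0
      dd <- 0
    }
  }
  list(D = D, dirderiv = dd)
}

#' Line search satisfying the weak Wolfe conditions
#'
#' Bisection/expansion search for a step `eta` with sufficient decrease
#' (Armijo, constant `c1`) and curvature `phi'(eta) >= c2 * phi'(0)`.
#' If `dphi` is not supplied only the Armijo condition is enforced
#' (backtracking).  If the cap is reached, the best step achieving plain
#' decrease is returned with `wolfe = FALSE` (weak acceptance); if no
#' decrease was found the step is 0 and `stall = TRUE`.
#'
#' @param phi objective as a function of the step size, `phi(0)` is the
#'   current value.
#' @param dphi0 directional derivative at 0, must be negative.
#' @param dphi optional derivative function `phi'(eta)`.
#' @param control a [tlse_control()] list (uses `c1`, `c2`,
#'   `max_backtracks`).
#' @param eta0 initial trial step.
#' @return list with `step`, `value`, `wolfe` (both conditions met),
#'   `stall` (no decrease found), `evals`.
#' @export
wolfe_line_search <- function(phi, dphi0, dphi = NULL,
                              control = tlse_control(), eta0 = 1) {
  if (!(dphi0 < 0)) stop("wolfe_line_search requires a descent direction")
  c1 <- control$c1; c2 <- control$c2
  phi0 <- phi(0)
  lo <- 0; hi <- Inf
  eta <- eta0
  best_eta <- 0; best_f <- phi0
  for (k in seq_len(max(2L, control$max_backtracks))) {
    f <- phi(eta)
    if (is.finite(f) && f < best_f) { best_f <- f; best_eta <- eta }
    if (!is.finite(f) || f > phi0 + c1 * eta * dphi0) {
      hi <- eta
      eta <- (lo + hi) / 2
    } else if (!is.null(dphi) && dphi(eta) < c2 * dphi0) {
      lo <- eta
      eta <- if (is.finite(hi)) (lo + hi) / 2 else 2 * eta
    } else {
      return(list(step = eta, value = f, wolfe = TRUE, stall = FALSE,
                  evals = k))
    }
  }
  list(step = best_eta, value = best_f, wolfe = FALSE,
       stall = best_eta == 0, evals = control$max_backtracks)
}

#' Fit a t-logistic semantic embedding of a network
#'
#' Learns `d`-dimensional coordinates for every node and a global bias
#' `b` by minimising the t-logistic negative log-likelihood over the
#' network's edges (positives) and a weighted sample of its non-edges
#' (negatives).  The optimiser alternates (a) a 1-D backtracking
#' gradient descent on `b` with the coordinates fixed and (b) one
#' coordinate update along a preconditioned descent direction with a
#' Wolfe line search, so the objective is non-increasing throughout.
#'
#' @param net a [ppi_network()] (embed connected components separately
#'   for the classical protocol; disconnected input is allowed and
#'   handled by the repulsion of cross-component negatives).
#' @param dim embedding dimension `d >= 1`.
#' @param t t-logistic loss parameter in `[1, 2)`; `t = 1` is the
#'   convex logistic loss, the default `1.9` the heavy-tailed robust
#'   loss.
#' @param seed integer seed driving initialisation and negative
#'   sampling through independent substreams.
#' @param control a [tlse_control()] list.
#' @param init_coords optional n x d matrix overriding the random
#'   initialisation (used e.g. for warm starts and invariance checks).
#' @param neg_pairs optional explicit negative pair matrix overriding
#'   the sampler (with `neg_weight` attribute, default 1).
#' @return an object of class `tlse` with components `coords` (n x d,
#'   rownames are node labels), `bias`, `t`, `dim`, `network`, `pairs`,
#'   `objective`, `trace` (per-iteration data.frame), `converged`,
#'   `reason`, `seed`, `control`.
#' @seealso [predict.tlse()], [summary.tlse()], [mdsgeo()]
#' @examples
#' net <- gen_geometric(60, 2, 150, seed = 1)$net
#' fit <- tlse(net, dim = 2, t = 1.9, seed = 1,
#'             control = tlse_control(max_iter = 50))
#' fit
#' @export
tlse <- function(net, dim = 2, t = 1.9, seed = 1,
                 control = tlse_control(),
                 init_coords = NULL, neg_pairs = NULL) {
  stopifnot(inherits(net, "ppi_net"))
  check_t(t)
  if (n_nodes(net) < 2 || n_edges(net) < 1) {
    stop("tlse needs a network with at least 2 nodes and 1 edge")
  }
  if (dim < 1) stop("dim must be >= 1")
  seeds <- derive_seeds(seed, control$restarts + 1L)
  seed_neg <- seeds[1]

  # negatives resampled once per fit: the minimised objective is fixed
  if (!is.null(neg_pairs)) {
    pairs <- structure(list(pos = net$edges,
                            neg = matrix(as.integer(neg_pairs), ncol = 2),
                            neg_weight = attr(neg_pairs, "neg_weight") %||% 1),
                       class = "pair_set")
  } else {
    n_non <- n_nodes(net) * (n_nodes(net) - 1) / 2 - n_edges(net)
    exact <- control$exact_negatives %||% (n_non <= 2.5e5)
    pairs <- make_pair_set(net, neg_ratio = control$neg_ratio,
                           exact = exact, seed = seed_neg)
  }

  best <- NULL
  for (r in seq_len(control$restarts)) {
    Z0 <- init_coords
    if (is.null(Z0)) {
      Z0 <- init_embedding(net, dim, t, control, seed = seeds[r + 1L])
    }
    fit <- tlse_run(net, Z0, t, pairs, control)
    if (is.null(best) || fit$objective < best$objective) best <- fit
    if (!is.null(init_coords)) break
  }
  best$seed <- seed
  best$call <- match.call()
  best
}

init_embedding <- function(net, dim, t, control, seed) {
  n <- n_nodes(net)
  if (control$init == "mdsgeo" && n >= 3) {
    Z <- mdsgeo(net, dim = dim, disconnected = "impute")$coords
    jitter_sd <- 1e-3 * max(1, stats::sd(Z))
    return(Z + with_seed(seed, matrix(stats::rnorm(n * dim, sd = jitter_sd),
                                      n, dim)))
  }
  with_seed(seed, matrix(stats::rnorm(n * dim, sd = control$init_scale),
                         n, dim))
}

# inner optimisation loop on a fixed pair set
tlse_run <- function(net, Z, t, pairs, control) {
  b <- stats::median(pair_sqdist(Z, pairs$pos))  # F near 1/2 on edges
  obj <- tlse_objective(Z, b, t, pairs)
  tr_obj <- numeric(0); tr_dd <- numeric(0); tr_step <- numeric(0)
  reason <- "max_iter"
  converged <- FALSE
  np <- nrow(pairs$pos)
  nn <- nrow(pairs$neg)
  y <- rep(c(1, -1), c(np, nn))
  wt <- rep(c(1, pairs$neg_weight), c(np, nn))

  for (iter in seq_len(control$max_iter)) {
    ## (a) bias update: cheap 1-D problem, distances fixed
    d2 <- c(pair_sqdist(Z, pairs$pos), pair_sqdist(Z, pairs$neg))
    fg_b <- function(bb) {
      lg <- t_loss_grad(y * (bb - d2), t)
      list(f = sum(lg$loss * wt), g = sum(lg$dloss * y * wt))
    }
    b <- descend_1d(fg_b, b, tol = control$tol)

    ## (b) one coordinate step along the preconditioned direction
    st <- eval_state(Z, b, t, pairs)
    obj_after_b <- st$obj
    dir <- search_direction(st, control)
    if (dir$dirderiv >= 0) { reason <- "stationary"; converged <- TRUE
      obj <- obj_after_b; break }
    cache <- new.env(parent = emptyenv())
    eval_at <- function(eta) {
      if (is.null(cache$eta) || cache$eta != eta) {
        cache$st <- eval_state(Z + eta * dir$D, b, t, pairs)
        cache$eta <- eta
      }
      cache$st
    }
    phi <- function(eta) if (eta == 0) obj_after_b else eval_at(eta)$obj
    dphi <- function(eta) sum(eval_at(eta)$dZ * dir$D)
    ls <- wolfe_line_search(phi, dir$dirderiv, dphi, control)
    if (ls$stall) { reason <- "stall"; obj <- obj_after_b; break }
    Z <- Z + ls$step * dir$D
    obj_new <- ls$value

    tr_obj <- c(tr_obj, obj_new)
    tr_dd <- c(tr_dd, dir$dirderiv)
    tr_step <- c(tr_step, ls$step)
    if (abs(obj - obj_new) <= control$tol * max(1, abs(obj))) {
      obj <- obj_new; reason <- "tol"; converged <- TRUE; break
    }
    obj <- obj_new
  }

  rownames(Z) <- net$nodes
  structure(list(coords = Z, bias = b, t = t, dim = ncol(Z),
                 network = net, pairs = pairs, objective = obj,
                 trace = data.frame(iter = seq_along(tr_obj),
                                    objective = tr_obj,
                                    dirderiv = tr_dd, step = tr_step),
                 converged = converged, reason = reason,
                 control = control),
            class = "tlse")
}

# backtracking gradient descent on a smooth 1-D function, run to
# (local) optimality; `fg(x)` returns list(f, g) in one pass.  The
# first trial step is scaled to a modest move in x (the raw gradient of
# a pair sum can be huge) and then adapts across steps.
descend_1d <- function(fg, x, tol = 1e-8, max_steps = 30) {
  cur <- fg(x)
  eta <- 0.1 * max(1, abs(x)) / (abs(cur$g) + 1e-12)
  for (k in seq_len(max_steps)) {
    if (abs(cur$g) < tol * max(1, abs(cur$f))) break
    accepted <- FALSE
    for (h in 1:60) {
      x_new <- x - eta * cur$g
      new <- fg(x_new)
      if (is.finite(new$f) && new$f <= cur$f - 1e-4 * eta * cur$g^2) {
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) break
    x <- x_new
    if (cur$f - new$f <= tol * max(1, abs(cur$f))) break
    cur <- new
    eta <- eta * 2
  }
  x
}
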
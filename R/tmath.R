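#' The t-exponential function
#'
#' Generalised exponential underlying the t-logistic loss.  For `t = 1` it
#' is the ordinary exponential; for `1 < t < 2` it is
#' \eqn{\exp_t(x) = [1 + (1-t)x]_+^{1/(1-t)}}, which decays polynomially
#' (heavy-tailed) as \eqn{x \to -\infty}.  That heavy tail is what bounds
#' the influence of badly-fit pairs in the embedding loss.
#'
#' @param x numeric vector.
#' @param t loss parameter, a single value in `[1, 2)`.
#' @return numeric vector, `exp_t(x)`.
#' @details For `t > 1` the function is only defined where
#'   `1 + (1 - t) * x > 0`, i.e. `x < 1/(t - 1)`; arguments at or beyond
#'   that point raise an error rather than silently returning `Inf`.
#' @seealso [log_t()], [t_link()]
#' @examples
#' exp_t(0, 1.9)          # 1
#' exp_t(-1, 1.5)         # (3/2)^-2
#' @export
exp_t <- function(x, t = 1.9) {
  check_t(t)
  if (t == 1) return(exp(x))
  bracket <- 1 + (1 - t) * x
  if (any(bracket <= 0)) {
    stop("exp_t: argument outside the valid domain (1 + (1-t)x must be > 0)")
  }
  # exp(log(.)/(1-t)) is stable for t close to 1
  exp(log(bracket) / (1 - t))
}

#' The t-logarithm, inverse of [exp_t()]
#'
#' @param x positive numeric vector.
#' @inheritParams exp_t
#' @return numeric vector with `log_t(exp_t(x)) = x` on the valid domain.
#' @export
log_t <- function(x, t = 1.9) {
  check_t(t)
  if (any(x <= 0)) stop("log_t requires x > 0")
  if (t == 1) return(log(x))
  expm1((1 - t) * log(x)) / (1 - t)
}

#' Normaliser of the two-class t-exponential probability model
#'
#' Solves for the unique `g` with
#' `exp_t(u/2 - g) + exp_t(-u/2 - g) = 1`,
#' so that the two class probabilities `F_t(u) = exp_t(u/2 - g)` and
#' `F_t(-u) = exp_t(-u/2 - g)` sum to one.  The left-hand side is strictly
#' decreasing and convex in `g`, so a Newton iteration started at the
#' lower bound `|u|/2` converges monotonically; a bisection safeguard
#' covers any stragglers.
#'
#' @param u numeric vector of margins.
#' @inheritParams exp_t
#' @param tol tolerance on the normalisation residual.
#' @param max_iter iteration cap for the Newton stage.
#' @return numeric vector `g = G_t(u)`; for `t = 1` the closed form
#'   `log(2 cosh(u/2))` is returned.
#' @export
t_normalizer <- function(u, t = 1.9, tol = 1e-12, max_iter = 200) {
  check_t(t)
  if (t == 1) return(abs(u) / 2 + log1p(exp(-abs(u))))
  cpp_t_normalizer(as.numeric(u), t, tol)
}

# loss and its derivative together, sharing one normalizer solve
# (the optimiser's hot path)
t_loss_grad <- function(u, t) {
  if (t == 1) {
    g <- abs(u) / 2 + log1p(exp(-abs(u)))
    return(list(loss = g - u / 2, dloss = -exp(-u / 2 - g)))
  }
  cpp_t_loss_grad(as.numeric(u), t, 1e-12)
}

# exp_t without the domain check, for internal use where the argument is
# guaranteed to be <= 0 (the solver keeps it there).
exp_tu <- function(x, t) {
  if (t == 1) return(exp(x))
  exp(log1p((1 - t) * x) / (1 - t))
}

#' Evaluate the t-logistic link, loss and loss derivative
#'
#' For margins `u`, computes the interaction probability
#' `p_pos = F_t(u) = exp_t(u/2 - G_t(u))`, the complementary probability
#' `p_neg = F_t(-u)`, the t-logistic loss `-log(p_pos)` and its
#' derivative with respect to `u`.  At `t = 1` all quantities reduce to
#' the ordinary logistic expressions; for `t > 1` the derivative is
#' bounded and eventually *decreasing* as `u` falls, which caps the
#' influence any one pair can exert on the fit.
#'
#' @inheritParams t_normalizer
#' @return a `data.frame` with columns `u`, `g`, `p_pos`, `p_neg`,
#'   `loss`, `dloss_du` (one row per margin).
#' @details The derivative uses the implicit-differentiation identity
#'   `dloss/du = -p_pos^(t-1) p_neg^t / (p_pos^t + p_neg^t)`, which is
#'   validated against finite differences in the test-suite.
#' @export
t_link <- function(u, t = 1.9, tol = 1e-12) {
  check_t(t)
  g <- t_normalizer(u, t, tol = tol)
  a <- u / 2 - g
  b <- -u / 2 - g
  p_pos <- exp_tu(a, t)
  p_neg <- exp_tu(b, t)
  if (t == 1) {
    loss <- g - u / 2                 # -log p_pos, exactly
  } else {
    loss <- -log1p((1 - t) * a) / (1 - t)
  }
  dloss <- -p_pos^(t - 1) * p_neg^t / (p_pos^t + p_neg^t)
  data.frame(u = u, g = g, p_pos = p_pos, p_neg = p_neg,
             loss = loss, dloss_du = dloss)
}

# loss only (hot path inside the optimizer)
t_loss <- function(u, t) {
  if (t == 1) return(abs(u) / 2 + log1p(exp(-abs(u))) - u / 2)
  g <- t_normalizer(u, t)
  -log1p((1 - t) * (u / 2 - g)) / (1 - t)
}

# loss derivative only (hot path)
t_dloss <- function(u, t) {
  g <- t_normalizer(u, t)
  p <- exp_tu(u / 2 - g, t)
  q <- exp_tu(-u / 2 - g, t)
  if (t == 1) return(-q)
  -p^(t - 1) * q^t / (p^t + q^t)
}

check_t <- function(t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 1 || t >= 2) {
    stop("t must be a single number in [1, 2)")
  }
  invisible(t)
}
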
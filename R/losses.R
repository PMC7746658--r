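# Loss functions of the WGAN-GP-LSR objective. All are pure functions; the
# probability floor (1e-12) keeps every log finite on degenerate softmax
# outputs.

P_FLOOR <- 1e-12

check_prob <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  pmax(p, P_FLOOR)
}

#' Multiclass cross-entropy loss
#'
#' `-sum(q_i * log p_i) = -log p_y` for a one-hot target `q`.
#'
#' @param p probability vector over the `N` classes (non-negative, sums to 1).
#' @param q one-hot target vector of the same length.
#' @return non-negative scalar loss; zero iff `p[y] = 1`.
#' @export
cross_entropy <- function(p, q) {
  stopifnot(length(p) == length(q), all(q %in% c(0, 1)), sum(q) == 1)
  p <- check_prob(p)
  -sum(q * log(p))
}

#' Label-smoothing-regularized cross-entropy
#'
#' `-(1 - eps) * log p(y) - (eps / N) * sum_i log p(i)`, the sum running over
#' all `N` classes including `y`. Equivalent to cross-entropy against the
#' smoothed target `(1 - eps) * onehot(y) + eps / N`, so `eps = 0` reproduces
#' [cross_entropy()] exactly and the loss is linear in `eps` for fixed `p`.
#'
#' @param p probability vector over the classes.
#' @param y 0-based true-class index.
#' @param params list with `epsilon` (in `[0, 1]`, default 0.22) and
#'   optionally `n_classes` (checked against `length(p)`).
#' @return non-negative scalar loss.
#' @export
lsr_loss <- function(p, y, params = lsr_params()) {
  eps <- params$epsilon
  stopifnot(eps >= 0, eps <= 1, y >= 0, y < length(p))
  if (!is.null(params$n_classes) && params$n_classes != length(p))
    stop("length(p) does not match params$n_classes")
  p <- check_prob(p)
  n <- length(p)
  -(1 - eps) * log(p[y + 1]) - (eps / n) * sum(log(p))
}

#' Label-smoothing parameters
#'
#' @param epsilon smoothing weight in `[0, 1]`; default 0.22 (image quality
#'   was reported best for epsilon in 0.20-0.25).
#' @param n_classes optional class count for validation.
#' @export
lsr_params <- function(epsilon = 0.22, n_classes = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  list(epsilon = epsilon, n_classes = n_classes)
}

#' Wasserstein critic loss
#'
#' `-mean(real_scores) + mean(fake_scores)`; with validity labels +1 for real
#' and -1 for fake this is `mean(-label * score)`. Minimizing it drives the
#' critic to score real images higher than generated ones; the negated value
#' is the Wasserstein distance estimate.
#'
#' @param real_scores,fake_scores numeric vectors of critic validity scores.
#' @export
wasserstein_critic_loss <- function(real_scores, fake_scores) {
  if (length(real_scores) == 0 || length(fake_scores) == 0)
    stop("empty score batch")
  -mean(real_scores) + mean(fake_scores)
}

#' Wasserstein generator loss
#'
#' `-mean(fake_scores)`: the generator is rewarded when the critic scores its
#' images as real.
#'
#' @param fake_scores numeric vector of critic validity scores on generated
#'   images.
#' @export
wasserstein_generator_loss <- function(fake_scores) {
  if (length(fake_scores) == 0) stop("empty score batch")
  -mean(fake_scores)
}

#' Gradient-penalty parameters
#'
#' @param lambda_gp penalty weight (default 10).
#' @export
gp_params <- function(lambda_gp = 10) {
  stopifnot(lambda_gp >= 0)
  list(lambda_gp = lambda_gp)
}

#' Two-sided gradient penalty of a critic
#'
#' `lambda * mean_n (||grad_x critic(xhat_n)||_2 - 1)^2` where
#' `xhat_n = u_n * real_n + (1 - u_n) * fake_n` and `u_n ~ Uniform(0, 1)` per
#' sample (the interpolation coefficient is called `u` throughout; `epsilon`
#' is reserved for label smoothing).
#'
#' @param critic an `lg_discriminator`; the penalty is taken on the validity
#'   head only.
#' @param real_batch,fake_batch `[H, W, C, N]` arrays in the network input
#'   range, same shape.
#' @param params [gp_params()].
#' @param u optional vector of interpolation draws (length N) for
#'   reproducibility; drawn from the current RNG when `NULL`.
#' @return scalar penalty value.
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch,
                             params = gp_params(), u = NULL) {
  gradient_penalty_full(critic, real_batch, fake_batch, params, u,
                        want_grads = FALSE)$penalty
}

# Full gradient-penalty computation: value plus (optionally) its exact
# gradient with respect to every critic weight.
#
# For piecewise-linear critics the input gradient g_n = grad_x D(xhat_n) is,
# at fixed activation pattern, a chain of linear maps in the weights.
# Writing the penalty P = lambda/B * sum_n (||g_n|| - 1)^2,
#   dP/dtheta = sum_n c_n * g_n' (dg_n/dtheta),  c_n = 2 lambda (||g_n||-1) /
#   (B ||g_n||),
# and sum_n v_n' (dg_n/dtheta) with v_n = c_n g_n is computed exactly by one
# tangent (linearized forward) pass of v through the frozen network: the
# weight-gradient of layer k is its usual outer-product rule with the cached
# backward delta and the tangent input in place of the activation.
gradient_penalty_full <- function(critic, real_batch, fake_batch,
                                  params = gp_params(), u = NULL,
                                  want_grads = TRUE) {
  stopifnot(identical(dim(real_batch), dim(fake_batch)))
  d <- dim(real_batch); B <- d[4]
  if (is.null(u)) u <- runif(B)
  uu <- array(rep(u, each = prod(d[1:3])), dim = d)
  xhat <- uu * real_batch + (1 - uu) * fake_batch

  fwd <- discriminator_forward(critic, xhat)
  bwd <- discriminator_backward(critic, fwd, dvalidity = rep(1, B),
                                record_deltas = want_grads)
  g <- bwd$dx
  gm <- g; dim(gm) <- c(prod(d[1:3]), B)
  norms <- sqrt(colSums(gm^2))
  penalty <- params$lambda_gp * mean((norms - 1)^2)
  if (!want_grads)
    return(list(penalty = penalty, grad_norms = norms))

  cn <- 2 * params$lambda_gp * (norms - 1) / (B * pmax(norms, 1e-12))
  v <- sweep(gm, 2, cn, "*"); dim(v) <- d

  tg <- chain_tangent(critic$layers, fwd$caches, v)
  grads <- vector("list", length(critic$layers))
  for (i in seq_along(critic$layers)) {
    ly <- critic$layers[[i]]
    if (is.null(ly$w)) next
    s <- tg$inputs[[i]]; delta <- bwd$deltas[[i]]
    grads[[i]] <- if (ly$type == "conv") {
      cc <- critic$layers[[i]]
      cache <- fwd$caches[[i]]
      r <- conv2d_bw_cpp(s, dim(s), cc$w, dim(cc$w), delta, cc$stride,
                         cache$ph[1], cache$pw[1], cache$os[1], cache$os[2],
                         FALSE, TRUE)
      list(w = r$dw, b = rep(0, cc$out_ch))
    } else {
      list(w = tcrossprod(delta, s), b = rep(0, length(ly$b)))
    }
  }
  # validity head: h = sum_n v_n' g_n depends on W_head through the backward
  # seed; its tangent input is the trunk-tangent output, its delta the seed.
  head_grad <- list(w = tcrossprod(matrix(1, 1, B), tg$out), b = 0)
  list(penalty = penalty, grad_norms = norms, grads = grads,
       head_v = head_grad)
}

# Gradient of the LSR loss wrt logits, batched: probs and smoothed targets
# are [K, B]; labels 0-based. Returns (p - t) / B (mean reduction).
lsr_logit_grad <- function(probs, labels, epsilon) {
  K <- nrow(probs); B <- ncol(probs)
  t_ <- matrix(epsilon / K, K, B)
  t_[cbind(labels + 1L, seq_len(B))] <- t_[cbind(labels + 1L, seq_len(B))] +
    (1 - epsilon)
  (probs - t_) / B
}

# Mean LSR loss of a batch of probability columns.
lsr_batch_loss <- function(probs, labels, epsilon) {
  K <- nrow(probs); B <- ncol(probs)
  p <- pmax(probs, P_FLOOR)
  py <- p[cbind(labels + 1L, seq_len(B))]
  mean(-(1 - epsilon) * log(py) - (epsilon / K) * colSums(log(p)))
}
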
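test_that("cross-entropy matches hand-evaluated cases and edge behavior", {
  # exact match of target: zero loss
  expect_equal(cross_entropy(c(0, 1, 0), c(0, 1, 0)), 0)
  # uniform prediction: log N by symmetry
  for (N in c(2, 5, 38))
    expect_equal(cross_entropy(rep(1 / N, N), c(1, rep(0, N - 1))), log(N))
  # -ln(0.8) evaluated independently
  expect_equal(cross_entropy(c(0.8, rep(0.05, 4)), c(1, 0, 0, 0, 0)),
               0.2231435513, tolerance = 1e-9)
  # zero probability on the target is floored, never infinite
  expect_true(is.finite(cross_entropy(c(0, 1), c(1, 0))))
  expect_error(cross_entropy(c(0.5, 0.4), c(1, 0)), "sum to 1")
})

test_that("LSR loss reproduces its defining identities", {
  set.seed(7)
  # eps = 0 reproduces cross-entropy exactly
  for (i in 1:20) {
    N <- sample(2:40, 1)
    p <- runif(N); p <- p / sum(p)
    y <- sample(N, 1) - 1L
    q <- rep(0, N); q[y + 1] <- 1
    expect_equal(lsr_loss(p, y, lsr_params(0)), cross_entropy(p, q),
                 tolerance = 1e-12)
    # mixture identity: (1-eps) CE + eps * uniform-CE
    eps <- runif(1)
    unif_ce <- -mean(log(pmax(p, 1e-12)))
    expect_equal(lsr_loss(p, y, lsr_params(eps)),
                 (1 - eps) * cross_entropy(p, q) + eps * unif_ce,
                 tolerance = 1e-10)
  }
  # uniform p: log N independent of eps
  for (eps in c(0, 0.22, 0.7, 1))
    expect_equal(lsr_loss(rep(1 / 38, 38), 5L, lsr_params(eps)), log(38))
  # eps = 0.22, N = 38, p(y) = 0.5, remaining mass uniform (hand-evaluated)
  p <- c(0.5, rep(0.5 / 37, 37))
  expect_equal(lsr_loss(p, 0L, lsr_params(0.22)), 1.4666438071,
               tolerance = 1e-9)
  # linear in eps for fixed p
  l0 <- lsr_loss(p, 0L, lsr_params(0))
  l1 <- lsr_loss(p, 0L, lsr_params(1))
  expect_equal(lsr_loss(p, 0L, lsr_params(0.3)), 0.7 * l0 + 0.3 * l1,
               tolerance = 1e-10)
})

test_that("Wasserstein losses are the documented score arithmetic", {
  expect_equal(wasserstein_critic_loss(c(1, 1), c(-1, -1)), -2)
  s <- rnorm(5)
  expect_equal(wasserstein_critic_loss(s, s), 0)
  # translation invariance
  expect_equal(wasserstein_critic_loss(s + 3.7, rev(s) + 3.7),
               wasserstein_critic_loss(s, rev(s)))
  expect_equal(wasserstein_generator_loss(c(0, 0)), 0)
  expect_equal(wasserstein_generator_loss(c(2, 4)), -3)
  # homogeneity
  expect_equal(wasserstein_generator_loss(2 * s),
               2 * wasserstein_generator_loss(s))
  expect_error(wasserstein_critic_loss(numeric(), 1), "empty")
  expect_error(wasserstein_generator_loss(numeric()), "empty")
})

test_that("gradient penalty matches the linear-critic closed form", {
  set.seed(11)
  dims <- c(4, 4, 3)
  mk <- function(n) array(rnorm(prod(dims) * n), c(dims, n))
  # unit-norm linear critic: penalty identically 0
  w <- rnorm(prod(dims)); w <- w / sqrt(sum(w^2))
  critic1 <- leafgan:::new_linear_critic(w, dims)
  expect_equal(gradient_penalty(critic1, mk(3), mk(3), gp_params(10)), 0,
               tolerance = 1e-12)
  # ||w|| = 3, lambda = 10 -> 10 * (3 - 1)^2 = 40
  critic3 <- leafgan:::new_linear_critic(3 * w, dims)
  expect_equal(gradient_penalty(critic3, mk(2), mk(2), gp_params(10)), 40,
               tolerance = 1e-9)
  # lambda = 0 kills the penalty for any critic
  expect_equal(gradient_penalty(critic3, mk(2), mk(2), gp_params(0)), 0)
  # random-norm property: lambda (||w|| - 1)^2
  for (i in 1:10) {
    wr <- rnorm(prod(dims)) * runif(1, 0.1, 4)
    cr <- leafgan:::new_linear_critic(wr, dims)
    expect_equal(gradient_penalty(cr, mk(2), mk(2), gp_params(10)),
                 10 * (sqrt(sum(wr^2)) - 1)^2, tolerance = 1e-6)
  }
})

test_that("gradient-penalty parameter gradients agree with finite differences", {
  set.seed(13)
  spec <- network_spec("discriminator", image_size = 16, n_classes = 2,
                       base_channels = 2)
  D <- build_discriminator(spec, seed = 5)
  real <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  fake <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  u <- c(0.3, 0.8)
  full <- leafgan:::gradient_penalty_full(D, real, fake, gp_params(10), u = u)
  pen <- function(net) gradient_penalty(net, real, fake, gp_params(10), u = u)
  h <- 1e-4
  # first conv kernel
  w1 <- D$layers[[1]]$w
  idx <- sample(length(w1), 12)
  for (i in idx) {
    Dp <- D; Dp$layers[[1]]$w[i] <- w1[i] + h
    Dm <- D; Dm$layers[[1]]$w[i] <- w1[i] - h
    expect_equal(full$grads[[1]]$w[i], (pen(Dp) - pen(Dm)) / (2 * h),
                 tolerance = 1e-4)
  }
  # validity head
  wv <- D$head_v$w
  for (i in sample(length(wv), 8)) {
    Dp <- D; Dp$head_v$w[i] <- wv[i] + h
    Dm <- D; Dm$head_v$w[i] <- wv[i] - h
    expect_equal(full$head_v$w[i], (pen(Dp) - pen(Dm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("all losses stay finite on floored degenerate inputs", {
  p <- c(1, 0, 0)
  expect_true(is.finite(lsr_loss(p, 1L, lsr_params(0.22))))
  expect_true(is.finite(cross_entropy(p, c(0, 0, 1))))
  probs <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)
  expect_true(is.finite(leafgan:::lsr_batch_loss(probs, c(2L, 0L), 0.22)))
})
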
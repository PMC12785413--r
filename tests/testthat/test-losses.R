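# Training losses: closed-form values, gating, focal/BCE reduction, ramps
# and analytic gradients.

test_that("noise loss is gated by the label and follows its closed form", {
  e0 <- replicate(3, matrix(0, 4, 4), simplify = FALSE)
  e1 <- replicate(3, matrix(1, 4, 4), simplify = FALSE)
  expect_equal(noise_loss(e0, e1, y = 1), 0)
  expect_equal(noise_loss(e1, e1, y = 0), 0)
  expect_equal(noise_loss(e0, e1, y = 0), 1)
  expect_error(noise_loss(e0[1:2], e1, 0), class = "scafdl_invalid_argument")
})

test_that("smooth L1 takes its single-pixel closed-form values", {
  one <- matrix(1, 1, 1)
  expect_equal(smooth_l1(one, matrix(1, 1, 1)), 0)
  expect_equal(smooth_l1(one, matrix(0.5, 1, 1)), 0.125)
  expect_equal(smooth_l1(one, matrix(0, 1, 1)), 0.5)   # boundary branch
})

test_that("focal loss matches hand-computed values and reduces to BCE", {
  one <- matrix(1, 1, 1)
  # alpha * (1-p_t)^gamma * (-log p_t) = 0.75 * 0.25 * ln 2
  expect_equal(focal_loss(one, matrix(0.5, 1, 1), alpha = 0.75, gamma = 2),
               0.75 * 0.25 * log(2), tolerance = 1e-9)
  expect_lt(focal_loss(one, matrix(1 - 1e-7, 1, 1)), 1e-5)
  # gamma = 0, alpha = 0.5 halves an independently computed BCE
  withr::with_seed(1, {
    M <- matrix(rbinom(64, 1, 0.4), 8, 8)
    p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  })
  bce <- -mean(M * log(p) + (1 - M) * log(1 - p))
  expect_equal(focal_loss(M, p, alpha = 0.5, gamma = 0), 0.5 * bce,
               tolerance = 1e-10)
})

test_that("increasing alpha reweights positive versus negative errors", {
  M <- matrix(c(1, 0), 1, 2)
  p <- matrix(c(0.3, 0.7), 1, 2)   # both wrong
  pos_err <- function(a) focal_loss(matrix(1, 1, 1), matrix(0.3, 1, 1), alpha = a)
  neg_err <- function(a) focal_loss(matrix(0, 1, 1), matrix(0.7, 1, 1), alpha = a)
  expect_gt(pos_err(0.9), pos_err(0.6))
  expect_lt(neg_err(0.9), neg_err(0.6))
})

test_that("mask loss combines terms and ramps the focusing exponent", {
  withr::with_seed(2, {
    M <- matrix(rbinom(64, 1, 0.2), 8, 8)
    p <- matrix(runif(64, 0.01, 0.99), 8, 8)
  })
  cfg0 <- loss_config(gamma_mask = 0)
  expect_equal(mask_loss(M, p, cfg0), smooth_l1(M, p))
  cfg <- loss_config()
  expect_equal(scafdl:::gamma_focal_at(cfg, 0, 100), 2)
  expect_equal(scafdl:::gamma_focal_at(cfg, 99, 100), 3.5)
  expect_gte(mask_loss(M, p, cfg), smooth_l1(M, p))
  expect_equal(mask_loss(M, p, cfg, epoch = 0, n_epochs = 10),
               smooth_l1(M, p) + focal_loss(M, p, alpha = 0.75, gamma = 2))
})

test_that("total loss sums batch-averaged components", {
  expect_equal(total_loss(0.2, 0.3)$total, 0.5)
  expect_equal(total_loss(numeric(0), numeric(0))$total, 0)
  expect_equal(total_loss(c(0.1, 0.3), c(0.2, 0.4))$total, 0.5)
})

test_that("loss gradients agree with finite differences", {
  withr::with_seed(3, {
    M <- matrix(rbinom(36, 1, 0.3), 6, 6)
    p <- matrix(runif(36, 0.05, 0.95), 6, 6)
  })
  cfg <- loss_config()
  g <- scafdl:::mask_loss_grad(M, p, cfg, 1, 10)
  h <- 1e-6
  for (idx in c(1, 9, 20, 36)) {
    p2 <- p; p2[idx] <- p[idx] + h
    p3 <- p; p3[idx] <- p[idx] - h
    fd <- (mask_loss(M, p2, cfg, 1, 10) - mask_loss(M, p3, cfg, 1, 10)) / (2 * h)
    expect_equal(g[idx], fd, tolerance = 1e-4)
  }
})

test_that("detached reconstruction keeps mask gradients away from the denoiser", {
  # finite-difference check on a tiny model: perturbing denoiser weights
  # changes the reconstruction (hence mask loss), but the training gradient
  # applied to the denoiser comes from the noise loss alone, so with
  # eps_pred == eps_true the denoiser gradient is exactly zero even though
  # the mask loss is positive.
  den <- denoiser_new(16, c(4, 4, 8), depth = 1, heads = 2, seed = 1)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  invisible(nn_forward_denoiser(den, x, 10, train = TRUE))
  eh <- nn_forward_denoiser(den, x, 10, train = TRUE)
  scafdl:::nn_backward_denoiser(den, 0 * eh)   # zero noise-loss residual
  g <- nn_params(den, grads = TRUE)
  expect_true(all(vapply(g, function(W) all(W == 0), logical(1))))
  expect_error(loss_config(detach_reconstruction = FALSE),
               class = "scafdl_invalid_argument")
})
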
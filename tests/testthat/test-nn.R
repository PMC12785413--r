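# Native networks: shapes, determinism, output ranges, gradient
# correctness (directional finite differences) and checkpoint round trips.

test_that("denoiser output matches input shape and is deterministic in eval mode", {
  den <- denoiser_new(16, c(4, 6, 8), depth = 2, heads = 2, seed = 3)
  withr::with_seed(1, x <- array(runif(16 * 16 * 2), c(16, 16, 2)))
  y1 <- nn_forward_denoiser(den, x, c(30, 90))
  y2 <- nn_forward_denoiser(den, x, c(30, 90))
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(16, 16, 2))
  # time conditioning reaches the output
  y3 <- nn_forward_denoiser(den, x, c(150, 150))
  expect_false(identical(y1, y3))
  # same seed reproduces initialization
  den2 <- denoiser_new(16, c(4, 6, 8), depth = 2, heads = 2, seed = 3)
  expect_identical(nn_params(den), nn_params(den2))
})

test_that("localizer emits saliency in (0,1) at the input resolution", {
  loc <- localizer_new(16, c(4, 6, 8), se_ratio = 2, seed = 4)
  withr::with_seed(2, x <- array(runif(16 * 16 * 2 * 3), c(16, 16, 2, 3)))
  y <- nn_forward_localizer(loc, x)
  expect_equal(dim(y), c(16, 16, 3))
  expect_true(all(y > 0 & y < 1))
})

test_that("backward passes agree with directional finite differences", {
  withr::with_seed(5, {
    den <- denoiser_new(16, c(4, 6, 8), depth = 2, heads = 2, seed = 3)
    x <- array(runif(16 * 16 * 2), c(16, 16, 2))
    R0 <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
    lossf <- function() sum(nn_forward_denoiser(den, x, c(30, 90)) * R0)
    invisible(nn_forward_denoiser(den, x, c(30, 90), train = TRUE))
    scafdl:::nn_backward_denoiser(den, R0)
    g <- nn_params(den, grads = TRUE)
    p <- nn_params(den)
    v <- lapply(p, function(W) matrix(rnorm(length(W)), nrow(W), ncol(W)))
    h <- 1e-3
    pp <- Map(function(W, V) W + h * V, p, v)
    pm <- Map(function(W, V) W - h * V, p, v)
    nn_set_params(den, pp); up <- lossf()
    nn_set_params(den, pm); dn <- lossf()
    fd <- (up - dn) / (2 * h)
    an <- sum(mapply(function(G, V) sum(G * V), g, v))
    expect_equal(an, fd, tolerance = 0.05)
  })
})

test_that("localizer backward agrees with directional finite differences", {
  withr::with_seed(6, {
    loc <- localizer_new(16, c(4, 6, 8), se_ratio = 2, seed = 4)
    x <- array(runif(16 * 16 * 2 * 2), c(16, 16, 2, 2))
    R0 <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
    lossf <- function() sum(nn_forward_localizer(loc, x) * R0)
    invisible(nn_forward_localizer(loc, x, train = TRUE))
    scafdl:::nn_backward_localizer(loc, R0)
    g <- nn_params(loc, grads = TRUE)
    p <- nn_params(loc)
    v <- lapply(p, function(W) matrix(rnorm(length(W)), nrow(W), ncol(W)))
    h <- 1e-3
    nn_set_params(loc, Map(function(W, V) W + h * V, p, v)); up <- lossf()
    nn_set_params(loc, Map(function(W, V) W - h * V, p, v)); dn <- lossf()
    fd <- (up - dn) / (2 * h)
    an <- sum(mapply(function(G, V) sum(G * V), g, v))
    expect_equal(an, fd, tolerance = 0.05)
  })
})

test_that("zero-gradient samples contribute nothing to parameter gradients", {
  den <- denoiser_new(16, c(4, 6, 8), depth = 1, heads = 2, seed = 8)
  withr::with_seed(7, {
    x <- array(runif(16 * 16 * 4), c(16, 16, 4))
    dy <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  })
  dy_half <- dy; dy_half[, , c(2, 4)] <- 0
  invisible(nn_forward_denoiser(den, x, 20, train = TRUE))
  scafdl:::nn_backward_denoiser(den, dy_half)
  g_half <- nn_params(den, grads = TRUE)
  cpp_zero <- scafdl:::cpp_den_zero_grad
  cpp_zero(den$ptr)
  invisible(nn_forward_denoiser(den, x[, , c(1, 3)], 20, train = TRUE))
  scafdl:::nn_backward_denoiser(den, dy_half[, , c(1, 3)])
  g_sub <- nn_params(den, grads = TRUE)
  for (nm in names(g_half))
    expect_equal(g_half[[nm]], g_sub[[nm]], tolerance = 1e-6)
})

test_that("an Adam step reduces a simple regression objective", {
  loc <- localizer_new(16, c(4, 4, 4), se_ratio = 2, seed = 9)
  withr::with_seed(8, x <- array(runif(16 * 16 * 2), c(16, 16, 2, 1)))
  target <- matrix(0, 16, 16); target[4:8, 4:8] <- 1
  loss_at <- function() {
    y <- nn_forward_localizer(loc, x)[, , 1]
    mean((y - target)^2)
  }
  l0 <- loss_at()
  for (i in 1:30) {
    y <- nn_forward_localizer(loc, x, train = TRUE)[, , 1]
    dM <- array(2 * (y - target) / length(target), c(16, 16, 1))
    scafdl:::nn_backward_localizer(loc, dM)
    scafdl:::nn_adam(loc, 1e-2)
  }
  expect_lt(loss_at(), 0.5 * l0)
})

test_that("checkpoints round-trip the full bundle", {
  sb <- smoke_bundle()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(sb$bundle, path)
  back <- load_checkpoint(path)
  img <- read_gray(file.path(sb$manifest$root, sb$manifest$test$image[1]))
  p1 <- predict_saliency(sb$bundle, img, seed = 3)
  p2 <- predict_saliency(back, img, seed = 3)
  expect_identical(p1$M_hat, p2$M_hat)
  expect_identical(p1$score, p2$score)
  expect_error(load_checkpoint("/nonexistent/ck.rds"), class = "scafdl_io")
})
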
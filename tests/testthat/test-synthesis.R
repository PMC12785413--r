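# Stage I: foreground segmentation, fracture shapes, masking, texture
# blending and augmentation.

test_that("oracle foreground equals the stored mask; threshold backend is accurate", {
  ph <- desk_phantom(2, 128)
  expect_identical(segment_foreground(ph, "oracle"), ph$foreground)
  iou <- vapply(0:49, function(s) {
    p <- generate_phantom(s, 128)
    f <- segment_foreground(p$image, "threshold")
    sum(f == 1 & p$foreground == 1) / sum(f == 1 | p$foreground == 1)
  }, numeric(1))
  expect_true(all(iou >= 0.90))
})

test_that("degenerate images are rejected by the threshold backend", {
  expect_error(segment_foreground(matrix(0, 32, 32), "threshold"),
               class = "scafdl_degenerate_input")
})

test_that("fracture shapes are deterministic with 1-5 interior points, all counts occurring", {
  ks <- vapply(1:200, function(s) sample_fracture_shape(s, 64)$k, numeric(1))
  expect_true(all(ks %in% 1:5))
  expect_setequal(unique(ks), 1:5)
  a <- sample_fracture_shape(17, 64)
  b <- sample_fracture_shape(17, 64)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$mask, b$mask)
  # single 8-connected component
  lab <- EBImage::bwlabel(EBImage::Image(a$mask))
  expect_equal(max(lab), 1)
})

test_that("anomaly mask is the elementwise product of foreground and shape", {
  withr::with_seed(3, {
    F_ <- matrix(rbinom(256, 1, 0.5), 16, 16)
    P <- matrix(rbinom(256, 1, 0.5), 16, 16)
  })
  M <- make_anomaly_mask(F_, P)
  # brute-force per-pixel AND
  for (i in 1:16) for (j in 1:16)
    expect_equal(M[i, j], as.numeric(F_[i, j] == 1 && P[i, j] == 1))
  expect_equal(make_anomaly_mask(matrix(1, 16, 16), P), P)
  expect_equal(sum(make_anomaly_mask(0 * F_, P)), 0)
  expect_error(make_anomaly_mask(F_, matrix(1, 8, 8)),
               class = "scafdl_invalid_argument")
})

test_that("texture fill follows the opacity blend exactly", {
  bank <- tiny_bank()
  N <- matrix(0.6, 32, 32)
  M <- matrix(0, 32, 32)
  expect_equal(fill_texture(M, bank, N, beta = 0, seed = 1), N)
  A1 <- fill_texture(M, bank, N, beta = 1, seed = 1)
  expect_true(any(A1 != N))  # pure texture
  cb <- bank
  cb$patches <- list(matrix(0.2, 32, 32))
  expect_equal(fill_texture(M, cb, N, beta = 0.5, seed = 1),
               matrix(0.4, 32, 32))
  bad <- structure(list(patches = list()), class = "scafdl_texture_bank")
  expect_error(fill_texture(M, bad, N, 0.5), class = "scafdl_invalid_argument")
})

test_that("pseudofracture blending matches the per-pixel oracle", {
  withr::with_seed(5, {
    N <- matrix(runif(256), 16, 16)
    A <- matrix(runif(256), 16, 16)
    M <- matrix(rbinom(256, 1, 0.3), 16, 16)
  })
  s <- blend_pseudofracture(N, A, M)
  for (i in 1:16) for (j in 1:16) {
    want <- if (M[i, j] == 1) A[i, j] else N[i, j]
    expect_equal(s$S[i, j], min(max(want, 0), 1))
  }
  expect_equal(s$y, 1L)
  s0 <- blend_pseudofracture(N, A, 0 * M)
  expect_identical(s0$S, N)
  expect_equal(s0$y, 0L)
  s1 <- blend_pseudofracture(N, A, matrix(1, 16, 16))
  expect_equal(s1$S, A)
})

test_that("photometric-only augmentation leaves the mask untouched", {
  ph <- desk_phantom(3)
  M <- sample_fracture_shape(1, 32)$mask
  out <- augment_pair(ph$image, M, default_augmentation_pool(photometric_only = TRUE),
                      seed = 4)
  expect_identical(out$M, M)
  expect_true(all(out$S >= 0 & out$S <= 1))
  out2 <- augment_pair(ph$image, M, default_augmentation_pool(photometric_only = TRUE),
                       seed = 4)
  expect_identical(out$S, out2$S)
})

test_that("geometric warps move mask and image pixels together", {
  # mark one bright pixel; rotate by 90 degrees; its mask must track it
  S <- matrix(0, 33, 33)
  M <- matrix(0, 33, 33)
  S[10, 25] <- 1
  M[10, 25] <- 1
  res <- scafdl:::apply_geometric(S, M, scafdl:::rot_lin(90))
  hot <- which(res$S > 0.5, arr.ind = TRUE)
  expect_equal(nrow(hot), 1)
  expect_equal(res$M[hot], 1)
  expect_equal(sum(res$M), 1)
})

test_that("synthesized batches respect ratio, containment and locality", {
  phs <- lapply(1:16, function(s) generate_phantom(s, 32))
  bank <- tiny_bank()
  batch <- synthesize_batch(phs, bank, list(ratio = 0.5), seed = 2)
  y <- vapply(batch, `[[`, integer(1), "y")
  expect_equal(sum(y), 8)
  for (i in seq_along(batch)) {
    s <- batch[[i]]
    src <- phs[[i]]
    if (s$y == 1) {
      expect_gt(sum(s$M), 0)
      expect_equal(sum(s$M == 1 & src$foreground == 0), 0)   # M inside F
    } else {
      expect_identical(s$S, src$image)
    }
    expect_true(all((s$S == src$image)[s$M == 0]))            # locality
  }
})
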
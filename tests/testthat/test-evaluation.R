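# Metric suite: top-K image score, AUROC against the pairwise oracle, PRO
# curve against a per-pixel loop, PRO-score geometry, and the
# oracle-saliency end-to-end pipeline.

test_that("image score matches its closed-form cases", {
  expect_equal(image_score(matrix(0.3, 10, 10), K = 50), 0.3)
  m <- matrix(0, 10, 10); m[1:50] <- 1
  expect_equal(image_score(m, K = 50), 1)
  m25 <- matrix(0, 10, 10); m25[1:25] <- 1
  expect_equal(image_score(m25, K = 50), 0.5)
  expect_error(image_score(matrix(1, 5, 5), K = 26),
               class = "scafdl_invalid_argument")
})

test_that("image score is monotone in every pixel", {
  withr::with_seed(1, m <- matrix(runif(100), 10, 10))
  s0 <- image_score(m, K = 20)
  for (idx in c(1, 37, 100)) {
    m2 <- m
    m2[idx] <- min(1, m[idx] + 0.2)
    expect_gte(image_score(m2, K = 20), s0)
  }
})

test_that("auroc equals the exhaustive pairwise statistic on random instances", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), class = "scafdl_undefined_metric")
  withr::with_seed(7, {
    for (rep in 1:200) {
      n <- sample(4:30, 1)
      sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # ties likely
      lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
      expect_equal(auroc(sc, lb), auroc_pairwise(sc, lb))
    }
  })
})

test_that("pixel AUROC equals auroc on the concatenated pixels", {
  withr::with_seed(2, {
    items <- lapply(1:3, function(i) {
      G <- matrix(rbinom(64, 1, 0.2), 8, 8)
      if (sum(G) == 0) G[1] <- 1
      scored_image(matrix(runif(64), 8, 8), 1, G)
    })
  })
  sc <- unlist(lapply(items, function(it) as.vector(it$M_hat)))
  lb <- unlist(lapply(items, function(it) as.vector(it$G)))
  expect_equal(pixel_auroc(items), auroc(sc, lb))
  # perfect and inverted predictors
  G <- matrix(rbinom(64, 1, 0.3), 8, 8); G[1] <- 1
  expect_equal(pixel_auroc(list(scored_image(G, 1, G))), 1)
  expect_equal(pixel_auroc(list(scored_image(1 - G, 1, G))), 0)
})

test_that("PRO curve equals the per-pixel loop oracle at every threshold", {
  withr::with_seed(3, {
    items <- list(
      scored_image(matrix(runif(256), 16, 16), 1,
                   {g <- matrix(rbinom(256, 1, 0.15), 16, 16); g[5] <- 1; g}),
      scored_image(matrix(runif(256), 16, 16), 1,
                   {g <- matrix(rbinom(256, 1, 0.1), 16, 16); g[7] <- 1; g}),
      scored_image(matrix(runif(256), 16, 16), 0)
    )
  })
  thr <- seq(0, 1, length.out = 50)
  curve <- pro_curve(items, thresholds = thr)
  for (k in seq(1, 50, by = 7)) {
    want <- pro_point_loop(items, curve$threshold[k])
    expect_equal(curve$pro[k], unname(want["pro"]))
    expect_equal(curve$fpr[k], unname(want["fpr"]))
  }
  # extremes under strict binarization
  lo <- pro_curve(items, thresholds = -1)
  expect_equal(lo$pro, 1); expect_equal(lo$fpr, 1)
  hi <- pro_curve(items, thresholds = 1)
  expect_equal(hi$pro, 0); expect_equal(hi$fpr, 0)
  expect_error(pro_curve(items[3], thresholds = thr),
               class = "scafdl_undefined_metric")
})

test_that("FPR is non-increasing in the threshold", {
  withr::with_seed(4, {
    items <- lapply(1:2, function(i) {
      G <- matrix(rbinom(256, 1, 0.2), 16, 16); G[1] <- 1
      scored_image(matrix(runif(256), 16, 16), 1, G)
    })
  })
  curve <- pro_curve(items)
  expect_true(all(diff(curve$fpr) <= 0))
})

test_that("PRO-score integrates the capped curve correctly", {
  ideal <- tibble::tibble(threshold = c(0, 0.5, 1), pro = c(1, 1, 1),
                          fpr = c(1, 0.5, 0))
  expect_equal(pro_score(ideal), 1)
  flat0 <- tibble::tibble(threshold = c(0, 1), pro = c(0, 0), fpr = c(1, 0))
  expect_equal(pro_score(flat0), 0)
  # triangle: PRO = FPR / 0.3 up to the cap -> normalized area 0.5
  tri <- tibble::tibble(threshold = c(0, 1), pro = c(1, 0), fpr = c(0.3, 0))
  expect_equal(pro_score(tri), 0.5)
})

test_that("adding all-zero-saliency normal images leaves PRO unchanged", {
  withr::with_seed(5, {
    anom <- lapply(1:2, function(i) {
      G <- matrix(rbinom(64, 1, 0.25), 8, 8); G[2] <- 1
      scored_image(matrix(runif(64), 8, 8), 1, G)
    })
  })
  normals <- replicate(3, scored_image(matrix(0, 8, 8), 0), simplify = FALSE)
  thr <- seq(0, 1, length.out = 20)
  c1 <- pro_curve(anom, thresholds = thr)
  c2 <- pro_curve(c(anom, normals), thresholds = thr)
  expect_equal(c1$pro, c2$pro)          # PRO never sees normal images
  expect_true(all(c2$fpr <= c1$fpr))    # pooled negatives only grow
})

test_that("oracle-saliency evaluation yields perfect metrics end to end", {
  dir <- withr::local_tempdir()
  m <- build_dataset(dir, 0, 4, 4, seed = 3, size = 32)
  rep <- evaluate_scafdl(m, "oracle")
  expect_equal(rep$image_auroc, 1)
  expect_equal(rep$pixel_auroc, 1)
  expect_equal(rep$pro_score, 1)
  expect_true(all(rep$scores$score >= 0 & rep$scores$score <= 1))
  out <- file.path(dir, "report")
  evaluate_scafdl(m, "oracle", out_dir = out)
  expect_true(all(file.exists(file.path(out, c(
    "report.json", "scores.csv", "pro_curve.csv", "roc_curve.csv")))))
})

test_that("random saliency yields chance-level image AUROC", {
  # null simulation: scores carry no information about the labels
  withr::with_seed(6, {
    aurocs <- replicate(60, {
      sc <- runif(80)
      lb <- rep(0:1, each = 40)
      auroc(sc, lb)
    })
  })
  expect_true(mean(aurocs > 0.3 & aurocs < 0.7) >= 0.95)
})
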
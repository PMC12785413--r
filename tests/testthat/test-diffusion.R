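# Stage II algebra: schedules, forward/inverse diffusion, time-step triples
# and the guided one-step reconstruction with its analytic oracle.

test_that("linear schedules have the expected alpha-bar structure", {
  s <- build_schedule(1000)
  expect_equal(alpha_bar(s, 0), 1)
  expect_lt(alpha_bar(s, 1000), 1e-4)
  expect_true(all(diff(s$alpha_bar) < 0))
  s10 <- build_schedule(10)
  expect_equal(alpha_bar(s10, 1), 1 - s10$beta[1])
  expect_error(build_schedule(2), class = "scafdl_invalid_argument")
  expect_error(build_schedule(100, beta_bounds = c(0.2, 0.1)),
               class = "scafdl_invalid_argument")
  expect_error(build_schedule(100, segments = list(s = c(0, 50), m = c(60, 70),
                                                   l = c(70, 90))),
               class = "scafdl_invalid_argument")
})

test_that("forward diffusion matches its closed form and t = 0 is the identity", {
  sched <- tiny_schedule()
  withr::with_seed(1, {
    x0 <- matrix(runif(64), 8, 8)
    eps <- matrix(rnorm(64), 8, 8)
  })
  expect_identical(forward_diffuse(x0, 0, eps, sched), x0)
  xt <- forward_diffuse(matrix(0, 8, 8), 50, eps, sched)
  expect_equal(xt, sqrt(1 - alpha_bar(sched, 50)) * eps)
  expect_error(forward_diffuse(x0, 500, eps, sched),
               class = "scafdl_invalid_argument")
})

test_that("forward-diffused samples have the analytic mean and variance", {
  sched <- tiny_schedule()
  t <- 80
  x0 <- matrix(0.4, 8, 8)
  draws <- withr::with_seed(2, replicate(10000, {
    forward_diffuse(x0, t, matrix(rnorm(64), 8, 8), sched)[3, 5]
  }))
  ab <- alpha_bar(sched, t)
  expect_equal(mean(draws), sqrt(ab) * 0.4, tolerance = 0.02)
  expect_equal(var(draws), 1 - ab, tolerance = 0.05)
})

test_that("predict_x0 inverts forward_diffuse at every t (round trip)", {
  sched <- tiny_schedule(200)
  withr::with_seed(3, {
    x0 <- matrix(runif(64), 8, 8)
    eps <- matrix(rnorm(64), 8, 8)
  })
  for (t in 1:200) {
    xt <- forward_diffuse(x0, t, eps, sched)
    expect_lt(max(abs(predict_x0(xt, t, eps, sched) - x0)), 1e-6)
  }
  expect_error(predict_x0(x0, 0, eps, sched), class = "scafdl_invalid_argument")
  # eps_hat = 0 reduces to pure rescaling
  xt <- forward_diffuse(x0, 60, eps, sched)
  expect_equal(predict_x0(xt, 60, 0 * eps, sched),
               xt / sqrt(alpha_bar(sched, 60)))
})

test_that("time-step triples respect their segments in both modes", {
  sched <- tiny_schedule()
  expect_equal(sample_timestep_triple(sched, guidance_config(mode = "fixed")),
               c(60L, 100L, 140L))
  sched1000 <- build_schedule(1000)
  expect_equal(sample_timestep_triple(sched1000, guidance_config(mode = "fixed")),
               c(300L, 500L, 700L))
  cfg <- guidance_config(mode = "random")
  seg <- sched$segments
  for (s in 1:100) {
    tr <- sample_timestep_triple(sched, cfg, seed = s)
    expect_true(tr[1] > seg$s[1] && tr[1] <= seg$s[2])
    expect_true(tr[2] > seg$m[1] && tr[2] <= seg$m[2])
    expect_true(tr[3] > seg$l[1] && tr[3] <= seg$l[2])
    expect_true(tr[1] < tr[2] && tr[2] < tr[3])
  }
  expect_identical(sample_timestep_triple(sched, cfg, 7),
                   sample_timestep_triple(sched, cfg, 7))
})

test_that("guided reconstruction reduces to plain one-step at zero weights", {
  sched <- tiny_schedule()
  ph <- desk_phantom(5)
  x_star <- generate_phantom(6, 32)$image
  den <- oracle_denoiser(x_star, sched)
  cfg0 <- guidance_config(0, 0)
  res <- ing_reconstruct(ph$image, den, sched, cfg = cfg0, seed = 9)
  ins <- res$intermediates
  plain <- predict_x0(ins$x_ts, ins$triple[1], den(ins$x_ts, ins$triple[1]), sched)
  expect_lt(max(abs(ins$x0_guide_raw - plain)), 1e-9)
  expect_equal(max(abs(ins$delta)), 0)
})

test_that("ING with the oracle denoiser matches the derived closed form", {
  # Substituting the oracle noise predictor through the guidance chain with a
  # shared noise draw collapses to:
  #   x0_guide = x_star + (1 - alpha_bar_ts) * (w1 + w2) * (x_star - x_in)
  sched <- tiny_schedule()
  x_in <- desk_phantom(7)$image
  x_star <- generate_phantom(8, 32)$image
  den <- oracle_denoiser(x_star, sched)
  for (t_s in c(10, 40, 60)) {
    for (w in list(c(0.5, 0.5), c(0.3, 0.9), c(0, 1.2))) {
      cfg <- guidance_config(w[1], w[2])
      triple <- c(t_s, 100, 140)
      res <- ing_reconstruct(x_in, den, sched, triple, cfg, seed = 21)
      ab <- alpha_bar(sched, t_s)
      want <- x_star + (1 - ab) * (w[1] + w[2]) * (x_star - x_in)
      expect_lt(max(abs(res$intermediates$x0_guide_raw - want)), 1e-6)
    }
  }
})

test_that("the oracle target is a fixed point of guided reconstruction", {
  sched <- tiny_schedule()
  x_star <- desk_phantom(9)$image
  den <- oracle_denoiser(x_star, sched)
  res <- ing_reconstruct(x_star, den, sched, cfg = guidance_config(0.8, 1.3),
                         seed = 2)
  expect_lt(max(abs(res$x0_guide - x_star)), 1e-6)
})

test_that("reconstruction is continuous in the guidance weights", {
  sched <- tiny_schedule()
  x_in <- desk_phantom(10)$image
  den <- oracle_denoiser(generate_phantom(11, 32)$image, sched)
  base <- ing_reconstruct(x_in, den, sched, cfg = guidance_config(0, 0),
                          seed = 5)$intermediates$x0_guide_raw
  eps_w <- 1e-4
  near <- ing_reconstruct(x_in, den, sched,
                          cfg = guidance_config(eps_w, eps_w),
                          seed = 5)$intermediates$x0_guide_raw
  expect_lt(max(abs(near - base)), 1e-2)
})

test_that("batched reconstruction is consistent and permutation-equivariant", {
  sched <- tiny_schedule()
  cfg <- guidance_config()
  imgs <- lapply(1:3, function(s) generate_phantom(s, 32)$image)
  den <- oracle_denoiser(imgs[[1]], sched)
  single <- ing_reconstruct(imgs[[2]],
                            den, sched,
                            triple = sample_timestep_triple(sched, cfg),
                            cfg = cfg,
                            seed = scafdl:::derive_seed(4, scafdl:::content_hash(imgs[[2]])))
  batch <- reconstruct_batch(imgs, den, sched, cfg, seed = 4)
  expect_identical(batch[[2]], single$x0_guide)
  perm <- reconstruct_batch(imgs[c(3, 1, 2)], den, sched, cfg, seed = 4)
  expect_identical(perm[[1]], batch[[3]])
  expect_identical(perm[[3]], batch[[2]])
  dup <- reconstruct_batch(list(imgs[[1]], imgs[[1]]), den, sched, cfg, seed = 4)
  expect_identical(dup[[1]], dup[[2]])
})
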
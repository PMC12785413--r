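# Joint training of the diffusion denoiser (noise MSE on normal samples
# only) and the SE-U-Net localizer (smooth-L1 + focal on pseudofracture
# masks), plus inference and the guidance-mode ablation harness.

#' Training/inference profiles
#'
#' `desk`: 32x32 images, T = 200 with segments (0,60]/(60,100]/(100,140],
#' narrow networks and a learning rate suited to short runs — the profile
#' every test and example uses. `paper`: 128x128, T = 1000, segments up to
#' 700 with fixed evaluation triple (300, 500, 700), transformer depth 12,
#' lr 1e-5, 1500 epochs, batch 16 — the full-scale configuration, stored for
#' completeness.
#'
#' @param name `"desk"` or `"paper"`.
#' @return Named list of profile settings.
#' @export
scafdl_profile <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "desk") {
    list(name = "desk", size = 32L, T = 200L,
         beta_bounds = c(1e-4, 0.02),
         segments = list(s = c(0, 60), m = c(60, 100), l = c(100, 140)),
         den_widths = c(8, 16, 32), den_depth = 2L, heads = 4L,
         loc_widths = c(8, 16, 24), se_ratio = 4L,
         batch = 16L, lr = 1e-3, steps = 1500L)
  } else {
    list(name = "paper", size = 128L, T = 1000L,
         beta_bounds = c(1e-4, 0.02),
         segments = list(s = c(0, 300), m = c(300, 500), l = c(500, 700)),
         den_widths = c(64, 128, 128), den_depth = 12L, heads = 8L,
         loc_widths = c(32, 64, 128), se_ratio = 16L,
         batch = 16L, lr = 1e-5, epochs = 1500L, steps = NULL)
  }
}

#' Train the two-stage model on a phantom dataset
#'
#' Each step: draw a batch of healthy training images, synthesize an
#' interleaved 50/50 normal/pseudofracture batch, apply three stochastic
#' augmentations per sample, sample a fresh short/medium/long time-step
#' triple, diffuse every sample to the three steps with one shared noise
#' draw, predict the noise (training the denoiser on normal samples only),
#' form the guided one-step reconstruction from those predictions, run the
#' localizer on (image, reconstruction) and apply the total loss. The
#' reconstruction is treated as a constant for the mask loss (detached), so
#' the denoiser is trained purely by noise prediction.
#'
#' @param manifest A `scafdl_manifest` whose train split is non-empty and
#'   all-normal.
#' @param profile Profile name or list, see [scafdl_profile()].
#' @param seed Integer seed; the run is reproducible given it.
#' @param steps Number of optimization steps (default from the profile).
#' @param config Optional overrides: `synthesis` (see [synthesize_batch()]),
#'   `guidance` (`w1`, `w2`, `reuse_noise`), `loss` (see [loss_config()]),
#'   `lr`, `batch`, `bank_n`, `log_every`, `log_path`, `quiet`.
#' @param resume_from Optional checkpoint path to continue from.
#' @return A `scafdl_model` bundle: both networks, schedule, guidance and
#'   loss configuration, and a training history tibble.
#' @export
train_scafdl <- function(manifest, profile = "desk", seed = 0, steps = NULL,
                         config = list(), resume_from = NULL) {
  if (is.character(profile)) profile <- scafdl_profile(profile)
  if (nrow(manifest$train) == 0) stop_validation("train split is empty")
  if (any(manifest$train$label != 0))
    stop_validation("train split must contain only normal images")
  if (manifest$size != profile$size)
    stop_invalid(sprintf("manifest images are %dpx but profile expects %dpx",
                         manifest$size, profile$size))
  cfg <- utils::modifyList(list(
    synthesis = list(), guidance = list(w1 = 0.5, w2 = 0.5, reuse_noise = TRUE),
    loss = list(), lr = profile$lr, batch = profile$batch,
    bank_n = 8L, log_every = 25L, log_path = NULL, quiet = TRUE
  ), config)
  steps <- as.integer(steps %||% profile$steps %||% 1500L)

  sched <- build_schedule(profile$T, beta_bounds = profile$beta_bounds,
                          segments = profile$segments)
  g_rand <- guidance_config(cfg$guidance$w1, cfg$guidance$w2, mode = "random",
                            reuse_noise = cfg$guidance$reuse_noise)
  g_eval <- guidance_config(cfg$guidance$w1, cfg$guidance$w2, mode = "fixed",
                            reuse_noise = cfg$guidance$reuse_noise)
  l_cfg <- do.call(loss_config, cfg$loss)

  imgs <- load_split_images(manifest, "train")
  fgs <- lapply(imgs, segment_foreground, method = "threshold")
  normals <- Map(function(N, F_) list(N = N, F = F_), imgs, fgs)
  bank <- generate_texture_bank(derive_seed(seed, 1001), cfg$bank_n, profile$size)

  if (!is.null(resume_from)) {
    prev <- load_checkpoint(resume_from)
    den <- prev$denoiser; loc <- prev$localizer
  } else {
    den <- denoiser_new(profile$size, profile$den_widths, profile$den_depth,
                        profile$heads, derive_seed(seed, 11))
    loc <- localizer_new(profile$size, profile$loc_widths, profile$se_ratio,
                         derive_seed(seed, 12))
  }

  B <- cfg$batch
  HW <- profile$size^2
  n_train <- length(normals)
  steps_per_epoch <- max(1L, ceiling(n_train / B))
  n_epochs <- max(1L, ceiling(steps / steps_per_epoch))
  pool <- default_augmentation_pool()
  if (!is.null(cfg$log_path)) file.create(cfg$log_path)
  history <- vector("list", 0)

  for (step in seq_len(steps)) {
    s_step <- derive_seed(seed, 2, step)
    idx <- withr::with_seed(s_step, sample(n_train, B, replace = n_train < B))
    batch <- synthesize_batch(normals[idx], bank, cfg$synthesis,
                              seed = derive_seed(s_step, 3))
    for (i in seq_len(B)) {
      aug <- augment_pair(batch[[i]]$S, batch[[i]]$M, pool,
                          seed = derive_seed(s_step, 4, i))
      batch[[i]]$S <- aug$S; batch[[i]]$M <- aug$M
      batch[[i]]$y <- as.integer(sum(aug$M) > 0)
    }
    y <- vapply(batch, `[[`, integer(1), "y")
    X <- array(unlist(lapply(batch, `[[`, "S")), c(profile$size, profile$size, B))
    triple <- sample_timestep_triple(sched, g_rand, derive_seed(s_step, 5))
    eps <- withr::with_seed(derive_seed(s_step, 6),
                            array(rnorm(HW * B), dim(X)))

    # denoiser: forward + immediate backward at each of the three steps
    eps_hat <- vector("list", 3)
    gate <- rep(1 - y, each = HW)
    noise_terms <- numeric(B)
    for (j in 1:3) {
      t_j <- triple[j]
      Xt <- sqrt(alpha_bar(sched, t_j)) * X + sqrt(1 - alpha_bar(sched, t_j)) * eps
      eh <- nn_forward_denoiser(den, Xt, t_j, train = TRUE)
      dY <- array(gate, dim(X)) * (eh - eps) * (2 / (3 * HW * B))
      nn_backward_denoiser(den, dY)
      eps_hat[[j]] <- eh
      noise_terms <- noise_terms + (1 - y) *
        apply((eh - eps)^2, 3, mean) / 3
    }

    # guided reconstruction from the detached noise predictions (Eqs 4-7)
    ab <- alpha_bar(sched, triple)
    Xts <- sqrt(ab[1]) * X + sqrt(1 - ab[1]) * eps
    xhat0_m <- (sqrt(ab[2]) * X + sqrt(1 - ab[2]) * eps -
                  sqrt(1 - ab[2]) * eps_hat[[2]]) / sqrt(ab[2])
    xhat0_l <- (sqrt(ab[3]) * X + sqrt(1 - ab[3]) * eps -
                  sqrt(1 - ab[3]) * eps_hat[[3]]) / sqrt(ab[3])
    delta <- g_rand$w1 * (sqrt(ab[1]) * xhat0_m + sqrt(1 - ab[1]) * eps - Xts) +
      g_rand$w2 * (sqrt(ab[1]) * xhat0_l + sqrt(1 - ab[1]) * eps - Xts)
    eps_g <- eps_hat[[1]] - sqrt(1 - ab[1]) * delta
    x0_guide <- clip01((Xts - sqrt(1 - ab[1]) * eps_g) / sqrt(ab[1]))

    # localizer on (image, reconstruction)
    Xloc <- array(0, c(profile$size, profile$size, 2, B))
    Xloc[, , 1, ] <- X
    Xloc[, , 2, ] <- x0_guide
    M_hat <- nn_forward_localizer(loc, Xloc, train = TRUE)
    epoch <- (step - 1) %/% steps_per_epoch
    dM <- array(0, dim(M_hat))
    mask_terms <- numeric(B)
    for (i in seq_len(B)) {
      Mi <- batch[[i]]$M
      mask_terms[i] <- mask_loss(Mi, M_hat[, , i], l_cfg, epoch, n_epochs)
      dM[, , i] <- mask_loss_grad(Mi, M_hat[, , i], l_cfg, epoch, n_epochs) / B
    }
    nn_backward_localizer(loc, dM)

    nn_adam(den, cfg$lr)
    nn_adam(loc, cfg$lr)

    losses <- total_loss(noise_terms, mask_terms)
    if (step %% cfg$log_every == 0 || step == 1 || step == steps) {
      rec <- list(step = step, epoch = epoch, loss_noise = losses$noise,
                  loss_mask = losses$mask, loss_total = losses$total,
                  gamma_focal = gamma_focal_at(l_cfg, epoch, n_epochs))
      history[[length(history) + 1]] <- rec
      if (!is.null(cfg$log_path))
        cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 8), "\n",
            file = cfg$log_path, append = TRUE, sep = "")
      if (!isTRUE(cfg$quiet))
        message(sprintf("step %d/%d  L_noise %.4f  L_mask %.4f",
                        step, steps, losses$noise, losses$mask))
    }
  }

  structure(list(
    denoiser = den, localizer = loc, sched = sched, guidance = g_eval,
    loss_cfg = l_cfg, profile = profile,
    history = tibble::as_tibble(do.call(rbind.data.frame, history))
  ), class = "scafdl_model")
}

#' @export
print.scafdl_model <- function(x, ...) {
  cat(sprintf("scafdl model bundle (profile %s, T = %d)\n",
              x$profile$name, x$sched$T))
  print(x$denoiser); print(x$localizer)
  if (nrow(x$history)) {
    cat(sprintf("  trained %d steps, final L_total %.4f\n",
                max(x$history$step), tail(x$history$loss_total, 1)))
  }
  invisible(x)
}

#' Saliency prediction for one image
#'
#' Runs the guided reconstruction and the localizer on a single image and
#' returns the saliency map, reconstruction, and top-K image score.
#'
#' @param bundle A `scafdl_model`.
#' @param img Grayscale image matrix in `[0, 1]`.
#' @param seed Integer seed for the reconstruction noise.
#' @param mode Guidance mode: `"ing"` (both guidance terms), `"ng"`
#'   (single-step guidance, `w2 = 0`) or `"ddpm"` (plain unguided one-step
#'   reconstruction, `w1 = w2 = 0`).
#' @param K Top-K pixels for the image score.
#' @return List with `M_hat`, `x0_guide`, `score`.
#' @export
predict_saliency <- function(bundle, img, seed = 0, mode = c("ing", "ng", "ddpm"),
                             K = 50) {
  mode <- match.arg(mode)
  g <- bundle$guidance
  cfg <- switch(mode,
    ing = g,
    ng = guidance_config(g$w1, 0, mode = "fixed", triple = g$triple,
                         reuse_noise = g$reuse_noise),
    ddpm = guidance_config(0, 0, mode = "fixed", triple = g$triple,
                           reuse_noise = g$reuse_noise))
  rec <- ing_reconstruct(img, denoiser_fun(bundle$denoiser), bundle$sched,
                         cfg = cfg, seed = seed)
  x0 <- rec$x0_guide
  Xloc <- array(0, c(nrow(img), ncol(img), 2, 1))
  Xloc[, , 1, 1] <- img
  Xloc[, , 2, 1] <- x0
  M_hat <- nn_forward_localizer(bundle$localizer, Xloc, train = FALSE)[, , 1]
  list(M_hat = M_hat, x0_guide = x0,
       score = image_score(M_hat, K = min(K, length(M_hat))))
}

#' Guidance-mode ablation harness
#'
#' Evaluates one trained bundle under the three guidance modes — plain
#' one-step reconstruction (`ddpm`), single-time-step guidance (`ng`) and
#' full multi-time-step guidance (`ing`) — on the same test split and
#' returns a comparison table.
#'
#' @param bundle A `scafdl_model`.
#' @param manifest Dataset manifest.
#' @param modes Character vector of modes to run.
#' @param seed Integer seed.
#' @return Tibble with one row per mode: image AUROC, pixel AUROC,
#'   PRO-score.
#' @export
run_ablation <- function(bundle, manifest, modes = c("ddpm", "ng", "ing"),
                         seed = 0) {
  rows <- lapply(modes, function(mode) {
    rep <- evaluate_bundle_mode(bundle, manifest, mode, seed)
    tibble::tibble(mode = mode, image_auroc = rep$image_auroc,
                   pixel_auroc = rep$pixel_auroc, pro_score = rep$pro_score)
  })
  do.call(rbind, rows)
}

evaluate_bundle_mode <- function(bundle, manifest, mode, seed = 0) {
  test <- manifest$test
  items <- vector("list", nrow(test))
  for (i in seq_len(nrow(test))) {
    img <- read_gray(file.path(manifest$root, test$image[i]))
    G <- if (!is.na(test$mask[i]))
      as_mask(read_gray(file.path(manifest$root, test$mask[i])) > 0.5) else NULL
    p <- predict_saliency(bundle, img, seed = derive_seed(seed, i), mode = mode)
    items[[i]] <- scored_image(p$M_hat, test$label[i], G = G)
  }
  scores <- vapply(items, `[[`, numeric(1), "score")
  labels <- vapply(items, `[[`, integer(1), "label")
  list(image_auroc = auroc(scores, labels),
       pixel_auroc = pixel_auroc(items),
       pro_score = pro_score(pro_curve(items)))
}
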
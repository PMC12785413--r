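# Training losses: gated noise MSE, smooth-L1 + focal mask loss, total loss,
# plus the analytic gradients the training loop feeds into the networks.

#' Gated noise-prediction loss
#'
#' Mean squared error between true and predicted noise, averaged over the
#' three sampled time steps and gated by the sample label: pseudofracture
#' samples (`y = 1`) contribute nothing, so the denoiser is trained on normal
#' images only.
#'
#' \deqn{L_{noise} = \frac{1}{3}(1-y) \sum_{t \in \{t_s,t_m,t_l\}}
#'   \overline{\|\epsilon_t - \hat\epsilon_t\|^2}}
#'
#' @param eps_true List of 3 noise fields (matrices).
#' @param eps_pred List of 3 predicted noise fields.
#' @param y Sample label: 1 = pseudofracture, 0 = normal.
#' @return Scalar loss.
#' @export
noise_loss <- function(eps_true, eps_pred, y) {
  if (length(eps_true) != 3 || length(eps_pred) != 3)
    stop_invalid("eps_true and eps_pred must each hold 3 noise fields")
  if (!y %in% c(0, 1)) stop_invalid("y must be 0 or 1")
  for (i in 1:3) check_same_dim(eps_true[[i]], eps_pred[[i]], "noise fields")
  if (y == 1) return(0)
  mean(vapply(1:3, function(i) mean((eps_true[[i]] - eps_pred[[i]])^2), numeric(1)))
}

#' Smooth L1 loss
#'
#' Per-pixel Huber-style penalty between a binary target mask and a saliency
#' map, averaged over pixels: \eqn{0.5 (y-p)^2} when \eqn{|y-p| < 1},
#' \eqn{|y-p| - 0.5} otherwise.
#'
#' @param M Binary target mask.
#' @param M_hat Saliency map in `[0, 1]`.
#' @return Scalar loss.
#' @export
smooth_l1 <- function(M, M_hat) {
  check_same_dim(M, M_hat, "M and M_hat")
  d <- abs(M - M_hat)
  mean(ifelse(d < 1, 0.5 * d^2, d - 0.5))
}

#' Focal loss
#'
#' Class-balanced, hardness-weighted binary cross-entropy averaged over
#' pixels: \eqn{\alpha_t (1 - p_t)^\gamma \mathrm{BCE}(y, p)} with
#' \eqn{\alpha_t = \alpha} for positives and \eqn{1-\alpha} for negatives, and
#' \eqn{p_t = y p + (1-y)(1-p)}. Predictions are clamped away from 0 and 1 by
#' `eps_clip` for numerical safety.
#'
#' @param M Binary target mask.
#' @param M_hat Saliency map in `[0, 1]`.
#' @param alpha Positive-class weight in `(0, 1)` (default 0.75).
#' @param gamma Focusing exponent (default 2).
#' @param eps_clip Clamp distance from the `{0, 1}` boundary.
#' @return Scalar loss.
#' @export
focal_loss <- function(M, M_hat, alpha = 0.75, gamma = 2, eps_clip = 1e-6) {
  check_same_dim(M, M_hat, "M and M_hat")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  if (gamma < 0) stop_invalid("gamma must be non-negative")
  p <- pmin(pmax(M_hat, eps_clip), 1 - eps_clip)
  p_t <- M * p + (1 - M) * (1 - p)
  a_t <- M * alpha + (1 - M) * (1 - alpha)
  mean(a_t * (1 - p_t)^gamma * (-log(p_t)))
}

# d(focal)/d(p), same shape as M_hat; used by the training loop.
focal_loss_grad <- function(M, M_hat, alpha = 0.75, gamma = 2, eps_clip = 1e-6) {
  p <- pmin(pmax(M_hat, eps_clip), 1 - eps_clip)
  p_t <- M * p + (1 - M) * (1 - p)
  a_t <- M * alpha + (1 - M) * (1 - alpha)
  # d/dp_t [ (1-p_t)^g * (-log p_t) ] = g(1-p_t)^(g-1) log p_t - (1-p_t)^g / p_t
  dpt <- a_t * (gamma * (1 - p_t)^pmax(gamma - 1, 0) * log(p_t) - (1 - p_t)^gamma / p_t)
  g <- dpt * (2 * M - 1) / length(M)    # dp_t/dp = 2y - 1
  g[M_hat < eps_clip | M_hat > 1 - eps_clip] <- 0
  g
}

smooth_l1_grad <- function(M, M_hat) {
  d <- M_hat - M
  ifelse(abs(d) < 1, d, sign(d)) / length(M)
}

#' Loss configuration
#'
#' @param alpha Focal positive-class weight (default 0.75).
#' @param gamma_focal_start,gamma_focal_end Linear ramp of the focal
#'   focusing exponent across training (defaults 2 and 3.5).
#' @param gamma_mask Weight of the focal term relative to smooth L1 in the
#'   mask loss (default 1).
#' @param detach_reconstruction Keep the reconstruction detached so the mask
#'   loss never reaches the denoiser (default `TRUE`; the only implemented
#'   mode).
#' @return List of class `scafdl_loss_config`.
#' @export
loss_config <- function(alpha = 0.75, gamma_focal_start = 2,
                        gamma_focal_end = 3.5, gamma_mask = 1,
                        detach_reconstruction = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  if (gamma_focal_start < 0 || gamma_focal_end < 0)
    stop_invalid("focal gamma must be non-negative")
  if (!isTRUE(detach_reconstruction))
    stop_invalid("only detach_reconstruction = TRUE is implemented")
  structure(list(alpha = alpha, gamma_focal_start = gamma_focal_start,
                 gamma_focal_end = gamma_focal_end, gamma_mask = gamma_mask,
                 detach_reconstruction = TRUE),
            class = "scafdl_loss_config")
}

# Focal gamma interpolated linearly over epochs 0..(n_epochs - 1).
gamma_focal_at <- function(cfg, epoch, n_epochs) {
  if (n_epochs <= 1) return(cfg$gamma_focal_end)
  f <- min(max(epoch / (n_epochs - 1), 0), 1)
  cfg$gamma_focal_start + f * (cfg$gamma_focal_end - cfg$gamma_focal_start)
}

#' Mask loss: smooth L1 plus weighted focal loss
#'
#' \eqn{L_{mask} = L_{smooth} + \gamma_{mask} L_{focal}}, with the focal
#' focusing exponent ramped linearly from its start to its end value across
#' epochs.
#'
#' @param M,M_hat Target mask and saliency map.
#' @param cfg A [loss_config()].
#' @param epoch Zero-based epoch index.
#' @param n_epochs Total number of epochs (used by the gamma ramp).
#' @return Scalar loss.
#' @export
mask_loss <- function(M, M_hat, cfg = loss_config(), epoch = 0, n_epochs = 1) {
  g <- gamma_focal_at(cfg, epoch, n_epochs)
  smooth_l1(M, M_hat) +
    cfg$gamma_mask * focal_loss(M, M_hat, alpha = cfg$alpha, gamma = g)
}

mask_loss_grad <- function(M, M_hat, cfg = loss_config(), epoch = 0, n_epochs = 1) {
  g <- gamma_focal_at(cfg, epoch, n_epochs)
  smooth_l1_grad(M, M_hat) +
    cfg$gamma_mask * focal_loss_grad(M, M_hat, alpha = cfg$alpha, gamma = g)
}

#' Total training loss
#'
#' Sum of the batch-averaged noise and mask losses.
#'
#' @param noise_terms Numeric vector of per-sample noise losses.
#' @param mask_terms Numeric vector of per-sample mask losses.
#' @return List with `noise`, `mask`, `total`.
#' @export
total_loss <- function(noise_terms, mask_terms) {
  l_noise <- if (length(noise_terms)) mean(noise_terms) else 0
  l_mask <- if (length(mask_terms)) mean(mask_terms) else 0
  list(noise = l_noise, mask = l_mask, total = l_noise + l_mask)
}
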
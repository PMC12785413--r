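# R-side handles for the native networks: construction, forward/backward,
# Adam steps, parameter export/import and checkpoints.

#' Create a diffusion denoiser network
#'
#' A U-Net noise predictor with two stride-2 encoder stages and a
#' transformer mid-block: a stack of `depth` encoder layers, each with
#' multi-head self-attention, residual connections and layer normalization,
#' conditioned on the diffusion time step through an additive sinusoidal
#' time embedding on the mid tokens.
#'
#' @param size Input side length (divisible by 4).
#' @param widths Channel widths `c(stage1, stage2, mid)`.
#' @param depth Number of transformer encoder layers in the mid-block.
#' @param heads Attention heads (must divide `widths[3]`).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `scafdl_denoiser` wrapping a native handle.
#' @export
denoiser_new <- function(size = 32, widths = c(8, 16, 32), depth = 2,
                         heads = 4, seed = 0) {
  ptr <- cpp_den_create(size, size, widths[1], widths[2], widths[3],
                        depth, heads, as.integer(seed))
  structure(list(ptr = ptr, size = size, widths = widths, depth = depth,
                 heads = heads, seed = seed),
            class = "scafdl_denoiser")
}

#' Create a localization network
#'
#' An encoder-decoder segmentation network with skip connections, a
#' squeeze-and-excitation block closing each of the three encoder stages, and
#' a terminal sigmoid. Input is the 2-channel concatenation of the image and
#' its reconstruction; output is a saliency map in `(0, 1)`.
#'
#' @param size Input side length (divisible by 4).
#' @param widths Channel widths of the three encoder stages.
#' @param se_ratio Squeeze-and-excitation reduction ratio.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `scafdl_localizer`.
#' @export
localizer_new <- function(size = 32, widths = c(8, 16, 24), se_ratio = 4,
                          seed = 0) {
  ptr <- cpp_loc_create(size, size, widths[1], widths[2], widths[3],
                        as.integer(se_ratio), as.integer(seed))
  structure(list(ptr = ptr, size = size, widths = widths,
                 se_ratio = se_ratio, seed = seed),
            class = "scafdl_localizer")
}

as_batch_array <- function(x, channels = 1) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  if (channels == 1 && length(dim(x)) == 3) return(x)
  x
}

#' Denoiser forward pass
#'
#' @param den A `scafdl_denoiser`.
#' @param x Image batch: matrix or `H x W x N` array.
#' @param t Time step (scalar or length-N vector).
#' @param train Retain caches for a subsequent backward pass.
#' @return `H x W x N` array of predicted noise.
#' @export
nn_forward_denoiser <- function(den, x, t, train = FALSE) {
  cpp_den_forward(den$ptr, as_batch_array(x), as.numeric(t), isTRUE(train))
}

nn_backward_denoiser <- function(den, dy) cpp_den_backward(den$ptr, dy)

#' Localizer forward pass
#'
#' @param loc A `scafdl_localizer`.
#' @param x `H x W x 2 x N` array (or `H x W x 2` for one sample).
#' @param train Retain caches for a subsequent backward pass.
#' @return `H x W x N` array of saliency values in `(0, 1)`.
#' @export
nn_forward_localizer <- function(loc, x, train = FALSE) {
  cpp_loc_forward(loc$ptr, x, isTRUE(train))
}

nn_backward_localizer <- function(loc, dy) cpp_loc_backward(loc$ptr, dy)

nn_adam <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (inherits(model, "scafdl_denoiser")) cpp_den_adam(model$ptr, lr, beta1, beta2, eps)
  else cpp_loc_adam(model$ptr, lr, beta1, beta2, eps)
  invisible(model)
}

nn_zero_grad <- function(model) {
  if (inherits(model, "scafdl_denoiser")) cpp_den_zero_grad(model$ptr)
  else cpp_loc_zero_grad(model$ptr)
  invisible(model)
}

#' Export / import network parameters
#'
#' @param model A `scafdl_denoiser` or `scafdl_localizer`.
#' @param grads Return accumulated gradients instead of weights.
#' @return Named list of numeric matrices.
#' @export
nn_params <- function(model, grads = FALSE) {
  if (inherits(model, "scafdl_denoiser")) cpp_den_params(model$ptr, grads)
  else cpp_loc_params(model$ptr, grads)
}

#' @rdname nn_params
#' @param params Named list as returned by `nn_params()`.
#' @export
nn_set_params <- function(model, params) {
  if (inherits(model, "scafdl_denoiser")) cpp_den_set_params(model$ptr, params)
  else cpp_loc_set_params(model$ptr, params)
  invisible(model)
}

#' @rdname nn_params
#' @export
nn_n_params <- function(model) {
  if (inherits(model, "scafdl_denoiser")) cpp_den_n_params(model$ptr)
  else cpp_loc_n_params(model$ptr)
}

#' @export
print.scafdl_denoiser <- function(x, ...) {
  cat(sprintf("scafdl denoiser %dx%d, widths %s, transformer depth %d (%d params)\n",
              x$size, x$size, paste(x$widths, collapse = "/"), x$depth,
              nn_n_params(x)))
  invisible(x)
}

#' @export
print.scafdl_localizer <- function(x, ...) {
  cat(sprintf("scafdl SE-U-Net localizer %dx%d, widths %s (%d params)\n",
              x$size, x$size, paste(x$widths, collapse = "/"), nn_n_params(x)))
  invisible(x)
}

# A denoiser closure satisfying the `den(x, t)` contract of ing_reconstruct.
denoiser_fun <- function(den) {
  function(x_t, t) {
    y <- nn_forward_denoiser(den, x_t, t, train = FALSE)
    matrix(y[, , 1], nrow(x_t), ncol(x_t))
  }
}

#' Save / load a model bundle checkpoint
#'
#' The checkpoint stores schedule parameters, both architecture descriptors
#' and all weights; loading reconstructs the native networks.
#'
#' @param bundle A `scafdl_model` bundle (see [train_scafdl()]).
#' @param path Destination file.
#' @return `load_checkpoint` returns the reconstructed bundle.
#' @export
save_checkpoint <- function(bundle, path) {
  obj <- list(
    profile = bundle$profile,
    sched = bundle$sched[c("T", "kind", "beta_bounds", "segments")],
    guidance = unclass(bundle$guidance),
    loss_cfg = unclass(bundle$loss_cfg),
    den = list(size = bundle$denoiser$size, widths = bundle$denoiser$widths,
               depth = bundle$denoiser$depth, heads = bundle$denoiser$heads,
               seed = bundle$denoiser$seed, params = nn_params(bundle$denoiser)),
    loc = list(size = bundle$localizer$size, widths = bundle$localizer$widths,
               se_ratio = bundle$localizer$se_ratio, seed = bundle$localizer$seed,
               params = nn_params(bundle$localizer)),
    history = bundle$history
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no checkpoint at %s", path))
  obj <- readRDS(path)
  den <- denoiser_new(obj$den$size, obj$den$widths, obj$den$depth,
                      obj$den$heads, obj$den$seed)
  nn_set_params(den, obj$den$params)
  loc <- localizer_new(obj$loc$size, obj$loc$widths, obj$loc$se_ratio,
                       obj$loc$seed)
  nn_set_params(loc, obj$loc$params)
  sched <- build_schedule(obj$sched$T, obj$sched$kind, obj$sched$beta_bounds,
                          obj$sched$segments)
  structure(list(
    denoiser = den, localizer = loc, sched = sched,
    guidance = do.call(guidance_config, obj$guidance[c("w1", "w2", "mode", "triple", "reuse_noise")]),
    loss_cfg = do.call(loss_config, obj$loss_cfg[setdiff(names(obj$loss_cfg), NULL)]),
    profile = obj$profile, history = obj$history
  ), class = "scafdl_model")
}
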
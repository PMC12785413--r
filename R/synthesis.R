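# Stage I: pseudofracture synthesis. A healthy image becomes a
# (pseudofracture image, anomaly mask) training pair via foreground-
# constrained shape generation, texture filling, opacity blending and
# stochastic augmentation.

#' Segment the bone foreground
#'
#' Produces the binary foreground mask `F` that constrains where
#' pseudo-anomalies may be placed. Two backends: `"oracle"` returns the
#' phantom's stored mask (exact, available for generated data); `"threshold"`
#' applies Otsu thresholding, keeps the largest connected component and fills
#' holes — the fallback that works on any bright-bone / dark-background crop.
#'
#' @param N A grayscale image in `[0, 1]`, or a `scafdl_phantom` (whose
#'   stored mask the oracle backend returns).
#' @param method `"oracle"` or `"threshold"`.
#' @return Binary foreground mask.
#' @export
segment_foreground <- function(N, method = c("threshold", "oracle")) {
  method <- match.arg(method)
  if (method == "oracle") {
    if (!inherits(N, "scafdl_phantom"))
      stop_invalid("oracle foreground requires a scafdl_phantom input")
    return(N$foreground)
  }
  if (inherits(N, "scafdl_phantom")) N <- N$image
  check_gray(N)
  if (max(N) - min(N) < 1e-6) stop_degenerate("constant image has no foreground")
  thr <- EBImage::otsu(EBImage::Image(N))
  bw <- EBImage::Image(as_mask(N > thr))
  lab <- EBImage::bwlabel(bw)
  tab <- table(as.vector(lab[lab > 0]))
  if (length(tab) == 0) stop_degenerate("empty foreground after thresholding")
  keep <- as.integer(names(tab)[which.max(tab)])
  comp <- EBImage::Image(as_mask(as.matrix(lab) == keep))
  as_mask(as.matrix(EBImage::fillHull(comp)) > 0)
}

#' Sample a random fracture shape
#'
#' Two endpoints are drawn on opposite halves of the image border (top vs
#' bottom or left vs right, chosen at random), `k ~ Uniform{1..5}` interior
#' points are placed between them with perpendicular jitter, the polyline is
#' rasterized with Bresenham segments and dilated with a disk of radius
#' `thickness`. A low interior-point count yields subtle near-linear
#' fissures; higher counts yield the irregular trajectories of complex
#' fracture patterns. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param size Image side length (at least 32).
#' @param thickness Dilation radius in pixels (default 1, giving 2-3 px wide
#'   lines).
#' @return Object of class `scafdl_shape`: list with `mask` (binary matrix),
#'   `vertices` ((k+2) x 2 matrix of (row, col)), `thickness`, `k`.
#' @export
sample_fracture_shape <- function(seed, size = 128, thickness = 1) {
  if (size < 32) stop_invalid("size must be at least 32")
  withr::with_seed(seed, {
    if (runif(1) < 0.5) {   # top vs bottom border halves
      pa <- c(1, runif(1, 1, size))
      pb <- c(size, runif(1, 1, size))
    } else {                # left vs right
      pa <- c(runif(1, 1, size), 1)
      pb <- c(runif(1, 1, size), size)
    }
    k <- sample(1:5, 1)
    fr <- sort(runif(k, 0.15, 0.85))
    d <- pb - pa
    perp <- c(-d[2], d[1]) / sqrt(sum(d^2))
    inner <- t(vapply(fr, function(f) {
      pmin(pmax(pa + f * d + rnorm(1, 0, 0.08 * size) * perp, 1), size)
    }, numeric(2)))
    vertices <- rbind(pa, inner, pb)
    mask <- dilate_disk(rasterize_polyline(vertices, size), thickness)
    structure(list(mask = mask, vertices = vertices,
                   thickness = thickness, k = k),
              class = "scafdl_shape")
  })
}

#' Combine foreground and fracture shape into the anomaly mask
#'
#' The elementwise product `M = F * P`: the fracture shape clipped to the
#' bone foreground, so pseudo-anomalies never spill into the background.
#'
#' @param F Binary foreground mask.
#' @param shape A `scafdl_shape` or a binary shape mask `P`.
#' @return Binary anomaly mask `M`.
#' @export
make_anomaly_mask <- function(F, shape) {
  P <- if (inherits(shape, "scafdl_shape")) shape$mask else shape
  check_mask(F, "F"); check_mask(P, "P")
  check_same_dim(F, P, "F and P")
  as_mask(F * P)
}

#' Opacity-blend a texture over an image
#'
#' `A(x) = beta * T(x) + (1 - beta) * N(x)` for a bank patch `T` chosen per
#' seed. The blend is computed on all pixels; the anomaly mask restricts it
#' later in [blend_pseudofracture()].
#'
#' @param M Anomaly mask (shape check only).
#' @param bank A `scafdl_texture_bank`.
#' @param N The healthy image.
#' @param beta Opacity in `[0, 1]`.
#' @param seed Integer seed for the patch choice.
#' @return Blended image `A`.
#' @export
fill_texture <- function(M, bank, N, beta, seed = 0) {
  if (!inherits(bank, "scafdl_texture_bank") || length(bank$patches) == 0)
    stop_invalid("bank must be a non-empty scafdl_texture_bank")
  if (beta < 0 || beta > 1) stop_invalid("beta must be in [0, 1]")
  check_same_dim(M, N, "M and N")
  tex <- withr::with_seed(seed, bank$patches[[sample(length(bank$patches), 1)]])
  check_same_dim(tex, N, "texture patch and N")
  beta * tex + (1 - beta) * N
}

#' Blend a pseudofracture into a healthy image
#'
#' `S = M * A + (1 - M) * N`, clipped to `[0, 1]`: the textured anomaly `A`
#' replaces the healthy image inside the mask and leaves it untouched
#' elsewhere. The label is `y = 1` iff the mask is non-empty.
#'
#' @param N Healthy image.
#' @param A Textured anomaly image (see [fill_texture()]).
#' @param M Binary anomaly mask.
#' @param source_id Optional identifier of the source image.
#' @return Object of class `scafdl_pseudosample`: list with `S`, `M`, `y`,
#'   `source_id`.
#' @export
blend_pseudofracture <- function(N, A, M, source_id = NA) {
  check_same_dim(N, A, "N and A"); check_same_dim(N, M, "N and M")
  check_mask(M, "M")
  S <- clip01(M * A + (1 - M) * N)
  structure(list(S = S, M = as_mask(M), y = as.integer(sum(M) > 0),
                 source_id = source_id),
            class = "scafdl_pseudosample")
}

# ---- augmentation pool -----------------------------------------------------

# Inverse-mapped affine warp about the image center. `mat` maps output
# coordinates to source coordinates (2x2 linear part + offset).
warp_affine <- function(img, lin, off = c(0, 0), method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- row(img) - cy; cc <- col(img) - cx
  sr <- lin[1, 1] * rr + lin[1, 2] * cc + cy + off[1]
  sc <- lin[2, 1] * rr + lin[2, 2] * cc + cx + off[2]
  if (method == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out <- matrix(0, h, w)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  out <- matrix(0, h, w)
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- matrix(0, h, w)
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * gv(r0, c0) + (1 - fr) * fc * gv(r0, c0 + 1) +
    fr * (1 - fc) * gv(r0 + 1, c0) + fr * fc * gv(r0 + 1, c0 + 1)
  out
}

rot_lin <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)   # inverse rotation
}

apply_geometric <- function(S, M, lin, off = c(0, 0)) {
  list(S = clip01(warp_affine(S, lin, off, "bilinear")),
       M = as_mask(warp_affine(M, lin, off, "nearest")))
}

equalize_gray <- function(x, levels = 256) {
  q <- floor(pmin(x, 1 - 1e-9) * levels)
  cdf <- cumsum(tabulate(q + 1, nbins = levels)) / length(x)
  matrix(cdf[q + 1], nrow(x), ncol(x))
}

#' The photometric/geometric augmentation pool
#'
#' Returns the pool from which [augment_pair()] draws: photometric ops
#' (gamma in `[0.5, 2]`, brightness gain `[0.8, 1.2]` with offset
#' `±30/255`, solarize threshold `[32, 128]/255`, autocontrast, equalize)
#' touch only the image; the geometric op (rotation `±45` degrees) is applied
#' identically to image and mask. The more aggressive shape transforms
#' (rotation `±90`, shear `0-40` degrees, translation `±50%`, scale
#' `50-100%`) live in the separate shape pool applied to the fracture mask
#' before foreground clipping.
#'
#' @param photometric_only Drop the geometric entries (useful for tests).
#' @return List of ops; each op has `name`, `kind`, `sample(n)` and
#'   `apply(S, M, par)`.
#' @export
default_augmentation_pool <- function(photometric_only = FALSE) {
  pool <- list(
    list(name = "gamma", kind = "photometric",
         sample = function() runif(1, 0.5, 2),
         apply = function(S, M, par) list(S = S^par, M = M)),
    list(name = "brightness", kind = "photometric",
         sample = function() c(runif(1, 0.8, 1.2), runif(1, -30, 30) / 255),
         apply = function(S, M, par) list(S = clip01(par[1] * S + par[2]), M = M)),
    list(name = "solarize", kind = "photometric",
         sample = function() runif(1, 32, 128) / 255,
         apply = function(S, M, par) list(S = ifelse(S > par, 1 - S, S), M = M)),
    list(name = "autocontrast", kind = "photometric",
         sample = function() numeric(0),
         apply = function(S, M, par) {
           rg <- range(S)
           if (diff(rg) < 1e-9) return(list(S = S, M = M))
           list(S = (S - rg[1]) / diff(rg), M = M)
         }),
    list(name = "equalize", kind = "photometric",
         sample = function() numeric(0),
         apply = function(S, M, par) list(S = equalize_gray(S), M = M)),
    list(name = "rotate", kind = "geometric",
         sample = function() runif(1, -45, 45),
         apply = function(S, M, par) apply_geometric(S, M, rot_lin(par)))
  )
  if (photometric_only) pool <- Filter(function(op) op$kind == "photometric", pool)
  pool
}

shape_augmentation_pool <- function() {
  list(
    list(name = "mask_rotate", sample = function() runif(1, -90, 90),
         apply = function(P, par) warp_affine(P, rot_lin(par), method = "nearest")),
    list(name = "mask_shear", sample = function() tan(runif(1, 0, 40) * pi / 180),
         apply = function(P, par)
           warp_affine(P, matrix(c(1, 0, par, 1), 2), method = "nearest")),
    list(name = "mask_translate", sample = function() runif(2, -0.5, 0.5),
         apply = function(P, par)
           warp_affine(P, diag(2), off = par * dim(P), method = "nearest")),
    list(name = "mask_scale", sample = function() runif(1, 0.5, 1.0),
         apply = function(P, par)
           warp_affine(P, diag(2) / par, method = "nearest"))
  )
}

augment_shape_mask <- function(P, seed) {
  withr::with_seed(seed, {
    pool <- shape_augmentation_pool()
    op <- pool[[sample(length(pool), 1)]]
    as_mask(op$apply(P, op$sample()))
  })
}

#' Stochastically augment a pseudofracture pair
#'
#' Draws exactly 3 ops from the pool without replacement and applies them in
#' draw order: photometric ops alter only the image; geometric ops are
#' applied identically to image (bilinear) and mask (nearest neighbor). The
#' image stays clipped to `[0, 1]` and the mask stays binary. Deterministic
#' per seed.
#'
#' @param S Image.
#' @param M Binary mask.
#' @param pool Augmentation pool, see [default_augmentation_pool()].
#' @param seed Integer seed.
#' @return List with augmented `S` and `M`.
#' @export
augment_pair <- function(S, M, pool = default_augmentation_pool(), seed = 0) {
  check_mask(M, "M"); check_same_dim(S, M, "S and M")
  withr::with_seed(seed, {
    n_ops <- min(3, length(pool))
    chosen <- sample(length(pool), n_ops)
    for (i in chosen) {
      op <- pool[[i]]
      par <- op$sample()
      res <- op$apply(S, M, par)
      S <- clip01(res$S); M <- as_mask(res$M)
    }
  })
  list(S = S, M = M)
}

#' Synthesize a training batch of pseudofracture samples
#'
#' Turns a list of healthy images (with foregrounds) into an interleaved
#' batch of untouched normal samples (`y = 0`) and pseudofracture samples
#' (`y = 1`) at the configured ratio (default 50/50, so a batch of 16 holds 8
#' of each). Each pseudofracture draws a fresh fracture shape (optionally
#' passed through an aggressive shape transform), clips it to the foreground,
#' fills it with a texture at opacity `beta ~ U(beta_range)` and blends it in.
#' Shapes that miss the foreground are resampled a few times before the
#' sample falls back to normal.
#'
#' @param normals List of `scafdl_phantom` objects or lists with elements
#'   `N` (image) and `F` (foreground mask).
#' @param bank A `scafdl_texture_bank`.
#' @param config List: `ratio` (pseudofracture fraction, default 0.5),
#'   `beta_range` (default `c(0.5, 1)`), `thickness` (default 1),
#'   `augment_shape` (default `TRUE`).
#' @param seed Integer seed.
#' @return List of `scafdl_pseudosample` objects, one per input.
#' @export
synthesize_batch <- function(normals, bank, config = list(), seed = 0) {
  if (length(normals) == 0) stop_invalid("normals must be non-empty")
  cfg <- utils::modifyList(
    list(ratio = 0.5, beta_range = c(0.5, 1), thickness = 1,
         augment_shape = TRUE),
    config)
  n <- length(normals)
  idx <- seq_len(n)
  is_pseudo <- (floor(idx * cfg$ratio) - floor((idx - 1) * cfg$ratio)) == 1

  out <- vector("list", n)
  for (i in idx) {
    item <- normals[[i]]
    if (inherits(item, "scafdl_phantom")) {
      N <- item$image; F_ <- item$foreground
    } else {
      N <- item$N; F_ <- item$F
    }
    if (!is_pseudo[i]) {
      out[[i]] <- structure(
        list(S = N, M = matrix(0, nrow(N), ncol(N)), y = 0L, source_id = i),
        class = "scafdl_pseudosample")
      next
    }
    samp <- NULL
    for (attempt in 1:5) {
      s_i <- derive_seed(seed, i, attempt)
      shape <- sample_fracture_shape(s_i, nrow(N), cfg$thickness)
      P <- shape$mask
      if (isTRUE(cfg$augment_shape))
        P <- augment_shape_mask(P, derive_seed(s_i, 1))
      M <- make_anomaly_mask(F_, P)
      if (sum(M) == 0) next
      beta <- withr::with_seed(derive_seed(s_i, 2),
                               runif(1, cfg$beta_range[1], cfg$beta_range[2]))
      A <- fill_texture(M, bank, N, beta, seed = derive_seed(s_i, 3))
      samp <- blend_pseudofracture(N, A, M, source_id = i)
      break
    }
    if (is.null(samp)) {   # shape never hit the foreground: keep as normal
      samp <- structure(
        list(S = N, M = matrix(0, nrow(N), ncol(N)), y = 0L, source_id = i),
        class = "scafdl_pseudosample")
    }
    out[[i]] <- samp
  }
  out
}
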
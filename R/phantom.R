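# Seeded phantom-radiograph generator: bone-like bright foreground on a
# cluttered darker background, plus true-fracture inscription and texture
# banks. Everything downstream is testable against these phantoms without
# any clinical data.

default_phantom_params <- function() {
  list(
    frac_range = c(0.20, 0.50),   # target foreground pixel fraction
    aspect_range = c(0.55, 0.90), # minor/major axis ratio
    exponent_range = c(1.8, 3.2), # super-ellipse exponent
    fg_level = 0.70,              # mean bone intensity
    bg_level = 0.14,              # soft-tissue background level
    density_amp = 0.16,           # amplitude of the smooth bone-density field
    clutter_range = c(1L, 3L),    # number of faint elongated distractor blobs
    blur_sigma = 0.7,             # global Gaussian smoothing (px)
    noise_sd = 0.01               # additive pixel noise
  )
}

bilinear_upsample <- function(m, size) {
  sr <- seq(1, nrow(m), length.out = size)
  sc <- seq(1, ncol(m), length.out = size)
  r0 <- pmin(floor(sr), nrow(m) - 1); fr <- sr - r0
  c0 <- pmin(floor(sc), ncol(m) - 1); fc <- sc - c0
  a <- m[r0, c0, drop = FALSE]; b <- m[r0 + 1, c0, drop = FALSE]
  d <- m[r0, c0 + 1, drop = FALSE]; e <- m[r0 + 1, c0 + 1, drop = FALSE]
  (1 - fr) * ((1 - fc[col(a)]) * a + fc[col(a)] * d) +
    fr * ((1 - fc[col(a)]) * b + fc[col(a)] * e)
}

superellipse_mask <- function(size, cx, cy, a, b, p, theta) {
  j <- col(matrix(0, size, size)); i <- row(matrix(0, size, size))
  dx <- j - cx; dy <- i - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  rho <- (abs(u) / a)^p + (abs(v) / b)^p
  list(mask = as_mask(rho <= 1), rho = rho)
}

#' Generate a phantom radiograph
#'
#' Produces a synthetic grayscale image emulating a cropped bone radiograph:
#' a bright super-ellipse foreground with a smooth multiplicative
#' bone-density field, over a darker background carrying 1-3 faint elongated
#' distractor blobs (stand-ins for neighboring bones) and pixel noise. The
#' exact foreground mask is returned alongside. Deterministic given
#' `(seed, size, params)`.
#'
#' @param seed Integer seed.
#' @param size Image side length in pixels (at least 32; default 128).
#' @param params Optional overrides of the generator parameters; see
#'   `scafdl:::default_phantom_params()` for the full list and defaults.
#' @return Object of class `scafdl_phantom`: list with `image` (matrix in
#'   `[0, 1]`), `foreground` (binary matrix, a single connected component
#'   covering 15-60% of pixels) and `meta`.
#' @export
generate_phantom <- function(seed, size = 128, params = list()) {
  if (size < 32) stop_invalid("size must be at least 32")
  pp <- utils::modifyList(default_phantom_params(), params)
  withr::with_seed(seed, {
    frac <- runif(1, pp$frac_range[1], pp$frac_range[2])
    aspect <- runif(1, pp$aspect_range[1], pp$aspect_range[2])
    p <- runif(1, pp$exponent_range[1], pp$exponent_range[2])
    theta <- runif(1, 0, pi)
    cx <- size / 2 + runif(1, -0.08, 0.08) * size
    cy <- size / 2 + runif(1, -0.08, 0.08) * size

    # super-ellipse area = 4ab * Gamma(1+1/p)^2 / Gamma(1+2/p)
    gp <- gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)
    ab <- frac * size^2 / (4 * gp)
    a <- sqrt(ab / aspect); b <- a * aspect
    lim <- 0.46 * size
    if (max(a, b) > lim) { s <- lim / max(a, b); a <- a * s; b <- b * s }

    se <- superellipse_mask(size, cx, cy, a, b, p, theta)
    for (iter in 1:25) {
      fr <- mean(se$mask)
      if (fr >= 0.16 && fr <= 0.58) break
      s <- if (fr < 0.16) 1.07 else 0.93
      a <- a * s; b <- b * s
      se <- superellipse_mask(size, cx, cy, a, b, p, theta)
    }
    fg <- se$mask

    density <- 1 + pp$density_amp *
      pmin(pmax(bilinear_upsample(matrix(rnorm(25), 5, 5), size), -1.6), 1.6)
    # mild brightening toward the bone center
    fg_val <- pp$fg_level * density * (1 - 0.18 * pmin(se$rho, 1))

    bg <- matrix(pp$bg_level, size, size) +
      0.04 * bilinear_upsample(matrix(rnorm(36), 6, 6), size)
    n_blob <- sample(seq(pp$clutter_range[1], pp$clutter_range[2]), 1)
    jj <- col(bg); ii <- row(bg)
    for (k in seq_len(n_blob)) {
      bx <- runif(1, 0.1, 0.9) * size; by <- runif(1, 0.1, 0.9) * size
      ang <- runif(1, 0, pi)
      sl <- runif(1, 0.15, 0.30) * size; ss <- runif(1, 0.03, 0.07) * size
      amp <- runif(1, 0.08, 0.18)
      u <- (jj - bx) * cos(ang) + (ii - by) * sin(ang)
      v <- -(jj - bx) * sin(ang) + (ii - by) * cos(ang)
      bg <- bg + amp * exp(-0.5 * ((u / sl)^2 + (v / ss)^2))
    }

    img <- bg
    img[fg == 1] <- fg_val[fg == 1]
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = pp$blur_sigma))
    img <- img + pp$noise_sd * matrix(rnorm(size^2), size, size)
    img <- clip01(img)

    structure(list(
      image = img,
      foreground = fg,
      meta = list(seed = seed, size = size, center = c(cx, cy),
                  axes = c(a, b), angle = theta, exponent = p,
                  frac = mean(fg), params = pp)
    ), class = "scafdl_phantom")
  })
}

#' @export
print.scafdl_phantom <- function(x, ...) {
  cat(sprintf("scafdl phantom %dx%d (seed %d, foreground %.1f%%)\n",
              nrow(x$image), ncol(x$image), x$meta$seed, 100 * x$meta$frac))
  invisible(x)
}

# Bresenham raster of the segment (r0,c0)-(r1,c1); returns matrix of (row, col).
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  if (sr == 0) sr <- 1L
  if (sc == 0) sc <- 1L
  err <- dc - dr
  pts <- matrix(0L, dr + dc + 1, 2)
  r <- r0; c <- c0; n <- 0L
  repeat {
    n <- n + 1L
    pts[n, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  pts[seq_len(n), , drop = FALSE]
}

rasterize_polyline <- function(vertices, size) {
  m <- matrix(0, size, size)
  v <- round(vertices)
  v[, 1] <- pmin(pmax(v[, 1], 1), size)
  v[, 2] <- pmin(pmax(v[, 2], 1), size)
  for (i in seq_len(nrow(v) - 1)) {
    pts <- bresenham(v[i, 1], v[i, 2], v[i + 1, 1], v[i + 1, 2])
    m[pts] <- 1
  }
  m
}

dilate_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  as_mask(as.matrix(EBImage::dilate(EBImage::Image(mask), brush)) > 0)
}

fracture_severities <- c("subtle", "line", "displaced")

#' Inscribe a true fracture into a phantom
#'
#' Draws a polyline fracture crossing the bone foreground (roughly
#' perpendicular to its principal axis) and alters the image along it:
#' `subtle` and `line` darken the track (with a smaller intensity drop for
#' `subtle`), `displaced` additionally shifts a band of bone on one side of
#' the track, emulating displacement. The returned mask marks exactly the
#' altered pixels; the image is untouched elsewhere, and all alterations stay
#' strictly inside the foreground.
#'
#' @param phantom A `scafdl_phantom`.
#' @param seed Integer seed.
#' @param severity One of `"subtle"`, `"line"`, `"displaced"` — this
#'   package's working proxy for occult / nondisplaced / displaced fracture
#'   appearance (no claim of radiological realism).
#' @return List with `image` (altered matrix) and `mask` (binary matrix of
#'   altered pixels).
#' @export
inscribe_true_fracture <- function(phantom, seed,
                                   severity = c("line", "subtle", "displaced")) {
  severity <- match.arg(severity, fracture_severities)
  fg <- phantom$foreground
  size <- nrow(fg)
  if (sum(fg) < 80) stop_degenerate("foreground too small to host a fracture line")
  withr::with_seed(seed, {
    co <- which(fg == 1, arr.ind = TRUE)
    ctr <- colMeans(co)
    ev <- eigen(stats::cov(co))$vectors
    minor <- ev[, 2]   # crossing direction: along the bone's short axis
    major <- ev[, 1]
    ext <- max(abs((co[, 1] - ctr[1]) * major[1] + (co[, 2] - ctr[2]) * major[2]))
    shift <- runif(1, -0.35, 0.35) * ext
    ang <- runif(1, -25, 25) * pi / 180
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    dirn <- as.vector(rot %*% minor)
    base <- ctr + shift * major
    L <- 0.9 * size
    pa <- base - L * dirn; pb <- base + L * dirn

    k <- sample(1:5, 1)
    fr <- sort(runif(k, 0.2, 0.8))
    perp <- c(-dirn[2], dirn[1])
    inner <- t(vapply(fr, function(f) {
      pa + f * (pb - pa) + rnorm(1, 0, 0.04 * size) * perp
    }, numeric(2)))
    vertices <- rbind(pa, inner, pb)

    radius <- if (severity == "displaced") 2L else 1L
    track <- dilate_disk(rasterize_polyline(vertices, size), radius)
    core <- as_mask(track == 1 & fg == 1)
    if (sum(core) < 5) stop_degenerate("fracture line misses the foreground")

    img0 <- phantom$image
    img <- img0
    if (severity == "displaced") {
      # shift a band on one side of the track by 1-2 px along the normal
      band <- as_mask(dilate_disk(track, 3L) == 1 & fg == 1 & track == 0)
      dvec <- round(sample(1:2, 1) * perp)
      side <- ((co[, 1] - ctr[1]) * perp[1] + (co[, 2] - ctr[2]) * perp[2])
      idx <- which(band == 1, arr.ind = TRUE)
      sgn <- sign((idx[, 1] - base[1]) * perp[1] + (idx[, 2] - base[2]) * perp[2])
      keep <- sgn > 0
      src <- idx[keep, , drop = FALSE]
      src_from <- cbind(src[, 1] - dvec[1], src[, 2] - dvec[2])
      ok <- src_from[, 1] >= 1 & src_from[, 1] <= size &
        src_from[, 2] >= 1 & src_from[, 2] <= size
      img[src[ok, , drop = FALSE]] <- img0[src_from[ok, , drop = FALSE]]
    }
    depth <- switch(severity,
      subtle = runif(1, 0.16, 0.24),
      line = runif(1, 0.42, 0.52),
      displaced = runif(1, 0.48, 0.58))
    img[core == 1] <- img0[core == 1] * (1 - depth)
    img <- clip01(img)
    img[fg == 0] <- img0[fg == 0]   # containment: background never altered

    mask <- as_mask(img != img0)
    if (sum(mask) == 0) stop_degenerate("fracture produced no altered pixels")
    list(image = img, mask = mask, severity = severity)
  })
}

#' Generate a texture bank
#'
#' Builds `n` texture patches at the target image size, alternating between
#' two provenance classes: `bone-overlap-like` (band-limited bright noise,
#' emulating overlapping bone seen in lateral views) and `background-like`
#' (near-uniform dark patches). Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param n Number of patches (at least 1).
#' @param size Patch side length in pixels.
#' @return Object of class `scafdl_texture_bank`: list with `patches` (list
#'   of matrices in `[0, 1]`) and `provenance` (character vector).
#' @export
generate_texture_bank <- function(seed, n = 8, size = 128) {
  if (n < 1) stop_invalid("n must be at least 1")
  withr::with_seed(seed, {
    patches <- vector("list", n)
    prov <- character(n)
    for (i in seq_len(n)) {
      if (i %% 2 == 1) {
        prov[i] <- "bone-overlap-like"
        base <- runif(1, 0.45, 0.60)
        tex <- base + 0.22 * as.matrix(EBImage::gblur(
          EBImage::Image(matrix(rnorm(size^2), size, size)), sigma = 1.5))
      } else {
        prov[i] <- "background-like"
        base <- runif(1, 0.08, 0.15)
        tex <- base + 0.015 * matrix(rnorm(size^2), size, size)
      }
      patches[[i]] <- clip01(tex)
    }
    structure(list(patches = patches, provenance = prov, size = size),
              class = "scafdl_texture_bank")
  })
}
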
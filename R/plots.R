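# Visualization: saliency heatmap overlays (blue -> red) and curve plots.

# Blue-to-red colormap over [0, 1].
saliency_colors <- function(n = 256) {
  grDevices::colorRampPalette(c("#0000ff", "#00ffff", "#ffff00", "#ff0000"))(n)
}

#' Write a heatmap overlay PNG
#'
#' Renders the saliency map as a blue-to-red heatmap alpha-blended over the
#' grayscale image and writes an RGB PNG.
#'
#' @param img Grayscale image in `[0, 1]`.
#' @param M_hat Saliency map in `[0, 1]`.
#' @param path Output PNG path.
#' @param alpha Heatmap opacity in `[0, 1]`.
#' @return The path, invisibly.
#' @export
write_heatmap_overlay <- function(img, M_hat, path, alpha = 0.5) {
  check_same_dim(img, M_hat, "img and M_hat")
  pal <- grDevices::col2rgb(saliency_colors(256)) / 255
  idx <- pmin(pmax(floor(M_hat * 255) + 1, 1), 256)
  out <- array(0, c(nrow(img), ncol(img), 3))
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * img +
      alpha * matrix(pal[ch, idx], nrow(img), ncol(img))
  }
  png::writePNG(clip01(out), path)
  invisible(path)
}

#' Plot a PRO or ROC curve
#'
#' @param curve A tibble with an `fpr` column and either `pro` or `tpr`.
#' @param fpr_cap Optional vertical guide at the FPR cap.
#' @return A ggplot object.
#' @export
plot_pro_curve <- function(curve, fpr_cap = 0.3) {
  ycol <- if ("pro" %in% names(curve)) "pro" else "tpr"
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data[[ycol]])) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate",
                  y = if (ycol == "pro") "per-region overlap" else "true positive rate") +
    ggplot2::theme_minimal()
  if (!is.null(fpr_cap) && ycol == "pro")
    p <- p + ggplot2::geom_vline(xintercept = fpr_cap, linetype = "dashed",
                                 color = "grey50")
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.scafdl_eval <- function(object, ...) {
  plot_pro_curve(object$pro_curve)
}

#' Contact sheet of pseudofracture samples
#'
#' Tiles sample images (with their masks outlined in red) into one PNG, a
#' quick visual check of the synthesis stage.
#'
#' @param samples List of `scafdl_pseudosample` objects.
#' @param path Output PNG path.
#' @param ncol Number of tiles per row.
#' @return The path, invisibly.
#' @export
write_contact_sheet <- function(samples, path, ncol = 4) {
  n <- length(samples)
  nrow_ <- ceiling(n / ncol)
  h <- nrow(samples[[1]]$S); w <- ncol(samples[[1]]$S)
  sheet <- array(0, c(nrow_ * h, ncol * w, 3))
  for (i in seq_len(n)) {
    r0 <- ((i - 1) %/% ncol) * h
    c0 <- ((i - 1) %% ncol) * w
    S <- samples[[i]]$S; M <- samples[[i]]$M
    for (ch in 1:3) sheet[r0 + 1:h, c0 + 1:w, ch] <- S
    sheet[r0 + 1:h, c0 + 1:w, 1][M == 1] <- 1   # mask outlined in red
    sheet[r0 + 1:h, c0 + 1:w, 2][M == 1] <- 0.2
    sheet[r0 + 1:h, c0 + 1:w, 3][M == 1] <- 0.2
  }
  png::writePNG(clip01(sheet), path)
  invisible(path)
}
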
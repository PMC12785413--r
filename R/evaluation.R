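# Metric suite: top-K image score, image/pixel AUROC, PRO curve and the
# capped-FPR PRO-score.

#' Top-K image-level anomaly score
#'
#' The mean of the `K` largest values of the flattened saliency map. High
#' values indicate that the map contains a compact high-confidence anomalous
#' region somewhere in the image.
#'
#' @param M_hat Saliency map (numeric matrix, values in `[0, 1]`).
#' @param K Number of top pixels averaged (default 50).
#' @return Scalar score in `[0, 1]`.
#' @export
image_score <- function(M_hat, K = 50) {
  if (!is.matrix(M_hat) || !is.numeric(M_hat)) stop_invalid("M_hat must be a numeric matrix")
  if (K < 1 || K > length(M_hat)) stop_invalid("K must be in 1..length(M_hat)")
  v <- sort(as.vector(M_hat), decreasing = TRUE)
  mean(v[seq_len(K)])
}

#' Area under the ROC curve
#'
#' Rank-based AUROC with the midrank tie convention, equivalent to the
#' probability that a random positive outscores a random negative with ties
#' counted one half.
#'
#' @param scores Numeric vector of scores.
#' @param labels Vector of class labels in `{0, 1}`.
#' @return Scalar AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_invalid("scores and labels differ in length")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_invalid("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop_metric("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Scored image container
#'
#' Bundles a saliency map with its image label, optional ground-truth mask
#' and top-K image score.
#'
#' @param M_hat Saliency map.
#' @param label Image label, 0 (normal) or 1 (anomalous).
#' @param G Ground-truth anomaly mask; required (and non-empty) when
#'   `label = 1`, an all-zero mask is substituted for normal images.
#' @param K Top-K parameter forwarded to [image_score()].
#' @return A list of class `scafdl_scored` with elements `M_hat`, `label`,
#'   `G`, `score`.
#' @export
scored_image <- function(M_hat, label, G = NULL, K = 50) {
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop_invalid("label must be 0 or 1")
  if (label == 1L) {
    if (is.null(G)) stop_invalid("anomalous images require a ground-truth mask")
    check_mask(G, "G")
    check_same_dim(M_hat, G, "M_hat and G")
    if (sum(G) == 0) stop_invalid("ground-truth mask of an anomalous image must be non-empty")
  } else if (is.null(G)) {
    G <- matrix(0, nrow(M_hat), ncol(M_hat))
  }
  structure(list(M_hat = M_hat, label = label, G = as_mask(G),
                 score = image_score(M_hat, K = min(K, length(M_hat)))),
            class = "scafdl_scored")
}

#' Pixel-level AUROC
#'
#' AUROC over the pixels of all images pooled together; normal images
#' contribute all-zero ground truth.
#'
#' @param items List of [scored_image()] objects.
#' @return Scalar AUROC.
#' @export
pixel_auroc <- function(items) {
  scores <- unlist(lapply(items, function(it) as.vector(it$M_hat)))
  labels <- unlist(lapply(items, function(it) as.vector(it$G)))
  auroc(scores, labels)
}

default_thresholds <- function(items, max_levels = 256) {
  v <- sort(unique(unlist(lapply(items, function(it) as.vector(it$M_hat)))))
  if (length(v) > max_levels)
    v <- v[unique(round(seq(1, length(v), length.out = max_levels)))]
  # -1e-9 turns everything positive under strict `>`; 1 turns everything off.
  sort(unique(c(-1e-9, v, 1)))
}

#' Per-region-overlap (PRO) curve
#'
#' For each threshold, saliency maps are binarized with a strict `>`
#' comparison. PRO is the mean over *anomalous* images of
#' \eqn{|P \cap G| / |G|}; FPR is \eqn{|P \cap \bar G| / |\bar G|} pooled over
#' the non-anomalous pixels of *all* images (normal images are excluded from
#' PRO only).
#'
#' @param items List of [scored_image()] objects; at least one anomalous.
#' @param thresholds Numeric vector of thresholds; by default the sorted
#'   unique saliency values subsampled to at most 256 levels, extended so the
#'   sweep spans the all-positive and all-negative extremes.
#' @return A tibble of class `scafdl_pro_curve` with columns `threshold`,
#'   `pro`, `fpr`, sorted by increasing threshold (hence non-increasing FPR).
#' @export
pro_curve <- function(items, thresholds = NULL) {
  anom <- Filter(function(it) it$label == 1L, items)
  if (length(anom) == 0) stop_metric("PRO undefined: no anomalous images")
  if (is.null(thresholds)) thresholds <- default_thresholds(items)
  thresholds <- sort(unique(thresholds))

  neg_total <- sum(vapply(items, function(it) sum(it$G == 0), numeric(1)))
  g_sizes <- vapply(anom, function(it) sum(it$G), numeric(1))

  pro <- fpr <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    thr <- thresholds[k]
    pro[k] <- mean(vapply(seq_along(anom), function(i) {
      it <- anom[[i]]
      sum(it$M_hat > thr & it$G == 1) / g_sizes[i]
    }, numeric(1)))
    fp <- sum(vapply(items, function(it) sum(it$M_hat > thr & it$G == 0), numeric(1)))
    fpr[k] <- fp / neg_total
  }
  structure(tibble::tibble(threshold = thresholds, pro = pro, fpr = fpr),
            class = c("scafdl_pro_curve", class(tibble::tibble())))
}

#' Capped-FPR PRO-score
#'
#' Trapezoidal area of the PRO-vs-FPR curve restricted to
#' `FPR <= fpr_cap`, linearly interpolated at the cap and normalized by the
#' cap. Duplicate FPR values keep the best (largest) PRO, the dominating
#' operating point.
#'
#' @param curve A [pro_curve()] result.
#' @param fpr_cap FPR cap as a fraction (default 0.3).
#' @return Scalar PRO-score in `[0, 1]`.
#' @export
pro_score <- function(curve, fpr_cap = 0.3) {
  if (nrow(curve) == 0) stop_invalid("empty PRO curve")
  d <- curve[order(curve$fpr, curve$pro), ]
  best <- tapply(d$pro, d$fpr, max)
  fpr <- as.numeric(names(best)); pro <- as.numeric(best)
  if (min(fpr) > 0) { fpr <- c(0, fpr); pro <- c(pro[1], pro) }
  if (max(fpr) < fpr_cap) { pro <- c(pro, pro[length(pro)]); fpr <- c(fpr, fpr_cap) }
  if (max(fpr) > fpr_cap) {
    i <- which(fpr > fpr_cap)[1]
    if (fpr[i - 1] < fpr_cap) {
      w <- (fpr_cap - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
      pro_cap <- pro[i - 1] + w * (pro[i] - pro[i - 1])
      fpr <- c(fpr[seq_len(i - 1)], fpr_cap)
      pro <- c(pro[seq_len(i - 1)], pro_cap)
    } else {
      fpr <- fpr[seq_len(i - 1)]
      pro <- pro[seq_len(i - 1)]
    }
  }
  sum(diff(fpr) * (head(pro, -1) + tail(pro, -1)) / 2) / fpr_cap
}

roc_curve_points <- function(scores, labels) {
  thr <- sort(unique(c(-Inf, scores, Inf)))
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(h) sum(scores > h & labels == 1) / pos, numeric(1)),
    fpr = vapply(thr, function(h) sum(scores > h & labels == 0) / neg, numeric(1))
  )
}

# Upper-left operating point: maximal TPR - FPR (Youden), ties at lowest FPR.
optimal_operating_point <- function(curve_df, gain, cost) {
  j <- curve_df[[gain]] - curve_df[[cost]]
  i <- order(-j, curve_df[[cost]])[1]
  curve_df[i, ]
}

#' Evaluate a model bundle on the test split of a dataset
#'
#' Runs guided reconstruction and localization on every test image, scores
#' each saliency map, and computes image AUROC, pixel AUROC and PRO-score
#' together with the upper-left operating points of both curves. The model
#' bundle may be `"oracle"`, a stub backend whose saliency equals the ground
#' truth mask (all-zero for normals), used to validate the metric pipeline
#' end to end.
#'
#' @param manifest A dataset manifest (see [build_dataset()]).
#' @param bundle A trained model bundle (see [train_scafdl()]) or `"oracle"`.
#' @param cfg Evaluation options: list with `K` (top-K for the image score),
#'   `fpr_cap` (PRO integration cap) and `max_levels` (threshold sweep
#'   resolution).
#' @param out_dir Optional directory; when given, `report.json`,
#'   `scores.csv`, `pro_curve.csv` and `roc_curve.csv` are written there.
#' @param seed Integer seed for reconstruction noise.
#' @return A list of class `scafdl_eval`: metrics, operating points, per-image
#'   score tibble, and both curves.
#' @export
evaluate_scafdl <- function(manifest, bundle = "oracle",
                            cfg = list(K = 50, fpr_cap = 0.3, max_levels = 256),
                            out_dir = NULL, seed = 0) {
  test <- manifest$test
  if (nrow(test) == 0 || length(unique(test$label)) < 2)
    stop_metric("test split must contain both classes")
  K <- cfg$K %||% 50
  items <- vector("list", nrow(test))
  for (i in seq_len(nrow(test))) {
    img <- read_gray(file.path(manifest$root, test$image[i]))
    G <- if (!is.na(test$mask[i])) {
      as_mask(read_gray(file.path(manifest$root, test$mask[i])) > 0.5)
    } else NULL
    M_hat <- saliency_for_image(img, bundle, G = G, seed = derive_seed(seed, i))
    items[[i]] <- scored_image(M_hat, test$label[i], G = G, K = K)
  }
  scores <- vapply(items, `[[`, numeric(1), "score")
  labels <- vapply(items, `[[`, integer(1), "label")

  img_auroc <- auroc(scores, labels)
  px_auroc <- pixel_auroc(items)
  fpr_cap <- cfg$fpr_cap %||% 0.3
  pc <- pro_curve(items, thresholds = default_thresholds(items, cfg$max_levels %||% 256))
  ps <- pro_score(pc, fpr_cap = fpr_cap)
  roc <- roc_curve_points(scores, labels)

  report <- structure(list(
    image_auroc = img_auroc,
    pixel_auroc = px_auroc,
    pro_score = ps,
    fpr_cap = fpr_cap,
    operating_points = list(
      roc = optimal_operating_point(roc, "tpr", "fpr"),
      pro = optimal_operating_point(pc, "pro", "fpr")
    ),
    scores = tibble::tibble(image = test$image, label = labels, score = scores),
    pro_curve = pc,
    roc_curve = roc,
    items = items
  ), class = "scafdl_eval")

  if (!is.null(out_dir)) write_eval_report(report, out_dir)
  report
}

saliency_for_image <- function(img, bundle, G = NULL, seed = 0) {
  if (identical(bundle, "oracle")) {
    if (is.null(G)) return(matrix(0, nrow(img), ncol(img)))
    return(as_mask(G))
  }
  predict_saliency(bundle, img, seed = seed)$M_hat
}

write_eval_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(image_auroc = report$image_auroc, pixel_auroc = report$pixel_auroc,
         pro_score = report$pro_score,
         operating_points = lapply(report$operating_points, as.list)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(report$pro_curve, file.path(out_dir, "pro_curve.csv"), row.names = FALSE)
  utils::write.csv(report$roc_curve, file.path(out_dir, "roc_curve.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.scafdl_eval <- function(x, ...) {
  cat("scafdl evaluation report\n")
  cat(sprintf("  image AUROC: %.4f\n", x$image_auroc))
  cat(sprintf("  pixel AUROC: %.4f\n", x$pixel_auroc))
  cat(sprintf("  PRO-score  : %.4f (FPR cap %.2g)\n", x$pro_score, x$fpr_cap %||% 0.3))
  cat(sprintf("  test images: %d (%d anomalous)\n",
              nrow(x$scores), sum(x$scores$label == 1)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
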
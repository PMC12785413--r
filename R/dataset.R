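# Dataset plumbing: on-disk layout, PNG I/O and the JSON manifest.
#
# Layout: root/train/normal/*.png, root/test/normal/*.png,
#         root/test/fractured/*.png, root/ground_truth/fractured/*_mask.png,
#         root/manifest.json. Masks: 0 = normal, 255 = anomalous.

#' Read / write an 8-bit grayscale PNG
#'
#' Images live in `[0, 1]` in memory and as 8-bit grayscale PNG on disk, so a
#' write/read round trip agrees to within 1/255 per pixel.
#'
#' @param path File path.
#' @param img Numeric matrix in `[0, 1]`.
#' @return `read_gray` returns a numeric matrix; `write_gray` its path,
#'   invisibly.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' @rdname read_gray
#' @export
write_gray <- function(path, img) {
  check_gray(img)
  ok <- tryCatch({ png::writePNG(img, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stop_io(sprintf("cannot write %s", path))
  invisible(path)
}

default_severity_probs <- c(subtle = 0.2, line = 0.5, displaced = 0.3)

#' Build a phantom dataset on disk
#'
#' Generates phantoms, writes train (all fracture-free) and test splits as
#' 8-bit PNGs with pixel-level ground-truth masks for the fractured test
#' images, and a JSON manifest that round-trips through [read_manifest()].
#' Fracture severities are drawn from `severity_probs`, a mix weighted toward
#' visible fracture lines with a smaller share of subtle (occult-like) and
#' displaced cases.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_train Number of normal training images.
#' @param n_test_normal,n_test_fractured Test split sizes.
#' @param seed Integer seed; every image is a pure function of it.
#' @param size Image side length in pixels (default 128).
#' @param severity_probs Named sampling weights over
#'   `c("subtle", "line", "displaced")`.
#' @param params Phantom generator overrides, see [generate_phantom()].
#' @return The manifest, an object of class `scafdl_manifest` (invisibly
#'   written to `out_dir/manifest.json`): list with `root`, `seed`, `size`,
#'   and `train` / `test` tibbles (`image`, `label`, `mask`).
#' @export
build_dataset <- function(out_dir, n_train, n_test_normal, n_test_fractured,
                          seed = 0, size = 128,
                          severity_probs = default_severity_probs,
                          params = list()) {
  if (any(c(n_train, n_test_normal, n_test_fractured) < 0))
    stop_invalid("counts must be non-negative")
  for (d in c("train/normal", "test/normal", "test/fractured",
              "ground_truth/fractured")) {
    ok <- dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(file.path(out_dir, d)))
      stop_io(sprintf("cannot create directory %s", file.path(out_dir, d)))
  }
  total <- n_train + n_test_normal + n_test_fractured
  draws <- withr::with_seed(seed, list(
    seeds = sample.int(2147483646L, max(total, 1) * 2),
    sev = sample(names(severity_probs), max(n_test_fractured, 1),
                 replace = TRUE, prob = severity_probs)
  ))

  rel <- function(...) file.path(...)
  train <- tibble::tibble(image = character(0), label = integer(0))
  test <- tibble::tibble(image = character(0), label = integer(0),
                         mask = character(0))
  k <- 0
  for (i in seq_len(n_train)) {
    k <- k + 1
    ph <- generate_phantom(draws$seeds[k], size, params)
    f <- rel("train", "normal", sprintf("train_%03d.png", i))
    write_gray(file.path(out_dir, f), ph$image)
    train <- rbind(train, tibble::tibble(image = f, label = 0L))
  }
  for (i in seq_len(n_test_normal)) {
    k <- k + 1
    ph <- generate_phantom(draws$seeds[k], size, params)
    f <- rel("test", "normal", sprintf("normal_%03d.png", i))
    write_gray(file.path(out_dir, f), ph$image)
    test <- rbind(test, tibble::tibble(image = f, label = 0L, mask = NA_character_))
  }
  for (i in seq_len(n_test_fractured)) {
    k <- k + 1
    ph <- generate_phantom(draws$seeds[k], size, params)
    fr <- inscribe_true_fracture(ph, draws$seeds[total + i], draws$sev[i])
    f <- rel("test", "fractured", sprintf("fractured_%03d.png", i))
    fm <- rel("ground_truth", "fractured", sprintf("fractured_%03d_mask.png", i))
    write_gray(file.path(out_dir, f), fr$image)
    write_gray(file.path(out_dir, fm), fr$mask)
    test <- rbind(test, tibble::tibble(image = f, label = 1L, mask = fm))
  }

  manifest <- structure(
    list(root = normalizePath(out_dir), seed = seed, size = size,
         train = train, test = test),
    class = "scafdl_manifest")
  jsonlite::write_json(
    list(seed = seed, size = size,
         train = as.data.frame(train), test = as.data.frame(test)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.json` or to the dataset root directory.
#' @return Object of class `scafdl_manifest`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop_io(sprintf("no manifest at %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  train <- tibble::as_tibble(j$train)
  test <- tibble::as_tibble(j$test)
  if (nrow(test) == 0) test <- tibble::tibble(image = character(0),
                                              label = integer(0),
                                              mask = NA_character_)
  if (!"mask" %in% names(test)) test$mask <- NA_character_
  if (any(test$label == 1 & is.na(test$mask)))
    stop_validation("every fractured test entry must have a mask path")
  if (nrow(train) > 0 && any(train$label != 0))
    stop_validation("train split must contain only normal (label 0) images")
  structure(list(root = normalizePath(dirname(path)), seed = j$seed,
                 size = j$size, train = train, test = test),
            class = "scafdl_manifest")
}

#' @export
print.scafdl_manifest <- function(x, ...) {
  cat(sprintf("scafdl manifest: %d train / %d test (%d fractured), size %d, seed %d\n",
              nrow(x$train), nrow(x$test), sum(x$test$label == 1), x$size, x$seed))
  invisible(x)
}

load_split_images <- function(manifest, split = c("train", "test")) {
  split <- match.arg(split)
  df <- manifest[[split]]
  lapply(seq_len(nrow(df)), function(i) {
    read_gray(file.path(manifest$root, df$image[i]))
  })
}
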
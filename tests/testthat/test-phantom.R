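# Phantom generator: determinism, foreground invariants, fracture
# inscription, texture banks and the on-disk dataset.

test_that("phantom generation is deterministic and seed-sensitive", {
  a <- generate_phantom(7, 128)
  b <- generate_phantom(7, 128)
  expect_identical(a$image, b$image)
  expect_identical(a$foreground, b$foreground)
  c <- generate_phantom(8, 128)
  expect_gt(mean(a$image != c$image), 0.01)
  expect_error(generate_phantom(1, size = 16), class = "scafdl_invalid_argument")
})

test_that("foreground fraction stays within 15-60% across 100 seeds", {
  fr <- vapply(0:99, function(s) mean(generate_phantom(s, 128)$foreground),
               numeric(1))
  expect_true(all(fr >= 0.15 & fr <= 0.60))
})

test_that("phantom foreground is one connected component with values in [0,1]", {
  for (s in c(3, 11, 25)) {
    ph <- generate_phantom(s, 64)
    expect_true(all(ph$image >= 0 & ph$image <= 1))
    lab <- EBImage::bwlabel(EBImage::Image(ph$foreground))
    expect_equal(max(lab), 1)
  }
})

test_that("inscribed fractures are local, contained, and severity-ordered", {
  ph <- desk_phantom(4, 64)
  fr_line <- inscribe_true_fracture(ph, 9, "line")
  # locality: untouched outside the mask
  expect_true(all((fr_line$image == ph$image)[fr_line$mask == 0]))
  # containment: mask never leaves the foreground
  expect_equal(sum(fr_line$mask == 1 & ph$foreground == 0), 0)
  fr_sub <- inscribe_true_fracture(ph, 9, "subtle")
  drop_line <- mean((ph$image - fr_line$image)[fr_line$mask == 1])
  drop_sub <- mean((ph$image - fr_sub$image)[fr_sub$mask == 1])
  expect_lt(drop_sub, drop_line)
  fr_disp <- inscribe_true_fracture(ph, 9, "displaced")
  expect_equal(sum(fr_disp$mask == 1 & ph$foreground == 0), 0)
  expect_gt(sum(fr_disp$mask), 0)
})

test_that("line fractures are darker than the surrounding foreground ring", {
  for (s in 1:5) {
    ph <- generate_phantom(s, 64)
    fr <- inscribe_true_fracture(ph, s + 100, "line")
    ring <- scafdl:::dilate_disk(fr$mask, 3) == 1 & fr$mask == 0 &
      ph$foreground == 1
    expect_lt(mean(fr$image[fr$mask == 1]), mean(fr$image[ring]))
  }
})

test_that("fracture inscription rejects degenerate foregrounds", {
  ph <- desk_phantom(1, 32)
  ph$foreground[] <- 0
  ph$foreground[1:5, 1:5] <- 1
  expect_error(inscribe_true_fracture(ph, 1, "line"),
               class = "scafdl_degenerate_input")
})

test_that("texture bank mixes classes with ordered variance", {
  bank <- generate_texture_bank(3, n = 8, size = 32)
  expect_length(bank$patches, 8)
  expect_true(all(vapply(bank$patches, function(p) all(p >= 0 & p <= 1),
                         logical(1))))
  v <- vapply(bank$patches, function(p) stats::var(as.vector(p)), numeric(1))
  expect_gt(min(v[bank$provenance == "bone-overlap-like"]),
            max(v[bank$provenance == "background-like"]))
  expect_error(generate_texture_bank(1, n = 0), class = "scafdl_invalid_argument")
})

test_that("build_dataset writes a round-trippable manifest and images", {
  dir <- withr::local_tempdir()
  m <- build_dataset(dir, 6, 2, 2, seed = 1, size = 32)
  expect_equal(nrow(m$train), 6)
  expect_equal(nrow(m$test), 4)
  expect_equal(sum(!is.na(m$test$mask)), 2)
  expect_true(all(m$train$label == 0))
  m2 <- read_manifest(dir)
  expect_equal(m2$train, m$train)
  expect_equal(m2$test, m$test)
  # determinism of the manifest file content
  dir2 <- withr::local_tempdir()
  build_dataset(dir2, 6, 2, 2, seed = 1, size = 32)
  expect_identical(readLines(file.path(dir, "manifest.json")),
                   readLines(file.path(dir2, "manifest.json")))
  # PNG round trip within 8-bit quantization
  ph <- generate_phantom(11, 32)
  p <- file.path(dir, "rt.png")
  write_gray(p, ph$image)
  back <- read_gray(p)
  expect_lt(max(abs(back - ph$image)), 1 / 255 + 1e-9)
})
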
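# Dataset preprocessing, nnU-Net-style naming, and fold splitting.

test_that("flat image/mask pairs get trailing-number IDs and the _0000 suffix", {
  src <- tempfile(); dir.create(src)
  s <- generate_sample(synthetic_config(image_size = c(32L, 32L), seed = 1L), 1L)
  png::writePNG(s$image / 255, file.path(src, "lesion_07_0000.png"))
  png::writePNG(s$mask / 255, file.path(src, "lesion_07.png"))
  dst <- tempfile()
  mf <- preprocess_dataset(src, dst, target_size = c(32L, 32L))
  expect_identical(mf$id, "CASE_007")
  expect_true(file.exists(file.path(dst, "imagesTr", "CASE_007_0000.png")))
  expect_true(file.exists(file.path(dst, "labelsTr", "CASE_007.png")))
})

test_that("0/255 masks are binarized to {0,1} and resizing preserves binarity", {
  src <- tempfile(); dir.create(src)
  m <- matrix(0, 40, 40); m[10:20, 12:25] <- 1
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  png::writePNG(img, file.path(src, "case_1_0000.png"))
  png::writePNG(m, file.path(src, "case_1.png"))   # raw values 0 / 255
  dst <- tempfile()
  preprocess_dataset(src, dst, target_size = c(64L, 64L))
  msk <- png::readPNG(file.path(dst, "labelsTr", "CASE_001.png"))
  expect_true(all(round(msk * 255) %in% c(0, 1)))
  expect_gt(sum(msk > 0), 0)
})

test_that("non-binary masks and unpaired files are rejected", {
  src <- tempfile(); dir.create(src)
  png::writePNG(matrix(runif(64), 8, 8), file.path(src, "bad_1.png"))
  png::writePNG(array(runif(192), c(8, 8, 3)), file.path(src, "bad_1_0000.png"))
  expect_error(preprocess_dataset(src, tempfile(), target_size = c(8L, 8L)),
               "not binary")
  src2 <- tempfile(); dir.create(src2)
  png::writePNG(array(runif(192), c(8, 8, 3)), file.path(src2, "only_1_0000.png"))
  expect_error(preprocess_dataset(src2, tempfile()), "unpaired")
})

test_that("preprocessing an already-preprocessed directory is a byte-exact no-op", {
  d0 <- tempfile()
  generate_dataset(synthetic_config(image_size = c(48L, 48L), seed = 4L), 3L, d0)
  p1 <- tempfile(); p2 <- tempfile()
  preprocess_dataset(d0, p1, target_size = c(48L, 48L), prefix = "SYN")
  preprocess_dataset(p1, p2, target_size = c(48L, 48L), prefix = "SYN")
  files <- list.files(p1, recursive = TRUE)
  expect_identical(sort(files), sort(list.files(p2, recursive = TRUE)))
  for (f in files)
    expect_identical(readBin(file.path(p1, f), "raw", 1e7),
                     readBin(file.path(p2, f), "raw", 1e7))
})

test_that("preprocess -> load round-trip preserves the foreground pixel sets", {
  d0 <- tempfile()
  generate_dataset(synthetic_config(image_size = c(48L, 48L), seed = 6L), 3L, d0)
  orig <- load_dataset(d0)
  pd <- tempfile()
  preprocess_dataset(d0, pd, target_size = c(48L, 48L), prefix = "SYN")
  re <- load_dataset(pd)
  for (i in seq_along(orig)) expect_identical(re[[i]]$mask, orig[[i]]$mask)
})

test_that("fold splits are near-equal, deterministic, and exhaustive", {
  f10 <- make_folds(sprintf("s%02d", 1:10), k = 5L, seed = 1L)
  expect_true(all(table(f10) == 2L))
  expect_identical(sort(unique(unclass(f10))), 0:4)
  f812 <- make_folds(sprintf("s%03d", 1:812), k = 5L, seed = 2L)
  expect_true(all(table(f812) %in% c(162L, 163L)))
  expect_identical(sum(table(f812)), 812L)
  expect_identical(make_folds(sprintf("s%03d", 1:812), k = 5L, seed = 2L), f812)
  f2 <- make_folds(sprintf("s%03d", 1:812), k = 5L, seed = 3L)
  expect_false(identical(f2, f812))
  expect_error(make_folds(c("a", "b"), k = 5L), "at least")
})
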
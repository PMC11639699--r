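# Dataset preprocessing: uniform resizing, lossless PNG conversion, mask
# binarization, nnU-Net-style naming (image files carry a `_0000` channel
# suffix, masks do not), and seeded five-fold splitting.
#
# Coordinate convention (used package-wide): arrays are row-major-indexed
# matrices (row, col), 0-based pixel centers; images and masks share it.

strip_ext <- function(f) tools::file_path_sans_ext(basename(f))
strip_chan <- function(s) sub("_0000$", "", s)

read_image_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    a <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores (x, y, c); convert to (row, col, c)
    if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
  } else stop("unsupported image format: ", path)
}

resize_array <- function(a, th, tw, nearest = FALSE) {
  d <- dim(a)
  if (d[1] == th && d[2] == tw) return(a)
  img <- EBImage::Image(a)   # first dim treated as x; consistent in/out
  out <- EBImage::resize(img, w = th, h = tw,
                         filter = if (nearest) "none" else "bilinear")
  EBImage::imageData(out)
}

# locate image/mask pairs under src_dir; returns data.frame(image, mask, stem)
find_pairs <- function(src_dir) {
  sub_img <- intersect(list.dirs(src_dir, recursive = FALSE, full.names = FALSE),
                       c("imagesTr", "images"))
  sub_msk <- intersect(list.dirs(src_dir, recursive = FALSE, full.names = FALSE),
                       c("labelsTr", "masks", "labels"))
  exts <- "\\.(png|jpg|jpeg)$"
  if (length(sub_img) && length(sub_msk)) {
    imgs <- list.files(file.path(src_dir, sub_img[1]), exts, full.names = TRUE)
    msks <- list.files(file.path(src_dir, sub_msk[1]), exts, full.names = TRUE)
    istem <- strip_chan(strip_ext(imgs)); mstem <- strip_ext(msks)
  } else {
    all <- list.files(src_dir, exts, full.names = TRUE)
    stems <- strip_ext(all)
    is_img <- grepl("_0000$", stems) | tolower(tools::file_ext(all)) %in% c("jpg", "jpeg")
    imgs <- all[is_img]; msks <- all[!is_img]
    istem <- strip_chan(strip_ext(imgs)); mstem <- strip_ext(msks)
  }
  orphan_i <- setdiff(istem, mstem); orphan_m <- setdiff(mstem, istem)
  if (length(orphan_i) || length(orphan_m))
    stop("unpaired files under ", src_dir, ": images without masks [",
         paste(orphan_i, collapse = ", "), "], masks without images [",
         paste(orphan_m, collapse = ", "), "]")
  o <- order(istem)
  data.frame(image = imgs[o], mask = msks[o][match(istem[o], mstem[o])],
             stem = istem[o], stringsAsFactors = FALSE)
}

make_ids <- function(stems, prefix) {
  nums <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1", stems)))
  if (!anyNA(nums) && !anyDuplicated(nums)) {
    sprintf("%s_%03d", prefix, nums)
  } else {
    sprintf("%s_%03d", prefix, seq_along(stems))
  }
}

#' Preprocess a paired image/mask dataset
#'
#' Resizes every image to `target_size` (bilinear) and every mask (nearest
#' neighbour, preserving binarity), converts to lossless PNG, binarizes masks
#' to {0,1} (any positive value becomes 1), generates dataset-unique IDs from
#' trailing digits of the source names (sequential fallback), and writes the
#' nnU-Net-style layout `imagesTr/<ID>_0000.png`, `labelsTr/<ID>.png` plus a
#' manifest.  Running it on an already-preprocessed directory is a byte-exact
#' no-op.
#'
#' @param src_dir source directory (flat image/mask pairs, or `images`/`masks`
#'   or `imagesTr`/`labelsTr` subdirectories).
#' @param dst_dir destination directory.
#' @param target_size integer pair (h, w), default 512 x 512.
#' @param prefix ID prefix (encodes the dataset name).
#' @return data.frame manifest (id, image, mask).
#' @export
preprocess_dataset <- function(src_dir, dst_dir, target_size = c(512L, 512L),
                               prefix = "CASE") {
  pairs <- find_pairs(src_dir)
  ids <- make_ids(pairs$stem, prefix)
  dir.create(file.path(dst_dir, "imagesTr"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dst_dir, "labelsTr"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    img <- read_image_any(pairs$image[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3]
    img <- resize_array(img, target_size[1], target_size[2])
    msk_raw <- read_image_any(pairs$mask[i])
    if (length(dim(msk_raw)) == 3L) msk_raw <- msk_raw[, , 1]
    vals <- sort(unique(round(as.vector(msk_raw) * 255)))
    if (length(vals) > 2L)
      stop("mask ", basename(pairs$mask[i]), " is not binary: raw values ",
           paste(utils::head(vals, 6), collapse = ", "))
    msk <- (msk_raw > 0) * 1
    msk <- resize_array(msk, target_size[1], target_size[2], nearest = TRUE)
    img_file <- file.path("imagesTr", paste0(ids[i], "_0000.png"))
    msk_file <- file.path("labelsTr", paste0(ids[i], ".png"))
    png::writePNG(img, file.path(dst_dir, img_file))
    png::writePNG(msk / 255, file.path(dst_dir, msk_file))
    rows[[i]] <- data.frame(id = ids[i], image = img_file, mask = msk_file)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dst_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Load a preprocessed dataset into memory
#'
#' @param dir directory with `imagesTr/` and `labelsTr/` PNGs.
#' @return list of `image_sample`s: `image` (h x w x 3, 8-bit integers),
#'   `mask` (h x w, {0,1}), `id`.
#' @export
load_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "imagesTr"), "\\.png$", full.names = TRUE))
  lapply(imgs, function(f) {
    id <- strip_chan(strip_ext(f))
    mf <- file.path(dir, "labelsTr", paste0(id, ".png"))
    if (!file.exists(mf)) stop("missing mask for ", id)
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
    msk <- png::readPNG(mf)
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    structure(list(image = round(img[, , 1:3] * 255), mask = (msk > 0) * 1, id = id),
              class = "image_sample")
  })
}

#' Deterministic k-fold split of sample IDs
#'
#' Shuffles the IDs with the given seed and partitions them into `k` folds
#' whose sizes differ by at most one.
#'
#' @param ids character vector of sample IDs; `k` fold count; `seed` RNG seed.
#' @return a `fold_split`: named integer vector mapping id -> fold in
#'   0..(k-1).
#' @export
make_folds <- function(ids, k = 5L, seed = 1L) {
  n <- length(ids)
  if (n < k) stop("need at least k = ", k, " ids, got ", n)
  set.seed(seed)
  perm <- sample(ids)
  fold <- rep(seq_len(k) - 1L, length.out = n)
  structure(stats::setNames(fold[match(ids, perm)], ids),
            class = "fold_split")
}
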
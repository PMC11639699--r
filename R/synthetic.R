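# Synthetic non-salient lesion images.  Emulates the regime of clinical oral
# photographs: lesions whose mean intensity and texture closely match the
# surrounding tissue (controlled by a contrast offset), embedded in smoothly
# correlated background texture, plus high-contrast distractor structures
# (tooth-like bright blobs) that are NOT part of the lesion mask.

#' Synthetic dataset configuration
#'
#' @param image_size integer pair (h, w).
#' @param n_lesions lesions per image (>= 0).
#' @param contrast_delta mean intensity offset of the lesion interior relative
#'   to the background, as a fraction of the 8-bit dynamic range, in \[0, 1\].
#'   At 0 the lesion differs from the background only in texture phase.
#' @param texture_scale correlation length of the background texture, pixels.
#' @param distractors number of high-contrast non-lesion objects.
#' @param lesion_area_frac range (min, max) of per-lesion area as a fraction
#'   of the image area.
#' @param seed base RNG seed; a sample is fully determined by (seed, index).
#' @export
synthetic_config <- function(image_size = c(256L, 256L),
                             n_lesions = 1L,
                             contrast_delta = 0.1,
                             texture_scale = 8,
                             distractors = 2L,
                             lesion_area_frac = c(0.02, 0.08),
                             seed = 1L) {
  if (contrast_delta < 0 || contrast_delta > 1)
    stop("contrast_delta must be in [0, 1]")
  if (texture_scale <= 0) stop("texture_scale must be positive")
  if (n_lesions < 0 || distractors < 0) stop("counts must be >= 0")
  if (length(lesion_area_frac) != 2L || any(lesion_area_frac <= 0) ||
      diff(lesion_area_frac) < 0)
    stop("lesion_area_frac must be an increasing positive pair")
  structure(list(image_size = as.integer(image_size),
                 n_lesions = as.integer(n_lesions),
                 contrast_delta = contrast_delta,
                 texture_scale = texture_scale,
                 distractors = as.integer(distractors),
                 lesion_area_frac = lesion_area_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# smooth correlated noise in [0,1]: white noise low-passed by a separable
# Gaussian kernel of bandwidth `scale` pixels, then rescaled
correlated_noise <- function(h, w, scale) {
  pad <- ceiling(3 * scale)
  z <- matrix(stats::rnorm((h + 2 * pad) * (w + 2 * pad)), h + 2 * pad)
  k <- stats::dnorm(seq(-pad, pad), sd = scale)
  k <- k / sum(k)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(t(z), 2, function(col) stats::filter(col, k, sides = 2)))
  z <- z[pad + seq_len(h), pad + seq_len(w)]
  rng <- range(z)
  if (diff(rng) < 1e-12) return(matrix(0.5, h, w))
  (z - rng[1]) / diff(rng)
}

# closed smooth blob boundary: ellipse with a low-order radial Fourier
# perturbation.  The shape is drawn once; only the scale R varies afterwards,
# so the rasterized area can be tuned to a target.
blob_shape <- function(wobble = 0.25, aspect = NULL) {
  if (is.null(aspect)) aspect <- stats::runif(1, 0.6, 1.6)
  nharm <- 3L
  list(aspect = aspect,
       amp = stats::runif(nharm, 0, wobble / nharm),
       phs = stats::runif(nharm, 0, 2 * pi),
       rot = stats::runif(1, 0, pi))
}

blob_radius_fn <- function(sh) {
  function(theta) {
    pert <- 1
    for (k in seq_along(sh$amp)) pert <- pert + sh$amp[k] * cos(k * theta + sh$phs[k])
    pert / sqrt((cos(theta) / sh$aspect)^2 + (sin(theta) * sh$aspect)^2)
  }
}

# rasterize a blob shape at `center` scaled to `target_area` pixels; the scale
# is refined against the pixel count (area goes as R^2 for a fixed shape)
rasterize_blob <- function(h, w, center, target_area, sh) {
  rfun <- blob_radius_fn(sh)
  th <- seq(0, 2 * pi, length.out = 721L)[-721L]
  unit_area <- sum(rfun(th)^2) / 2 * (2 * pi / 720)
  R <- sqrt(target_area / unit_area)
  rows <- matrix(seq_len(h) - 1, h, w)
  cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  dy <- rows - center[1]; dx <- cols - center[2]
  theta <- atan2(dx, dy) - sh$rot
  rr <- sqrt(dy^2 + dx^2)
  base_r <- rfun(theta)
  blob <- (rr <= R * base_r) * 1
  for (adj in 1:4) {
    a <- sum(blob)
    if (a == 0 || abs(a - target_area) <= 1) break
    R <- R * sqrt(target_area / a)
    blob <- (rr <= R * base_r) * 1
  }
  blob
}

dilate_mask <- function(m, r) {
  d <- dist_to_set(m)
  (d <= r) * 1
}

#' Generate one synthetic image/mask sample
#'
#' Background texture, `n_lesions` low-contrast re-textured blobs (the mask),
#' and `distractors` high-contrast blobs kept clear of the lesions (not in
#' the mask).  Fully determined by `(cfg$seed, index)`.
#'
#' @param cfg a [synthetic_config()]; `index` sample number.
#' @return an `image_sample`: list with `image` (h x w x 3, 8-bit integers),
#'   `mask` (h x w, {0,1}) and `id`.
#' @export
generate_sample <- function(cfg, index = 1L) {
  set.seed((cfg$seed * 1000003L + as.integer(index)) %% 2147483647L)
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  base <- correlated_noise(h, w, cfg$texture_scale)
  # tissue-like palette: mid-range pink/red ramp, headroom for the contrast
  # offset and below the distractor intensity
  rgb_lo <- c(120, 60, 60) / 255
  rgb_hi <- c(190, 120, 115) / 255
  img <- array(0, dim = c(h, w, 3))
  for (c in 1:3) img[, , c] <- rgb_lo[c] + base * (rgb_hi[c] - rgb_lo[c])
  mask <- matrix(0, h, w)
  area <- h * w
  for (i in seq_len(cfg$n_lesions)) {
    frac <- stats::runif(1, cfg$lesion_area_frac[1], cfg$lesion_area_frac[2])
    placed <- FALSE
    for (try in 1:40) {
      ctr <- c(stats::runif(1, 0.2 * h, 0.8 * h), stats::runif(1, 0.2 * w, 0.8 * w))
      blob <- rasterize_blob(h, w, ctr, frac * area, blob_shape())
      a <- sum(blob)
      ok <- a >= cfg$lesion_area_frac[1] * area - 1 &&
        a <= cfg$lesion_area_frac[2] * area + 1 &&
        sum(blob * mask) == 0
      if (ok) { mask <- pmin(mask + blob, 1); placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place lesion ", i,
           " after bounded retries; try a smaller lesion_area_frac")
  }
  # lesion interior: independently re-phased texture plus the contrast offset
  if (sum(mask) > 0) {
    lesion_tex <- correlated_noise(h, w, cfg$texture_scale)
    inside <- mask == 1
    for (c in 1:3) {
      plane <- img[, , c]
      tex <- rgb_lo[c] + lesion_tex * (rgb_hi[c] - rgb_lo[c])
      plane[inside] <- tex[inside] + cfg$contrast_delta
      img[, , c] <- plane
    }
  }
  # distractors: bright tooth-like blobs, kept off the (dilated) lesions
  if (cfg$distractors > 0) {
    keepout <- if (sum(mask) > 0) dilate_mask(mask, 6) else mask
    for (i in seq_len(cfg$distractors)) {
      for (try in 1:40) {
        ctr <- c(stats::runif(1, 0.1 * h, 0.9 * h), stats::runif(1, 0.1 * w, 0.9 * w))
        blob <- rasterize_blob(h, w, ctr, stats::runif(1, 0.005, 0.02) * area,
                               blob_shape(wobble = 0.15,
                                          aspect = stats::runif(1, 0.8, 1.3)))
        if (sum(blob * keepout) == 0) {
          shade <- stats::runif(1, 0.88, 0.98)
          for (c in 1:3) {
            plane <- img[, , c]
            plane[blob == 1] <- shade - (c == 3) * 0.06
            img[, , c] <- plane
          }
          break
        }
      }
    }
  }
  img <- round(pmin(pmax(img, 0), 1) * 255)
  structure(list(image = img, mask = mask,
                 id = sprintf("SYN_%03d", as.integer(index))),
            class = "image_sample")
}

#' Generate and write a synthetic dataset
#'
#' Writes lossless PNGs under the nnU-Net-style layout `imagesTr/` (image
#' files with the `_0000` channel suffix) and `labelsTr/` (masks with raw
#' pixel values {0,1}), plus a `manifest.csv`.
#'
#' @param cfg a [synthetic_config()]; `n` number of samples; `out_dir`
#'   destination directory.
#' @return data.frame manifest (id, image, mask, mask_area, contrast_delta).
#' @export
generate_dataset <- function(cfg, n, out_dir) {
  dir.create(file.path(out_dir, "imagesTr"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labelsTr"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_sample(cfg, i)
    img_file <- file.path("imagesTr", paste0(s$id, "_0000.png"))
    msk_file <- file.path("labelsTr", paste0(s$id, ".png"))
    png::writePNG(s$image / 255, file.path(out_dir, img_file))
    png::writePNG(s$mask / 255, file.path(out_dir, msk_file))
    rows[[i]] <- data.frame(id = s$id, image = img_file, mask = msk_file,
                            mask_area = sum(s$mask),
                            contrast_delta = cfg$contrast_delta)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
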
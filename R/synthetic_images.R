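#' Specification for a synthetic fundus-like image
#'
#' Collects the geometry, texture and lesion parameters of the synthetic
#' generator and validates them. The generator emulates the clinical
#' appearance cue of retinoblastoma on fundus photographs: a bright circular
#' retinal field on a dark surround and, for the diseased class, a
#' yellowish-white lesion blob with its own texture.
#'
#' @param width,height Image size in pixels (at least 32).
#' @param fundus_radius_frac Radius of the retinal disc as a fraction of
#'   `min(width, height)`, in (0, 0.5].
#' @param background_noise_sigma Standard deviation of the additive intensity
#'   noise on the retinal field, in 0-255 units.
#' @param tumor_radius_range Length-2 numeric, minimum and maximum lesion
#'   radius in pixels; the maximum must stay inside the retinal disc.
#' @param tumor_brightness_gain Multiplicative intensity gain of the lesion
#'   over the local field (> 1).
#' @param texture_scale Correlation length of the background texture, pixels.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec (including the seed) and the label.
#' @return An object of class `synthetic_image_spec`.
#' @export
#' @examples
#' spec <- image_spec(width = 64, height = 64, seed = 1)
image_spec <- function(width = 128, height = 128, fundus_radius_frac = 0.45,
                       background_noise_sigma = 8, tumor_radius_range = c(6, 14),
                       tumor_brightness_gain = 1.6, texture_scale = 4, seed = 1L) {
  check_number(width, "width", min = 32, integer = TRUE)
  check_number(height, "height", min = 32, integer = TRUE)
  check_number(fundus_radius_frac, "fundus_radius_frac", min = 1e-9, max = 0.5)
  check_number(background_noise_sigma, "background_noise_sigma", min = 0)
  if (!is.numeric(tumor_radius_range) || length(tumor_radius_range) != 2L ||
      tumor_radius_range[1] > tumor_radius_range[2]) {
    stop_invalid("tumor_radius_range", "must be (min, max) with min <= max")
  }
  radius_px <- fundus_radius_frac * min(width, height)
  if (tumor_radius_range[2] >= radius_px) {
    stop_invalid("tumor_radius_range", "max must be smaller than the fundus radius in pixels")
  }
  check_number(tumor_brightness_gain, "tumor_brightness_gain", min = 1 + 1e-9)
  check_number(texture_scale, "texture_scale", min = 1e-9)
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    fundus_radius_frac = fundus_radius_frac,
    background_noise_sigma = background_noise_sigma,
    tumor_radius_range = as.numeric(tumor_radius_range),
    tumor_brightness_gain = tumor_brightness_gain,
    texture_scale = texture_scale, seed = as.integer(seed)
  ), class = "synthetic_image_spec")
}

new_labeled_image <- function(pixels, label, tumor_mask = NULL) {
  stopifnot(label %in% c("healthy", "tumor"))
  if (identical(label, "tumor") && is.null(tumor_mask)) {
    stop("tumor-labelled images must carry a tumor_mask")
  }
  if (identical(label, "healthy")) tumor_mask <- NULL
  structure(list(pixels = pixels, label = label, tumor_mask = tumor_mask),
            class = "labeled_image")
}

#' Generate one synthetic fundus-like image
#'
#' Renders a bright circular retinal field with band-limited texture on a dark
#' surround. For `label = "tumor"` a disc-shaped lesion with elevated mean
#' intensity, a yellowish-white hue shift and a finer texture is placed fully
#' inside the field; its footprint is returned as the ground-truth mask.
#'
#' @param spec A [image_spec()] object.
#' @param label `"healthy"` or `"tumor"`.
#' @return A `labeled_image`: `pixels` is an H x W x 3 array in \[0, 255\],
#'   `tumor_mask` a binary H x W matrix (tumour images only).
#' @export
generate_fundus_image <- function(spec, label = c("healthy", "tumor")) {
  if (!inherits(spec, "synthetic_image_spec")) {
    stop_invalid("spec", "must be created by image_spec()")
  }
  label <- match.arg(label)
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  radius <- spec$fundus_radius_frac * min(w, h)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  dist2 <- (rr - cy)^2 + (cc - cx)^2
  disc <- dist2 <= radius^2

  with_seed(derive_seed(spec$seed, if (label == "tumor") 1L else 0L), {
    # radial falloff gives the photographic vignetting of real fundus shots
    falloff <- 1 - 0.35 * sqrt(dist2) / radius
    falloff[!disc] <- 0
    tex <- textured_noise(h, w, spec$texture_scale)
    base <- 170 * falloff + spec$background_noise_sigma * tex
    # fundus colour balance: strong red, moderate green, weak blue
    px <- array(0, dim = c(h, w, 3))
    px[, , 1] <- base * 1.00
    px[, , 2] <- base * 0.55
    px[, , 3] <- base * 0.30
    px[, , 1][!disc] <- 8
    px[, , 2][!disc] <- 6
    px[, , 3][!disc] <- 5

    tumor_mask <- NULL
    if (label == "tumor") {
      tr <- runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
      # lesion centre uniform in the disc, margin keeps the blob inside
      repeat {
        ty <- runif(1, cy - radius, cy + radius)
        tx <- runif(1, cx - radius, cx + radius)
        if ((ty - cy)^2 + (tx - cx)^2 <= (radius - tr - 1)^2) break
      }
      tmask <- (rr - ty)^2 + (cc - tx)^2 <= tr^2
      ttex <- textured_noise(h, w, max(1, spec$texture_scale / 2))
      gain <- spec$tumor_brightness_gain
      # yellowish-white: all channels raised, blue least suppressed afterwards
      for (ch in 1:3) {
        lift <- c(1.0, 1.45, 2.2)[ch]   # pushes G and B toward white
        v <- px[, , ch]
        v[tmask] <- v[tmask] * gain * lift +
          0.6 * spec$background_noise_sigma * ttex[tmask]
        px[, , ch] <- v
      }
      tumor_mask <- matrix(0L, h, w)
      tumor_mask[tmask] <- 1L
    }
    px <- clip(px, 0, 255)
    new_labeled_image(px, label, tumor_mask)
  })
}

#' Stamp saturated specular light spots onto an image
#'
#' Places `n_spots` fully saturated (value 255) discs inside the retinal
#' field, emulating the specular reflections that inpainting is meant to
#' remove. Returns both the altered image and the exact binary mask of the
#' modified pixels.
#'
#' @param image A `labeled_image`.
#' @param n_spots Number of spots (>= 0).
#' @param spot_radius Spot radius in pixels (> 0).
#' @param seed Integer seed for spot placement.
#' @return A list with elements `image` (the spotted `labeled_image`) and
#'   `mask` (binary H x W matrix marking exactly the altered pixels).
#' @export
add_light_spots <- function(image, n_spots, spot_radius = 3, seed = 1L) {
  stopifnot(inherits(image, "labeled_image"))
  check_number(n_spots, "n_spots", min = 0, integer = TRUE)
  if (!is.numeric(spot_radius) || spot_radius <= 0) {
    stop_invalid("spot_radius", "must be > 0")
  }
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  mask <- matrix(0L, h, w)
  if (n_spots == 0) {
    return(list(image = image, mask = mask))
  }
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  radius <- 0.45 * min(w, h)   # stay well inside the field
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  with_seed(seed, {
    for (i in seq_len(n_spots)) {
      repeat {
        sy <- runif(1, cy - radius, cy + radius)
        sx <- runif(1, cx - radius, cx + radius)
        if ((sy - cy)^2 + (sx - cx)^2 <= (radius - spot_radius - 1)^2) break
      }
      mask[(rr - sy)^2 + (cc - sx)^2 <= spot_radius^2] <- 1L
    }
  })
  sel <- mask == 1L
  if (is_rgb(px)) {
    for (ch in 1:3) { v <- px[, , ch]; v[sel] <- 255; px[, , ch] <- v }
  } else {
    px[sel] <- 255
  }
  list(image = new_labeled_image(px, image$label, image$tumor_mask), mask = mask)
}

#' Generate a labelled synthetic image dataset
#'
#' Exactly `round(n_images * tumor_fraction)` images carry the tumour label;
#' label order is a seeded shuffle. Each image gets its own seed derived from
#' the dataset seed by a fixed counter scheme, so datasets are reproducible
#' element-wise.
#'
#' @param spec A [image_spec()] (its `seed` field is superseded per image).
#' @param n_images Number of images (>= 1).
#' @param tumor_fraction Fraction of tumour-labelled images in \[0, 1\].
#' @param seed Dataset-level integer seed.
#' @return A list of `labeled_image` objects.
#' @export
generate_image_dataset <- function(spec, n_images, tumor_fraction = 0.5, seed = 1L) {
  check_number(n_images, "n_images", min = 1, integer = TRUE)
  check_number(tumor_fraction, "tumor_fraction", min = 0, max = 1)
  n_tumor <- round(n_images * tumor_fraction)
  labels <- c(rep("tumor", n_tumor), rep("healthy", n_images - n_tumor))
  ord <- with_seed(seed, sample.int(n_images))
  labels <- labels[ord]
  lapply(seq_len(n_images), function(i) {
    si <- spec
    si$seed <- derive_seed(seed, i)
    generate_fundus_image(si, labels[i])
  })
}
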
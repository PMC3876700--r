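#' Synthetic fundus phantom specification
#'
#' Parameterizes [generate_phantom()]: dark curved tubular vessels with a
#' Gaussian cross-section on a brighter textured background, optionally with
#' a bright specular-reflex stripe along the centerline of thick vessels.
#' Widths and contrasts are loosely modeled on low-resolution fundus imagery
#' (vessels 2-7 px) up to the high-resolution regime (up to ~40 px).
#'
#' @param shape Integer `c(height, width)`, each >= 32.
#' @param n_vessels Number of vessels to render (>= 0).
#' @param width_range Vessel full width at half maximum, in pixels.
#' @param tortuosity Sd of the per-step heading increment (radians); 0 gives
#'   straight vessels.
#' @param contrast Depth of the vessel intensity dip, in (0, 1).
#' @param reflex List: `enabled`, `min_width` (vessels at least this wide get
#'   a centerline reflex) and `brightness` (stripe height as a fraction of
#'   the vessel depth).
#' @param texture_amplitude Amplitude of the background mottle.
#' @param texture_scale Correlation length of the mottle in pixels.
#' @param noise_sigma Sd of the i.i.d. Gaussian pixel noise.
#' @param seed Integer seed; fixes all randomness of the phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(512L, 512L), n_vessels = 6L,
                         width_range = c(2, 7), tortuosity = 0.08,
                         contrast = 0.35,
                         reflex = list(enabled = TRUE, min_width = 10,
                                       brightness = 0.9),
                         texture_amplitude = 0.03, texture_scale = 8,
                         noise_sigma = 0.01, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 32L), n_vessels >= 0,
            all(width_range >= 1), width_range[1] <= width_range[2],
            contrast > 0, contrast < 1, tortuosity >= 0,
            texture_amplitude >= 0, texture_scale >= 2, noise_sigma >= 0)
  if (width_range[2] >= min(shape))
    .stopf("vessel width %g exceeds the image size", width_range[2])
  structure(list(shape = as.integer(shape), n_vessels = as.integer(n_vessels),
                 width_range = width_range, tortuosity = tortuosity,
                 contrast = contrast, reflex = reflex,
                 texture_amplitude = texture_amplitude,
                 texture_scale = texture_scale,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic fundus phantom with ground truth
#'
#' Renders an RGB image whose green channel holds a bright background (base
#' level 0.72 plus smooth low-frequency texture and Gaussian noise) and dark
#' vessels built as bounded-curvature random-walk tubes: each centerline is a
#' heading random walk, rasterized and turned into a tube by the Euclidean
#' distance transform, with a Gaussian cross-section whose full width at half
#' maximum is the vessel width. Vessels at least `reflex$min_width` wide
#' (when enabled) get a bright centerline stripe emulating the camera-flash
#' specular reflex. The ground-truth mask is the tube support at the
#' half-maximum radius. Output is deterministic in the seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a `fundus_image`) and `gold` (0/1 matrix).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    h <- spec$shape[1]; w <- spec$shape[2]
    green <- matrix(0.72, h, w) +
      .smooth_texture(h, w, spec$texture_amplitude, spec$texture_scale)
    gold <- matrix(0L, h, w)
    depth <- matrix(0, h, w)
    shine <- matrix(0, h, w)
    for (v in seq_len(spec$n_vessels)) {
      wid <- runif(1, spec$width_range[1], spec$width_range[2])
      d <- .centerline_distance(h, w, spec$tortuosity)
      sdv <- wid / (2 * sqrt(2 * log(2)))        # FWHM = wid
      depth <- pmax(depth, spec$contrast * exp(-d^2 / (2 * sdv^2)))
      gold[d <= wid / 2] <- 1L
      if (isTRUE(spec$reflex$enabled) && wid >= spec$reflex$min_width) {
        sr <- max(0.8, wid / 8)
        shine <- pmax(shine, spec$reflex$brightness * spec$contrast *
                        exp(-d^2 / (2 * sr^2)))
      }
    }
    green <- green - depth + shine
    if (spec$noise_sigma > 0)
      green <- green + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    green <- pmin(pmax(green, 0), 1)
    img <- array(0, dim = c(h, w, 3L))
    img[, , 1] <- pmin(green + 0.2, 1)           # red: near-saturated
    img[, , 2] <- green
    img[, , 3] <- pmax(green - 0.45, 0)          # blue: under-illuminated
    list(image = structure(img, class = "fundus_image",
                           source_path = NA_character_,
                           bit_depth = NA_integer_),
         gold = gold)
  })
}

# Background mottle: white noise on a coarse grid, bilinearly upsampled so
# its correlation length is `scale` pixels (fine-grained, like choroidal
# texture, rather than long coherent ridges).
.smooth_texture <- function(h, w, amplitude, scale = 8) {
  if (amplitude == 0) return(matrix(0, h, w))
  ch <- max(2L, as.integer(ceiling(h / scale)))
  cw <- max(2L, as.integer(ceiling(w / scale)))
  coarse <- matrix(rnorm(ch * cw), ch, cw)
  up <- upsample_to(coarse, c(h, w))
  amplitude * up / max(abs(up))
}

# Distance of every pixel to a random-walk centerline crossing the frame.
.centerline_distance <- function(h, w, tortuosity) {
  cl <- matrix(1, h, w)
  # start on a random border point heading inwards
  side <- sample.int(4L, 1L)
  pos <- switch(side,
                c(runif(1, 1, h), 1),        c(runif(1, 1, h), w),
                c(1, runif(1, 1, w)),        c(h, runif(1, 1, w)))
  heading <- switch(side, 0, pi, pi / 2, -pi / 2) + runif(1, -0.5, 0.5)
  steps <- as.integer(1.5 * max(h, w))
  for (s in seq_len(steps)) {
    r <- as.integer(round(pos[1])); c <- as.integer(round(pos[2]))
    if (r >= 1 && r <= h && c >= 1 && c <= w) cl[r, c] <- 0
    heading <- heading + rnorm(1, 0, tortuosity)
    nxt <- pos + c(sin(heading), cos(heading))
    # steer back when about to leave the frame
    if (nxt[1] < 2 || nxt[1] > h - 1 || nxt[2] < 2 || nxt[2] > w - 1) {
      ctr_dir <- atan2(h / 2 - pos[1], w / 2 - pos[2])
      heading <- ctr_dir + runif(1, -0.3, 0.3)
      nxt <- pos + c(sin(heading), cos(heading))
    }
    pos <- nxt
  }
  d <- EBImage::distmap(EBImage::Image(t(cl)))
  t(EBImage::imageData(d))
}

#' Fixed phantom battery for end-to-end checks
#'
#' Five categories exercising the regimes the pipeline must handle:
#' `thin` (2-4 px, no reflex), `thick_reflex` (12-40 px, bright centerline
#' reflexes), `mixed` (3-20 px), `null` (background only) and `low_contrast`
#' (half the usual vessel depth). Per-image seeds are derived from `seed`, so
#' the whole battery is reproducible.
#'
#' @param seed Integer master seed.
#' @param n_per_category Images per category.
#' @param shape Image shape, `c(height, width)`.
#' @return List of elements `list(image, gold, label)`.
#' @export
phantom_suite <- function(seed = 42L, n_per_category = 10L,
                          shape = c(512L, 512L)) {
  cats <- list(
    thin         = list(width_range = c(2, 4), n_vessels = 8L,
                        reflex = list(enabled = FALSE, min_width = 10,
                                      brightness = 0.9)),
    thick_reflex = list(width_range = c(12, 40), n_vessels = 2L,
                        reflex = list(enabled = TRUE, min_width = 10,
                                      brightness = 0.9)),
    mixed        = list(width_range = c(3, 16), n_vessels = 5L,
                        reflex = list(enabled = TRUE, min_width = 10,
                                      brightness = 0.9)),
    null         = list(width_range = c(2, 4), n_vessels = 0L,
                        reflex = list(enabled = FALSE, min_width = 10,
                                      brightness = 0.9)),
    low_contrast = list(width_range = c(2, 10), n_vessels = 6L,
                        contrast = 0.18,
                        reflex = list(enabled = FALSE, min_width = 10,
                                      brightness = 0.9)))
  out <- list()
  for (ci in seq_along(cats)) {
    label <- names(cats)[ci]
    for (i in seq_len(n_per_category)) {
      args <- c(list(shape = shape,
                     seed = seed * 1000L + ci * 100L + i), cats[[ci]])
      ph <- generate_phantom(do.call(phantom_spec, args))
      out[[length(out) + 1L]] <- list(image = ph$image, gold = ph$gold,
                                      label = label)
    }
  }
  out
}
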
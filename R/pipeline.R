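#' Default segmentation configuration
#'
#' Nested list mirroring the YAML config accepted by [load_config()] and the
#' CLI. Blocks: `preprocess` (stretch percentiles, bilateral sigmas,
#' `enabled`), `frangi` (sigma, beta, c), `pyramid` (`n_levels` `"auto"` or
#' integer, `max_vessel_width`, `literal_order`), `reflex` (`enabled`,
#' `levels` `"coarsest"` or `"all"`), `binarize` (`high_fraction`,
#' `low_fraction`, either scalars or one value per level), `postprocess`
#' (`enabled`, `thinning`, `close_kernel`, `min_object_px`, `max_hole_px`,
#' `scale_object_size`), and `backend` (`"hierarchy"` or
#' `"frangi_reference"`). `min_object_px` refers to a 565-px-wide frame and
#' is scaled by `(width/565)^2` when `scale_object_size` is TRUE.
#'
#' @return A `segmentation_config` list.
#' @export
default_config <- function() {
  structure(list(
    preprocess = list(enabled = TRUE, stretch_low_pct = 1,
                      stretch_high_pct = 99, bilateral_sigma_spatial = 3,
                      bilateral_sigma_range = 0.1),
    frangi = list(sigma = 1, beta = 0.5, c = "auto"),
    pyramid = list(n_levels = "auto", max_vessel_width = 40,
                   literal_order = FALSE),
    reflex = list(enabled = TRUE, levels = "coarsest"),
    binarize = list(high_fraction = 0.02, low_fraction = 0.12),
    postprocess = list(enabled = TRUE, thinning = TRUE, close_kernel = 3,
                       min_object_px = 50, max_hole_px = 50,
                       scale_object_size = TRUE),
    backend = "hierarchy",
    seed = 1L), class = "segmentation_config")
}

#' Load a YAML configuration, merged over the defaults
#'
#' @param path Path to a YAML file whose top-level keys mirror
#'   [default_config()]. Missing keys keep their defaults.
#' @return A `segmentation_config` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]]))
      modifyList(cfg[[k]], user[[k]]) else user[[k]]
  }
  .validate_config(cfg)
  cfg
}

#' Serialize a configuration to YAML
#'
#' @param cfg A `segmentation_config`.
#' @return A YAML string (also usable to dump the defaults).
#' @export
dump_config <- function(cfg = default_config()) {
  yaml::as.yaml(unclass(cfg))
}

.validate_config <- function(cfg) {
  if (!cfg$backend %in% c("hierarchy", "frangi_reference"))
    .stopf("unknown backend '%s'", cfg$backend)
  stopifnot(cfg$frangi$sigma > 0, cfg$frangi$beta > 0)
  b <- cfg$binarize
  stopifnot(all(b$high_fraction > 0), all(b$low_fraction < 1),
            all(b$high_fraction < b$low_fraction))
  invisible(cfg)
}

# Per-level binarization fractions (scalars recycled across levels).
.level_fractions <- function(cfg, k, n) {
  pick <- function(x) if (length(x) >= n) x[[k]] else x[[1]]
  hysteresis_params(high_fraction = pick(cfg$binarize$high_fraction),
                    low_fraction = pick(cfg$binarize$low_fraction))
}

#' Segment the vessel tree of a fundus image
#'
#' The hierarchy backend runs: green-channel extraction, histogram
#' stretching, bilateral denoising, intensity inversion (vessels are dark on
#' the green channel; the vesselness measure enhances bright ridges), a
#' halving Gaussian resolution hierarchy, single-scale vesselness
#' (sigma = 1) on every level, specular-reflex correction on the coarsest
#' level(s), bilinear upsampling of each response to full resolution,
#' per-level hysteresis binarization, OR-fusion, gradient-guided thinning,
#' 3x3 morphological closing and object-size cleanup. The
#' `frangi_reference` backend replaces hierarchy + per-level steps with the
#' classic linear sigma sweep (1 to `max_vessel_width`, step 1), a single
#' hysteresis binarization, closing and cleanup — no reflex correction or
#' thinning, matching the original formulation. Both backends are fully
#' deterministic.
#'
#' @param img A `fundus_image`, an h x w x 3 array, or a numeric matrix (then
#'   taken as the green channel directly).
#' @param cfg A `segmentation_config`; see [default_config()].
#' @param keep_intermediates Keep per-level vesselness maps and masks in the
#'   diagnostics attribute.
#' @return Integer 0/1 vessel mask with attribute `diagnostics`: a list with
#'   `n_levels`, `vesselness_pixels` (pixels of vesselness computation per
#'   level), `pixel_ratio` (their sum over the full-resolution pixel count),
#'   `thresholds`, and optionally the intermediates.
#' @export
segment <- function(img, cfg = default_config(), keep_intermediates = FALSE) {
  .validate_config(cfg)
  g <- if (is.matrix(img)) img else extract_green(img)
  if (isTRUE(cfg$preprocess$enabled)) {
    pp <- preprocess_params(cfg$preprocess$stretch_low_pct,
                            cfg$preprocess$stretch_high_pct,
                            cfg$preprocess$bilateral_sigma_spatial,
                            cfg$preprocess$bilateral_sigma_range)
    g <- denoise_bilateral(stretch_histogram(g, pp), pp)
  }
  inv <- 1 - g
  fp <- frangi_params(sigma = cfg$frangi$sigma, beta = cfg$frangi$beta,
                      c = cfg$frangi$c)
  diag <- list(backend = cfg$backend)

  if (cfg$backend == "frangi_reference") {
    vm <- multiscale_frangi_reference(inv, cfg$frangi$sigma,
                                      cfg$pyramid$max_vessel_width,
                                      sigma_step = 1, p = fp)
    diag$vesselness_pixels <- length(inv) * length(vm$sigmas)
    mask <- hysteresis_threshold(vm, .level_fractions(cfg, 1L, 1L))
    diag$thresholds <- list(c(t_high = attr(mask, "t_high"),
                              t_low = attr(mask, "t_low")))
    fused <- .as_mask(mask)
  } else {
    n <- cfg$pyramid$n_levels
    if (identical(n, "auto"))
      n <- choose_levels(dim(g), cfg$pyramid$max_vessel_width)
    # the derivative kernel (support 2*ceil(4 sigma) + 1) must fit into the
    # coarsest level; drop levels that a larger sigma cannot process
    support <- 2L * as.integer(ceiling(4 * cfg$frangi$sigma)) + 1L
    while (n > 1L && min(ceiling(dim(g) / 2^(n - 1L))) < support)
      n <- n - 1L
    hier_v <- build_hierarchy(inv, n, literal_order = cfg$pyramid$literal_order)
    hier_i <- build_hierarchy(g, n, literal_order = cfg$pyramid$literal_order)
    masks <- vector("list", n)
    counts <- integer(n)
    thr <- vector("list", n)
    vmaps <- if (keep_intermediates) vector("list", n) else NULL
    for (k in seq_len(n)) {
      lev <- hier_v$levels[[k]]
      counts[k] <- length(lev)
      vm <- vesselness(eigenvalues_sym2x2(hessian_at_scale(lev, fp$sigma)),
                       fp, level_index = k - 1L)
      apply_reflex <- isTRUE(cfg$reflex$enabled) && n > 1L &&
        (identical(cfg$reflex$levels, "all") || k == n)
      v0 <- if (apply_reflex)
        correct_specular_reflex(vm, hier_i$levels[[k]]) else vm$v0
      v0 <- upsample_to(v0, dim(g))
      if (keep_intermediates) vmaps[[k]] <- v0
      mk <- hysteresis_threshold(v0, .level_fractions(cfg, k, n))
      thr[[k]] <- c(t_high = attr(mk, "t_high"), t_low = attr(mk, "t_low"))
      masks[[k]] <- .as_mask(mk)
    }
    diag$n_levels <- n
    diag$vesselness_pixels <- counts
    diag$thresholds <- thr
    if (keep_intermediates) {
      diag$vesselness_maps <- vmaps
      diag$level_masks <- masks
    }
    fused <- fuse_or(masks)
  }
  diag$pixel_ratio <- sum(diag$vesselness_pixels) / length(g)

  out <- fused
  if (isTRUE(cfg$postprocess$enabled)) {
    if (cfg$backend == "hierarchy" && isTRUE(cfg$postprocess$thinning))
      out <- thin_to_gradient(out, g)
    out <- morph_close(out, size = as.integer(cfg$postprocess$close_kernel))
    min_obj <- cfg$postprocess$min_object_px
    if (isTRUE(cfg$postprocess$scale_object_size))
      min_obj <- max(1, round(min_obj * (ncol(g) / 565)^2))
    out <- clean_objects(out, min_obj, cfg$postprocess$max_hole_px)
  }
  attr(out, "diagnostics") <- diag
  out
}

#' Parameter-robustness ablation
#'
#' Re-runs [segment()] on a set of images under named config variants and
#' tabulates sensitivity, specificity and accuracy against the gold masks,
#' plus the accuracy change relative to the baseline — the experiment design
#' used to show that threshold and sigma perturbations move accuracy far
#' less than dropping whole processing stages.
#'
#' @param images List of inputs accepted by [segment()].
#' @param golds List of matching gold-standard 0/1 masks.
#' @param cfg Baseline `segmentation_config`.
#' @param ablation Named list of variants; each element is either a function
#'   `cfg -> cfg` or a named list of config paths (e.g.
#'   `list("frangi.sigma" = 2)`) assigning new values. Use
#'   [default_ablation()] for the standard battery.
#' @return data.frame with columns `variant`, `se`, `sp`, `acc`, `d_acc`.
#' @export
run_ablation <- function(images, golds, cfg = default_config(),
                         ablation = default_ablation()) {
  stopifnot(length(images) == length(golds), length(images) > 0)
  apply_variant <- function(cfg, spec) {
    if (is.function(spec)) return(spec(cfg))
    for (path in names(spec)) {
      keys <- strsplit(path, ".", fixed = TRUE)[[1]]
      if (length(keys) == 1L && is.null(cfg[[keys]]) )
        .stopf("unknown config field '%s'", path)
      if (length(keys) == 2L) {
        if (is.null(cfg[[keys[1]]]) || !keys[2] %in% names(cfg[[keys[1]]]))
          .stopf("unknown config field '%s'", path)
        cfg[[keys[1]]][[keys[2]]] <- spec[[path]]
      } else cfg[[keys]] <- spec[[path]]
    }
    cfg
  }
  variants <- c(list(baseline = list()), ablation)
  rows <- lapply(names(variants), function(nm) {
    vcfg <- apply_variant(cfg, variants[[nm]])
    .validate_config(vcfg)
    ev <- lapply(seq_along(images), function(i)
      evaluate(segment(images[[i]], vcfg), golds[[i]]))
    data.frame(variant = nm,
               se = mean(vapply(ev, `[[`, numeric(1), "sensitivity")),
               sp = mean(vapply(ev, `[[`, numeric(1), "specificity")),
               acc = mean(vapply(ev, `[[`, numeric(1), "accuracy")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$d_acc <- out$acc - out$acc[out$variant == "baseline"]
  out
}

#' Calibrate binarization fractions for an imaging protocol
#'
#' The percent-of-pixels thresholds depend on the vessel/background ratio of
#' the imaging protocol (field of view, resolution), so they are meant to be
#' optimized once per protocol on a small subset of images with gold
#' standards, maximizing accuracy. This performs that optimization over a
#' small grid: the level-0 fractions are scaled globally by `scales` and
#' decayed geometrically across levels by `decays` (coarse levels resolve
#' only thick vessels, so the fraction of genuinely vessel-like pixels
#' shrinks with depth). The candidate with the highest mean accuracy on the
#' calibration images wins.
#'
#' @param images List of calibration inputs accepted by [segment()].
#' @param golds Matching gold-standard 0/1 masks.
#' @param cfg Base `segmentation_config`.
#' @param scales Global multipliers tried on both fractions.
#' @param decays Per-level geometric decay factors tried.
#' @return `cfg` with `binarize$high_fraction` / `low_fraction` replaced by
#'   the winning per-level vectors, and an attribute `calibration` holding
#'   the grid results.
#' @export
calibrate_fractions <- function(images, golds, cfg = default_config(),
                                scales = c(0.6, 0.8, 1, 1.2),
                                decays = c(1, 0.8, 0.6)) {
  stopifnot(length(images) == length(golds), length(images) > 0)
  dims <- dim(if (is.matrix(images[[1]])) images[[1]] else
    extract_green(images[[1]]))
  n <- cfg$pyramid$n_levels
  if (identical(n, "auto"))
    n <- choose_levels(dims, cfg$pyramid$max_vessel_width)
  h0 <- cfg$binarize$high_fraction[[1]]
  l0 <- cfg$binarize$low_fraction[[1]]
  grid <- expand.grid(scale = scales, decay = decays)
  grid$acc <- NA_real_
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    vcfg <- cfg
    k <- seq_len(n) - 1L
    hi <- pmax(5e-4, h0 * grid$scale[g] * grid$decay[g]^k)
    vcfg$binarize$high_fraction <- hi
    vcfg$binarize$low_fraction <-
      pmax(2 * hi, pmin(0.9, l0 * grid$scale[g] * grid$decay[g]^k))
    acc <- mean(vapply(seq_along(images), function(i)
      evaluate(segment(images[[i]], vcfg), golds[[i]])$accuracy, numeric(1)))
    grid$acc[g] <- acc
    if (is.null(best) || acc > best$acc) best <- list(acc = acc, cfg = vcfg)
  }
  out <- best$cfg
  attr(out, "calibration") <- grid
  out
}

#' Calibrated configuration for the synthetic phantom protocol
#'
#' Applies the package's protocol-calibration workflow to the phantom
#' imaging protocol of [phantom_suite()]: binarization fractions are
#' optimized with [calibrate_fractions()] on three calibration phantoms
#' (one per width regime, with seeds disjoint from any evaluation suite
#' derived from the same master seed), and the specular-reflex correction is
#' applied on every pyramid level — phantom reflex stripes are an eighth of
#' the vessel width, hence sub-pixel at the coarsest level, so the 3x3
#' correction must act at the levels where the stripe is about 1 px wide.
#'
#' @param seed Master seed; calibration phantoms use seeds derived from it.
#' @param shape Protocol image shape.
#' @return A calibrated `segmentation_config`.
#' @export
phantom_protocol_config <- function(seed = 42L, shape = c(512L, 512L)) {
  base_reflex <- list(enabled = TRUE, min_width = 10, brightness = 0.9)
  cal_specs <- list(
    phantom_spec(shape = shape, n_vessels = 5L, width_range = c(3, 16),
                 reflex = base_reflex, seed = seed * 1000L + 901L),
    phantom_spec(shape = shape, n_vessels = 8L, width_range = c(2, 4),
                 reflex = modifyList(base_reflex, list(enabled = FALSE)),
                 seed = seed * 1000L + 902L),
    phantom_spec(shape = shape, n_vessels = 2L, width_range = c(12, 40),
                 reflex = base_reflex, seed = seed * 1000L + 903L))
  cal <- lapply(cal_specs, generate_phantom)
  cfg <- default_config()
  cfg$reflex$levels <- "all"
  calibrate_fractions(lapply(cal, `[[`, "image"), lapply(cal, `[[`, "gold"),
                      cfg, scales = c(0.5, 0.7, 0.85, 1, 1.2),
                      decays = c(1, 0.8, 0.6, 0.45, 0.3))
}

#' Standard ablation battery
#'
#' Baseline plus: binarization fractions shifted by -/+ 1 percentage point,
#' preprocessing skipped, postprocessing skipped, doubled closing kernel
#' (3 -> 5, nearest odd), and Hessian sigma 2, 3, 4.
#'
#' @param threshold_delta Percentage-point shift of both fractions.
#' @return Named list of variants for [run_ablation()].
#' @export
default_ablation <- function(threshold_delta = 0.01) {
  shift <- function(d) function(cfg) {
    hi <- pmax(5e-4, cfg$binarize$high_fraction + d)
    cfg$binarize$high_fraction <- hi
    cfg$binarize$low_fraction <-
      pmax(2 * hi, pmin(0.98, cfg$binarize$low_fraction + d))
    cfg
  }
  list(
    thresholds_down = shift(-threshold_delta),
    thresholds_up = shift(threshold_delta),
    no_preprocess = list("preprocess.enabled" = FALSE),
    no_postprocess = list("postprocess.enabled" = FALSE),
    double_kernel = list("postprocess.close_kernel" = 5),
    sigma_2 = list("frangi.sigma" = 2),
    sigma_3 = list("frangi.sigma" = 3),
    sigma_4 = list("frangi.sigma" = 4))
}
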
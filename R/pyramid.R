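#' Number of pyramid levels for a target vessel width
#'
#' With the filter scale fixed at sigma = 1, a level resolves vessels about
#' `w0 = 4` px wide at that level's resolution; each halving doubles the
#' width reachable at full resolution. Hence
#' `n = max(2, ceil(log2(max_vessel_width / w0)) + 1)`, capped so the
#' coarsest level stays at least 8 x 8. Low-resolution fundus images
#' (vessels up to ~8-10 px) need 2-3 levels; high-resolution images with
#' vessels up to ~40 px need 5.
#'
#' @param img_shape Integer vector `c(height, width)`.
#' @param max_vessel_width Thickest expected vessel in pixels (>= 1).
#' @param w0 Width well captured by sigma = 1 at native resolution.
#' @return Integer number of levels (level 0 = original resolution).
#' @export
choose_levels <- function(img_shape, max_vessel_width, w0 = 4) {
  stopifnot(max_vessel_width >= 1, length(img_shape) >= 2)
  n <- max(2L, as.integer(ceiling(log2(max_vessel_width / w0)) + 1))
  min(n, .max_levels(img_shape))
}

# Largest level count keeping the coarsest level >= 8 x 8.
.max_levels <- function(img_shape) {
  h <- img_shape[1]; w <- img_shape[2]
  k <- 1L
  while (ceiling(h / 2^k) >= 8 && ceiling(w / 2^k) >= 8) k <- k + 1L
  k
}

#' Build the halving resolution hierarchy
#'
#' Level 0 is the input unmodified; each further level is the previous one
#' smoothed with a Gaussian anti-alias kernel (sigma = 1) and then decimated
#' by taking every second pixel starting at index 0 (so an odd dimension `d`
#' becomes `ceil(d / 2)`). `literal_order = TRUE` decimates before smoothing
#' instead — that ordering aliases and exists only for comparison.
#'
#' @param img Numeric matrix.
#' @param n_levels Number of levels (>= 1); the coarsest must be >= 8 x 8.
#' @param sigma_aa Anti-alias Gaussian sd.
#' @param literal_order Decimate before smoothing (not recommended).
#' @return A `resolution_hierarchy`: list with `levels` (list of matrices)
#'   and `n_levels`.
#' @export
build_hierarchy <- function(img, n_levels, sigma_aa = 1,
                            literal_order = FALSE) {
  .check_matrix(img)
  stopifnot(n_levels >= 1)
  cap <- .max_levels(dim(img))
  if (n_levels > cap)
    .stopf("n_levels = %d too many for a %d x %d image (max %d so the coarsest level stays >= 8 x 8)",
           n_levels, nrow(img), ncol(img), cap)
  k0 <- .gauss_kernel(sigma_aa, 0L)
  levels <- vector("list", n_levels)
  levels[[1]] <- img
  for (k in seq_len(n_levels - 1L)) {
    prev <- levels[[k]]
    if (literal_order) {
      dec <- prev[seq(1L, nrow(prev), by = 2L), seq(1L, ncol(prev), by = 2L),
                  drop = FALSE]
      levels[[k + 1L]] <- .sep_conv_cpp(dec, k0, k0)
    } else {
      sm <- .sep_conv_cpp(prev, k0, k0)
      levels[[k + 1L]] <- sm[seq(1L, nrow(sm), by = 2L),
                             seq(1L, ncol(sm), by = 2L), drop = FALSE]
    }
  }
  structure(list(levels = levels, n_levels = n_levels),
            class = "resolution_hierarchy")
}

#' Bilinear upsampling to a target shape
#'
#' Align-corners bilinear interpolation: the corner pixels of the coarse grid
#' map onto the corner pixels of the target grid. Being a convex combination
#' of source pixels, the output never exceeds the source extremes. Requesting
#' the identical shape returns the input bit-identically.
#'
#' @param map A `vesselness_map` or numeric matrix.
#' @param target_shape Integer `c(height, width)`, each >= the source dims.
#' @return Numeric matrix of the target shape.
#' @export
upsample_to <- function(map, target_shape) {
  m <- .v0(map)
  th <- as.integer(target_shape[1]); tw <- as.integer(target_shape[2])
  sh <- nrow(m); sw <- ncol(m)
  if (th < sh || tw < sw)
    .stopf("upsample_to: target %d x %d smaller than source %d x %d",
           th, tw, sh, sw)
  if (th == sh && tw == sw) return(m)
  ry <- .lin_coords(sh, th)
  rx <- .lin_coords(sw, tw)
  # interpolate rows, then columns
  a <- m[ry$i0, , drop = FALSE] * (1 - ry$f) + m[ry$i1, , drop = FALSE] * ry$f
  t(t(a[, rx$i0, drop = FALSE]) * (1 - rx$f) +
    t(a[, rx$i1, drop = FALSE]) * rx$f)
}

.lin_coords <- function(n_src, n_dst) {
  pos <- if (n_src == 1L) rep(0, n_dst)
         else (seq_len(n_dst) - 1) * (n_src - 1) / (n_dst - 1)
  i0 <- pmin(floor(pos), n_src - 1)
  f <- pos - i0
  list(i0 = as.integer(i0) + 1L, i1 = as.integer(pmin(i0 + 1, n_src - 1)) + 1L,
       f = f)
}
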
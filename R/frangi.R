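#' Frangi vesselness parameters
#'
#' Sensitivity constants of the vesselness measure. `beta` controls how hard
#' blob-like structures (eigenvalue ratio near 1) are suppressed; `c` sets the
#' scale of the second-order structuredness term that separates structure from
#' flat background noise. `c = "auto"` resolves to half the maximum of
#' S = sqrt(lambda1^2 + lambda2^2) over the image, the usual convention when
#' no value is calibrated. The printed equation enhances bright ridges
#' (responses are zeroed where lambda2 > 0); dark vessels are handled by
#' inverting the input image in the pipeline rather than by flipping signs
#' here, so the measure is applied verbatim.
#'
#' @param sigma Gaussian-derivative scale in pixels (> 0).
#' @param beta Blob-dissimilarity sensitivity (> 0); default 0.5.
#' @param c Structuredness sensitivity (> 0) or `"auto"`.
#' @return A `frangi_params` list.
#' @export
frangi_params <- function(sigma = 1, beta = 0.5, c = "auto") {
  stopifnot(is.numeric(sigma), sigma > 0, is.numeric(beta), beta > 0)
  if (!(identical(c, "auto") || (is.numeric(c) && c > 0)))
    .stopf("'c' must be a positive number or \"auto\"")
  structure(list(sigma = sigma, beta = beta, c = c), class = "frangi_params")
}

# Sampled Gaussian-derivative kernels, truncated at 4*sigma, with discrete
# moment corrections so that order 0 sums to 1 exactly, order 1 annihilates
# constants and responds to f(x)=x with 1, and order 2 annihilates constants
# and responds to f(x)=x^2 with 2.
.gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = { k <- x * g; k / sum(x * k) },
         "2" = { k <- (x^2 - sigma^2) * g
                 k <- k - mean(k)              # exact zero DC
                 k / sum(x^2 * k / 2) },
         .stopf("unsupported derivative order %s", order))
}

#' Scale-normalized Hessian of an image
#'
#' Second-order Gaussian derivatives at scale `sigma` by separable
#' convolution (kernels truncated at 4 sigma, symmetric border reflection),
#' multiplied by the gamma-normalization factor sigma^2 so that responses at
#' different scales are comparable.
#'
#' @param img Numeric matrix.
#' @param sigma Derivative scale in pixels (> 0). The image must be at least
#'   as large as the kernel support on each side.
#' @return A `hessian_field` list with matrices `hxx`, `hxy`, `hyy` and the
#'   scale `sigma`. `x` is the column direction, `y` the row direction.
#' @export
hessian_at_scale <- function(img, sigma) {
  .check_matrix(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    .stopf("sigma must be a single positive number")
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  if (min(dim(img)) < 2L * r + 1L)
    .stopf("image (%d x %d) smaller than the derivative kernel support (%d)",
           nrow(img), ncol(img), 2L * r + 1L)
  k0 <- .gauss_kernel(sigma, 0L)
  k1 <- .gauss_kernel(sigma, 1L)
  k2 <- .gauss_kernel(sigma, 2L)
  s2 <- sigma^2
  structure(list(
    hxx = s2 * .sep_conv_cpp(img, k2, k0),
    hxy = s2 * .sep_conv_cpp(img, k1, k1),
    hyy = s2 * .sep_conv_cpp(img, k0, k2),
    sigma = sigma), class = "hessian_field")
}

#' Eigenvalues of a field of symmetric 2x2 matrices
#'
#' Closed form: m +/- sqrt(d^2 + hxy^2) with m = (hxx+hyy)/2 and
#' d = (hxx-hyy)/2, ordered by magnitude so that |lambda1| <= |lambda2| at
#' every pixel (the ordering under which the eigenvalue ratio behaves as a
#' blob/line dissimilarity measure). An exact magnitude tie with opposite
#' signs assigns the more negative value to lambda2, which favors detection
#' of dark-on-inverted (bright) ridges.
#'
#' @param h A `hessian_field` from [hessian_at_scale()].
#' @return An `eigen_pair` list with matrices `lambda1`, `lambda2`.
#' @export
eigenvalues_sym2x2 <- function(h) {
  stopifnot(inherits(h, "hessian_field") ||
              all(c("hxx", "hxy", "hyy") %in% names(h)))
  m <- (h$hxx + h$hyy) / 2
  d <- (h$hxx - h$hyy) / 2
  r <- sqrt(d * d + h$hxy * h$hxy)
  ea <- m + r                      # ea >= eb always
  eb <- m - r
  swap <- abs(ea) > abs(eb)        # tie goes to eb (more negative) as lambda2
  lambda2 <- ifelse(swap, ea, eb)
  lambda1 <- ifelse(swap, eb, ea)
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "eigen_pair")
}

#' Single-scale Frangi vesselness
#'
#' For each pixel, with eigenvalues ordered |lambda1| <= |lambda2|:
#' \deqn{R_B = \lambda_1/\lambda_2, \quad S = \sqrt{\lambda_1^2+\lambda_2^2}}
#' \deqn{V_0 = \cases{0 & \lambda_2 > 0 \cr
#'   \exp(-R_B^2/2\beta^2)\,(1-\exp(-S^2/2c^2)) & otherwise}}
#' Pixels with lambda2 = 0 are also set to 0 (the ratio is undefined there
#' and S is ~0 anyway). With `c = "auto"`, c is half the maximum of S over
#' the image; if S is identically zero the map is all zeros and a warning is
#' emitted.
#'
#' @param e An `eigen_pair` from [eigenvalues_sym2x2()].
#' @param p A [frangi_params()] object.
#' @param level_index Optional pyramid level tag carried on the result.
#' @return A `vesselness_map` list: matrix `v0` in `[0, 1)`, the resolved
#'   `c`, and `level_index`.
#' @export
vesselness <- function(e, p = frangi_params(), level_index = 0L) {
  stopifnot(inherits(e, "eigen_pair") ||
              all(c("lambda1", "lambda2") %in% names(e)))
  l1 <- e$lambda1; l2 <- e$lambda2
  s2 <- l1 * l1 + l2 * l2
  cc <- p$c
  if (identical(cc, "auto")) {
    smax <- sqrt(max(s2))
    if (smax == 0) {
      warning("vesselness: S is identically zero; returning an all-zero map",
              call. = FALSE)
      return(structure(list(v0 = array(0, dim(l1)), c = NA_real_,
                            level_index = level_index),
                       class = "vesselness_map"))
    }
    cc <- smax / 2
  }
  v0 <- matrix(0, nrow(l1), ncol(l1))
  ok <- l2 < 0                         # zero where lambda2 >= 0
  rb2 <- (l1[ok] / l2[ok])^2
  v0[ok] <- exp(-rb2 / (2 * p$beta^2)) * (1 - exp(-s2[ok] / (2 * cc^2)))
  structure(list(v0 = v0, c = cc, level_index = level_index),
            class = "vesselness_map")
}

# Accept either a vesselness_map or a bare matrix.
.v0 <- function(v) {
  if (inherits(v, "vesselness_map") || (is.list(v) && !is.null(v$v0)))
    return(v$v0)
  .check_matrix(v, "vesselness map")
  v
}

#' Reference multiscale Frangi filter
#'
#' The original formulation: sweep the Gaussian scale linearly from
#' `sigma_min` to `sigma_max` and combine per-scale vesselness maps by a
#' pixelwise maximum. Comparability of the per-scale responses is provided by
#' the sigma^2 gamma-normalization of the second derivatives (the "weight" of
#' the maximum projection). Used by the comparison backend of [segment()];
#' the hierarchy backend replaces the sweep with a resolution pyramid.
#'
#' @param img Numeric matrix (already inverted if vessels are dark).
#' @param sigma_min,sigma_max,sigma_step Scale sweep, `sigma_min <= sigma_max`,
#'   step defaults to 1 (increments of 1 up to the thickest expected vessel).
#' @param p A [frangi_params()] object; its `sigma` field is ignored in favor
#'   of the sweep, `c = "auto"` is resolved per scale.
#' @return A `vesselness_map` whose `v0` is the pixelwise maximum over scales.
#' @export
multiscale_frangi_reference <- function(img, sigma_min, sigma_max,
                                        sigma_step = 1,
                                        p = frangi_params()) {
  .check_matrix(img)
  if (sigma_min > sigma_max) .stopf("empty scale range [%g, %g]",
                                    sigma_min, sigma_max)
  sigmas <- seq(sigma_min, sigma_max, by = sigma_step)
  vmax <- NULL
  for (s in sigmas) {
    ps <- p; ps$sigma <- s
    v <- vesselness(eigenvalues_sym2x2(hessian_at_scale(img, s)), ps)$v0
    vmax <- if (is.null(vmax)) v else pmax(vmax, v)
  }
  structure(list(v0 = vmax, c = p$c, level_index = NA_integer_,
                 sigmas = sigmas), class = "vesselness_map")
}
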
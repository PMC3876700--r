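test_that("Hessian of a constant image is zero, of x^2 is 2 sigma^2", {
  h <- hessian_at_scale(matrix(0.7, 32, 32), 1)
  expect_lt(max(abs(h$hxx), abs(h$hxy), abs(h$hyy)), 1e-14)

  # f(x, y) = x^2 with x the 0-based column index
  n <- 48
  img <- matrix(rep((0:(n - 1))^2, each = n), n, n)
  for (sigma in c(1, 2)) {
    h <- hessian_at_scale(img, sigma)
    r <- ceiling(4 * sigma)
    interior <- (r + 2):(n - r - 1)
    expect_equal(h$hxx[interior, interior],
                 matrix(2 * sigma^2, length(interior), length(interior)),
                 tolerance = 0.01)
    expect_lt(max(abs(h$hxy[interior, interior])), 1e-8)
    expect_lt(max(abs(h$hyy[interior, interior])), 1e-8)
  }
})

test_that("hyy is most negative on the centerline of a horizontal ridge", {
  n <- 41
  ridge <- matrix(rep(exp(-((1:n) - 21)^2 / (2 * 2^2)), n), n, n,
                  byrow = FALSE)  # bright band across rows, centered row 21
  h <- hessian_at_scale(ridge, 2)
  expect_equal(unname(apply(h$hyy[, 10:30], 2, which.min)),
               rep(21L, 21))
})

test_that("hessian_at_scale equals dense explicit-kernel convolution", {
  img <- random_matrix(28, 33, seed = 12)
  sigma <- 1.5
  k0 <- retivess:::.gauss_kernel(sigma, 0L)
  k1 <- retivess:::.gauss_kernel(sigma, 1L)
  k2 <- retivess:::.gauss_kernel(sigma, 2L)
  h <- hessian_at_scale(img, sigma)
  expect_equal(h$hxx, sigma^2 * dense_conv2(img, outer(k0, k2)),
               tolerance = 1e-8)
  expect_equal(h$hyy, sigma^2 * dense_conv2(img, outer(k2, k0)),
               tolerance = 1e-8)
  expect_equal(h$hxy, sigma^2 * dense_conv2(img, outer(k1, k1)),
               tolerance = 1e-8)
})

test_that("sigma and size preconditions are enforced", {
  expect_error(hessian_at_scale(matrix(0, 32, 32), -1), "sigma")
  expect_error(hessian_at_scale(matrix(0, 10, 10), 2), "smaller")
})

test_that("closed-form eigenvalues match the magnitude-ordering contract", {
  ep <- eigenvalues_sym2x2(list(hxx = matrix(2), hxy = matrix(0),
                                hyy = matrix(0)))
  expect_equal(c(ep$lambda1, ep$lambda2), c(0, 2))
  # magnitude tie broken toward the more negative value as lambda2
  ep <- eigenvalues_sym2x2(list(hxx = matrix(0), hxy = matrix(1),
                                hyy = matrix(0)))
  expect_equal(c(ep$lambda1, ep$lambda2), c(1, -1))
})

test_that("eigenvalues agree with a general symmetric eigensolver", {
  set.seed(33)
  n <- 1000
  hxx <- matrix(rnorm(n), 1); hyy <- matrix(rnorm(n), 1)
  hxy <- matrix(rnorm(n), 1)
  ep <- eigenvalues_sym2x2(list(hxx = hxx, hxy = hxy, hyy = hyy))
  for (i in seq_len(n)) {
    ev <- eigen(matrix(c(hxx[i], hxy[i], hxy[i], hyy[i]), 2, 2),
                symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(c(ep$lambda1[i], ep$lambda2[i])), sort(ev),
                 tolerance = 1e-10)
    expect_lte(abs(ep$lambda1[i]), abs(ep$lambda2[i]))
  }
})

test_that("trace and determinant identities hold on random fields", {
  h <- list(hxx = random_matrix(40, 40, 1), hxy = random_matrix(40, 40, 2),
            hyy = random_matrix(40, 40, 3))
  ep <- eigenvalues_sym2x2(h)
  expect_equal(ep$lambda1 + ep$lambda2, h$hxx + h$hyy, tolerance = 1e-8)
  expect_equal(ep$lambda1 * ep$lambda2, h$hxx * h$hyy - h$hxy^2,
               tolerance = 1e-8)
})

test_that("vesselness follows the analytic formula", {
  p <- frangi_params(beta = 0.5, c = 1)
  # any lambda2 > 0 -> exactly zero
  ep <- list(lambda1 = matrix(c(0, 0.1, -0.2), 1),
             lambda2 = matrix(c(0.5, 1, 2), 1))
  expect_true(all(vesselness(ep, p)$v0 == 0))
  # ideal line: lambda1 = 0, lambda2 = -L, c = L/2  ->  1 - exp(-2)
  L <- 3
  ep <- list(lambda1 = matrix(0), lambda2 = matrix(-L))
  v <- vesselness(ep, frangi_params(beta = 0.5, c = L / 2))
  expect_equal(v$v0[1, 1], 1 - exp(-2), tolerance = 1e-12)
  # ideal blob: lambda1 = lambda2 = -L -> attenuated by exp(-1/(2 beta^2))
  epb <- list(lambda1 = matrix(-L), lambda2 = matrix(-L))
  vb <- vesselness(epb, frangi_params(beta = 0.5, c = L / 2))
  s2 <- 2 * L^2
  expect_equal(vb$v0[1, 1], exp(-2) * (1 - exp(-s2 / (2 * (L / 2)^2))),
               tolerance = 1e-12)
  # lambda2 == 0 pixels are defined background
  ep0 <- list(lambda1 = matrix(0), lambda2 = matrix(0))
  expect_equal(vesselness(ep0, p)$v0[1, 1], 0)
})

test_that("vesselness map stays in [0, 1) and zero where lambda2 >= 0", {
  img <- random_matrix(48, 48, seed = 14)
  ep <- eigenvalues_sym2x2(hessian_at_scale(img, 1))
  v <- vesselness(ep, frangi_params())
  expect_true(all(v$v0 >= 0 & v$v0 < 1))
  expect_true(all(v$v0[ep$lambda2 >= 0] == 0))
  # degenerate all-zero field with c = "auto"
  ep0 <- list(lambda1 = matrix(0, 4, 4), lambda2 = matrix(0, 4, 4))
  expect_warning(v0 <- vesselness(ep0, frangi_params()), "zero")
  expect_true(all(v0$v0 == 0))
})

test_that("vesselness is invariant to adding a constant to the image", {
  img <- random_matrix(40, 40, seed = 15)
  v1 <- vesselness(eigenvalues_sym2x2(hessian_at_scale(img, 1)))
  v2 <- vesselness(eigenvalues_sym2x2(hessian_at_scale(img + 0.25, 1)))
  expect_equal(v1$v0, v2$v0, tolerance = 1e-10)
})

test_that("vesselness is equivariant under 90-degree rotation", {
  img <- random_matrix(36, 36, seed = 16)
  v <- vesselness(eigenvalues_sym2x2(hessian_at_scale(img, 1)),
                  frangi_params(c = 0.5))$v0
  vr <- vesselness(eigenvalues_sym2x2(
    hessian_at_scale(rot90 <- t(img)[ncol(img):1, ], 1)),
    frangi_params(c = 0.5))$v0
  expect_equal(vr, t(v)[ncol(v):1, ], tolerance = 1e-12)
})

test_that("multiscale reference reduces to single scale and is monotone", {
  img <- random_matrix(40, 40, seed = 17)
  p <- frangi_params(c = 0.6)
  single <- vesselness(eigenvalues_sym2x2(hessian_at_scale(img, 1)), p)$v0
  ref <- multiscale_frangi_reference(img, 1, 1, p = p)$v0
  expect_identical(ref, single)
  sub <- multiscale_frangi_reference(img, 1, 2, p = p)$v0
  sup <- multiscale_frangi_reference(img, 1, 4, p = p)$v0
  expect_true(all(sup >= sub))
  expect_error(multiscale_frangi_reference(img, 3, 1), "empty")
})

test_that("the scale sweep peaks near the theoretically matched sigma", {
  # Gaussian ridge with sd t: gamma-normalized response peaks at sqrt(2) t
  n <- 64
  t_sd <- 6 / (2 * sqrt(2 * log(2)))   # width-6 ridge (FWHM)
  ridge <- matrix(rep(exp(-((1:n) - n / 2)^2 / (2 * t_sd^2)), each = n), n, n)
  p <- frangi_params(c = 0.05)
  resp <- vapply(1:6, function(s)
    max(vesselness(eigenvalues_sym2x2(hessian_at_scale(ridge, s)), p)$v0),
    numeric(1))
  expect_lte(abs(which.max(resp) - sqrt(2) * t_sd), 1)
})
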
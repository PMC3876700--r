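test_that("extract_green selects channel 2 scaled to [0,1]", {
  a <- array(0, dim = c(16, 16, 3))
  a[, , 1] <- 200 / 255; a[, , 2] <- 100 / 255; a[, , 3] <- 10 / 255
  g <- extract_green(a)
  expect_equal(g[1, 1], 100 / 255)
  expect_equal(dim(g), c(16L, 16L))
  expect_true(all(extract_green(array(0, dim = c(16, 16, 3))) == 0))
})

test_that("histogram stretching maps the percentile window linearly", {
  p <- preprocess_params(stretch_low_pct = 0, stretch_high_pct = 100)
  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  expect_equal(stretch_histogram(ramp, p), ramp, tolerance = 1e-12)
  trio <- matrix(c(0.4, 0.5, 0.6), 3, 3)
  expect_equal(stretch_histogram(trio, p), matrix(c(0, 0.5, 1), 3, 3),
               tolerance = 1e-12)
  expect_warning(out <- stretch_histogram(matrix(0.3, 8, 8), p), "constant")
  expect_equal(out, matrix(0.3, 8, 8))
})

test_that("histogram stretching is monotone non-decreasing", {
  img <- random_matrix(30, 30, seed = 8)
  out <- stretch_histogram(img, preprocess_params())
  o <- order(img)
  expect_true(all(diff(out[o]) >= 0))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("bilateral filter matches a direct dense-loop reference", {
  # independent reference: textbook definition, plain R loops
  bilateral_ref <- function(img, ss, sr, radius) {
    nr <- nrow(img); nc <- ncol(img)
    refl <- function(i, n) { while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
    out <- img
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      num <- 0; den <- 0
      for (di in -radius:radius) for (dj in -radius:radius) {
        v <- img[refl(i + di, nr), refl(j + dj, nc)]
        w <- exp(-(di^2 + dj^2) / (2 * ss^2)) *
          exp(-(v - img[i, j])^2 / (2 * sr^2))
        num <- num + w * v; den <- den + w
      }
      out[i, j] <- num / den
    }
    out
  }
  img <- random_matrix(14, 17, seed = 21)
  p <- preprocess_params(bilateral_sigma_spatial = 2,
                         bilateral_sigma_range = 0.15)
  expect_equal(denoise_bilateral(img, p),
               bilateral_ref(img, 2, 0.15, 4), tolerance = 1e-12)
})

test_that("bilateral filter smooths noise but preserves strong edges", {
  p <- preprocess_params()
  # constant image untouched
  expect_equal(denoise_bilateral(matrix(0.4, 20, 20), p), matrix(0.4, 20, 20),
               tolerance = 1e-6)
  # variance of i.i.d. noise strictly reduced
  set.seed(9)
  noisy <- matrix(0.5 + rnorm(40 * 40, 0, 0.05), 40, 40)
  den <- denoise_bilateral(noisy, p)
  expect_lt(var(as.vector(den)), var(as.vector(noisy)))
  expect_true(all(den >= 0 & den <= 1))
  # total variation reduced on pure noise
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  expect_lt(tv(den), tv(noisy))
  # ideal step edge of height 1 >> sigma_range: preserved within 10%
  step <- cbind(matrix(0, 24, 12), matrix(1, 24, 12))
  dstep <- denoise_bilateral(step, p)
  expect_lt(max(abs(dstep[, c(1:11, 14:24)] - step[, c(1:11, 14:24)])), 0.1)
  # midpoint stays within 1 px of the edge, no overshoot
  expect_true(all(dstep >= 0 & dstep <= 1))
  expect_true(all(dstep[, 12] < 0.5) && all(dstep[, 13] > 0.5))
})
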
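test_that("phantom generation is deterministic in the seed", {
  sp <- phantom_spec(shape = c(96L, 96L), n_vessels = 3L, seed = 11L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$gold, b$gold)
  # a different seed gives a different phantom
  c2 <- generate_phantom(phantom_spec(shape = c(96L, 96L), n_vessels = 3L,
                                      seed = 12L))
  expect_false(identical(a$gold, c2$gold))
  # generation does not disturb the session RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_phantom(sp)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("vessels are dark tubes of the requested width on a bright ground", {
  ph <- generate_phantom(phantom_spec(shape = c(128L, 128L), n_vessels = 1L,
                                      width_range = c(6, 6), tortuosity = 0,
                                      noise_sigma = 0, seed = 21L))
  g <- extract_green(ph$image)
  expect_gt(sum(ph$gold), 0)
  # tube area is consistent with width 6 (allowing obliqueness and borders)
  len_est <- sum(ph$gold) / 6
  expect_gt(len_est, 40)
  # vessel pixels are darker than the background
  expect_lt(mean(g[ph$gold == 1L]), mean(g[ph$gold == 0L]) - 0.1)
})

test_that("reflex stripes brighten the centerline of thick vessels", {
  base <- list(shape = c(128L, 128L), n_vessels = 1L, width_range = c(20, 20),
               tortuosity = 0, noise_sigma = 0, seed = 31L)
  with_r <- do.call(phantom_spec, c(base, list(
    reflex = list(enabled = TRUE, min_width = 10, brightness = 0.9))))
  without <- do.call(phantom_spec, c(base, list(
    reflex = list(enabled = FALSE, min_width = 10, brightness = 0.9))))
  gr <- extract_green(generate_phantom(with_r)$image)
  g0 <- extract_green(generate_phantom(without)$image)
  expect_true(all(gr >= g0 - 1e-12))
  inside <- generate_phantom(with_r)$gold == 1L
  expect_gt(max((gr - g0)[inside]), 0.1)   # bright stripe inside the vessel
})

test_that("degenerate specifications are rejected", {
  expect_error(phantom_spec(shape = c(64L, 64L), width_range = c(2, 70)),
               "exceeds")
  expect_error(phantom_spec(contrast = 0))
})

test_that("the phantom battery covers its five categories", {
  suite <- phantom_suite(seed = 7L, n_per_category = 2L,
                         shape = c(64L, 64L))
  expect_length(suite, 10L)
  labs <- vapply(suite, `[[`, character(1), "label")
  expect_equal(sort(unique(labs)),
               sort(c("thin", "thick_reflex", "mixed", "null",
                      "low_contrast")))
  for (el in suite[labs == "null"]) expect_true(all(el$gold == 0L))
  for (el in suite[labs != "null"]) expect_gt(sum(el$gold), 0)
  # reproducible end to end
  suite2 <- phantom_suite(seed = 7L, n_per_category = 2L, shape = c(64L, 64L))
  expect_identical(lapply(suite, `[[`, "gold"),
                   lapply(suite2, `[[`, "gold"))
})
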
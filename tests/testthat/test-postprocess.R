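test_that("fuse_or is a proper union with shape checking", {
  a <- random_mask(10, 10, 0.3, seed = 1)
  empty <- matrix(0L, 10, 10)
  expect_identical(fuse_or(list(a, empty)), a)
  b <- matrix(0L, 10, 10); b[1, 1:3] <- 1L
  a2 <- matrix(0L, 10, 10); a2[5, 5] <- 1L
  expect_equal(sum(fuse_or(list(a2, b))), sum(a2) + sum(b))  # disjoint
  sub <- a; sub[a == 1L][1] <- 0L
  expect_identical(fuse_or(list(sub, a)), a)                  # absorption
  # commutative / associative / idempotent
  c3 <- random_mask(10, 10, 0.5, seed = 3)
  expect_identical(fuse_or(list(a, c3)), fuse_or(list(c3, a)))
  expect_identical(fuse_or(list(a, b, c3)),
                   fuse_or(list(fuse_or(list(a, b)), c3)))
  expect_identical(fuse_or(list(a, a)), a)
  expect_error(fuse_or(list()), "non-empty")
  expect_error(fuse_or(list(a, matrix(0L, 9, 10))), "differ")
})

test_that("closing seals small gaps and is idempotent and extensive", {
  bar <- matrix(0L, 9, 13)
  bar[4:6, 3:11] <- 1L
  gap <- bar; gap[5, 7] <- 0L                 # 1-px hole inside a thick bar
  expect_identical(morph_close(gap), bar)
  closed <- morph_close(random_mask(20, 20, 0.4, seed = 6))
  expect_identical(morph_close(closed), closed)
  expect_identical(morph_close(matrix(0L, 8, 8)), matrix(0L, 8, 8))
  m <- random_mask(15, 15, 0.3, seed = 7)
  expect_true(all(morph_close(m) >= m))
})

test_that("object cleanup removes small blobs and fills enclosed holes", {
  m <- matrix(0L, 20, 20)
  m[3:4, 3:4] <- 1L; m[4, 5] <- 1L            # 5-px blob
  expect_true(all(clean_objects(m, min_object_px = 10, max_hole_px = 0) == 0L))
  ring <- matrix(0L, 12, 12)
  ring[4:8, 4:8] <- 1L
  ring[5:7, 5:7] <- 0L                        # 9-px enclosed hole
  filled <- clean_objects(ring, 0, 10)
  expect_true(all(filled[4:8, 4:8] == 1L))    # 9 < 10: filled
  # a hole at least max_hole_px survives
  expect_identical(clean_objects(ring, 0, 9), ring)
  # background touching the frame border is never filled
  expect_true(all(filled[1, ] == 0L))
  # zero thresholds are the identity
  r <- random_mask(25, 25, 0.4, seed = 9)
  expect_identical(clean_objects(r, 0, 0), r)
})

test_that("gradient thinning stops at step edges and preserves topology", {
  # dark rectangle on bright ground; gradient crest sits at the edge
  img <- matrix(0.9, 40, 40)
  img[10:30, 12:28] <- 0.2
  rect <- matrix(0L, 40, 40); rect[10:30, 12:28] <- 1L
  expect_identical(thin_to_gradient(rect, img), rect)
  # mask dilated 2 px beyond the edge shrinks back to the edge +/- 1
  dil <- matrix(0L, 40, 40); dil[8:32, 10:30] <- 1L
  thin <- thin_to_gradient(dil, img)
  core <- matrix(0L, 40, 40); core[11:29, 13:27] <- 1L
  halo <- matrix(0L, 40, 40); halo[9:31, 11:29] <- 1L
  expect_true(all(thin[core == 1L] == 1L))
  # the endpoint/connectivity guards may leave a few protected pixels at
  # corners; everything else retreats to the edge +/- 1
  expect_lte(sum(thin[halo == 0L]), 5)
  # 1-px line: untouched by the connectivity/endpoint guards
  line <- matrix(0L, 20, 20); line[10, 3:17] <- 1L
  expect_identical(thin_to_gradient(line, random_matrix(20, 20, 4)), line)
})

test_that("thinning only removes pixels and never splits components", {
  n_comp <- function(m) max(retivess:::.label_components_cpp(m, 8L))
  for (s in 1:8) {
    m <- morph_close(random_mask(30, 30, 0.35, seed = 400 + s))
    img <- random_matrix(30, 30, seed = 500 + s)
    th <- thin_to_gradient(m, img)
    expect_true(all(th <= m))
    expect_lte(n_comp(th), n_comp(m))
  }
})
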
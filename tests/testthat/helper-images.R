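# Small deterministic rasters used across tests.

random_matrix <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}

random_mask <- function(nr, nc, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

# RGB array from a green-channel matrix
as_rgb <- function(g) {
  a <- array(0, dim = c(nrow(g), ncol(g), 3L))
  a[, , 1] <- pmin(g + 0.2, 1); a[, , 2] <- g; a[, , 3] <- pmax(g - 0.4, 0)
  a
}

# Independent dense 2-D convolution with symmetric (half-sample) padding,
# used as the oracle for the separable Gaussian-derivative path.
dense_conv2 <- function(img, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  refl <- function(i, n) { while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + kern[di + r + 1, dj + r + 1] *
        img[refl(i + di, n), refl(j + dj, m)]
    out[i, j] <- acc
  }
  out
}

# Brute-force hysteresis oracle: BFS over the low mask from high seeds.
hysteresis_oracle <- function(v, t_high, t_low) {
  nr <- nrow(v); nc <- ncol(v)
  low <- v >= t_low
  out <- matrix(FALSE, nr, nc)
  queue <- which(v >= t_high & low)
  out[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
    for (di in -1:1) for (dj in -1:1) {
      qi <- i + di; qj <- j + dj
      if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
      q <- qi + (qj - 1L) * nr
      if (low[q] && !out[q]) { out[q] <- TRUE; queue <- c(queue, q) }
    }
  }
  matrix(as.integer(out), nr, nc)
}
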
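#' Specular reflex correction of a vesselness map
#'
#' The camera flash can leave a bright stripe along the centerline of thick
#' vessels; the Hessian ridge response dips there, threatening to split the
#' vessel in two. On the coarsest pyramid level (where only thick vessels
#' respond), a pixel is declared reflex-affected when, for some pair of
#' opposite 3x3 neighbors, its vesselness is lower than both neighbors while
#' its intensity in the (non-inverted) green-channel image of the same level
#' is higher than both — a ridge gap that is *bright*, not dark. Such pixels
#' are replaced by the mean of the qualifying neighbor pair; when several of
#' the four opposite-direction pairs (N-S, E-W, NE-SW, NW-SE) qualify, the
#' pair giving the largest replacement wins. One pass, reading only from the
#' input map, so the correction never lowers a response and border pixels
#' (without a full 3x3 neighborhood) are untouched.
#'
#' @param v A `vesselness_map` or numeric matrix.
#' @param intensity Green-channel image of the same pyramid level (same
#'   shape, original polarity: reflex = bright).
#' @return Corrected vesselness matrix, `>= v` pixelwise.
#' @export
correct_specular_reflex <- function(v, intensity) {
  vm <- .v0(v)
  .check_matrix(intensity, "intensity image")
  if (!all(dim(vm) == dim(intensity)))
    .stopf("vesselness (%d x %d) and intensity (%d x %d) shapes differ",
           nrow(vm), ncol(vm), nrow(intensity), ncol(intensity))
  # opposite-direction pairs as (dy, dx) offsets
  pairs <- list(c(-1L, 0L), c(0L, 1L), c(-1L, 1L), c(-1L, -1L))
  best <- matrix(-Inf, nrow(vm), ncol(vm))
  hit <- matrix(FALSE, nrow(vm), ncol(vm))
  for (d in pairs) {
    va <- .shift_mat(vm, d[1], d[2]);  vb <- .shift_mat(vm, -d[1], -d[2])
    ia <- .shift_mat(intensity, d[1], d[2])
    ib <- .shift_mat(intensity, -d[1], -d[2])
    ok <- !is.na(va) & !is.na(vb) &
      vm < va & vm < vb & intensity > ia & intensity > ib
    repl <- (va + vb) / 2
    upd <- ok & repl > best
    best[upd] <- repl[upd]
    hit <- hit | ok
  }
  # only pixels with a full 3x3 neighborhood are eligible
  hit[c(1L, nrow(hit)), ] <- FALSE
  hit[, c(1L, ncol(hit))] <- FALSE
  out <- vm
  out[hit] <- best[hit]
  out
}
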
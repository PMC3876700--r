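#' Read a color fundus photograph
#'
#' Decodes a PNG, TIFF, JPEG or PPM raster into a `fundus_image`: a
#' height x width x 3 array of intensities normalized to `[0, 1]` by the
#' format's maximum value (so 8- and 16-bit inputs share one scale without
#' clipping). An alpha channel, if present, is dropped. Grayscale rasters are
#' rejected: the pipeline needs the green channel of a color photograph.
#'
#' @param path Path to the image file.
#' @return A `fundus_image` object: the pixel array with attributes
#'   `source_path` and `bit_depth` (NA when the decoder does not report it).
#' @export
read_fundus <- function(path) {
  px <- .read_raster(path)
  if (length(dim(px$pixels)) < 3L || dim(px$pixels)[3] < 3L)
    .stopf("'%s' is not a color fundus image (need >= 3 channels)", path)
  arr <- px$pixels[, , 1:3, drop = FALSE]
  if (nrow(arr) < 16L || ncol(arr) < 16L)
    .stopf("'%s' is too small (%d x %d); need at least 16 x 16",
           path, nrow(arr), ncol(arr))
  structure(arr, class = "fundus_image",
            source_path = path, bit_depth = px$bit_depth)
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("fundus_image %d x %d px, 3 channels (source: %s)\n",
              d[1], d[2], attr(x, "source_path") %||% "<memory>"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decode any supported raster into a normalized array (h x w [x c]).
# EBImage handles PNG/TIFF/JPEG; PPM/PGM are parsed directly.
.read_raster <- function(path) {
  if (!file.exists(path)) .stopf("cannot read '%s': file does not exist", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ppm", "pgm")) return(.read_pnm(path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    .stopf("cannot read '%s': %s", path, conditionMessage(e)))
  a <- EBImage::imageData(img)   # dim = (x, y[, c]); values already in [0,1]
  a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  list(pixels = a, bit_depth = NA_integer_)
}

# Minimal PNM reader: P2/P3 (ASCII) and P5/P6 (binary), maxval <= 65535.
.read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    .stopf("cannot read '%s': unsupported PNM magic '%s'", path, magic)
  tok <- function() {
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (length(ch) == 0L || ch == "") .stopf("truncated PNM file '%s'", path)
      if (ch == "#") { repeat { c2 <- rawToChar(readBin(con, "raw", 1L))
        if (c2 == "\n" || c2 == "") break } ; next }
      if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (ch == "" || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    v <- numeric(n)
    for (i in seq_len(n)) v[i] <- as.numeric(tok())
    v
  } else if (maxv < 256L) {
    as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE))
  } else {
    as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                       endian = "big"))
  }
  if (length(vals) < n) .stopf("truncated PNM file '%s'", path)
  vals <- vals / maxv
  a <- if (nch == 3L) {
    aperm(array(vals, dim = c(3L, w, h)), c(3L, 2L, 1L))
  } else {
    t(matrix(vals, nrow = w, ncol = h))
  }
  list(pixels = a, bit_depth = if (maxv < 256L) 8L else 16L)
}

#' Read a binary vessel or field-of-view mask
#'
#' Decodes a raster and binarizes it at a fraction of the format maximum
#' (default 0.5, tolerant of antialiased nominally-binary masks).
#' Multi-channel rasters are reduced by the channel mean before thresholding.
#'
#' @param path Path to the mask file (PNG/TIFF/JPEG/PPM/PGM).
#' @param threshold_fraction Fraction of the format maximum at or above which
#'   a pixel counts as foreground; in (0, 1].
#' @return An integer 0/1 matrix (8-connectivity convention package-wide).
#' @export
read_mask <- function(path, threshold_fraction = 0.5) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  px <- .read_raster(path)$pixels
  g <- if (length(dim(px)) == 3L) apply(px, c(1L, 2L), mean) else px
  .as_mask(g >= threshold_fraction)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Vessel pixels are written as 255, background as 0, so that
#' `read_mask(write_mask(m, f))` round-trips exactly.
#'
#' @param mask Integer 0/1 matrix.
#' @param path Destination path (extension selects the format; PNG advised).
#' @export
write_mask <- function(mask, path) {
  .check_mask(mask)
  ok <- tryCatch({
    EBImage::writeImage(EBImage::Image(t(mask)), path)
    TRUE
  }, error = function(e) .stopf("cannot write '%s': %s", path,
                                conditionMessage(e)))
  invisible(ok)
}

#' List a fundus dataset directory
#'
#' Convenience globbing for the common DRIVE / STARE / HRF folder layouts
#' (images alongside manual gold-standard masks and optional field-of-view
#' masks). Purely local: pairs files by shared basename stem, no downloads.
#'
#' @param dir Dataset root directory.
#' @param layout One of `"drive"`, `"stare"`, `"hrf"` or `"flat"`. `"flat"`
#'   expects `images/`, `gold/` and optionally `fov/` subdirectories.
#' @return A data.frame with columns `image`, `gold`, `fov` (NA when absent).
#' @export
list_fundus_dataset <- function(dir, layout = c("flat", "drive", "stare", "hrf")) {
  layout <- match.arg(layout)
  sub <- switch(layout,
    flat  = list(img = "images", gold = "gold", fov = "fov"),
    drive = list(img = "images", gold = "1st_manual", fov = "mask"),
    stare = list(img = "stare-images", gold = "labels-ah", fov = NULL),
    hrf   = list(img = "images", gold = "manual1", fov = "mask"))
  pat <- "\\.(png|tif|tiff|jpg|jpeg|ppm|pgm)$"
  stem <- function(f) sub("[_.].*$", "", basename(f))
  imgs <- sort(list.files(file.path(dir, sub$img), pattern = pat,
                          ignore.case = TRUE, full.names = TRUE))
  if (length(imgs) == 0L)
    .stopf("no images found under '%s'", file.path(dir, sub$img))
  find_match <- function(d) {
    if (is.null(d)) return(rep(NA_character_, length(imgs)))
    cand <- list.files(file.path(dir, d), pattern = pat,
                       ignore.case = TRUE, full.names = TRUE)
    vapply(stem(imgs), function(s) {
      hit <- cand[startsWith(stem(cand), s) | startsWith(s, stem(cand))]
      if (length(hit)) hit[1] else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  data.frame(image = imgs, gold = find_match(sub$gold),
             fov = find_match(sub$fov), stringsAsFactors = FALSE)
}
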
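#' Construct a gel image object
#'
#' A `gel_image` wraps an H x W matrix of 8-bit intensities (rows are the
#' migration axis with the wells at row 1, columns run across the lanes)
#' together with its polarity: whether DNA bands are encoded as bright or as
#' dark pixels.  All downstream routines assume `bands_bright`; use
#' [normalize_polarity()] to get there.
#'
#' @param pixels numeric matrix with values in `[0, 255]`.
#' @param polarity `"bands_bright"` or `"bands_dark"`.
#' @param source optional path the image was read from.
#' @return An object of class `gel_image`.
#' @export
gel_image <- function(pixels, polarity = c("bands_bright", "bands_dark"),
                      source = NA_character_) {
  polarity <- match.arg(polarity)
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop("pixels must be a matrix with at least one row and column")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(
    list(pixels = pixels, polarity = polarity, source = source),
    class = "gel_image"
  )
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image %d x %d, polarity %s>\n",
              nrow(x$pixels), ncol(x$pixels), x$polarity))
  invisible(x)
}

#' @export
dim.gel_image <- function(x) dim(x$pixels)

#' Read a grayscale gel image from PNG or TIFF
#'
#' 8-bit grayscale is the native densitometer format; RGB input is converted
#' to luminance (Rec. 601 weights) and 16-bit input is rescaled to
#' `[0, 255]`, both losslessly for the 8-bit case.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param polarity polarity of the file's bands; defaults to `bands_dark`,
#'   the silver-stain convention (dark bands on a light background).
#' @return A [gel_image()].
#' @export
load_gel_image <- function(path, polarity = c("bands_dark", "bands_bright")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format '", ext, "': ", path)
    ),
    error = function(e) stop("failed to decode image ", path, ": ",
                             conditionMessage(e))
  )
  if (length(dim(raw)) == 3) {
    nch <- dim(raw)[3]
    raw <- if (nch >= 3) {
      0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw[, , 1]
    }
  }
  if (length(dim(raw)) != 2 || any(dim(raw) < 1)) {
    stop("zero-area or non-2D image: ", path)
  }
  gel_image(round(raw * 255), polarity = polarity, source = path)
}

#' Write a gel image as 8-bit grayscale PNG
#'
#' @param image a [gel_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gel_image <- function(image, path) {
  stopifnot(inherits(image, "gel_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Crop a gel image
#'
#' Crops to the analysis region of interest (the well-resolved middle of the
#' lanes, away from wells and gel-front artifacts).  The rectangle is given
#' in 1-based pixel coordinates with `top`/`left` inclusive.
#'
#' @param image a [gel_image()].
#' @param top,left first row/column kept (1-based).
#' @param height,width extent in pixels.
#' @return The cropped [gel_image()]; polarity is preserved.
#' @export
crop_gel <- function(image, top, left, height, width) {
  stopifnot(inherits(image, "gel_image"))
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  if (height < 1 || width < 1) stop("crop height and width must be >= 1")
  if (top < 1) stop("crop rectangle exceeds the top edge")
  if (left < 1) stop("crop rectangle exceeds the left edge")
  if (top + height - 1 > H) stop("crop rectangle exceeds the bottom edge")
  if (left + width - 1 > W) stop("crop rectangle exceeds the right edge")
  gel_image(image$pixels[top:(top + height - 1), left:(left + width - 1),
                         drop = FALSE],
            polarity = image$polarity, source = image$source)
}

#' Normalize band polarity to bands-bright
#'
#' Every downstream stage assumes bands are intensity maxima (so lane
#' boundaries are minima of the cumulative column profile).  Silver-stained
#' PAGE scans encode bands as dark pixels and are inverted here
#' (`v -> 255 - v`).
#'
#' `mode = "auto"` infers the input polarity from the cumulative row profile:
#' bands are thin horizontal stripes, so they appear as spiky departures of
#' the row profile from its slowly varying baseline.  Positive skew of the
#' detrended row profile means bands are bright, negative skew dark.  A near
#' symmetric residual falls back to `bands_dark` (the silver-stain default)
#' with a message.
#'
#' @param image a [gel_image()].
#' @param mode `"auto"`, or the known input polarity (`"bands_bright"`,
#'   `"bands_dark"`).  A `bands_bright` declaration passes the pixels through
#'   unchanged.
#' @return A [gel_image()] with `polarity == "bands_bright"`.
#' @export
normalize_polarity <- function(image,
                               mode = c("auto", "bands_bright", "bands_dark")) {
  stopifnot(inherits(image, "gel_image"))
  mode <- match.arg(mode)
  if (mode == "auto") {
    r <- rowSums(image$pixels)
    k <- min(max(9L, 2L * (nrow(image$pixels) %/% 20L) + 1L),
             if (length(r) %% 2 == 0) length(r) - 1 else length(r))
    resid <- if (length(r) >= 3) r - stats::runmed(r, k) else r - stats::median(r)
    s <- sum(resid^3)
    if (abs(s) < .Machine$double.eps * length(r)) {
      message("polarity auto-detection inconclusive; assuming bands_dark")
      mode <- "bands_dark"
    } else {
      mode <- if (s > 0) "bands_bright" else "bands_dark"
      message("polarity auto-detected as ", mode)
    }
  }
  px <- if (mode == "bands_dark") 255 - image$pixels else image$pixels
  gel_image(px, polarity = "bands_bright", source = image$source)
}
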
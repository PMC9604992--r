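#' Construct a RasterImage
#'
#' @param pixels a \code{height x width x 3} numeric or integer array of
#'   8-bit channel values, or a \code{height x width} matrix which is
#'   promoted to RGB by channel replication (grayscale).
#' @return a [RasterImage-class].
#' @examples
#' img <- RasterImage(array(c(0, 255, 0, 200, 0, 0, 0, 200,
#'                            0, 0, 255, 200), dim = c(2, 2, 3)))
#' dim(img)
#' @export
RasterImage <- function(pixels) {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  if (is.double(pixels)) {
    if (any(abs(pixels - round(pixels)) > 1e-8, na.rm = TRUE))
      stop("channel values must be whole numbers in [0, 255]")
    storage.mode(pixels) <- "integer"
  }
  new("RasterImage", pixels = pixels)
}

#' @describeIn RasterImage image dimensions as \code{c(height, width)}.
#' @param x a \code{RasterImage}.
#' @export
setMethod("dim", "RasterImage", function(x) dim(x@pixels)[1:2])

#' Pixel array accessor
#'
#' @param x a [RasterImage-class].
#' @return the underlying \code{height x width x 3} integer array.
#' @export
pixelArray <- function(x) {
  stopifnot(is(x, "RasterImage"))
  x@pixels
}

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RasterImage %d x %d (w x h), 8-bit RGB\n", d[2L], d[1L]))
})

.sniffFormat <- function(path) {
  magic <- readBin(path, "raw", n = 8L)
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(magic) >= 8L && identical(magic, png_sig)) return("png")
  if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8))))
    return("jpeg")
  stop("unsupported or undecodable image format: ", path)
}

#' Read a cropped tooth image
#'
#' Decodes a PNG or JPEG file (detected from its signature, not the file
#' extension) into an 8-bit RGB [RasterImage-class]. Grayscale images are
#' promoted to RGB by channel replication. An alpha channel is accepted only
#' when fully opaque — transparency in a tooth-on-black crop would silently
#' contaminate the background matte, so it is treated as an invalid crop.
#'
#' @param path path to a PNG or JPEG file.
#' @return a [RasterImage-class].
#' @seealso [writeToothImage()], [measurePlaque()]
#' @export
readToothImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- .sniffFormat(path)
  arr <- if (fmt == "png") png::readPNG(path) else jpeg::readJPEG(path)
  if (is.matrix(arr))
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  nc <- dim(arr)[3L]
  if (nc == 2L) {                      # gray + alpha
    alpha <- arr[, , 2L]
    arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  } else if (nc == 4L) {
    alpha <- arr[, , 4L]
    arr <- arr[, , 1:3, drop = FALSE]
  } else alpha <- NULL
  if (!is.null(alpha) && any(alpha < 1))
    stop("image has a non-opaque alpha channel (invalid crop)")
  RasterImage(clamp8(arr * 255))
}

#' Write a RasterImage to PNG or JPEG
#'
#' PNG output is lossless: reading it back reproduces the pixel grid
#' bit-identically. JPEG is lossy even at high quality; in particular the
#' black background matte may no longer be exactly (0,0,0) after a JPEG
#' round-trip (see the \code{blackTol} setting of [thresholdConfig()]).
#'
#' @param image a [RasterImage-class].
#' @param path output path; the parent directory must exist.
#' @param format `"png"` or `"jpeg"`.
#' @param quality JPEG quality in (0, 1]; ignored for PNG.
#' @return the path, invisibly.
#' @export
writeToothImage <- function(image, path, format = c("png", "jpeg"),
                            quality = 0.95) {
  stopifnot(is(image, "RasterImage"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  arr <- image@pixels / 255
  if (format == "png") png::writePNG(arr, target = path)
  else jpeg::writeJPEG(arr, target = path, quality = quality)
  invisible(path)
}
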
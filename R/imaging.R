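#' RGB image block
#'
#' Constructor/validator for the unit of feature extraction: an `H x W x 3`
#' integer array of 8-bit intensities.
#'
#' @param pixels Numeric or integer array, `H x W x 3`, values in `[0, 255]`.
#' @return The array with class `rgb_block`.
#' @export
rgb_block <- function(pixels) {
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("an rgb_block must be an H x W x 3 array")
  if (d[1] < 2 || d[2] < 2) stop("an rgb_block must be at least 2 x 2 pixels")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_block")
}

#' @export
print.rgb_block <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_block> %d x %d px, 3 channels, range [%d, %d]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Read an image block from a PNG, TIFF or JPEG file
#'
#' Decodes the file to 8-bit RGB. Single-channel (grayscale) images are
#' rejected; an alpha channel, if present, is dropped. TIFFs with more than
#' 8 bits per sample are rescaled to 8 bits with a warning.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return An [rgb_block()].
#' @export
load_block <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(x, "bits.per.sample")
      if (!is.null(bits) && bits > 8)
        warning(sprintf("'%s': %d-bit samples rescaled to 8-bit", path, bits))
      x
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop(sprintf("cannot read image '%s': unsupported extension '%s'", path, ext))
  )
  d <- dim(img)
  if (is.null(d) || length(d) == 2L || d[3] == 1L)
    stop(sprintf("cannot use image '%s': single-channel (grayscale) input; 3-channel RGB required",
                 path))
  if (d[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L)
    stop(sprintf("cannot use image '%s': expected 3 color channels, found %d", path, d[3]))
  rgb_block(round(img * 255))
}

#' Decompose a block into color planes
#'
#' Computes the nine per-pixel color planes used by the color features:
#' R, G, B on `[0, 255]`; H, S, V from normalized RGB, with hue expressed as
#' a fraction of a turn in `[0, 1)` and saturation/value in `[0, 1]`;
#' CIELAB L* (`[0, 100]`), a* and b* via sRGB with the D65 white point; and a
#' luma-weighted gray plane `round(0.2989 R + 0.5870 G + 0.1140 B)`.
#'
#' Hue is treated as an ordinary (non-circular) quantity by downstream
#' statistics; see the feature dictionary ([feature_names()]).
#'
#' @param block An [rgb_block()].
#' @return An object of class `color_planes`: a named list of `H x W`
#'   matrices `R, G, B, H, S, V, L, As, Bs, gray`.
#' @export
#' @examples
#' b <- generate_block(default_class_specs(2)[[1]], size = 16, seed = 1)
#' p <- to_planes(b)
#' range(p$S)
to_planes <- function(block) {
  stopifnot(inherits(block, "rgb_block"))
  d <- dim(block)
  r <- block[, , 1]; g <- block[, , 2]; b <- block[, , 3]
  hsv <- grDevices::rgb2hsv(as.vector(r), as.vector(g), as.vector(b),
                            maxColorValue = 255)
  lab <- grDevices::convertColor(cbind(as.vector(r), as.vector(g),
                                       as.vector(b)) / 255,
                                 from = "sRGB", to = "Lab")
  shape <- function(v) matrix(v, nrow = d[1], ncol = d[2])
  structure(list(
    R = r, G = g, B = b,
    H = shape(hsv["h", ] %% 1), S = shape(hsv["s", ]), V = shape(hsv["v", ]),
    L = shape(lab[, 1]), As = shape(lab[, 2]), Bs = shape(lab[, 3]),
    gray = shape(as.integer(round(0.2989 * r + 0.5870 * g + 0.1140 * b)))
  ), class = "color_planes")
}

# population standard deviation (block = full pixel population)
#' @noRd
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Color features of a block
#'
#' Mean and population standard deviation of each of the nine color planes,
#' in the canonical order `ave_R, std_R, ..., ave_Bs, std_Bs` (18 values).
#' `As`/`Bs` denote the CIELAB a* and b* components; `L` is CIELAB L*.
#'
#' @param planes A [to_planes()] result (an [rgb_block()] is also accepted
#'   and converted).
#' @return Named numeric vector of length 18.
#' @export
color_features <- function(planes) {
  if (inherits(planes, "rgb_block")) planes <- to_planes(planes)
  stopifnot(inherits(planes, "color_planes"))
  ord <- c("R", "G", "B", "H", "S", "V", "L", "As", "Bs")
  out <- numeric(2 * length(ord))
  nms <- character(2 * length(ord))
  for (k in seq_along(ord)) {
    v <- planes[[ord[k]]]
    out[2 * k - 1] <- mean(v)
    out[2 * k] <- pop_sd(v)
    nms[2 * k - 1] <- paste0("ave_", ord[k])
    nms[2 * k] <- paste0("std_", ord[k])
  }
  stats::setNames(out, nms)
}
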
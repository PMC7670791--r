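#' Define a synthetic plant class
#'
#' A `class_spec` describes the appearance of one plant class in the synthetic
#' block generator: a base HSV color, per-channel Gaussian color jitter, and a
#' band-pass luminance texture field with a dominant spatial frequency. Classes
#' that differ in `base_color` separate on color statistics; classes that
#' differ in `texture_freq` separate on wavelet-subband texture statistics.
#'
#' @param name Class label (single string).
#' @param base_color Mean color as `c(h, s, v)` with hue in `[0, 1)` and
#'   saturation/value in `[0, 1]`.
#' @param color_jitter Per-channel standard deviation of the Gaussian color
#'   jitter, `c(sd_h, sd_s, sd_v)`. Hue jitter wraps around the hue circle;
#'   saturation and value are clipped to `[0, 1]`.
#' @param texture_freq Dominant spatial frequency of the additive luminance
#'   noise field, in cycles/pixel, in `(0, 0.5]`.
#' @param texture_amp Amplitude (standard deviation, in value-channel units)
#'   of the luminance noise field; `>= 0`.
#' @return An object of class `class_spec`.
#' @seealso [default_class_specs()], [generate_block()], [generate_dataset()]
#' @export
#' @examples
#' class_spec("peanut", base_color = c(0.30, 0.55, 0.50))
class_spec <- function(name, base_color = c(1 / 3, 0.5, 0.5),
                       color_jitter = c(0.02, 0.05, 0.05),
                       texture_freq = 0.1, texture_amp = 0.08) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  base_color <- as.numeric(base_color)
  color_jitter <- as.numeric(color_jitter)
  if (length(base_color) != 3L || length(color_jitter) != 3L)
    stop("base_color and color_jitter must each have 3 components (h, s, v)")
  if (base_color[1] < 0 || base_color[1] >= 1)
    stop("hue must lie in [0, 1)")
  if (any(base_color[2:3] < 0) || any(base_color[2:3] > 1))
    stop("saturation and value must lie in [0, 1]")
  if (any(color_jitter < 0)) stop("color_jitter components must be >= 0")
  if (texture_freq <= 0 || texture_freq > 0.5)
    stop("texture_freq must lie in (0, 0.5] cycles/pixel")
  if (texture_amp < 0) stop("texture_amp must be >= 0")
  structure(list(name = name, base_color = base_color,
                 color_jitter = color_jitter,
                 texture_freq = texture_freq, texture_amp = texture_amp),
            class = "class_spec")
}

#' @export
print.class_spec <- function(x, ...) {
  cat(sprintf(
    "<class_spec> %s: hsv=(%.3f, %.3f, %.3f) jitter=(%.3f, %.3f, %.3f) freq=%.3f amp=%.3f\n",
    x$name, x$base_color[1], x$base_color[2], x$base_color[3],
    x$color_jitter[1], x$color_jitter[2], x$color_jitter[3],
    x$texture_freq, x$texture_amp))
  invisible(x)
}

#' Default synthetic class specifications
#'
#' The package's fixture classes. The two-class table emulates the
#' crop-versus-weed setting: a "peanut" class and a single "weed" class that
#' differ clearly in hue, saturation, chroma and dominant texture frequency.
#' The four-class table emulates one crop plus three broadleaf weeds with
#' smaller pairwise differences. These are fixtures chosen to exercise the
#' feature families (color vs. wavelet texture), not measurements of real
#' plants.
#'
#' @param n_classes 2 or 4.
#' @return A list of [class_spec()] objects.
#' @export
#' @examples
#' default_class_specs(2)
default_class_specs <- function(n_classes = 4) {
  if (n_classes == 2) {
    list(
      class_spec("Peanut", base_color = c(0.32, 0.60, 0.45),
                 color_jitter = c(0.015, 0.05, 0.05),
                 texture_freq = 0.06, texture_amp = 0.07),
      class_spec("Weed", base_color = c(0.22, 0.35, 0.60),
                 color_jitter = c(0.015, 0.05, 0.05),
                 texture_freq = 0.25, texture_amp = 0.10)
    )
  } else if (n_classes == 4) {
    list(
      class_spec("Peanut", base_color = c(0.32, 0.60, 0.45),
                 color_jitter = c(0.015, 0.05, 0.05),
                 texture_freq = 0.06, texture_amp = 0.07),
      class_spec("Velvetleaf", base_color = c(0.26, 0.45, 0.55),
                 color_jitter = c(0.015, 0.05, 0.05),
                 texture_freq = 0.12, texture_amp = 0.08),
      class_spec("FalseDaisy", base_color = c(0.36, 0.40, 0.60),
                 color_jitter = c(0.015, 0.05, 0.05),
                 texture_freq = 0.20, texture_amp = 0.09),
      class_spec("Nicandra", base_color = c(0.22, 0.55, 0.50),
                 color_jitter = c(0.015, 0.05, 0.05),
                 texture_freq = 0.30, texture_amp = 0.10)
    )
  } else stop("n_classes must be 2 or 4")
}

# isotropic band-pass noise field: white Gaussian noise filtered in the
# Fourier domain to an annulus around `freq` (cycles/pixel), unit variance
#' @noRd
bandpass_field <- function(size, freq, rel_width = 0.2) {
  noise <- matrix(stats::rnorm(size * size), size, size)
  f1 <- (seq_len(size) - 1) / size
  f1[f1 > 0.5] <- f1[f1 > 0.5] - 1
  r <- sqrt(outer(f1^2, f1^2, "+"))
  lo <- freq * (1 - rel_width)
  hi <- freq * (1 + rel_width)
  mask <- r >= lo & r <= hi
  if (!any(mask)) {
    # annulus misses the discrete grid (tiny images): take nearest shell
    d <- abs(r - freq)
    mask <- d <= min(d) + 1e-12
  }
  field <- Re(stats::fft(stats::fft(noise) * mask, inverse = TRUE)) / size^2
  s <- stats::sd(field)
  if (s > 0) field / s else field
}

# vectorized hsv -> rgb on [0,1] (same convention as grDevices::hsv)
#' @noRd
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Generate one synthetic RGB block
#'
#' Draws per-pixel HSV colors as `base_color` plus Gaussian jitter (hue wraps,
#' saturation/value are clipped to `[0, 1]`), adds a band-pass filtered
#' luminance noise field of amplitude `texture_amp` centred on `texture_freq`
#' to the value channel, converts to RGB, and quantizes to 8 bits. The output
#' is fully determined by `(spec, size, seed)`.
#'
#' @param spec A [class_spec()].
#' @param size Block side length in pixels; must be even and at least 8
#'   (the wavelet stage halves each dimension).
#' @param seed Integer seed for this block.
#' @return An [rgb_block()]: a `size x size x 3` integer array in `[0, 255]`.
#' @export
#' @examples
#' b <- generate_block(default_class_specs(2)[[1]], size = 32, seed = 7)
#' dim(b)
generate_block <- function(spec, size = 100, seed = 1) {
  stopifnot(inherits(spec, "class_spec"))
  if (!is.numeric(size) || length(size) != 1L || size < 8 || size %% 2 != 0)
    stop("size must be an even integer >= 8 (the wavelet stage halves dimensions)")
  size <- as.integer(size)
  with_seed(seed, function() {
    n <- size * size
    h <- spec$base_color[1] + stats::rnorm(n, sd = spec$color_jitter[1])
    s <- spec$base_color[2] + stats::rnorm(n, sd = spec$color_jitter[2])
    v <- spec$base_color[3] + stats::rnorm(n, sd = spec$color_jitter[3])
    h <- h %% 1
    s <- pmin(pmax(s, 0), 1)
    if (spec$texture_amp > 0) {
      field <- bandpass_field(size, spec$texture_freq)
      v <- v + spec$texture_amp * as.vector(field)
    }
    v <- pmin(pmax(v, 0), 1)
    rgb <- hsv_to_rgb(h, s, v)
    px <- array(0L, dim = c(size, size, 3L))
    px[, , 1] <- as.integer(round(rgb$r * 255))
    px[, , 2] <- as.integer(round(rgb$g * 255))
    px[, , 3] <- as.integer(round(rgb$b * 255))
    rgb_block(px)
  })
}

#' Generate a labeled synthetic dataset of RGB blocks
#'
#' Produces `n_per_class` blocks per class. Each block is generated on its own
#' deterministic substream derived from the global `seed` and the block index,
#' so the dataset is reproducible and independent of generation order.
#'
#' @param specs List of [class_spec()] objects (non-empty).
#' @param n_per_class Blocks per class, `>= 1`.
#' @param size Block side length (even, `>= 8`).
#' @param seed Global integer seed.
#' @return An object of class `synthetic_dataset`: a list with `blocks` (list
#'   of [rgb_block()]), `labels` (character), `seed` and `spec`.
#' @export
#' @examples
#' d <- generate_dataset(default_class_specs(2), n_per_class = 2, size = 16, seed = 1)
#' table(d$labels)
generate_dataset <- function(specs, n_per_class = 50, size = 100, seed = 1) {
  if (length(specs) == 0) stop("specs must contain at least one class_spec")
  stopifnot(all(vapply(specs, inherits, logical(1), "class_spec")))
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("class names must be unique")
  blocks <- vector("list", length(specs) * n_per_class)
  labels <- character(length(blocks))
  k <- 0L
  for (ci in seq_along(specs)) {
    for (bi in seq_len(n_per_class)) {
      k <- k + 1L
      blocks[[k]] <- generate_block(specs[[ci]], size = size,
                                    seed = substream_seed(seed, k))
      labels[k] <- nms[ci]
    }
  }
  structure(list(blocks = blocks, labels = labels, seed = as.integer(seed),
                 spec = specs),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  d <- dim(x$blocks[[1]])
  cat(sprintf("<synthetic_dataset> %d blocks (%dx%d px), %d classes, seed %d\n",
              length(x$blocks), d[1], d[2], length(x$spec), x$seed))
  print(table(x$labels))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes one PNG per block, named `<class>_<idx>.png`, plus a `labels.csv`
#' manifest with columns `filename` and `class`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- stats::ave(seq_along(dataset$labels), dataset$labels,
                    FUN = seq_along)
  fn <- sprintf("%s_%03d.png", dataset$labels, idx)
  for (i in seq_along(dataset$blocks)) {
    png::writePNG(unclass(dataset$blocks[[i]]) / 255,
                  target = file.path(dir, fn[i]))
  }
  manifest <- data.frame(filename = fn, class = dataset$labels,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}
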
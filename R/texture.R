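#' Quantize a gray-level image into G levels
#'
#' Equal-width binning of the input's own `[min, max]` range into `levels`
#' bins, labeled `0 .. levels - 1`. A constant input maps entirely to bin 0.
#' Signed inputs (wavelet detail subbands) are handled the same way, over
#' their own range.
#'
#' @param gray 2-D numeric matrix.
#' @param levels Number of gray levels `G >= 2`.
#' @return Integer matrix of bin labels in `0 .. levels - 1`.
#' @export
quantize <- function(gray, levels = 8) {
  stopifnot(is.matrix(gray))
  if (levels < 2) stop("levels must be >= 2")
  lo <- min(gray); hi <- max(gray)
  if (hi == lo) {
    out <- matrix(0L, nrow(gray), ncol(gray))
    return(out)
  }
  b <- floor((gray - lo) / (hi - lo) * levels)
  b[b >= levels] <- levels - 1
  storage.mode(b) <- "integer"
  b
}

# (row, col) pixel offset for each co-occurrence direction at unit distance
glcm_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts co-occurring label pairs `(i, j)` at the given pixel offset and
#' normalizes to a probability matrix summing to 1. With `symmetric = TRUE`
#' (the default) each pair is also counted in reverse, making the matrix
#' symmetric.
#'
#' @param labels Integer matrix of gray-level labels (see [quantize()]).
#' @param distance Offset length in pixels, `>= 1`.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param symmetric Count each pair in both orders?
#' @param levels Number of gray levels `G`; defaults to `max(labels) + 1`.
#' @return A `glcm` object: `G x G` probability matrix with attributes
#'   `distance` and `angle`.
#' @export
glcm_single <- function(labels, distance = 1, angle = 0, symmetric = TRUE,
                        levels = max(labels) + 1L) {
  stopifnot(is.matrix(labels))
  key <- as.character(angle)
  if (!key %in% names(glcm_offsets))
    stop("angle must be one of 0, 45, 90, 135")
  if (distance < 1) stop("distance must be >= 1")
  off <- glcm_offsets[[key]] * as.integer(distance)
  nr <- nrow(labels); nc <- ncol(labels)
  if (nr - abs(off[1]) < 1 || nc - abs(off[2]) < 1)
    stop("image is smaller than the co-occurrence offset")
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  i <- labels[r1, c1, drop = FALSE]
  j <- labels[r1 + off[1], c1 + off[2], drop = FALSE]
  G <- as.integer(levels)
  counts <- matrix(tabulate(as.vector(i) * G + as.vector(j) + 1L, nbins = G * G),
                   G, G, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  p <- counts / sum(counts)
  structure(p, class = "glcm", distance = distance, angle = angle,
            symmetric = symmetric)
}

#' Direction-averaged co-occurrence matrix
#'
#' Element-wise mean of the four normalized directional GLCMs (0, 45, 90,
#' 135 degrees) at the given distance; the result still sums to 1.
#'
#' @inheritParams glcm_single
#' @return A `glcm` object with attribute `angle = "mean"`.
#' @export
glcm_mean <- function(labels, distance = 1, symmetric = TRUE,
                      levels = max(labels) + 1L) {
  ms <- lapply(c(0, 45, 90, 135), function(a)
    glcm_single(labels, distance = distance, angle = a,
                symmetric = symmetric, levels = levels))
  p <- Reduce(`+`, lapply(ms, unclass)) / 4
  structure(p, class = "glcm", distance = distance, angle = "mean",
            symmetric = symmetric)
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d levels, distance %s, angle %s, sum %.6f\n",
              nrow(x), format(attr(x, "distance")), format(attr(x, "angle")),
              sum(x)))
  invisible(x)
}

#' Names of the 16 co-occurrence texture descriptors
#' @return Character vector of length 16, in canonical order.
#' @export
texture_feature_names <- function() {
  c("entropy", "energy", "inertia", "correlation", "homogeneity",
    "dissimilarity", "sum_of_squares", "sum_average", "sum_variance",
    "sum_entropy", "difference_variance", "difference_entropy",
    "cluster_shade", "cluster_prominence", "inverse_difference_moment",
    "maximum_probability")
}

#' Haralick-family texture descriptors of a co-occurrence matrix
#'
#' Computes the 16 descriptors from a normalized GLCM `p(i, j)` with indices
#' `i, j = 1..G`: energy, entropy (bits), inertia (contrast), correlation,
#' homogeneity, dissimilarity, sum of squares (variance), sum
#' average/variance/entropy over `p_{x+y}`, difference variance/entropy over
#' `p_{x-y}`, cluster shade and prominence, inverse difference moment, and
#' maximum probability. For a degenerate matrix with zero marginal variance
#' (constant image) the correlation is defined as 0.
#'
#' @param glcm A `glcm` object or normalized square probability matrix.
#' @return Named numeric vector of length 16 (see [texture_feature_names()]).
#' @export
texture_features <- function(glcm) {
  p <- unclass(glcm)
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  if (abs(sum(p) - 1) > 1e-6) stop("GLCM must be normalized to sum 1")
  G <- nrow(p)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sigx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(G) - muy)^2 * py))

  # diagonal-band marginals
  ks_sum <- 2:(2 * G)
  p_sum <- vapply(ks_sum, function(k) sum(p[i + j == k]), numeric(1))
  ks_dif <- 0:(G - 1)
  p_dif <- vapply(ks_dif, function(k) sum(p[abs(i - j) == k]), numeric(1))

  sum_average <- sum(ks_sum * p_sum)
  dif_mean <- sum(ks_dif * p_dif)

  correlation <- if (sigx == 0 || sigy == 0) {
    message("constant-image GLCM: correlation defined as 0")
    0
  } else sum((i - mux) * (j - muy) * p) / (sigx * sigy)

  out <- c(
    entropy = entropy_bits(p),
    energy = sum(p^2),
    inertia = sum((i - j)^2 * p),
    correlation = correlation,
    homogeneity = sum(p / (1 + abs(i - j))),
    dissimilarity = sum(abs(i - j) * p),
    sum_of_squares = sum((i - mux)^2 * p),
    sum_average = sum_average,
    sum_variance = sum((ks_sum - sum_average)^2 * p_sum),
    sum_entropy = entropy_bits(p_sum),
    difference_variance = sum((ks_dif - dif_mean)^2 * p_dif),
    difference_entropy = entropy_bits(p_dif),
    cluster_shade = sum((i + j - mux - muy)^3 * p),
    cluster_prominence = sum((i + j - mux - muy)^4 * p),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    maximum_probability = max(p)
  )
  out[texture_feature_names()]
}

#' One-level 2-D Haar wavelet decomposition
#'
#' Separable orthonormal Haar analysis (low-pass `(1, 1)/sqrt(2)`, high-pass
#' `(1, -1)/sqrt(2)`) applied across rows then across columns, producing four
#' half-size subbands: the approximation LL and the horizontal (LH), vertical
#' (HL) and diagonal (HH) details. The transform is orthonormal, so energy is
#' conserved and the synthesis transform reconstructs the input exactly (to
#' floating-point precision).
#'
#' @param gray 2-D numeric matrix with even numbers of rows and columns.
#' @return Object of class `wavelet_subbands`: list of matrices
#'   `LL, LH, HL, HH`, each `(H/2) x (W/2)`.
#' @export
#' @examples
#' s <- haar_dwt2(matrix(1:16, 4, 4))
#' sum(unlist(s)^2) - sum((1:16)^2)  # ~0: energy conservation
haar_dwt2 <- function(gray) {
  stopifnot(is.matrix(gray))
  nr <- nrow(gray); nc <- ncol(gray)
  if (nr %% 2 != 0 || nc %% 2 != 0)
    stop("haar_dwt2 requires even image dimensions (no padding is applied)")
  odd_r <- seq(1, nr, by = 2); evn_r <- odd_r + 1
  # stage 1: filter across rows (pairs of rows)
  A <- (gray[odd_r, , drop = FALSE] + gray[evn_r, , drop = FALSE]) / sqrt(2)
  D <- (gray[odd_r, , drop = FALSE] - gray[evn_r, , drop = FALSE]) / sqrt(2)
  odd_c <- seq(1, nc, by = 2); evn_c <- odd_c + 1
  # stage 2: filter across columns
  structure(list(
    LL = (A[, odd_c, drop = FALSE] + A[, evn_c, drop = FALSE]) / sqrt(2),
    LH = (D[, odd_c, drop = FALSE] + D[, evn_c, drop = FALSE]) / sqrt(2),
    HL = (A[, odd_c, drop = FALSE] - A[, evn_c, drop = FALSE]) / sqrt(2),
    HH = (D[, odd_c, drop = FALSE] - D[, evn_c, drop = FALSE]) / sqrt(2)
  ), class = "wavelet_subbands")
}

#' Inverse one-level 2-D Haar transform
#'
#' Synthesis counterpart of [haar_dwt2()]; reconstructs the original image.
#'
#' @param subbands A `wavelet_subbands` object.
#' @return Numeric matrix of twice the subband dimensions.
#' @export
haar_idwt2 <- function(subbands) {
  LL <- subbands$LL; LH <- subbands$LH; HL <- subbands$HL; HH <- subbands$HH
  nr2 <- nrow(LL); nc2 <- ncol(LL)
  # undo stage 2
  A <- matrix(0, nr2, 2 * nc2); D <- matrix(0, nr2, 2 * nc2)
  odd_c <- seq(1, 2 * nc2, by = 2); evn_c <- odd_c + 1
  A[, odd_c] <- (LL + HL) / sqrt(2); A[, evn_c] <- (LL - HL) / sqrt(2)
  D[, odd_c] <- (LH + HH) / sqrt(2); D[, evn_c] <- (LH - HH) / sqrt(2)
  # undo stage 1
  out <- matrix(0, 2 * nr2, 2 * nc2)
  odd_r <- seq(1, 2 * nr2, by = 2); evn_r <- odd_r + 1
  out[odd_r, ] <- (A + D) / sqrt(2)
  out[evn_r, ] <- (A - D) / sqrt(2)
  out
}

#' Wavelet-subband texture descriptors
#'
#' Decomposes the gray image with [haar_dwt2()], then, for each of the four
#' subbands, re-quantizes the (signed) coefficients over their own range,
#' builds the direction-averaged GLCM and computes the 16 texture
#' descriptors. Names are suffixed `_LL`, `_LH`, `_HL`, `_HH` (64 values).
#'
#' @param gray 2-D numeric matrix (even dimensions).
#' @param levels Gray-level count for the subband GLCMs.
#' @return Named numeric vector of length 64.
#' @export
wavelet_features <- function(gray, levels = 8) {
  sub <- haar_dwt2(gray)
  out <- lapply(c("LL", "LH", "HL", "HH"), function(b) {
    f <- texture_features(glcm_mean(quantize(sub[[b]], levels),
                                    levels = levels))
    stats::setNames(f, paste0(names(f), "_", b))
  })
  unlist(out)
}

#' Canonical names of the 98 block features
#'
#' The feature dictionary, in the canonical column order used throughout the
#' package: 18 color statistics (mean and population standard deviation of
#' R, G, B on `[0,255]`, H in `[0,1)` as a fraction of a turn, S and V in
#' `[0,1]`, CIELAB L* in `[0,100]` and a*/b* (`As`/`Bs`)), the 16
#' co-occurrence descriptors of the gray image, and the 16 descriptors of
#' each Haar subband (`_LL`, `_LH`, `_HL`, `_HH`).
#'
#' @return Character vector of length 98.
#' @export
feature_names <- function() {
  planes <- c("R", "G", "B", "H", "S", "V", "L", "As", "Bs")
  color <- as.vector(rbind(paste0("ave_", planes), paste0("std_", planes)))
  tex <- texture_feature_names()
  wav <- as.vector(vapply(c("LL", "LH", "HL", "HH"),
                          function(b) paste0(tex, "_", b),
                          character(16)))
  c(color, tex, wav)
}

#' Extract the full 98-feature descriptor of one block
#'
#' @param block An [rgb_block()].
#' @param glcm_levels Gray-level count `G` for all co-occurrence matrices.
#' @return Named numeric vector of length 98 in canonical order.
#' @export
block_features <- function(block, glcm_levels = 8) {
  planes <- to_planes(block)
  gray <- planes$gray
  c(color_features(planes),
    texture_features(glcm_mean(quantize(gray, glcm_levels),
                               levels = glcm_levels)),
    wavelet_features(gray, levels = glcm_levels))
}

#' Extract a feature table from a dataset or an image directory
#'
#' For a [generate_dataset()] result, returns a data frame with a `class`
#' factor column followed by the 98 feature columns. For a directory, reads
#' the `labels.csv` manifest (columns `filename`, `class`) and the referenced
#' image files, and adds a `filename` column.
#'
#' @param x A `synthetic_dataset` or a directory path.
#' @param glcm_levels Gray-level count for all co-occurrence matrices.
#' @param labels Manifest file name inside the directory.
#' @return Data frame: (`filename`,) `class`, then 98 feature columns.
#' @export
extract_features <- function(x, glcm_levels = 8, labels = "labels.csv") {
  if (inherits(x, "synthetic_dataset")) {
    feats <- t(vapply(x$blocks, block_features, numeric(98),
                      glcm_levels = glcm_levels))
    out <- data.frame(class = factor(x$labels), feats,
                      stringsAsFactors = FALSE, check.names = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  if (is.character(x) && dir.exists(x)) {
    man <- utils::read.csv(file.path(x, labels), stringsAsFactors = FALSE)
    if (!all(c("filename", "class") %in% names(man)))
      stop("manifest must have columns 'filename' and 'class'")
    feats <- t(vapply(man$filename, function(f)
      block_features(load_block(file.path(x, f)), glcm_levels = glcm_levels),
      numeric(98)))
    out <- data.frame(filename = man$filename, class = factor(man$class),
                      feats, stringsAsFactors = FALSE, check.names = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  stop("x must be a synthetic_dataset or an existing directory")
}
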
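#' RGB to YUV decomposition
#'
#' Splits a color image into a luminance plane Y and two chroma planes U, V
#' using full-range BT.601 coefficients (the convention of mainstream
#' imaging libraries), with neutral chroma at 128. Only the Y plane is
#' denoised downstream; U and V pass through untouched.
#'
#' `Y = 0.299 R + 0.587 G + 0.114 B`; U and V are the scaled blue- and
#' red-difference planes offset by 128. Chroma is clamped to \[0, 255\],
#' which costs at most half a gray level and keeps the round trip through
#' [yuv_to_rgb()] within one gray level per sample.
#'
#' @param img H x W x 3 array in \[0, 255\] (red, green, blue).
#' @return an object of class `"yuv_image"`: a list with numeric matrices
#'   `y`, `u`, `v` of identical dimensions.
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))[rep(1, 4), rep(1, 4), ]
#' rgb_to_yuv(img)$y[1, 1]   # 76.245, the BT.601 luma of pure red
#' @export
rgb_to_yuv <- function(img) {
  img <- as_color_image(img)
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  u <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  v <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  structure(list(y = .clamp255(y), u = .clamp255(u), v = .clamp255(v)),
            class = "yuv_image")
}

#' YUV to RGB recombination
#'
#' Inverse of [rgb_to_yuv()] up to quantization; output samples are clamped
#' to \[0, 255\]. An unmodified round trip reproduces the input within one
#' gray level per sample.
#'
#' @param yuv a `"yuv_image"` (list with equal-sized matrices `y`, `u`, `v`).
#' @return an H x W x 3 array in \[0, 255\].
#' @export
yuv_to_rgb <- function(yuv) {
  if (!is.list(yuv) || !all(c("y", "u", "v") %in% names(yuv))) {
    stop("expected a yuv_image (list with planes y, u, v)")
  }
  y <- as_gray_plane(yuv$y)
  u <- as_gray_plane(yuv$u)
  v <- as_gray_plane(yuv$v)
  if (!identical(dim(y), dim(u)) || !identical(dim(y), dim(v))) {
    stop("dimension error: y, u, v planes must share identical dimensions")
  }
  du <- u - 128; dv <- v - 128
  r <- y + 1.402 * dv
  g <- y - 0.344136 * du - 0.714136 * dv
  b <- y + 1.772 * du
  out <- array(0, dim = c(dim(y), 3L))
  out[, , 1L] <- .clamp255(r)
  out[, , 2L] <- .clamp255(g)
  out[, , 3L] <- .clamp255(b)
  out
}

#' Grayscale transform for metric computation
#'
#' Converts a color image to a gray plane as the unweighted arithmetic mean
#' `(R + G + B) / 3`. This is deliberately not the BT.601 luma: the
#' benchmarking protocol computes PSNR on arithmetic-mean gray images, and
#' the unweighted mean commutes with channel permutation. Luma-weighted
#' grayscale is available via `rgb_to_yuv(img)$y`.
#'
#' @param img H x W x 3 array in \[0, 255\], or a gray plane (returned as is).
#' @return a numeric H x W matrix in \[0, 255\].
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(as_gray_plane(img))
  img <- as_color_image(img)
  (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
}

#' Median brightness of a plane
#'
#' The statistical median of all samples; for an even sample count, the
#' midpoint of the two central order statistics. Feeds the µ term of the
#' ALA threshold.
#'
#' @param y gray plane matrix.
#' @return a scalar in \[0, 255\].
#' @export
median_brightness <- function(y) {
  y <- as_gray_plane(y)
  stats::median(y)
}

#' Laplacian noise estimate
#'
#' Estimates the pixel noise standard deviation of a plane from the
#' absolute response of the 3 x 3 Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` over the valid interior (no border
#' padding). The Laplacian annihilates constant and affine intensity
#' fields, so for smooth scenes the statistic is driven by pixel-to-pixel
#' noise; under i.i.d. Gaussian noise of standard deviation σ the kernel
#' response has variance `20 σ^2`, so the mean absolute response equals
#' `σ sqrt(40 / π)` and is rescaled by `sqrt(π / 40)` to estimate σ itself
#' (the classic Laplacian noise-level estimator). Image structure (edges,
#' texture) inflates the estimate somewhat; that conservative bias is
#' acceptable for its single use, the σ term of [ala_threshold()], which
#' must sit just above the noise floor.
#'
#' @param y gray plane matrix, at least 3 x 3.
#' @return a non-negative scalar, an estimate of the noise standard
#'   deviation on the gray-value scale.
#' @export
estimate_noise_sigma <- function(y) {
  y <- as_gray_plane(y)
  h <- nrow(y); w <- ncol(y)
  if (h < 3L || w < 3L) stop("size error: plane must be at least 3 x 3")
  i <- 2:(h - 1L); j <- 2:(w - 1L)
  lap <- y[i - 1L, j] + y[i + 1L, j] + y[i, j - 1L] + y[i, j + 1L] -
    4 * y[i, j]
  sqrt(pi / 40) * mean(abs(lap))
}

#' Global image statistics for the ALA threshold
#'
#' Bundles the two global statistics the adaptive filter depends on: the
#' median brightness µ and the Laplacian noise estimate σ of a luminance
#' plane.
#'
#' @param y gray plane matrix (normally the Y channel), at least 3 x 3.
#' @return an object of class `"noise_stats"`: list with `mu_median` and
#'   `sigma_laplacian`.
#' @seealso [ala_threshold()]
#' @export
noise_stats <- function(y) {
  structure(list(mu_median = median_brightness(y),
                 sigma_laplacian = estimate_noise_sigma(y)),
            class = "noise_stats")
}

#' @export
print.noise_stats <- function(x, ...) {
  cat(sprintf("noise_stats: mu_median = %.3f, sigma_laplacian = %.3f  (Th = %.3f)\n",
              x$mu_median, x$sigma_laplacian, ala_threshold(x)))
  invisible(x)
}

#' Variability threshold from global statistics
#'
#' The single tuning parameter of the adaptive local averaging filter,
#' computed from global image statistics as
#'
#' `Th = 2 sigma + mu / 60`
#'
#' where µ is the median brightness and σ the Laplacian noise estimate of
#' the luminance plane. The formula is applied as is, with no clamping: Th
#' is affine in both arguments.
#'
#' @param stats a `"noise_stats"` object (or any list with fields
#'   `mu_median` and `sigma_laplacian`).
#' @return a non-negative scalar threshold on the gray-value scale.
#' @examples
#' ala_threshold(list(mu_median = 120, sigma_laplacian = 3))  # 8
#' @export
ala_threshold <- function(stats) {
  mu <- stats$mu_median
  sigma <- stats$sigma_laplacian
  if (!is.numeric(mu) || !is.numeric(sigma) || length(mu) != 1L ||
      length(sigma) != 1L || is.na(mu) || is.na(sigma)) {
    stop("stats must carry scalar mu_median and sigma_laplacian")
  }
  if (sigma < 0) stop("domain error: sigma_laplacian must be non-negative")
  sigma * 2 + mu / 60
}
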
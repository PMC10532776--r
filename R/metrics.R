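#' Pairwise peak signal-to-noise ratio
#'
#' `PSNR = 20 log10(255 / sqrt(MSE))` in decibels, with
#' `MSE = mean((a - b)^2)`. Identical planes give `+Inf` by convention.
#' High values mean the two images are similar — which for a noisy-input /
#' denoised-output pair can equally signal weak denoising, hence the
#' single-image companion [psnr_single()].
#'
#' @param a,b gray plane matrices of equal dimensions (color images are
#'   gray-transformed with [rgb_to_gray()] first).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr_pair <- function(a, b) {
  a <- rgb_to_gray(a); b <- rgb_to_gray(b)
  if (!identical(dim(a), dim(b))) {
    stop("dimension error: planes must have identical dimensions")
  }
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  20 * log10(255 / sqrt(mse))
}

#' Single-image peak signal-to-noise ratio
#'
#' `PSNR = 20 log10(255 / mu)` with µ the arithmetic mean gray value of the
#' image itself. Brighter images score lower; the measure characterizes one
#' image without reference to another, sidestepping the
#' similar-to-the-noisy-input pitfall of pairwise PSNR.
#'
#' @param a gray plane matrix (color images are gray-transformed first).
#' @return PSNR in dB; `Inf` with a warning for an all-zero plane.
#' @export
psnr_single <- function(a) {
  a <- rgb_to_gray(a)
  mu <- mean(a)
  if (mu <= 0) {
    warning("all-zero plane: single-image PSNR is infinite")
    return(Inf)
  }
  20 * log10(255 / mu)
}

#' Structural similarity index
#'
#' Mean local SSIM between two planes with the standard constants
#' `K1 = 0.01`, `K2 = 0.03`, dynamic range `L = 255`, a uniform square
#' window (default 7 x 7) and sample (n − 1) normalization for the local
#' variances and covariance. Windows are evaluated at every position where
#' they fit entirely inside the planes (no padding), and the map is
#' averaged. Symmetric in its arguments; exactly 1 for identical planes.
#'
#' @param a,b gray plane matrices of equal dimensions, at least
#'   `window` pixels on each side (color images are gray-transformed first).
#' @param window odd window side length (default 7).
#' @param K1,K2 stability constants.
#' @param L dynamic range of the samples.
#' @return a scalar in \[-1, 1\].
#' @export
ssim_index <- function(a, b, window = 7L, K1 = 0.01, K2 = 0.03, L = 255) {
  a <- rgb_to_gray(a); b <- rgb_to_gray(b)
  if (!identical(dim(a), dim(b))) {
    stop("dimension error: planes must have identical dimensions")
  }
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be an odd integer >= 3")
  h <- nrow(a); w <- ncol(a)
  if (h < window || w < window) {
    stop("dimension error: planes smaller than the SSIM window")
  }
  r <- window %/% 2L
  crop <- function(m) m[(r + 1L):(h - r), (r + 1L):(w - r), drop = FALSE]
  n <- as.numeric(window)^2
  s_a  <- crop(.box_sum(a, r));      s_b  <- crop(.box_sum(b, r))
  s_aa <- crop(.box_sum(a * a, r));  s_bb <- crop(.box_sum(b * b, r))
  s_ab <- crop(.box_sum(a * b, r))
  mu_a <- s_a / n; mu_b <- s_b / n
  va  <- (s_aa - n * mu_a * mu_a) / (n - 1)
  vb  <- (s_bb - n * mu_b * mu_b) / (n - 1)
  cab <- (s_ab - n * mu_a * mu_b) / (n - 1)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  num <- (2 * mu_a * mu_b + C1) * (2 * cab + C2)
  den <- (mu_a * mu_a + mu_b * mu_b + C1) * (va + vb + C2)
  mean(num / den)
}

#' Mean brightness
#'
#' Arithmetic mean of all samples of a gray plane (color images are
#' gray-transformed first). Used to verify that denoising conserves image
#' brightness.
#'
#' @param a gray plane matrix or color image.
#' @return a scalar in \[0, 255\].
#' @export
brightness <- function(a) {
  mean(rgb_to_gray(a))
}

#' Quality report for an image (pair)
#'
#' Bundles the evaluation metrics for a test image, optionally against a
#' reference: pairwise PSNR and SSIM between `image` and `reference` (NA
#' when no reference is given), plus the single-image PSNR and mean
#' brightness of `image`. Color inputs are gray-transformed first, the
#' protocol under which all metrics here are defined.
#'
#' @param image the image under evaluation (e.g. the denoised output).
#' @param reference optional comparison image (e.g. noisy input or ground
#'   truth).
#' @return an object of class `"quality_report"`: list with
#'   `psnr_pair_db`, `ssim`, `psnr_single_db`, `mean_brightness`.
#' @export
quality_report <- function(image, reference = NULL) {
  g <- rgb_to_gray(image)
  rep <- list(
    psnr_pair_db = NA_real_,
    ssim = NA_real_,
    psnr_single_db = psnr_single(g),
    mean_brightness = brightness(g)
  )
  if (!is.null(reference)) {
    gr <- rgb_to_gray(reference)
    rep$psnr_pair_db <- psnr_pair(g, gr)
    rep$ssim <- ssim_index(g, gr)
  }
  structure(rep, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report: PSNR(pair) = %s dB, SSIM = %s, PSNR(single) = %.2f dB, brightness = %.2f\n",
              if (is.na(x$psnr_pair_db)) "NA" else sprintf("%.2f", x$psnr_pair_db),
              if (is.na(x$ssim)) "NA" else sprintf("%.4f", x$ssim),
              x$psnr_single_db, x$mean_brightness))
  invisible(x)
}
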
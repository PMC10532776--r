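#' ALA filter parameters
#'
#' Configuration of the adaptive local averaging filter. `threshold` is the
#' single tuning parameter Th on the gray-value scale; `NULL` means "derive
#' it from the plane's own global statistics" via [ala_threshold()].
#' `min_extent`/`max_extent` bound the side length of the expanding
#' quadratic patch (defaults 2 and 40 pixels); patches are realized as
#' centered odd-sided windows of side `2r + 1` with radius
#' `r = 1 .. max_extent %/% 2`, so the default maximum corresponds to a
#' 20-pixel radius — the halo width the tiling layer uses.
#'
#' @param threshold non-negative scalar Th, or `NULL` for automatic
#'   derivation from global image statistics.
#' @param min_extent integer lower bound on patch side length (>= 1).
#' @param max_extent integer upper bound on patch side length
#'   (> `min_extent`).
#' @param variability_statistic how patch variability is measured:
#'   `"stddev"` (population standard deviation, the default, on the same
#'   scale as Th) or `"range"` (max minus min).
#' @return an object of class `"ala_params"`.
#' @export
ala_params <- function(threshold = NULL, min_extent = 2L, max_extent = 40L,
                       variability_statistic = c("stddev", "range")) {
  variability_statistic <- match.arg(variability_statistic)
  if (!is.null(threshold)) {
    if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
      stop("threshold must be a single number or NULL")
    }
    if (threshold < 0) stop("domain error: threshold must be non-negative")
  }
  min_extent <- as.integer(min_extent)
  max_extent <- as.integer(max_extent)
  if (min_extent < 1L) stop("min_extent must be >= 1")
  if (max_extent <= min_extent) stop("max_extent must exceed min_extent")
  structure(list(threshold = threshold,
                 min_extent = min_extent,
                 max_extent = max_extent,
                 variability_statistic = variability_statistic),
            class = "ala_params")
}

#' @export
print.ala_params <- function(x, ...) {
  th <- if (is.null(x$threshold)) "auto" else sprintf("%.4g", x$threshold)
  cat(sprintf("ala_params: Th = %s, patch extent %d..%d px (radius 1..%d), variability = %s\n",
              th, x$min_extent, x$max_extent, x$max_extent %/% 2L,
              x$variability_statistic))
  invisible(x)
}

## Resolve a NULL threshold from the plane's own global statistics.
.resolve_params <- function(y, params) {
  if (is.null(params$threshold)) {
    params$threshold <- ala_threshold(noise_stats(y))
  }
  params
}

## ---- windowed moment machinery -------------------------------------------
##
## Box sums are computed by adding shifted copies of the plane in a fixed
## offset order (-r, ..., +r along columns, then along rows), zero-padded
## outside the plane. Each output element is then the sum of exactly its own
## window's samples, accumulated in an order that depends only on the
## window contents -- not on the pixel's absolute position. Consequence:
## a window evaluated inside a padded tile yields the bit-identical float
## as the same window in the full frame, which is what makes halo tiling
## exactly seam-free; and for integer-valued (8-bit) planes every sum is
## exact. A global prefix-sum table would be O(1) per query but loses both
## properties to accumulated rounding.

.box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  p <- cbind(matrix(0, h, r), m, matrix(0, h, r))
  acc <- p[, seq_len(w), drop = FALSE]
  for (d in seq_len(2L * r)) acc <- acc + p[, d + seq_len(w), drop = FALSE]
  q <- rbind(matrix(0, r, w), acc, matrix(0, r, w))
  out <- q[seq_len(h), , drop = FALSE]
  for (d in seq_len(2L * r)) out <- out + q[d + seq_len(h), , drop = FALSE]
  out
}

## Number of in-bounds samples in each clipped window (exact integers).
.box_count <- function(h, w, r) {
  rows <- pmin(seq_len(h) + r, h) - pmax(seq_len(h) - r, 1L) + 1L
  cols <- pmin(seq_len(w) + r, w) - pmax(seq_len(w) - r, 1L) + 1L
  outer(rows, cols)
}

## Windowed max - min over clipped windows (separable running extrema).
.box_range <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  run <- function(m, pad, fun, byrow) {
    if (byrow) {
      p <- rbind(matrix(pad, r, w), m, matrix(pad, r, w))
      acc <- p[seq_len(h), , drop = FALSE]
      for (d in seq_len(2L * r)) acc <- fun(acc, p[d + seq_len(h), , drop = FALSE])
    } else {
      p <- cbind(matrix(pad, h, r), m, matrix(pad, h, r))
      acc <- p[, seq_len(w), drop = FALSE]
      for (d in seq_len(2L * r)) acc <- fun(acc, p[, d + seq_len(w), drop = FALSE])
    }
    acc
  }
  mx <- run(run(m, -Inf, pmax, FALSE), -Inf, pmax, TRUE)
  mn <- run(run(m, Inf, pmin, FALSE), Inf, pmin, TRUE)
  mx - mn
}

## ---- the filter -----------------------------------------------------------

#' Variability of a quadratic patch
#'
#' The brightness variability inside the window of side `2 * half_width + 1`
#' centered on (`row`, `col`), intersected with the image bounds (no
#' padding; windows at borders use fewer samples). `"stddev"` is the
#' population standard deviation of the window samples, `"range"` their max
#' minus min.
#'
#' @param y gray plane matrix.
#' @param row,col 1-based center coordinates.
#' @param half_width window radius r >= 1.
#' @param statistic `"stddev"` or `"range"`.
#' @return a non-negative scalar.
#' @export
patch_variability <- function(y, row, col, half_width,
                              statistic = c("stddev", "range")) {
  statistic <- match.arg(statistic)
  y <- as_gray_plane(y)
  if (half_width < 1L) stop("half_width must be >= 1")
  h <- nrow(y); w <- ncol(y)
  if (row < 1L || row > h || col < 1L || col > w) {
    stop("coordinate error: center (", row, ", ", col, ") outside the plane")
  }
  win <- y[max(1L, row - half_width):min(h, row + half_width),
           max(1L, col - half_width):min(w, col + half_width)]
  if (statistic == "stddev") {
    mu <- mean(win)
    sqrt(mean((win - mu)^2))
  } else {
    max(win) - min(win)
  }
}

#' Adaptive local average at one pixel
#'
#' The scalar the ALA filter assigns to a single pixel: the patch radius
#' grows from 1 while the window's variability stays at or below the
#' threshold, and the returned value is the mean of the last (largest)
#' window that passed. If already the smallest window exceeds the
#' threshold, the original pixel value is returned unchanged (this is what
#' preserves contours); if no window ever exceeds it, the maximum-radius
#' window is averaged. Windows are clipped at image borders.
#'
#' This per-pixel form is the plain reading of the algorithm; [ala_filter()]
#' computes the identical quantity for all pixels at once.
#'
#' @param y gray plane matrix.
#' @param row,col 1-based pixel coordinates.
#' @param params an [ala_params()] object; a `NULL` threshold is derived
#'   from `y`'s global statistics.
#' @return the filtered gray value.
#' @export
ala_pixel <- function(y, row, col, params = ala_params()) {
  y <- as_gray_plane(y)
  params <- .resolve_params(y, params)
  h <- nrow(y); w <- ncol(y)
  if (row < 1L || row > h || col < 1L || col > w) {
    stop("coordinate error: center (", row, ", ", col, ") outside the plane")
  }
  th <- params$threshold
  rmax <- params$max_extent %/% 2L
  val <- y[row, col]
  for (r in seq_len(rmax)) {
    win <- y[max(1L, row - r):min(h, row + r),
             max(1L, col - r):min(w, col + r)]
    n <- length(win)
    s1 <- sum(win)
    ## the pass test compares n^2 * variance against (n * Th)^2 -- exact
    ## integer arithmetic for 8-bit planes, so threshold ties (windows whose
    ## population sd equals Th exactly) are decided without rounding
    pass <- if (params$variability_statistic == "stddev") {
      n * sum(win * win) - s1 * s1 <= (n * th)^2
    } else {
      max(win) - min(win) <= th
    }
    if (!pass) break
    val <- s1 / n
  }
  val
}

#' Adaptive local averaging filter
#'
#' Denoises a luminance plane by replacing every pixel with the mean of the
#' largest centered quadratic window whose brightness variability does not
#' exceed the threshold Th. The patch radius grows from 1 (3 x 3 window) to
#' `max_extent %/% 2` (41 x 41 at defaults) and stops at the first radius
#' whose variability exceeds Th; near contours the admissible window is
#' small (or the pixel is left untouched), in homogeneous regions it is
#' large, which trades spatial resolution for signal-to-noise ratio without
#' crossing edges.
#'
#' All radii are evaluated with vectorized windowed moments; the result
#' equals [ala_pixel()] applied at every coordinate (exactly so for
#' integer-valued planes). Output values never leave the input's
#' \[min, max\] range, and constant planes are fixed points.
#'
#' @param y gray plane matrix (at least `min_extent` pixels on each side).
#' @param params an [ala_params()] object; a `NULL` threshold is derived
#'   from `y`'s global statistics.
#' @return the filtered plane, same dimensions as `y`.
#' @seealso [filter_tiled()] for seam-free multi-core execution.
#' @examples
#' y <- matrix(96, 32, 32) + matrix(rnorm(32 * 32, sd = 4), 32, 32)
#' y <- pmin(pmax(y, 0), 255)
#' f <- ala_filter(y, ala_params(threshold = 8))
#' c(sd(y), sd(f))   # variance shrinks on noise-only planes
#' @export
ala_filter <- function(y, params = ala_params()) {
  y <- as_gray_plane(y)
  params <- .resolve_params(y, params)
  h <- nrow(y); w <- ncol(y)
  if (h < params$min_extent || w < params$min_extent) {
    stop("size error: plane smaller than min_extent (", params$min_extent, ")")
  }
  th <- params$threshold
  rmax <- params$max_extent %/% 2L
  use_sd <- params$variability_statistic == "stddev"
  y2 <- if (use_sd) y * y
  out <- y
  alive <- matrix(TRUE, h, w)   # pixels whose every window so far passed
  for (r in seq_len(rmax)) {
    cnt <- .box_count(h, w, r)
    s1 <- .box_sum(y, r)
    mu <- s1 / cnt
    ## decision on n^2 * variance vs (n * Th)^2: exact for 8-bit planes,
    ## so threshold ties are reproducible across all computation paths
    pass <- if (use_sd) {
      cnt * .box_sum(y2, r) - s1 * s1 <= (cnt * th)^2
    } else {
      .box_range(y, r) <= th
    }
    upd <- alive & pass
    out[upd] <- mu[upd]
    alive <- upd
    if (!any(alive)) break
  }
  out
}
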
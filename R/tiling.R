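#' Tile a plane with halo overlap
#'
#' Splits an `height` x `width` plane into `n_tiles` core regions that
#' partition the plane exactly (no overlap, no gap), each carrying a padded
#' region expanded by `halo` pixels on every side and clipped to the plane
#' bounds. For `n_tiles = 4` the split is the classic quadrant layout;
#' any other count produces equal-height row strips.
#'
#' The halo is what makes tiled filtering seam-free: when it is at least
#' the filter's maximum window radius, every core pixel's window lies
#' entirely inside the padded region, so tile-local filtering reproduces
#' full-frame filtering exactly.
#'
#' @param height,width plane dimensions in pixels.
#' @param n_tiles number of tiles (>= 1).
#' @param halo overlap width in pixels (>= 0, default 20 — the maximum ALA
#'   window radius at default parameters).
#' @return a list of tile specs; each is a list with integer vectors
#'   `core` and `padded` of the form `c(row1, row2, col1, col2)`
#'   (1-based, inclusive) and the scalar `halo`.
#' @export
make_tiles <- function(height, width, n_tiles = 4L, halo = 20L) {
  height <- as.integer(height); width <- as.integer(width)
  n_tiles <- as.integer(n_tiles); halo <- as.integer(halo)
  if (n_tiles < 1L) stop("configuration error: n_tiles must be >= 1")
  if (halo < 0L) stop("configuration error: halo must be >= 0")
  if (height < 1L || width < 1L) stop("configuration error: empty plane")

  cores <- if (n_tiles == 4L && height >= 2L && width >= 2L) {
    rs <- height %/% 2L; cs <- width %/% 2L
    list(c(1L, rs, 1L, cs), c(1L, rs, cs + 1L, width),
         c(rs + 1L, height, 1L, cs), c(rs + 1L, height, cs + 1L, width))
  } else {
    if (n_tiles > height) {
      stop("configuration error: n_tiles (", n_tiles,
           ") exceeds plane height (", height, ")")
    }
    b <- unique(as.integer(round(seq(0L, height, length.out = n_tiles + 1L))))
    lapply(seq_len(length(b) - 1L), function(i) c(b[i] + 1L, b[i + 1L], 1L, width))
  }
  lapply(cores, function(co) {
    list(core = co,
         padded = c(max(1L, co[1L] - halo), min(height, co[2L] + halo),
                    max(1L, co[3L] - halo), min(width, co[4L] + halo)),
         halo = halo)
  })
}

#' Tiled (optionally parallel) ALA filtering
#'
#' Runs [ala_filter()] independently on each tile's padded region, crops
#' out the core, and stitches the cores back together. With a halo of at
#' least the maximum window radius (`max_extent %/% 2`, the default) the
#' result is sample-for-sample identical to full-frame filtering: windows
#' of core pixels never reach the padded border, and tiles at true image
#' borders clip their windows exactly as the full frame would. Reducing the
#' halo below the window radius re-introduces the horizontal/vertical line
#' artifacts tiling is known for (useful as a negative control only).
#'
#' A `NULL` threshold in `params` is resolved once from the full plane's
#' global statistics before tiling, so tiles share the single global Th.
#'
#' @param y gray plane matrix.
#' @param params an [ala_params()] object.
#' @param n_tiles number of tiles (default 4).
#' @param parallel dispatch tiles to forked worker processes
#'   (`parallel::mclapply`); the result is identical to serial execution.
#' @param halo overlap width override; defaults to `max_extent %/% 2`.
#'   Values below that default emit a warning.
#' @return the filtered plane, same dimensions as `y`.
#' @export
filter_tiled <- function(y, params = ala_params(), n_tiles = 4L,
                         parallel = FALSE, halo = NULL) {
  y <- as_gray_plane(y)
  params <- .resolve_params(y, params)
  rmax <- params$max_extent %/% 2L
  if (is.null(halo)) {
    halo <- rmax
  } else if (halo < rmax) {
    warning("halo (", halo, ") smaller than the maximum window radius (",
            rmax, "): tile seams will differ from full-frame filtering")
  }
  tiles <- make_tiles(nrow(y), ncol(y), n_tiles = n_tiles, halo = halo)
  worker <- function(i) {
    t <- tiles[[i]]
    p <- t$padded
    sub <- y[p[1L]:p[2L], p[3L]:p[4L], drop = FALSE]
    f <- tryCatch(ala_filter(sub, params), error = function(e) {
      stop("tile ", i, " [rows ", t$core[1L], "-", t$core[2L], ", cols ",
           t$core[3L], "-", t$core[4L], "]: ", conditionMessage(e),
           call. = FALSE)
    })
    co <- t$core
    f[(co[1L] - p[1L] + 1L):(co[2L] - p[1L] + 1L),
      (co[3L] - p[3L] + 1L):(co[4L] - p[3L] + 1L), drop = FALSE]
  }
  results <- if (parallel) {
    n_cores <- max(1L, min(length(tiles), parallel::detectCores()))
    res <- parallel::mclapply(seq_along(tiles), worker, mc.cores = n_cores)
    bad <- vapply(res, inherits, logical(1L), what = "try-error")
    if (any(bad)) stop(attr(res[[which(bad)[1L]]], "condition")$message)
    res
  } else {
    lapply(seq_along(tiles), worker)
  }
  out <- matrix(0, nrow(y), ncol(y))
  for (i in seq_along(tiles)) {
    co <- tiles[[i]]$core
    out[co[1L]:co[2L], co[3L]:co[4L]] <- results[[i]]
  }
  out
}
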
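#' Synthetic test scenes
#'
#' Deterministic clean scenes for exercising the denoising pipeline without
#' external data. Every kind except `flat` contains at least one sharp
#' contour and at least one homogeneous region — the two features the
#' adaptive filter must respectively preserve and smooth.
#'
#' Kinds:
#' * `flat` — constant image at `levels[1]`.
#' * `two_region_step` — left half `levels[1]`, right half `levels[2]`,
#'   vertical boundary between columns `floor(W/2)` and `floor(W/2) + 1`.
#' * `gradient_ramp` — horizontal linear ramp from `levels[1]` to
#'   `levels[2]`.
#' * `checker` — checkerboard of 16-pixel blocks alternating `levels[1]`
#'   and `levels[2]`.
#' * `blobs_texture` — seeded elliptical blobs of distinct gray levels over
#'   a background whose left third carries a high-contrast piecewise-constant
#'   stripe texture (8-px stripes at levels 45/150) while the rest stays
#'   homogeneous. Every scene feature is either a sharp high-contrast
#'   contour (blob and stripe boundaries, which an edge-preserving filter
#'   must keep) or a flat region (which it must smooth); mid-contrast
#'   texture below the variability threshold is deliberately absent, since
#'   adaptive local averaging flattens it by construction (see the package
#'   vignette on limitations).
#'
#' Scene values are integers; the three color channels are identical
#' (channel-dependent behavior is exercised through per-channel noise in
#' [add_noise()]).
#'
#' @param kind scene kind, see above.
#' @param size integer `c(H, W)` (default 128 x 128).
#' @param levels region gray values; defaults per kind.
#' @param seed RNG seed for the randomized `blobs_texture` kind
#'   (deterministic given the seed; ignored by the other kinds).
#' @return an H x W x 3 array in \[0, 255\].
#' @export
make_scene <- function(kind = c("flat", "two_region_step", "gradient_ramp",
                                "checker", "blobs_texture"),
                       size = c(128L, 128L), levels = NULL, seed = 1L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 2L)) {
    stop("configuration error: size must be two integers >= 2")
  }
  h <- size[1L]; w <- size[2L]
  if (is.null(levels)) {
    levels <- switch(kind,
                     flat = 96, two_region_step = c(50, 200),
                     gradient_ramp = c(0, 255), checker = c(40, 215),
                     blobs_texture = 90)
  }
  g <- switch(kind,
    flat = matrix(levels[1L], h, w),
    two_region_step = {
      m <- matrix(levels[1L], h, w)
      m[, (w %/% 2L + 1L):w] <- levels[2L]
      m
    },
    gradient_ramp = {
      ramp <- levels[1L] + (levels[2L] - levels[1L]) * (seq_len(w) - 1L) / (w - 1L)
      matrix(ramp, h, w, byrow = TRUE)
    },
    checker = {
      blk <- 16L
      ri <- (seq_len(h) - 1L) %/% blk
      ci <- (seq_len(w) - 1L) %/% blk
      par <- outer(ri, ci, `+`) %% 2L
      matrix(levels[1L + par], h, w)
    },
    blobs_texture = {
      set.seed(as.integer(seed))
      m <- matrix(levels[1L], h, w)
      xs <- matrix(seq_len(w), h, w, byrow = TRUE)
      ys <- matrix(seq_len(h), h, w)
      band <- seq_len(max(2L, w %/% 3L))
      stripe <- ((xs[, band] - 1L) %/% 8L) %% 2L
      m[, band] <- ifelse(stripe == 0L, 45, 150)
      ## non-overlapping blobs on the homogeneous background, one per cell
      ## of a 2 x 3 grid, with levels at least 60 gray values from the
      ## background so every contour in the scene is high-contrast
      bx0 <- max(band) + 1L
      lv <- sample(c(0, 30, 160, 200, 220, 250))
      cw <- (w - bx0 + 1L) / 3
      ch <- h / 2
      k <- 0L
      for (cr in 0:1) for (cc in 0:2) {
        k <- k + 1L
        cx <- bx0 - 1L + (cc + stats::runif(1, 0.35, 0.65)) * cw
        cy <- (cr + stats::runif(1, 0.35, 0.65)) * ch
        rx <- stats::runif(1, 0.18, 0.30) * cw
        ry <- stats::runif(1, 0.18, 0.30) * ch
        m[((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1] <- lv[k]
      }
      m
    })
  gray_to_color(.clamp255(round(g)))
}

#' Add sensor noise to an image
#'
#' Seeded, reproducible noise models emulating camera sensor noise:
#'
#' * `gaussian` — additive `N(0, sigma^2)`, a stand-in for
#'   readout/dark-current noise.
#' * `poisson_gaussian` — `Poisson(pixel * scale) / scale + N(0, sigma^2)`,
#'   the standard signal-dependent composite in which shot-noise variance
#'   grows with brightness (variance `pixel / scale` at gray value
#'   `pixel`), plus an additive Gaussian floor.
#'
#' `per_channel_sigma` applies a different Gaussian level to each color
#' channel, emulating the channel-dependent noise of real color sensors.
#' Samples are clamped to \[0, 255\] after noise addition (8-bit camera
#' behavior; this introduces a slight mean bias near 0 and 255).
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param model `"gaussian"` or `"poisson_gaussian"`.
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param poisson_scale photon scale s (> 0) of the Poisson component;
#'   larger values mean less shot noise.
#' @param per_channel_sigma optional length-3 vector of per-channel
#'   Gaussian levels, overriding `sigma`.
#' @param seed optional RNG seed; `NULL` draws from the current RNG state
#'   (used when accumulating frames).
#' @return the noisy image, same dimensions, clamped to \[0, 255\].
#' @export
add_noise <- function(img, model = c("gaussian", "poisson_gaussian"),
                      sigma = 5, poisson_scale = 2, per_channel_sigma = NULL,
                      seed = NULL) {
  model <- match.arg(model)
  img <- as_color_image(img)
  if (sigma < 0) stop("domain error: sigma must be non-negative")
  if (poisson_scale <= 0) stop("domain error: poisson_scale must be positive")
  if (!is.null(per_channel_sigma)) {
    if (length(per_channel_sigma) != 3L || any(per_channel_sigma < 0)) {
      stop("per_channel_sigma must be three non-negative values")
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(img)
  out <- if (model == "poisson_gaussian") {
    array(stats::rpois(n, lambda = img * poisson_scale) / poisson_scale,
          dim = dim(img))
  } else {
    img
  }
  if (is.null(per_channel_sigma)) {
    out <- out + stats::rnorm(n, sd = sigma)
  } else {
    for (ch in 1:3) {
      out[, , ch] <- out[, , ch] +
        stats::rnorm(n / 3L, sd = per_channel_sigma[ch])
    }
  }
  .clamp255(out)
}

#' Frame-averaged ground truth
#'
#' Emulates the acquisition protocol behind real-world noisy image
#' datasets: a static scene is "captured" `n_frames` times under the given
#' noise model and the per-pixel mean of the frames is taken as the ground
#' truth. As `n_frames` grows the result converges to the clean scene (up
#' to the small clamping bias near 0/255), with residual standard deviation
#' about `sigma / sqrt(n_frames)` for Gaussian noise.
#'
#' @param clean H x W x 3 clean scene in \[0, 255\].
#' @param n_frames number of averaged noisy realizations (>= 1;
#'   datasets of this kind typically use ~500).
#' @param seed RNG seed fixing the whole frame sequence.
#' @inheritParams add_noise
#' @return the per-pixel mean image, same dimensions as `clean`.
#' @export
make_ground_truth <- function(clean, n_frames = 500L,
                              model = c("gaussian", "poisson_gaussian"),
                              sigma = 5, poisson_scale = 2,
                              per_channel_sigma = NULL, seed = 1L) {
  model <- match.arg(model)
  clean <- as_color_image(clean)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  set.seed(as.integer(seed))
  acc <- array(0, dim = dim(clean))
  for (i in seq_len(n_frames)) {
    acc <- acc + add_noise(clean, model = model, sigma = sigma,
                           poisson_scale = poisson_scale,
                           per_channel_sigma = per_channel_sigma, seed = NULL)
  }
  acc / n_frames
}

#' Write a batch of synthetic fixtures to disk
#'
#' Generates `n_scenes` scenes (cycling through the non-flat kinds), adds
#' sensor noise, computes frame-averaged ground truth, and writes PNG
#' triplets named `<id>_clean.png`, `<id>_real.png`, `<id>_mean.png` — the
#' `_real` / `_mean` suffix convention under which [batch_evaluate()] pairs
#' noisy and ground-truth files — plus a tab-separated `manifest.tsv`
#' recording id, kind, noise parameters and seed.
#'
#' @param out_dir output directory (created if missing).
#' @param n_scenes number of scenes.
#' @param size scene size `c(H, W)`.
#' @param n_frames frames averaged into each ground-truth image.
#' @param seed master seed; scene i uses `seed + i` for its scene, noise
#'   and ground-truth draws.
#' @inheritParams add_noise
#' @return the manifest data frame, invisibly.
#' @export
write_fixture_batch <- function(out_dir, n_scenes = 10L, size = c(128L, 128L),
                                model = c("poisson_gaussian", "gaussian"),
                                sigma = 5, poisson_scale = 2,
                                per_channel_sigma = NULL,
                                n_frames = 100L, seed = 1L) {
  model <- match.arg(model)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  kinds <- c("two_region_step", "gradient_ramp", "checker", "blobs_texture")
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    kind <- kinds[(i - 1L) %% length(kinds) + 1L]
    s <- as.integer(seed) + i
    clean <- make_scene(kind, size = size, seed = s)
    noisy <- add_noise(clean, model = model, sigma = sigma,
                       poisson_scale = poisson_scale,
                       per_channel_sigma = per_channel_sigma, seed = s)
    truth <- make_ground_truth(clean, n_frames = n_frames, model = model,
                               sigma = sigma, poisson_scale = poisson_scale,
                               per_channel_sigma = per_channel_sigma,
                               seed = s + 10000L)
    id <- sprintf("scene%02d_%s", i, kind)
    write_image(clean, file.path(out_dir, paste0(id, "_clean.png")))
    write_image(noisy, file.path(out_dir, paste0(id, "_real.png")))
    write_image(truth, file.path(out_dir, paste0(id, "_mean.png")))
    rows[[i]] <- data.frame(id = id, kind = kind, model = model,
                            sigma = sigma, poisson_scale = poisson_scale,
                            n_frames = n_frames, seed = s,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
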
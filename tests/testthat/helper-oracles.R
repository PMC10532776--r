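## Independent reference implementations and fixture helpers shared by the
## test files. These deliberately re-derive each quantity along a different
## arithmetic route than the package (double loops, two-pass statistics)
## so agreement is evidence, not tautology.

## Brute-force per-pixel adaptive local averaging: grow the window radius
## until n^2 * variance exceeds (n * Th)^2 (exact integer arithmetic for
## 8-bit planes; the n^2-variance is evaluated as sum((n x - S1)^2) / n,
## a different exact decomposition than the package's n S2 - S1^2).
oracle_ala <- function(y, th, rmax = 20L, statistic = "stddev") {
  h <- nrow(y); w <- ncol(y)
  out <- y
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      val <- y[i, j]
      for (r in seq_len(rmax)) {
        win <- y[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
        n <- length(win)
        s1 <- sum(win)
        bad <- if (statistic == "stddev") {
          sum((n * win - s1)^2) / n > (n * th)^2
        } else {
          max(win) - min(win) > th
        }
        if (bad) break
        val <- s1 / n
      }
      out[i, j] <- val
    }
  }
  out
}

## Naive windowed SSIM: explicit loop over every fully-interior window,
## two-pass means/variances, same constants as the package.
oracle_ssim <- function(a, b, window = 7L, K1 = 0.01, K2 = 0.03, L = 255) {
  r <- window %/% 2L
  h <- nrow(a); w <- ncol(a)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in (r + 1L):(h - r)) {
    for (j in (r + 1L):(w - r)) {
      wa <- a[(i - r):(i + r), (j - r):(j + r)]
      wb <- b[(i - r):(i + r), (j - r):(j + r)]
      n <- length(wa)
      ma <- mean(wa); mb <- mean(wb)
      va <- sum((wa - ma)^2) / (n - 1)
      vb <- sum((wb - mb)^2) / (n - 1)
      cab <- sum((wa - ma) * (wb - mb)) / (n - 1)
      vals <- c(vals, ((2 * ma * mb + C1) * (2 * cab + C2)) /
                  ((ma^2 + mb^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

## Seeded 8-bit test plane: smooth sinusoidal shading, one flat dark patch
## (a contour), plus Gaussian pixel noise; rounded to integers.
make_test_plane <- function(h, w, sigma = 5, seed = 1) {
  set.seed(seed)
  base <- 120 + 60 * outer(sin(seq_len(h) / 9), cos(seq_len(w) / 11))
  base[seq_len(max(2L, h %/% 3)), seq_len(max(2L, w %/% 3))] <- 40
  round(pmin(pmax(base + stats::rnorm(h * w, sd = sigma), 0), 255))
}

## Half-max crossing of a vertical step edge: for each row, the
## (interpolated) column where the profile crosses the midpoint of the
## plane's extreme levels; returns the median over rows.
edge_position <- function(plane) {
  lo <- min(plane); hi <- max(plane)
  mid <- (lo + hi) / 2
  pos <- apply(plane, 1L, function(row) {
    above <- which(row >= mid)
    if (length(above) == 0L || above[1L] == 1L) return(NA_real_)
    j <- above[1L]
    j - 1 + (mid - row[j - 1]) / (row[j] - row[j - 1])
  })
  stats::median(pos, na.rm = TRUE)
}
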
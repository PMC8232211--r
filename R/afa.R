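#' Adaptive detrending of a time series
#'
#' Builds the globally smooth trend used by adaptive fractal analysis:
#' the series is partitioned into windows of odd length w = 2n + 1 whose
#' starts advance by n points, so neighbouring windows share n + 1 points;
#' each window is fitted with a polynomial of order `M` and the fits are
#' stitched in the overlaps with weights varying linearly from 1 to 0, which
#' makes the trend continuous.
#'
#' @param u numeric series
#' @param w odd window length >= 3, < length(u)
#' @param M polynomial order (1 = local linear, the standard choice)
#' @return numeric trend of the same length as `u`
#' @export
adaptive_trend <- function(u, w, M = 1) {
  N <- length(u)
  if (w %% 2 != 1 || w < 3) stop("w must be odd and >= 3")
  if (w >= N) stop("window length w must be smaller than the series")
  n <- (w - 1) / 2

  starts <- seq(1, N - w + 1, by = n)
  if (starts[length(starts)] + w - 1 < N) starts <- c(starts, N - w + 1)

  fitwin <- function(s) {
    idx <- s:(s + w - 1)
    x <- idx - s  # local coordinate
    co <- stats::lm.fit(outer(x, 0:M, "^"), u[idx])$coefficients
    as.numeric(outer(x, 0:M, "^") %*% co)
  }

  trend <- rep(NA_real_, N)
  prev_end <- 0
  for (s in starts) {
    y <- fitwin(s)
    e <- s + w - 1
    if (prev_end == 0) {
      trend[s:e] <- y
    } else {
      ov_lo <- s
      ov_hi <- min(prev_end, e)
      L <- ov_hi - ov_lo + 1
      if (L > 1) {
        l <- seq_len(L)
        w2 <- (l - 1) / (L - 1)   # new window weight ramps 0 -> 1
        trend[ov_lo:ov_hi] <- (1 - w2) * trend[ov_lo:ov_hi] +
          w2 * y[seq_len(L)]
      }
      if (e > ov_hi) trend[(ov_hi + 1):e] <- y[(ov_hi - s + 2):w]
    }
    prev_end <- max(prev_end, e)
  }
  trend
}

#' Fluctuation function and Hurst exponents by adaptive fractal analysis
#'
#' For each window size w the residual fluctuation
#' F(w) = sqrt(mean((u - trend_w)^2)) is computed; F(w) ~ w^H defines the
#' Hurst parameter H as the slope of log2 F against log2 w. Within the
#' fBm/fGn family 0 < H < 1/2 indicates anti-persistent, H = 1/2 short-range
#' and 1/2 < H < 1 persistent long-range correlations; H > 1 lies beyond
#' that family and signals superdiffusive processes.
#'
#' @param u numeric series
#' @param w window sizes (odd, increasing); defaults to dyadic 2^j + 1
#' @param M detrending polynomial order
#' @return object of class `afa_result`: data.frame `scaling` (w, F),
#'   `M`, and the input length; windows with F = 0 (perfectly detrended)
#'   are dropped with a warning
#' @export
afa <- function(u, w = NULL, M = 1) {
  N <- length(u)
  if (is.null(w)) {
    jmax <- floor(log2(N / 4))
    w <- 2^(2:jmax) + 1
  }
  w <- sort(unique(as.integer(w)))
  if (any(w %% 2 != 1)) stop("window sizes must be odd")
  w <- w[w < N]
  if (length(w) < 2) stop("need at least two usable window sizes")
  FF <- vapply(w, function(wi)
    sqrt(mean((u - adaptive_trend(u, wi, M))^2)), numeric(1))
  zero <- FF <= 1e-12 * (stats::sd(u) + abs(mean(u)) + 1e-300)
  if (any(zero)) {
    warning("dropping window(s) with zero residual fluctuation")
    w <- w[!zero]; FF <- FF[!zero]
    if (length(w) < 2)
      stop("signal is (almost) perfectly detrended at every window size")
  }
  structure(list(scaling = data.frame(w = w, F = FF), M = M, n = N),
            class = "afa_result")
}

#' @export
print.afa_result <- function(x, ...) {
  cat(sprintf("AFA (order-%d detrending) of a %d-point series\n", x$M, x$n))
  h <- afa_hurst(x)
  cat(sprintf("global Hurst fit: H = %.3f over w in [%d, %d]\n",
              h$H, min(x$scaling$w), max(x$scaling$w)))
  invisible(x)
}

#' Hurst exponent from an AFA scaling curve
#'
#' Least-squares slope of log2 F(w) vs log2 w, optionally restricted to a
#' window-size range (the scaling regime of interest).
#' @param res an `afa_result`
#' @param w_range c(min, max) window sizes to include
#' @return list: `H`, `intercept`, `n_points`
#' @export
afa_hurst <- function(res, w_range = NULL) {
  sc <- res$scaling
  if (!is.null(w_range))
    sc <- sc[sc$w >= w_range[1] & sc$w <= w_range[2], ]
  if (nrow(sc) < 2) stop("fewer than 2 points in the requested range")
  fit <- stats::lm.fit(cbind(1, log2(sc$w)), log2(sc$F))
  list(H = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n_points = nrow(sc))
}

#' Two-segment Hurst fit with automatic breakpoint detection
#'
#' Continuous two-segment linear fit of log2 F vs log2 w, scanning all
#' interior breakpoints and minimizing the total squared residual. Returns
#' the two slopes and the crossover window size.
#' @param res an `afa_result`
#' @param min_points smallest number of window sizes per segment
#' @return list: `H1`, `H2`, `w_cross`, `rss`
#' @export
afa_segments <- function(res, min_points = 3) {
  lw <- log2(res$scaling$w); lf <- log2(res$scaling$F)
  n <- length(lw)
  if (n < 2 * min_points) stop("too few window sizes for a two-segment fit")
  best <- NULL; best_rss <- Inf
  for (bp in min_points:(n - min_points + 1)) {
    hinge <- pmax(lw - lw[bp], 0)
    fit <- stats::lm.fit(cbind(1, lw, hinge), lf)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      co <- fit$coefficients
      best <- list(H1 = unname(co[2]), H2 = unname(co[2] + co[3]),
                   w_cross = 2^lw[bp], rss = rss)
    }
  }
  best
}

#' Extent of the super-unit scaling regime
#'
#' Local scaling exponents are computed between consecutive window sizes of
#' an AFA curve; the function returns the largest window size up to which
#' the local exponent still exceeds `threshold` (window sizes map to time
#' extents when the series is sampled on a uniform grid). Used to measure
#' for how long an H > 1 (superdiffusive) scaling regime persists.
#'
#' @param res an `afa_result`
#' @param threshold exponent threshold (default 1)
#' @return largest window size w with local slope above the threshold, or NA
#'   if the first local slope is already below it
#' @export
hurst_persistence <- function(res, threshold = 1) {
  sc <- res$scaling
  sl <- diff(log2(sc$F)) / diff(log2(sc$w))
  above <- which(sl > threshold)
  if (!length(above)) return(NA_real_)
  sc$w[max(above) + 1]
}

#' Fractional Brownian motion by circulant-embedding spectral synthesis
#'
#' Exact (Davies-Harte) synthesis: fractional Gaussian noise increments with
#' the target Hurst exponent are generated from the eigenvalues of the
#' circulant embedding of their autocovariance, then cumulated. Bit-for-bit
#' deterministic for a fixed seed; the caller's random-number state is left
#' untouched.
#'
#' @param H Hurst exponent, in (0, 1)
#' @param n series length (a power of two)
#' @param seed integer seed
#' @return numeric fBm path of length n (unit-variance increments)
#' @export
fbm_generator <- function(H, n, seed) {
  if (H <= 0 || H >= 1) stop("H must lie in (0, 1)")
  if (n < 2 || bitwAnd(n, n - 1L) != 0) stop("n must be a power of two")
  gam <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                              abs(k - 1)^(2 * H))
  m <- 2L * n
  first_row <- c(gam(0:n), gam((n - 1):1))
  ev <- Re(stats::fft(first_row))
  ev[ev < 0] <- 0  # clip tiny negative round-off

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  W <- complex(length.out = m)
  W[1] <- sqrt(ev[1]) * stats::rnorm(1)
  W[n + 1] <- sqrt(ev[n + 1]) * stats::rnorm(1)
  k <- 2:n
  re <- stats::rnorm(n - 1); im <- stats::rnorm(n - 1)
  W[k] <- sqrt(ev[k] / 2) * complex(real = re, imaginary = im)
  W[m + 2 - k] <- Conj(W[k])
  fgn <- Re(stats::fft(W, inverse = FALSE))[1:n] / sqrt(m)
  cumsum(fgn)
}
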
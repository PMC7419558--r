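#' Wiener filter configuration
#'
#' @param window odd window side in pixels (>= 3; default 5, small enough to
#'   preserve 8-mm lesions at sub-millimetre detector pitch).
#' @param noise_variance additive noise variance in counts^2, or `"auto"` to
#'   estimate it from the image via [estimate_noise_variance()].
#' @return A `wiener_config` list.
#' @export
wiener_config <- function(window = 5L, noise_variance = "auto") {
  window <- as.integer(window)
  .assert(window >= 3 && window %% 2 == 1, "window must be odd and >= 3")
  if (!identical(noise_variance, "auto")) {
    .assert(is.numeric(noise_variance) && noise_variance >= 0,
            "noise_variance must be >= 0 or \"auto\"")
  }
  structure(list(window = window, noise_variance = noise_variance),
            class = "wiener_config")
}

# sliding-window sums with symmetric reflection padding, via integral image
.box_sums <- function(img, w) {
  r <- (w - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  .assert(r >= 1 && r < n && r < m, "window must be smaller than the image")
  ridx <- c((r + 1L):2L, seq_len(n), (n - 1L):(n - r))
  cidx <- c((r + 1L):2L, seq_len(m), (m - 1L):(m - r))
  pad <- img[ridx, cidx]
  B <- apply(pad, 2, cumsum)
  B <- t(apply(B, 1, cumsum))
  I <- matrix(0, n + 2 * r + 1, m + 2 * r + 1)
  I[-1, -1] <- B
  i1 <- seq_len(n); j1 <- seq_len(m)
  I[i1 + 2 * r + 1, j1 + 2 * r + 1] - I[i1, j1 + 2 * r + 1] -
    I[i1 + 2 * r + 1, j1] + I[i1, j1]
}

# local mean and unbiased local variance over a w x w sliding window
.local_stats <- function(img, w) {
  n_win <- w * w
  s1 <- .box_sums(img, w)
  s2 <- .box_sums(img * img, w)
  m <- s1 / n_win
  v <- (s2 - n_win * m * m) / (n_win - 1)
  v[v < 0] <- 0
  list(mean = m, var = v)
}

#' Space-variant adaptive Wiener filter
#'
#' Local minimum-mean-square-error shrinkage toward the local mean,
#' targeted at additive noise of known (or estimated) variance:
#' `out = m + max(v - v_n, 0) / max(v, v_n) * (in - m)` with `m`, `v` the
#' local window mean and unbiased variance and `v_n` the noise variance.
#' Zero assumed noise gives the identity; a locally constant patch returns
#' the local mean. Edges are handled by symmetric reflection padding.
#'
#' @param image 2D numeric matrix (finite values).
#' @param config a [wiener_config()].
#' @return Filtered matrix of the same dimensions.
#' @export
adaptive_wiener <- function(image, config = wiener_config()) {
  .assert(is.matrix(image) && all(is.finite(image)),
          "image must be a finite numeric matrix")
  w <- config$window
  .assert(w < nrow(image) && w < ncol(image),
          "window must be smaller than the image")
  v_n <- if (identical(config$noise_variance, "auto")) {
    estimate_noise_variance(image, window = w)
  } else {
    config$noise_variance
  }
  st <- .local_stats(image, w)
  denom <- pmax(st$var, v_n)
  gain <- ifelse(denom > 0, pmax(st$var - v_n, 0) / denom, 0)
  st$mean + gain * (image - st$mean)
}

#' Estimate additive noise variance from an image
#'
#' Robust plug-in for the Wiener filter's `"auto"` mode: the median of the
#' sliding-window local variances. In smooth regions the local variance is
#' dominated by noise, so the median over the image tracks the additive
#' noise floor while ignoring high-variance structure.
#'
#' @param image 2D numeric matrix larger than the window.
#' @param window odd window side (default 5).
#' @return Nonnegative variance estimate (counts^2).
#' @export
estimate_noise_variance <- function(image, window = 5L) {
  .assert(is.matrix(image) && all(is.finite(image)),
          "image must be a finite numeric matrix")
  .assert(window < nrow(image) && window < ncol(image),
          "image must be larger than the window")
  st <- .local_stats(image, as.integer(window))
  max(0, stats::median(st$var))
}

#' Wiener-filter every view of a projection set
#'
#' @param pset a `projection_set`.
#' @param config a [wiener_config()].
#' @return The projection set with filtered images; geometry and metadata
#'   are unchanged, with `wiener` recorded in `noise_meta`.
#' @export
wiener_filter_projections <- function(pset, config = wiener_config()) {
  out <- pset
  out$images <- lapply(pset$images, adaptive_wiener, config = config)
  out$noise_meta <- c(pset$noise_meta,
                      list(wiener = list(window = config$window,
                                         noise_variance = config$noise_variance)))
  out
}
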
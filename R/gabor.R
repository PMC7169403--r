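#' Gaussian envelope width from the half-response spatial-frequency bandwidth
#'
#' The Gabor envelope sigma is never set directly: it is coupled to the
#' wavelength `lambda` through the half-response spatial-frequency bandwidth
#' `b` (in octaves),
#' \deqn{\sigma = \lambda \frac{1}{\pi}\sqrt{\frac{\ln 2}{2}}
#'       \frac{2^b + 1}{2^b - 1}.}
#' At the conventional default `b = 1` this gives `sigma = 0.56 lambda`.
#'
#' @param b bandwidth in octaves, `> 0`.
#' @param lambda wavelength in pixels per cycle, `> 0`.
#' @return sigma in pixels.
#' @seealso [bandwidth_from_sigma()] for the inverse relation.
#' @export
#' @examples
#' sigma_from_bandwidth(1, 10) # 5.6
sigma_from_bandwidth <- function(b, lambda) {
  if (any(b <= 0) || any(lambda <= 0))
    lv_error("lvmark_domain", "bandwidth and wavelength must be positive")
  lambda * (1 / pi) * sqrt(log(2) / 2) * (2^b + 1) / (2^b - 1)
}

#' Bandwidth in octaves from the sigma/lambda ratio
#'
#' Inverse of [sigma_from_bandwidth()]:
#' \deqn{b = \log_2 \frac{(\sigma/\lambda)\pi + \sqrt{\ln 2 / 2}}
#'                        {(\sigma/\lambda)\pi - \sqrt{\ln 2 / 2}}.}
#' Defined only for `sigma/lambda > sqrt(ln 2 / 2) / pi`; at or below that
#' pole the log argument is non-positive and a domain error is raised.
#'
#' @param sigma Gaussian envelope width, pixels.
#' @param lambda wavelength, pixels per cycle.
#' @return bandwidth in octaves.
#' @export
#' @examples
#' bandwidth_from_sigma(0.56, 1) # ~1
bandwidth_from_sigma <- function(sigma, lambda) {
  if (any(sigma <= 0) || any(lambda <= 0))
    lv_error("lvmark_domain", "sigma and wavelength must be positive")
  k <- sqrt(log(2) / 2)
  r <- (sigma / lambda) * pi
  if (any(r <= k))
    lv_error("lvmark_domain",
             sprintf("sigma/lambda must exceed %.6f for a finite bandwidth", k / pi))
  log2((r + k) / (r - k))
}

#' Gabor filter parameters
#'
#' Bundles the five free parameters of a real Gabor filter; the envelope
#' `sigma` is derived from `bandwidth` and `lambda` and cannot be set
#' directly.
#'
#' @param lambda wavelength, pixels per cycle (`> 0`).
#' @param theta orientation of the normal to the sinusoid, radians.
#' @param phase sinusoid phase offset, radians (`0` even, `pi/2` odd).
#' @param gamma spatial aspect ratio; values `< 1` make the envelope
#'   elliptical across the stripes.
#' @param bandwidth half-response spatial-frequency bandwidth, octaves.
#' @return a `gabor_params` object (list with a derived `sigma` field).
#' @export
gabor_params <- function(lambda, theta = 0, phase = 0, gamma = 0.5, bandwidth = 1) {
  if (lambda <= 0 || gamma <= 0 || bandwidth <= 0)
    lv_error("lvmark_domain", "lambda, gamma and bandwidth must be positive")
  structure(list(lambda = lambda, theta = theta, phase = phase, gamma = gamma,
                 bandwidth = bandwidth,
                 sigma = sigma_from_bandwidth(bandwidth, lambda)),
            class = "gabor_params")
}

#' @export
print.gabor_params <- function(x, ...) {
  cat(sprintf(
    "Gabor params: lambda=%.3g px, theta=%.3f rad, phase=%.3f, gamma=%.3g, b=%.3g oct (sigma=%.3g px)\n",
    x$lambda, x$theta, x$phase, x$gamma, x$bandwidth, x$sigma))
  invisible(x)
}

#' Sample a real Gabor kernel
#'
#' Evaluates
#' \deqn{g(x, y) = \exp\!\left(-\frac{x'^2 + \gamma^2 y'^2}{2\sigma^2}\right)
#'       \cos\!\left(\frac{2\pi x'}{\lambda} + \phi\right)}
#' with `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`
#' on the integer grid `[-radius, radius]^2`.  Rows index y (increasing
#' downward), columns index x, and the kernel center value equals
#' `cos(phase)`.
#'
#' @param p a [gabor_params()] object.
#' @param radius half-size in pixels; the default `ceiling(3 sigma)` captures
#'   essentially all of the Gaussian mass.
#' @return a `(2 radius + 1)` square numeric matrix.
#' @export
gabor_kernel <- function(p, radius = ceiling(3 * p$sigma)) {
  stopifnot(inherits(p, "gabor_params"))
  if (radius < 1) lv_error("lvmark_domain", "kernel radius must be >= 1")
  g <- seq(-radius, radius)
  x <- matrix(g, nrow = length(g), ncol = length(g), byrow = TRUE)
  y <- matrix(g, nrow = length(g), ncol = length(g))
  xr <- x * cos(p$theta) + y * sin(p$theta)
  yr <- -x * sin(p$theta) + y * cos(p$theta)
  exp(-(xr^2 + p$gamma^2 * yr^2) / (2 * p$sigma^2)) *
    cos(2 * pi * xr / p$lambda + p$phase)
}

#' Default Gabor bank
#'
#' Four orientations by two wavelengths, each in even/odd phase quadrature.
#' Only the bandwidth default (`b = 1`) is canonical; the rest is a small
#' standard bank that keeps the ROI step fast.
#'
#' @param orientations radians.
#' @param wavelengths pixels per cycle.
#' @param gamma,bandwidth shared across the bank.
#' @param phases phase offsets; `c(0, pi/2)` gives quadrature pairs.
#' @return list of [gabor_params()] objects.
#' @export
default_gabor_bank <- function(orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                               wavelengths = c(8, 16), gamma = 0.5,
                               bandwidth = 1, phases = c(0, pi / 2)) {
  bank <- list()
  for (lam in wavelengths)
    for (th in orientations)
      for (ph in phases)
        bank[[length(bank) + 1L]] <- gabor_params(lam, th, ph, gamma, bandwidth)
  bank
}

# 2-D convolution with reflected-boundary padding (avoids the dark-border
# artifacts circular wrapping would introduce in sector images).
conv2_reflect <- function(img, kern) {
  r <- (nrow(kern) - 1L) / 2L
  h <- nrow(img); w <- ncol(img)
  ri <- c(pmin(r:1, h), seq_len(h), pmax(h - seq_len(r) + 1L, 1L))
  ci <- c(pmin(r:1, w), seq_len(w), pmax(w - seq_len(r) + 1L, 1L))
  pad <- img[ri, ci, drop = FALSE]
  out <- EBImage::filter2(pad, kern, boundary = "circular")
  out[r + seq_len(h), r + seq_len(w), drop = FALSE]
}

#' Maximum-magnitude response of a Gabor bank
#'
#' Convolves the image with every kernel in the bank (reflected-boundary
#' padding) and returns the pointwise maximum of the absolute responses, a
#' non-negative saliency raster of the image's local oscillatory energy.
#'
#' @param img numeric matrix (rows = y).
#' @param bank non-empty list of [gabor_params()].
#' @return numeric matrix, same shape as `img`.
#' @export
filter_bank_response <- function(img, bank = default_gabor_bank()) {
  assert_gray(img)
  if (length(bank) == 0) lv_error("lvmark_domain", "Gabor bank must be non-empty")
  resp <- matrix(0, nrow(img), ncol(img))
  for (p in bank) {
    k <- gabor_kernel(p)
    resp <- pmax(resp, abs(conv2_reflect(img, k)))
  }
  resp
}

#' Region of interest from a saliency raster
#'
#' Thresholds the response with Otsu's method, closes small gaps
#' morphologically, keeps the largest connected component, and reports both
#' the component mask and its bounding box padded by `margin` and clipped to
#' the image.  The box is the search window handed to the Hough stage.
#'
#' @param response non-negative numeric matrix.
#' @param margin padding in pixels added to each side of the bounding box.
#' @return a `roi_mask`: list with `mask` (logical matrix) and `bbox`
#'   `(x0, y0, x1, y1)`, 0-based half-open.
#' @export
extract_roi <- function(response, margin = 8) {
  assert_gray(response)
  if (any(response < 0)) lv_error("lvmark_domain", "response must be non-negative")
  mx <- max(response)
  if (mx <= 0) lv_error("lvmark_no_roi", "response is identically zero")
  norm <- response / mx
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > thr
  if (!any(mask)) lv_error("lvmark_no_roi", "no pixels above threshold")
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(5, shape = "disc"))
  lab <- EBImage::bwlabel(closed)
  areas <- tabulate(as.integer(lab))
  if (length(areas) == 0) lv_error("lvmark_no_roi", "no component survives closing")
  keep <- which.max(areas)
  mask <- matrix(as.integer(lab) == keep, nrow(response), ncol(response))
  roi_from_mask(mask, margin)
}

roi_from_mask <- function(mask, margin = 0) {
  rows <- which(apply(mask, 1, any))
  cols <- which(apply(mask, 2, any))
  bbox <- c(x0 = max(0L, min(cols) - 1L - margin),
            y0 = max(0L, min(rows) - 1L - margin),
            x1 = min(ncol(mask), max(cols) + margin),
            y1 = min(nrow(mask), max(rows) + margin))
  structure(list(mask = mask, bbox = bbox), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI: %d px mask, bbox x [%d, %d), y [%d, %d)\n",
              sum(x$mask), x$bbox["x0"], x$bbox["x1"], x$bbox["y0"], x$bbox["y1"]))
  invisible(x)
}
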
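#' Isotropic two-dimensional Gaussian point spread function
#'
#' Builds the spatial blur kernel `h(x, y) = K * exp(-(x^2 + y^2) / (2 sigma^2))`
#' on a centered odd-sized grid, with the constant K fixed by normalizing
#' the taps to unit sum. This is the standard model for the resolution loss
#' of a CT imaging system.
#'
#' @param sigma blur standard deviation in pixels (> 0).
#' @param size odd kernel width; default `ceil(6 sigma)` rounded up to odd,
#'   wide enough that truncation is negligible.
#' @return a `psf_kernel`: list with `values` (size x size matrix summing to
#'   1) and `center` (row/column index of the (0,0) tap).
#' @export
#' @examples
#' h <- gaussian_psf(1)
#' h$values[h$center[1] + 1, h$center[2]] / h$values[h$center[1], h$center[2]]
#' # exp(-0.5)
gaussian_psf <- function(sigma, size = NULL) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (is.null(size)) {
    size <- ceiling(6 * sigma)
    if (size %% 2L == 0L) size <- size + 1L
  }
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("size must be odd and >= 1", call. = FALSE)
  half <- (size - 1L) %/% 2L
  x <- seq(-half, half)
  g1 <- exp(-x^2 / (2 * sigma^2))
  values <- outer(g1, g1)          # separable: exp(-(x^2+y^2)/(2 sigma^2))
  values <- values / sum(values)
  structure(list(values = values, center = c(half + 1L, half + 1L)),
            class = "psf_kernel")
}

#' @export
print.psf_kernel <- function(x, ...) {
  cat(sprintf("psf_kernel: %d x %d taps, sum %.12f\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

new_otf <- function(values) {
  structure(list(values = values, shape = dim(values)), class = "otf")
}

#' @export
print.otf <- function(x, ...) {
  cat(sprintf("otf: %d x %d, H(0,0) = %.6g%+.3gi\n", x$shape[1L], x$shape[2L],
              Re(x$values[1L, 1L]), Im(x$values[1L, 1L])))
  invisible(x)
}

# Wrapped integer frequency coordinates: index 0..n-1 mapped to the centered
# grid -floor(n/2)..ceil(n/2)-1, then rotated so zero frequency is first.
wrapped_freq <- function(n) {
  idx <- 0:(n - 1L)
  ifelse(idx < ceiling(n / 2), idx, idx - n)
}

#' Turbulence optical transfer function
#'
#' The frequency-domain degradation `H(u, v) = exp(-k (u^2 + v^2)^(5/6))`,
#' borrowed from long-exposure atmospheric turbulence modelling; the 5/6
#' exponent makes it heavier-tailed than a Gaussian transfer function. In
#' the sequence-restoration pipeline it models the residual blur carried by
#' the sparse component. Evaluated on centered integer frequency
#' coordinates, returned with the zero frequency at index (1,1).
#'
#' @param shape length-2 integer vector (height, width).
#' @param k turbulence strength (>= 0); `k = 0` gives the identity transfer
#'   function.
#' @return an `otf`.
#' @export
turbulence_otf <- function(shape, k) {
  if (k < 0) stop("k must be nonnegative", call. = FALSE)
  stopifnot(length(shape) == 2L, all(shape >= 1))
  u <- wrapped_freq(shape[1L])
  v <- wrapped_freq(shape[2L])
  r2 <- outer(u^2, v^2, "+")
  new_otf(exp(-k * r2^(5 / 6)) + 0i)
}

#' Convert a spatial kernel to an optical transfer function
#'
#' Zero-pads the kernel to the frame shape, circularly shifts it so the
#' center tap sits at index (1,1), and takes the 2-D discrete Fourier
#' transform. For a normalized kernel the zero-frequency value is 1.
#'
#' @param kernel a `psf_kernel` (or plain odd-sized matrix, center assumed
#'   at the middle tap).
#' @param shape length-2 (height, width), at least the kernel size.
#' @return an `otf`.
#' @export
psf_to_otf <- function(kernel, shape) {
  if (inherits(kernel, "psf_kernel")) {
    values <- kernel$values; center <- kernel$center
  } else {
    values <- kernel
    center <- (dim(values) + 1L) %/% 2L
  }
  stopifnot(length(shape) == 2L)
  if (nrow(values) > shape[1L] || ncol(values) > shape[2L])
    stop("shape error: kernel is larger than the target shape", call. = FALSE)
  pad <- matrix(0, shape[1L], shape[2L])
  pad[seq_len(nrow(values)), seq_len(ncol(values))] <- values
  # circular shift so the center tap lands at (1,1)
  ri <- ((seq_len(shape[1L]) - 1L + center[1L] - 1L) %% shape[1L]) + 1L
  ci <- ((seq_len(shape[2L]) - 1L + center[2L] - 1L) %% shape[2L]) + 1L
  new_otf(stats::fft(pad[ri, ci, drop = FALSE]))
}

#' Wiener restoration in the frequency domain
#'
#' Applies the approximate Wiener deconvolution filter
#' `W = conj(H) / (|H|^2 + nsr)` to the degraded image and returns the real
#' part of the inverse transform. `nsr` is the constant noise-to-signal
#' power ratio standing in for the unknown spectra; with `nsr = 0` the
#' filter reduces to the inverse filter `1/H`, and frequencies with
#' `|H| < epsilon` are zeroed to keep the output finite.
#'
#' @param g degraded 2-D image (numeric matrix).
#' @param otf an `otf` whose shape matches `dim(g)`.
#' @param nsr nonnegative noise-to-signal ratio constant.
#' @param epsilon guard threshold on `|H|` used only when `nsr = 0`.
#' @return restored image, same shape as `g`.
#' @export
wiener_restore <- function(g, otf, nsr = 0.01, epsilon = 1e-8) {
  stopifnot(inherits(otf, "otf"))
  if (nsr < 0) stop("nsr must be nonnegative", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (!all(dim(g) == otf$shape))
    stop("shape error: image is ", paste(dim(g), collapse = "x"),
         " but otf is ", paste(otf$shape, collapse = "x"), call. = FALSE)
  W <- wiener_filter(otf, nsr, epsilon)
  Fhat <- W * stats::fft(g)
  Re(stats::fft(Fhat, inverse = TRUE)) / length(g)
}

# The frequency-response array of the Wiener filter; exposed internally so
# its gain bound can be asserted directly.
wiener_filter <- function(otf, nsr, epsilon = 1e-8) {
  H <- otf$values
  H2 <- Re(H * Conj(H))
  if (nsr == 0) {
    W <- matrix(0i, nrow(H), ncol(H))
    ok <- sqrt(H2) >= epsilon
    W[ok] <- Conj(H[ok]) / H2[ok]
    W
  } else {
    Conj(H) / (H2 + nsr)
  }
}

#' Match turbulence strength to a known Gaussian blur
#'
#' Finds the turbulence constant k whose transfer function
#' `exp(-k (u^2+v^2)^(5/6))` is closest (least squares over the frequency
#' grid) to the optical transfer function of a Gaussian point spread
#' function with the given standard deviation. Useful in simulation
#' studies where the true blur is Gaussian and the sparse-branch filter
#' needs an equivalent turbulence strength.
#'
#' @param sigma Gaussian blur standard deviation (pixels).
#' @param shape frame shape (height, width).
#' @return the matched k (nonnegative scalar).
#' @export
match_turbulence_k <- function(sigma, shape) {
  G <- Mod(psf_to_otf(gaussian_psf(sigma), shape)$values)
  r2 <- outer(wrapped_freq(shape[1L])^2, wrapped_freq(shape[2L])^2, "+")
  obj <- function(k) sum((exp(-k * r2^(5 / 6)) - G)^2)
  stats::optimize(obj, c(0, 10))$minimum
}

# Circular convolution of an image with an otf (degradation model).
apply_otf <- function(f, otf) {
  stopifnot(all(dim(f) == otf$shape))
  Re(stats::fft(otf$values * stats::fft(f), inverse = TRUE)) / length(f)
}
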
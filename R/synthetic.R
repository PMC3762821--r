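#' Specification of a synthetic CT-like phantom sequence
#'
#' Describes a ground-truthed test sequence with the statistical structure
#' the restoration method assumes: a shared smooth background of prescribed
#' rank across frames (the correlated anatomy), per-frame compact sparse
#' features (disks, mimicking slice-to-slice structures), and degradation
#' by convolutional blur plus additive Gaussian noise.
#'
#' Defaults are the study conditions used throughout the test suite:
#' 10 frames of 64 x 64, background rank 2, 2% sparse support at amplitude
#' 80, Gaussian blur sigma 2 and noise standard deviation 5 on the 0-255
#' scale.
#'
#' @param n_frames number of frames (>= 1).
#' @param height,width frame size in pixels.
#' @param background_rank target rank of the stacked clean background
#'   (<= n_frames).
#' @param sparse_fraction fraction of pixels per frame carrying sparse
#'   features, in \[0, 0.2\].
#' @param sparse_amplitude intensity of the sparse features (0-255 scale).
#' @param blur list `list(kind = "gaussian", sigma = 2)` or
#'   `list(kind = "turbulence", k = 0.0025)`; `sigma = 0` (or `k = 0`)
#'   means no blur.
#' @param noise_std additive Gaussian noise standard deviation (0-255
#'   scale).
#' @param coef_sd relative standard deviation of the per-frame brightness
#'   coefficient of the primary background mode.
#' @param bg_variation root-mean-square intensity (0-255 scale) of the
#'   per-frame deviation contributed by each secondary background mode.
#'   Small values emulate the strong inter-frame correlation of a real CT
#'   series, the regime the restoration model assumes; large values probe
#'   its stated failure mode.
#' @param seed RNG seed; the whole phantom is reproducible from it.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_frames = 10L, height = 64L, width = 64L,
                         background_rank = 2L, sparse_fraction = 0.02,
                         sparse_amplitude = 80,
                         blur = list(kind = "gaussian", sigma = 2),
                         noise_std = 5, coef_sd = 0.01, bg_variation = 2,
                         seed = 0L) {
  if (background_rank > n_frames)
    stop("infeasible spec: background_rank must be <= n_frames", call. = FALSE)
  if (sparse_fraction < 0 || sparse_fraction > 0.2)
    stop("sparse_fraction must lie in [0, 0.2]", call. = FALSE)
  if (noise_std < 0) stop("noise_std must be >= 0", call. = FALSE)
  stopifnot(n_frames >= 1L, height >= 1L, width >= 1L, bg_variation >= 0)
  blur$kind <- match.arg(blur$kind, c("gaussian", "turbulence"))
  structure(list(n_frames = as.integer(n_frames), height = as.integer(height),
                 width = as.integer(width),
                 background_rank = as.integer(background_rank),
                 sparse_fraction = sparse_fraction,
                 sparse_amplitude = sparse_amplitude, blur = blur,
                 noise_std = noise_std, coef_sd = coef_sd,
                 bg_variation = bg_variation, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth zero-mean random field: white noise convolved with a wide
# Gaussian, rescaled to unit rms amplitude.
smooth_field <- function(height, width, smooth_sigma = 8) {
  z <- matrix(stats::rnorm(height * width), height, width)
  # cap the kernel support so it fits small frames
  max_size <- min(height, width)
  if (max_size %% 2L == 0L) max_size <- max_size - 1L
  size <- ceiling(6 * smooth_sigma)
  if (size %% 2L == 0L) size <- size + 1L
  kern <- gaussian_psf(smooth_sigma, size = min(size, max_size))
  f <- apply_otf(z, psf_to_otf(kern, c(height, width)))
  f <- f - mean(f)
  f / sqrt(mean(f^2))
}

# One frame of compact sparse features: random disks on ~`fraction` of the
# pixels, at the given amplitude.
sparse_frame <- function(height, width, fraction, amplitude) {
  S <- matrix(0, height, width)
  if (fraction <= 0) return(S)
  target <- fraction * height * width
  covered <- 0
  while (covered < target) {
    r <- stats::runif(1L, 2, 4)
    cy <- stats::runif(1L, 1, height)
    cx <- stats::runif(1L, 1, width)
    yy <- outer(seq_len(height) - cy, rep(1, width))
    xx <- outer(rep(1, height), seq_len(width) - cx)
    disk <- (yy^2 + xx^2) <= r^2
    S[disk] <- amplitude
    covered <- sum(S != 0)
  }
  S
}

blur_otf_for <- function(blur, shape) {
  if (blur$kind == "gaussian") {
    if (is.null(blur$sigma) || blur$sigma <= 0) return(NULL)
    psf_to_otf(gaussian_psf(blur$sigma), shape)
  } else {
    if (is.null(blur$k) || blur$k <= 0) return(NULL)
    turbulence_otf(shape, blur$k)
  }
}

#' Generate a ground-truthed phantom sequence
#'
#' Builds the clean sequence as `background + sparse features`, where the
#' background is a rank-`background_rank` combination of smooth random
#' basis images with near-constant per-frame coefficients, then degrades
#' every frame by circular convolution with the specified blur and i.i.d.
#' Gaussian noise. All ground-truth components are returned so solver
#' recovery and end-to-end restoration error can be measured exactly.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom_truth` with elements `clean` and
#'   `degraded` ([image_sequence]s), `true_lowrank`, `true_sparse`,
#'   `true_noise` (matrices in stacked form, so that
#'   `stack(clean) = true_lowrank + true_sparse` exactly and
#'   `degraded = blur(clean) + noise`), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width; n <- spec$n_frames
  r <- spec$background_rank
  with_seed(spec$seed, {
    # rank-r background: basis 1 is the anatomy (bright, slowly varying),
    # the rest are low-amplitude per-frame modulations of rms
    # `bg_variation` each
    B <- matrix(0, h * w, r)
    B[, 1L] <- as.vector(t(120 + 25 * smooth_field(h, w)))
    if (r > 1L) for (j in 2:r)
      B[, j] <- as.vector(t(spec$bg_variation * smooth_field(h, w)))
    C <- matrix(0, r, n)
    C[1L, ] <- 1 + stats::rnorm(n, 0, spec$coef_sd)
    if (r > 1L) for (j in 2:r) C[j, ] <- stats::rnorm(n, 0, 1)
    true_lowrank <- B %*% C
    true_sparse <- vapply(seq_len(n), function(i)
      as.vector(t(sparse_frame(h, w, spec$sparse_fraction,
                               spec$sparse_amplitude))),
      numeric(h * w))
    true_sparse <- matrix(true_sparse, nrow = h * w, ncol = n)
    clean_mat <- true_lowrank + true_sparse
    clean <- unstack_matrix(clean_mat, height = h, width = w)

    otf <- blur_otf_for(spec$blur, c(h, w))
    blurred <- lapply(clean$frames, function(f)
      if (is.null(otf)) f else apply_otf(f, otf))
    noise <- lapply(seq_len(n), function(i)
      if (spec$noise_std == 0) matrix(0, h, w)
      else matrix(stats::rnorm(h * w, 0, spec$noise_std), h, w))
    degraded <- image_sequence(
      lapply(seq_len(n), function(i) blurred[[i]] + noise[[i]]),
      source_ids = clean$source_ids)
    true_noise <- vapply(noise, function(f) as.vector(t(f)), numeric(h * w))
    structure(list(clean = clean, degraded = degraded,
                   true_lowrank = true_lowrank, true_sparse = true_sparse,
                   true_noise = matrix(true_noise, nrow = h * w, ncol = n),
                   spec = spec),
              class = "phantom_truth")
  })
}

#' Degrade a single frame by blur and additive Gaussian noise
#'
#' Circular convolution through the given transfer function, plus i.i.d.
#' zero-mean Gaussian noise — the degradation model the restoration
#' pipeline inverts.
#'
#' @param frame numeric matrix.
#' @param otf an `otf` matching `dim(frame)`, or `NULL` for no blur.
#' @param noise_std noise standard deviation (>= 0).
#' @param seed optional seed; when given, the global RNG state is left
#'   untouched.
#' @return degraded frame.
#' @export
degrade <- function(frame, otf = NULL, noise_std = 0, seed = NULL) {
  if (noise_std < 0) stop("noise_std must be >= 0", call. = FALSE)
  g <- if (is.null(otf)) frame else apply_otf(frame, otf)
  add_noise <- function() {
    if (noise_std == 0) g
    else g + matrix(stats::rnorm(length(g), 0, noise_std),
                    nrow(g), ncol(g))
  }
  if (is.null(seed)) add_noise() else with_seed(seed, add_noise())
}
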
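#' Configuration of the sequence-restoration pipeline
#'
#' Gathers the decomposition model choice, its solver options, and the
#' Wiener/PSF parameters for the two restoration branches: the averaged
#' low-rank frame is deconvolved under a Gaussian point spread function
#' (the resolution model of the scanner), while each sparse frame is
#' deconvolved under the turbulence transfer function (the heavier-tailed
#' blur carried by per-frame structures).
#'
#' The PSF/Wiener defaults (`gauss_sigma = 2.5`, `turb_k = 0.0025`,
#' `nsr = 0.01`) are working values for 8-bit CT-like data, not canonical
#' constants; in simulation studies they should be set to the known
#' degradation parameters.
#'
#' @param model `"rpca"`, `"ladmap"`, or `"godec"`. RPCA/LADMAP suit
#'   low-noise sequences (they model no dense noise term); GoDec suits
#'   heavily noisy ones.
#' @param solver_opts a [solver_options()].
#' @param gauss_sigma Gaussian PSF standard deviation (pixels) for the
#'   low-rank branch.
#' @param gauss_nsr Wiener noise-to-signal constant for the low-rank
#'   branch.
#' @param turb_k turbulence strength for the sparse branch.
#' @param turb_nsr Wiener noise-to-signal constant for the sparse branch.
#' @param clip_range length-2 output intensity bounds.
#' @return a list of class `restoration_config`. The `alpha` element (1
#'   when the model carries an explicit noise component, else 0) is derived
#'   from `model`.
#' @export
restoration_config <- function(model = c("rpca", "ladmap", "godec"),
                               solver_opts = solver_options(),
                               gauss_sigma = 2.5, gauss_nsr = 0.01,
                               turb_k = 0.0025, turb_nsr = 0.01,
                               clip_range = c(0, 255)) {
  model <- match.arg(model)
  stopifnot(gauss_sigma > 0, gauss_nsr >= 0, turb_k >= 0, turb_nsr >= 0,
            length(clip_range) == 2L, clip_range[1L] < clip_range[2L])
  structure(list(model = model, solver_opts = solver_opts,
                 gauss_sigma = gauss_sigma, gauss_nsr = gauss_nsr,
                 turb_k = turb_k, turb_nsr = turb_nsr,
                 alpha = if (model == "godec") 1L else 0L,
                 clip_range = clip_range),
            class = "restoration_config")
}

#' Average the low-rank component into a single frame
#'
#' The column-wise arithmetic mean of the low-rank matrix, reshaped to
#' frame geometry: the shared anatomy estimate that the whole sequence
#' contributes to, restored once and added back to every frame.
#'
#' @param L a `data_matrix`, a `decomposition_result` (its `low_rank` with
#'   stored geometry), or a plain matrix with explicit `height`/`width`.
#' @param height,width frame geometry for plain matrices.
#' @return a height x width matrix.
#' @export
mean_lowrank <- function(L, height = NULL, width = NULL) {
  if (inherits(L, "decomposition_result")) {
    height <- if (is.null(height)) L$height else height
    width <- if (is.null(width)) L$width else width
    L <- L$low_rank
  } else if (inherits(L, "data_matrix")) {
    height <- L$height; width <- L$width; L <- L$values
  }
  if (is.null(height) || is.null(width))
    stop("height and width are required", call. = FALSE)
  vec_to_frame(rowMeans(L), height, width)
}

#' Restore a CT image sequence by low-rank decomposition and Wiener
#' filtering
#'
#' The full pipeline: (1) stack the sequence into a matrix, one vectorized
#' frame per column; (2) decompose it into low-rank + sparse (+ noise for
#' GoDec) with the configured solver; (3) average the low-rank columns into
#' one frame and Wiener-restore it under the Gaussian transfer function;
#' (4) Wiener-restore every sparse frame under the turbulence transfer
#' function; (5) recombine — restored frame i is restored sparse frame i
#' plus the restored mean low-rank frame, clipped to the output range. The
#' noise component, when present, is diagnostic only and never added back.
#'
#' A single-frame sequence is accepted (the frame's own low-rank part plays
#' the role of the average) with a warning, since the strength of the
#' method is the shared information across frames.
#'
#' @param seq an [image_sequence].
#' @param cfg a [restoration_config()].
#' @return a `restoration_result`: list with `restored`, `sparse_restored`
#'   ([image_sequence]s), `lowrank_mean_restored` (frame),
#'   `decomposition`, and `report` (quality before/after).
#' @export
restore_sequence <- function(seq, cfg = restoration_config()) {
  stopifnot(inherits(seq, "image_sequence"), inherits(cfg, "restoration_config"))
  if (seq$n_frames < 2L)
    warning("single-frame sequence: restoring from the frame's own low-rank part; ",
            "sequence mode is preferred", call. = FALSE)
  M <- stack_sequence(seq)
  dec <- switch(cfg$model,
                rpca = rpca_alm(M, cfg$solver_opts),
                ladmap = ladmap_rpca(M, cfg$solver_opts),
                godec = godec(M, cfg$solver_opts))
  shape <- c(seq$height, seq$width)
  g_otf <- psf_to_otf(gaussian_psf(cfg$gauss_sigma), shape)
  t_otf <- turbulence_otf(shape, cfg$turb_k)

  Lbar <- mean_lowrank(dec$low_rank, seq$height, seq$width)
  L_rest <- wiener_restore(Lbar, g_otf, cfg$gauss_nsr)
  S_rest <- lapply(seq_len(seq$n_frames), function(i)
    wiener_restore(vec_to_frame(dec$sparse[, i], seq$height, seq$width),
                   t_otf, cfg$turb_nsr))
  lo <- cfg$clip_range[1L]; hi <- cfg$clip_range[2L]
  restored <- lapply(S_rest, function(s) pmin(pmax(s + L_rest, lo), hi))

  restored_seq <- image_sequence(restored, source_ids = seq$source_ids)
  structure(list(
    restored = restored_seq,
    sparse_restored = image_sequence(S_rest, source_ids = seq$source_ids),
    lowrank_mean_restored = L_rest,
    decomposition = dec,
    config = cfg,
    report = list(before = quality_report(seq),
                  after = quality_report(restored_seq))),
    class = "restoration_result")
}

#' @export
print.restoration_result <- function(x, ...) {
  cat(sprintf("restoration_result [%s]: %d frame(s) of %d x %d\n",
              x$decomposition$model, x$restored$n_frames,
              x$restored$height, x$restored$width))
  b <- x$report$before$aggregate; a <- x$report$after$aggregate
  cat(sprintf("  mean SD    %8.4f -> %8.4f\n", b["sd"], a["sd"]))
  cat(sprintf("  mean IE    %8.4f -> %8.4f\n", b["ie"], a["ie"]))
  cat(sprintf("  mean IQMFV %8.1f -> %8.1f\n", b["iqmfv"], a["iqmfv"]))
  invisible(x)
}

#' Single-image Wiener restoration under a Gaussian PSF
#'
#' The whole-image baseline: Wiener deconvolution of one frame under the
#' Gaussian transfer function, with no decomposition. Used as the
#' comparator the sequence method is judged against.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian PSF standard deviation (> 0).
#' @param nsr Wiener noise-to-signal constant.
#' @return restored image.
#' @export
baseline_wiener_gaussian <- function(image, sigma, nsr = 0.01) {
  otf <- psf_to_otf(gaussian_psf(sigma), dim(image))
  wiener_restore(image, otf, nsr)
}

#' Estimate the noise standard deviation of a frame
#'
#' Robust estimate from the median absolute deviation of the high-pass
#' (Laplacian) residual, the usual quick gauge for choosing between the
#' convex models (low noise) and GoDec (high noise).
#'
#' @param image numeric matrix (at least 3 x 3).
#' @return estimated noise standard deviation in intensity units.
#' @export
estimate_noise_std <- function(image) {
  stopifnot(nrow(image) >= 3L, ncol(image) >= 3L)
  f <- image
  lap <- f[2:(nrow(f) - 1L), 2:(ncol(f) - 1L)] * 4 -
    f[1:(nrow(f) - 2L), 2:(ncol(f) - 1L)] -
    f[3:nrow(f), 2:(ncol(f) - 1L)] -
    f[2:(nrow(f) - 1L), 1:(ncol(f) - 2L)] -
    f[2:(nrow(f) - 1L), 3:ncol(f)]
  # MAD of the Laplacian response, normalized: Var(lap) = 20 sigma^2 for
  # i.i.d. noise
  stats::mad(lap) / sqrt(20)
}

#' Pick a decomposition model from the estimated noise level
#'
#' Convenience rule of thumb: `"rpca"` when the estimated noise standard
#' deviation is below `threshold`, `"godec"` above. Explicit model choice
#' is preferred; no quantitative switching rule is canonical.
#'
#' @param seq an [image_sequence].
#' @param threshold noise std (intensity units) separating the regimes.
#' @return `"rpca"` or `"godec"`.
#' @export
auto_select_model <- function(seq, threshold = 8) {
  stopifnot(inherits(seq, "image_sequence"))
  s <- mean(vapply(seq$frames, estimate_noise_std, numeric(1L)))
  if (s < threshold) "rpca" else "godec"
}
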
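#' Restoration-quality metrics
#'
#' Three no-reference indices commonly used to compare restored CT frames:
#'
#' * `std_dev()` — population standard deviation of the pixel values
#'   (normalized by M*N). A larger value means a more dispersed gray-level
#'   distribution, i.e. higher contrast and more visible detail.
#' * `img_entropy()` — Shannon information entropy in bits of the 256-level
#'   gray histogram (values rounded to the nearest integer level and
#'   clamped to \[0, 255\] before binning). Bounded by `log2(bins)`.
#' * `iqmfv()` — the image-quality measurement function value, the squared
#'   population standard deviation (variance) of the pixel values. This
#'   definition reproduces published (SD, IQMFV) pairs to print precision
#'   (e.g. 49.2172^2 = 2422.3); it grows with gray-level spread like SD but
#'   on a squared intensity scale.
#'
#' @param image numeric matrix of intensities on the \[0, 255\] scale.
#' @param bins number of histogram levels for the entropy (default 256).
#' @return a single number: intensity units for `std_dev`, bits for
#'   `img_entropy`, squared intensity units for `iqmfv`.
#' @name quality-metrics
#' @examples
#' img <- matrix(c(0, 2), 1, 2)
#' std_dev(img)   # 1
#' iqmfv(img)     # 1
#' img_entropy(img)  # 1 bit: two equiprobable levels
NULL

#' @rdname quality-metrics
#' @export
std_dev <- function(image) {
  stopifnot(length(image) >= 1L)
  mu <- mean(image)
  sqrt(mean((image - mu)^2))
}

#' @rdname quality-metrics
#' @export
img_entropy <- function(image, bins = 256L) {
  stopifnot(length(image) >= 1L, bins >= 2L)
  lev <- pmin(pmax(round(image), 0), bins - 1L)
  p <- tabulate(lev + 1L, nbins = bins) / length(lev)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @rdname quality-metrics
#' @export
iqmfv <- function(image) {
  std_dev(image)^2
}

#' Per-frame quality report for an image sequence
#'
#' Computes the three quality indices for every frame plus their means,
#' the tabular comparison used to judge restoration quality when no ground
#' truth is available.
#'
#' @param seq an [image_sequence].
#' @return a `quality_report`: list with `frames` (data.frame with columns
#'   `frame`, `sd`, `ie`, `iqmfv`) and `aggregate` (named vector of column
#'   means).
#' @export
quality_report <- function(seq) {
  stopifnot(inherits(seq, "image_sequence"))
  rows <- data.frame(
    frame = seq$source_ids,
    sd = vapply(seq$frames, std_dev, numeric(1L)),
    ie = vapply(seq$frames, img_entropy, numeric(1L)),
    iqmfv = vapply(seq$frames, iqmfv, numeric(1L)),
    stringsAsFactors = FALSE)
  structure(list(frames = rows,
                 aggregate = c(sd = mean(rows$sd), ie = mean(rows$ie),
                               iqmfv = mean(rows$iqmfv))),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("quality_report:\n")
  print(x$frames, row.names = FALSE)
  cat(sprintf("mean: SD %.4f  IE %.4f  IQMFV %.1f\n",
              x$aggregate["sd"], x$aggregate["ie"], x$aggregate["iqmfv"]))
  invisible(x)
}

#' Write a quality report as CSV
#'
#' Columns `frame,SD,IE,IQMFV`, one row per frame plus a `mean` row.
#'
#' @param report a `quality_report`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_quality_report <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  out <- report$frames
  names(out) <- c("frame", "SD", "IE", "IQMFV")
  out <- rbind(out, data.frame(frame = "mean",
                               SD = report$aggregate[["sd"]],
                               IE = report$aggregate[["ie"]],
                               IQMFV = report$aggregate[["iqmfv"]]))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Affinely rescale an image to a target standard deviation
#'
#' Maps `image` to `a * image + b` so that [std_dev()] of the result equals
#' `target_sd` and the mean equals `target_mean`. Used to put test images
#' on a prescribed contrast scale before computing quality indices.
#'
#' @param image non-constant numeric matrix.
#' @param target_sd desired population standard deviation (>= 0).
#' @param target_mean desired mean (default 128, mid-gray).
#' @return rescaled image.
#' @export
rescale_to_sd <- function(image, target_sd, target_mean = 128) {
  s <- std_dev(image)
  if (s == 0) stop("cannot rescale a constant image to a nonzero sd", call. = FALSE)
  (image - mean(image)) * (target_sd / s) + target_mean
}
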
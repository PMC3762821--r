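#' Construct an image sequence
#'
#' An `image_sequence` is an ordered stack of same-sized grayscale frames,
#' stored as numeric matrices on a \[0, 255\] intensity scale. It is the
#' in-memory form of a CT series (or any correlated frame stack) that the
#' decomposition solvers operate on.
#'
#' @param frames list of numeric matrices, all of identical dimensions.
#' @param source_ids optional character vector of per-frame provenance
#'   labels (file names, instance numbers); defaults to `"frame_1"`, ...
#' @return an object of class `image_sequence` with elements `frames`,
#'   `height`, `width`, `n_frames`, `source_ids`.
#' @export
#' @examples
#' seq <- image_sequence(list(matrix(0, 4, 4), matrix(1, 4, 4)))
#' seq$n_frames
image_sequence <- function(frames, source_ids = NULL) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  frames <- lapply(frames, function(f) {
    if (is.null(dim(f)) || length(dim(f)) != 2L)
      stop("each frame must be a 2-D matrix", call. = FALSE)
    storage.mode(f) <- "double"
    f
  })
  dims <- vapply(frames, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("dimension mismatch: all frames must share the same height and width",
         call. = FALSE)
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1L))))
    stop("frames contain non-finite intensity values", call. = FALSE)
  if (is.null(source_ids))
    source_ids <- paste0("frame_", seq_along(frames))
  structure(
    list(frames = frames, height = dims[1L, 1L], width = dims[2L, 1L],
         n_frames = length(frames), source_ids = as.character(source_ids)),
    class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  cat(sprintf("image_sequence: %d frame(s) of %d x %d, intensity range [%.4g, %.4g]\n",
              x$n_frames, x$height, x$width,
              min(vapply(x$frames, min, 0)), max(vapply(x$frames, max, 0))))
  invisible(x)
}

# RGB (H x W x 3) to gray with convex luminance weights.
rgb_to_gray <- function(arr, weights = c(0.299, 0.587, 0.114)) {
  weights <- weights / sum(weights)
  arr[, , 1L] * weights[1L] + arr[, , 2L] * weights[2L] + arr[, , 3L] * weights[3L]
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, all = TRUE),
    dcm = stop("DICOM input is not supported by this build; convert the series to PNG or TIFF first: ",
               path, call. = FALSE),
    stop("unsupported image format '", ext, "' for file: ", path, call. = FALSE))
  if (is.null(img))
    stop("could not read image file: ", path, call. = FALSE)
  pages <- if (is.list(img)) img else list(img)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] >= 3L) p <- rgb_to_gray(p[, , 1:3, drop = FALSE])
      else p <- p[, , 1L]
    }
    p * 255
  })
}

#' Load an image sequence from files or a directory
#'
#' Reads PNG/TIFF frames (multi-page TIFF stacks are expanded in page
#' order), converts RGB to grayscale with the given luminance weights, and
#' maps intensities to a float \[0, 255\] scale. Files are ordered
#' lexicographically by name so the stack preserves acquisition order for
#' conventionally numbered series.
#'
#' @param source a directory containing image files, or a character vector
#'   of file paths.
#' @param gray_weights length-3 convex weights for RGB-to-gray conversion;
#'   the default is the ITU-R BT.601 luminance triplet.
#' @return an [image_sequence].
#' @export
load_sequence <- function(source, gray_weights = c(0.299, 0.587, 0.114)) {
  stopifnot(length(gray_weights) == 3L, all(gray_weights >= 0), sum(gray_weights) > 0)
  if (length(source) == 1L && dir.exists(source)) {
    files <- list.files(source, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
  } else {
    files <- source
  }
  if (length(files) < 1L)
    stop("no readable image files found in source", call. = FALSE)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("cannot read file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  frames <- list()
  ids <- character()
  for (f in files) {
    pages <- read_image_file(f)
    if (any(!vapply(pages, function(p) length(dim(p)) == 2L, logical(1L))))
      stop("file did not decode to 2-D frames: ", f, call. = FALSE)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) rgb_to_gray(p, gray_weights) else p
    })
    frames <- c(frames, pages)
    ids <- c(ids, if (length(pages) == 1L) basename(f)
             else paste0(basename(f), "#", seq_along(pages)))
  }
  dims <- vapply(frames, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("dimension mismatch: frames have unequal sizes (",
         paste(unique(apply(dims, 2L, paste, collapse = "x")), collapse = " vs "),
         ")", call. = FALSE)
  image_sequence(frames, source_ids = ids)
}

#' Save an image sequence as lossless PNG or TIFF frames
#'
#' Intensities are clipped to \[0, 255\] and written as 8-bit (PNG) or
#' 8/16-bit (TIFF) files named `frame_0001.png`, ... Integer-valued inputs
#' round-trip exactly through [load_sequence()].
#'
#' @param seq an [image_sequence].
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return invisibly, the vector of files written.
#' @export
save_sequence <- function(seq, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "image_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "png") "png" else "tiff"
  paths <- file.path(dir, sprintf("frame_%04d.%s", seq_len(seq$n_frames), ext))
  for (i in seq_len(seq$n_frames)) {
    f <- pmin(pmax(seq$frames[[i]], 0), 255) / 255
    if (format == "png") png::writePNG(f, paths[i])
    else tiff::writeTIFF(f, paths[i], bits.per.sample = 16L, compression = "none")
  }
  invisible(paths)
}

#' Stack a sequence into a data matrix
#'
#' Builds the (height * width) x n_frames matrix whose column i is frame i
#' vectorized in row-major order. This is the input the decomposition
#' solvers factor into low-rank plus sparse parts: high inter-frame
#' correlation makes the column space low-dimensional.
#'
#' @param seq an [image_sequence].
#' @return a `data_matrix`: list with `values` (the stacked matrix),
#'   `height`, `width`.
#' @export
#' @examples
#' s <- image_sequence(list(matrix(1:4, 2, 2, byrow = TRUE)))
#' stack_sequence(s)$values[, 1]  # 1 2 3 4
stack_sequence <- function(seq) {
  stopifnot(inherits(seq, "image_sequence"))
  values <- vapply(seq$frames, function(f) as.vector(t(f)),
                   numeric(seq$height * seq$width))
  values <- matrix(values, nrow = seq$height * seq$width, ncol = seq$n_frames)
  structure(list(values = values, height = seq$height, width = seq$width),
            class = "data_matrix")
}

#' Unstack a data matrix back into an image sequence
#'
#' Inverse of [stack_sequence()]: each column is reshaped (row-major) into a
#' height x width frame.
#'
#' @param M a `data_matrix`, or a plain matrix plus explicit `height` and
#'   `width`.
#' @param height,width frame geometry, required when `M` is a bare matrix.
#' @param source_ids optional frame labels.
#' @return an [image_sequence].
#' @export
unstack_matrix <- function(M, height = NULL, width = NULL, source_ids = NULL) {
  if (inherits(M, "data_matrix")) {
    height <- M$height; width <- M$width; M <- M$values
  }
  if (is.null(height) || is.null(width))
    stop("height and width are required to unstack a bare matrix", call. = FALSE)
  if (nrow(M) != height * width)
    stop("shape error: matrix has ", nrow(M), " rows but height*width = ",
         height * width, call. = FALSE)
  frames <- lapply(seq_len(ncol(M)), function(i)
    matrix(M[, i], nrow = height, ncol = width, byrow = TRUE))
  image_sequence(frames, source_ids = source_ids)
}

# Reshape one column vector to a frame (row-major), shared helper.
vec_to_frame <- function(v, height, width) {
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}
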
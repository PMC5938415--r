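#' Read a grayscale raster image
#'
#' Reads PNG or TIFF into a numeric matrix in `[0, 1]`. Multi-channel images
#' are converted to luminance (Rec. 601 weights); 16-bit input is already
#' scaled to `[0, 1]` by the readers.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix, rows = image rows.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  as_gray(img)
}

#' Coerce an image array to a grayscale matrix
#'
#' @param img numeric matrix or h x w x c array in `[0, 1]`.
#' @return numeric matrix in `[0, 1]`.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc >= 3L) {
      return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
    }
    return(img[, , 1L])
  }
  stop("expected a matrix or h x w x c array")
}

#' Write a grayscale matrix as PNG
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Detect scale- and rotation-invariant keypoints
#'
#' Finds high-contrast extrema of the difference of Gaussians in scale space,
#' refines them to subpixel position, rejects edge responses, assigns each a
#' dominant gradient orientation (points with multiple strong orientations
#' are emitted once per orientation), and encodes a 128-dimensional
#' gradient-orientation histogram descriptor measured relative to that
#' orientation. Deterministic for a fixed image and configuration. A
#' constant-intensity image yields an empty feature set.
#'
#' @param image numeric matrix in `[0, 1]` (or array; converted via
#'   [as_gray()]), at least 2 x 2.
#' @param image_id identifier stored on the result.
#' @param n_octave_layers difference-of-Gaussians layers searched per octave.
#' @param contrast_threshold minimum refined extremum contrast.
#' @param edge_threshold principal-curvature ratio above which an extremum is
#'   discarded as an edge response.
#' @param sigma base blur of the first pyramid level, pixels.
#' @return object of class `feature_set`: list with `keypoints` (n x 4
#'   matrix: `row`, `col` in pixels, `scale`, `orientation` in radians) and
#'   `descriptors` (n x 128 matrix of nonnegative values).
#' @export
detect_features <- function(image, image_id = "image", n_octave_layers = 3L,
                            contrast_threshold = 0.04, edge_threshold = 10,
                            sigma = 1.6) {
  image <- as_gray(image)
  stopifnot(nrow(image) >= 2L, ncol(image) >= 2L, all(is.finite(image)))
  res <- .sift_detect(image, n_octave_layers, contrast_threshold,
                      edge_threshold, sigma)
  structure(list(keypoints = res$keypoints, descriptors = res$descriptors,
                 image_id = image_id, dim = dim(image)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set '%s': %d keypoint(s), %d-d descriptors\n",
              x$image_id, nrow(x$keypoints), ncol(x$descriptors)))
  invisible(x)
}

#' Number of features in a feature set
#' @param fs a `feature_set`.
#' @return integer count.
#' @export
n_features <- function(fs) nrow(fs$keypoints)

#' Match descriptors between a query and a target feature set
#'
#' For every query descriptor u the two most similar target descriptors v
#' (nearest) and w (second nearest) are found by Euclidean distance; (u, v)
#' is a match when `|u - v| < abs_threshold` (if enabled) and
#' `|u - v| / |u - w| < ratio`. Each query feature yields at most one match;
#' nearest-neighbor ties go to the smaller target index. Output rows are
#' ordered by query index.
#'
#' @param roi query `feature_set` (non-empty).
#' @param target target `feature_set` with at least 2 descriptors (the ratio
#'   test needs a second neighbor).
#' @param ratio ratio-test cutoff in (0, 1); default 0.8.
#' @param abs_threshold absolute distance cutoff, or `Inf` (default) to
#'   disable it so the ratio test is the operative filter.
#' @return data frame of class `match_set`: `roi_index`, `target_index`,
#'   `distance`.
#' @export
match_descriptors <- function(roi, target, ratio = 0.8, abs_threshold = Inf) {
  stopifnot(inherits(roi, "feature_set"), inherits(target, "feature_set"),
            ratio > 0, ratio < 1 || ratio == 1, abs_threshold > 0)
  if (n_features(roi) == 0L) stop("query feature set is empty")
  if (n_features(target) < 2L) {
    stop("target needs at least 2 descriptors for the ratio test")
  }
  m <- .match_bruteforce(roi$descriptors, target$descriptors, ratio, abs_threshold)
  out <- data.frame(roi_index = m[, 1L], target_index = m[, 2L],
                    distance = attr(m, "distances"))
  out <- out[order(out$roi_index), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, roi_id = roi$image_id, target_id = target$image_id,
            class = c("match_set", "data.frame"))
}

#' Matched point coordinates from a match set
#'
#' Extracts the (x, y) = (col, row) pixel coordinates of each matched pair,
#' ready for [ransac_homography()].
#'
#' @param matches a `match_set`.
#' @param roi,target the feature sets the matches refer to.
#' @return list with matrices `p` (query points) and `q` (target points),
#'   each n x 2 (x, y).
#' @export
match_points <- function(matches, roi, target) {
  p <- roi$keypoints[matches$roi_index, c("col", "row"), drop = FALSE]
  q <- target$keypoints[matches$target_index, c("col", "row"), drop = FALSE]
  colnames(p) <- colnames(q) <- c("x", "y")
  list(p = p, q = q)
}

#' Serialize a feature set to CSV
#'
#' Columns `row,col,scale,orientation,d0..d127`; mainly for debugging and
#' external inspection.
#'
#' @param fs a `feature_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  df <- as.data.frame(cbind(fs$keypoints, fs$descriptors))
  names(df) <- c("row", "col", "scale", "orientation",
                 paste0("d", seq_len(128L) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
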
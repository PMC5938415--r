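#' Fit a homography by the normalized direct linear transform
#'
#' Least-squares plane projective transform mapping points `p` to points `q`
#' (Hartley-normalized DLT). With exactly four correspondences in general
#' position the fit is exact (reprojection error below 1e-6 px). The result
#' is normalized so the bottom-right entry is 1 when nonzero.
#'
#' @param p,q n x 2 matrices of (x, y) coordinates, n >= 4, rows paired.
#' @return 3 x 3 homography matrix.
#' @export
fit_homography <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 2L, ncol(q) == 2L, nrow(p) == nrow(q), nrow(p) >= 4L,
            all(is.finite(p)), all(is.finite(q)))
  .fit_homography_cpp(p, q)
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography matrix.
#' @param p n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of transformed, dehomogenized points (rows mapping to
#'   the plane at infinity come back as `Inf`).
#' @export
apply_homography <- function(H, p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop("p must be n x 2")
  ph <- cbind(p, 1) %*% t(H)
  w <- ph[, 3L]
  out <- ph[, 1:2, drop = FALSE] / w
  out[abs(w) < 1e-300, ] <- Inf
  out
}

#' Reprojection error of a correspondence under a homography
#'
#' Euclidean distance in pixels between `H(p)` and `q`; infinite when `p`
#' maps to the plane at infinity.
#'
#' @param H 3 x 3 homography.
#' @param p,q n x 2 matrices (or length-2 vectors) of (x, y) points.
#' @return numeric vector of distances.
#' @export
reprojection_error <- function(H, p, q) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  if (is.null(dim(q))) q <- matrix(q, ncol = 2L)
  proj <- apply_homography(H, p)
  d <- sqrt(rowSums((proj - q)^2))
  d[!is.finite(proj[, 1L])] <- Inf
  d
}

#' Random-sample consensus homography search
#'
#' Repeatedly fits homographies to random minimal samples of four
#' correspondences and keeps the hypothesis with the most inliers --
#' correspondences whose reprojection error is strictly below the threshold.
#' That inlier count is the similarity metric used to rank candidate plates.
#' Degenerate samples (repeated points or three nearly collinear points) are
#' redrawn without consuming an iteration; ties between hypotheses keep the
#' earlier one; results are bit-reproducible for a fixed seed and input
#' order. By default the winning four-point fit is returned as-is; set
#' `refit = TRUE` to re-estimate it by least squares on its inliers.
#'
#' @param p,q n x 2 matrices of paired (x, y) points (query and target), or
#'   a list with elements `p` and `q` as returned by [match_points()] passed
#'   as the first argument.
#' @param iterations number of accepted random samples; default 2000.
#' @param inlier_threshold_px inlier reprojection-error threshold in pixels
#'   (strict inequality); default 10.
#' @param seed integer seed for the internal generator; default 0.
#' @param refit re-fit on the final inlier set (kept only if it does not
#'   lose inliers); default `FALSE`.
#' @return object of class `ransac_result`: list with `homography` (3 x 3 or
#'   `NULL` when fewer than four matches were supplied), `inlier_flags`
#'   (logical per correspondence), `inlier_count`.
#' @export
ransac_homography <- function(p, q = NULL, iterations = 2000L,
                              inlier_threshold_px = 10, seed = 0L,
                              refit = FALSE) {
  if (is.list(p) && !is.matrix(p) && is.null(q)) { q <- p$q; p <- p$p }
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 2L, ncol(q) == 2L, nrow(p) == nrow(q),
            iterations >= 1L, inlier_threshold_px > 0)
  n <- nrow(p)
  if (n < 4L) {
    return(structure(list(homography = NULL,
                          inlier_flags = rep(FALSE, n),
                          inlier_count = 0L, iterations_run = 0L),
                     class = "ransac_result"))
  }
  res <- .ransac_cpp(p, q, as.integer(iterations), inlier_threshold_px,
                     as.integer(seed), isTRUE(refit))
  structure(list(homography = res$homography,
                 inlier_flags = res$inlier_flags,
                 inlier_count = as.integer(res$inlier_count),
                 iterations_run = res$iterations_run),
            class = "ransac_result")
}

#' @export
print.ransac_result <- function(x, ...) {
  cat(sprintf("RANSAC consensus: %d inlier(s) of %d correspondence(s)\n",
              x$inlier_count, length(x$inlier_flags)))
  invisible(x)
}

#' Write a RANSAC result to CSV
#'
#' Emits one row per correspondence: `roi_index,target_index,inlier`.
#'
#' @param result a `ransac_result`.
#' @param matches the `match_set` the correspondences came from.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_ransac_csv <- function(result, matches, path) {
  stopifnot(inherits(result, "ransac_result"),
            length(result$inlier_flags) == nrow(matches))
  utils::write.csv(data.frame(roi_index = matches$roi_index,
                              target_index = matches$target_index,
                              inlier = result$inlier_flags),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
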
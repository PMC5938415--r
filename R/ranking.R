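#' Score one candidate plate against a query region of interest
#'
#' Runs the full feature pipeline: keypoint detection on both images (unless
#' pre-computed feature sets are supplied), ratio-test descriptor matching,
#' and RANSAC homography consensus. The candidate's similarity to the ROI is
#' its RANSAC inlier count, with the raw match count reported alongside.
#'
#' @param roi query image matrix or `feature_set`.
#' @param candidate candidate image matrix or `feature_set`.
#' @param ratio,abs_threshold ratio-test parameters ([match_descriptors()]).
#' @param iterations,inlier_threshold_px RANSAC parameters
#'   ([ransac_homography()]).
#' @param seed RANSAC seed.
#' @return list with `sift_matches`, `ransac_inliers`, and the underlying
#'   `matches` and `ransac` objects. A featureless candidate (or ROI) scores
#'   (0, 0) with a warning.
#' @export
score_candidate <- function(roi, candidate, ratio = 0.8, abs_threshold = Inf,
                            iterations = 2000L, inlier_threshold_px = 10,
                            seed = 0L) {
  if (!inherits(roi, "feature_set")) roi <- detect_features(roi, "roi")
  if (!inherits(candidate, "feature_set")) {
    candidate <- detect_features(candidate, "candidate")
  }
  if (n_features(roi) == 0L || n_features(candidate) < 2L) {
    warning("too few features to match (roi: ", n_features(roi),
            ", candidate: ", n_features(candidate), "); scoring 0")
    return(list(sift_matches = 0L, ransac_inliers = 0L,
                matches = NULL, ransac = NULL))
  }
  m <- match_descriptors(roi, candidate, ratio = ratio,
                         abs_threshold = abs_threshold)
  pts <- match_points(m, roi, candidate)
  rr <- ransac_homography(pts$p, pts$q, iterations = iterations,
                          inlier_threshold_px = inlier_threshold_px,
                          seed = seed)
  list(sift_matches = nrow(m), ransac_inliers = rr$inlier_count,
       matches = m, ransac = rr)
}

#' Rank candidate plates by similarity to a region of interest
#'
#' Scores every candidate with [score_candidate()] and sorts by RANSAC
#' inliers (descending), then raw match count, then input order. Each
#' candidate's RANSAC run gets its own derived seed (`seed` + position - 1)
#' so the ranking is reproducible while runs stay independent.
#'
#' @param roi query image matrix or `feature_set`.
#' @param candidates list of image matrices and/or `feature_set`s; names (or
#'   a `plate_stack`'s level numbers) become candidate ids.
#' @param ratio,abs_threshold,iterations,inlier_threshold_px,seed see
#'   [score_candidate()].
#' @return data frame of class `plate_ranking` with columns `rank`,
#'   `candidate_id`, `sift_matches`, `ransac_inliers`; the top candidate id
#'   is in `attr(, "best")`.
#' @export
rank_plates <- function(roi, candidates, ratio = 0.8, abs_threshold = Inf,
                        iterations = 2000L, inlier_threshold_px = 10,
                        seed = 0L) {
  stopifnot(length(candidates) >= 1L)
  if (!inherits(roi, "feature_set")) roi <- detect_features(roi, "roi")
  ids <- names(candidates)
  if (is.null(ids)) ids <- as.character(seq_along(candidates))
  scores <- lapply(seq_along(candidates), function(i) {
    sc <- score_candidate(roi, candidates[[i]], ratio = ratio,
                          abs_threshold = abs_threshold,
                          iterations = iterations,
                          inlier_threshold_px = inlier_threshold_px,
                          seed = seed + i - 1L)
    data.frame(candidate_id = ids[i], sift_matches = sc$sift_matches,
               ransac_inliers = sc$ransac_inliers)
  })
  out <- do.call(rbind, scores)
  ord <- order(-out$ransac_inliers, -out$sift_matches, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, best = out$candidate_id[1L],
            class = c("plate_ranking", "data.frame"))
}

#' @export
print.plate_ranking <- function(x, ...) {
  cat("Plate ranking (best:", attr(x, "best"), ")\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Write a plate ranking to CSV
#'
#' Emits `rank,candidate_id,sift_matches,ransac_inliers`.
#'
#' @param ranking a `plate_ranking`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
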
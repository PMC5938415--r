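test_that("constant and degenerate images yield empty feature sets", {
  expect_identical(n_features(detect_features(matrix(0.5, 64, 64))), 0L)
  expect_identical(n_features(detect_features(matrix(0, 64, 64))), 0L)
  expect_error(detect_features(matrix(0.5, 1, 1)), ">= 2")
})

test_that("detection is deterministic and well-formed", {
  img <- fixture_image()
  a <- detect_features(img)
  b <- detect_features(img)
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$descriptors, b$descriptors)
  expect_gte(n_features(a), 100L)
  expect_identical(ncol(a$descriptors), 128L)
  expect_true(all(a$descriptors >= 0))
  kp <- a$keypoints
  expect_true(all(kp[, "row"] >= 1 & kp[, "row"] <= nrow(img)))
  expect_true(all(kp[, "col"] >= 1 & kp[, "col"] <= ncol(img)))
  expect_true(all(kp[, "scale"] > 0))
  expect_true(all(kp[, "orientation"] >= 0 & kp[, "orientation"] < 2 * pi))
  expect_identical(nrow(kp), nrow(a$descriptors))
})

test_that("multi-channel input is converted to luminance", {
  img <- fixture_image()
  rgb <- array(rep(img, 3), c(dim(img), 3))
  a <- detect_features(img)
  b <- detect_features(rgb)
  expect_equal(a$keypoints, b$keypoints, tolerance = 1e-6)
})

test_that("descriptors match across a 90 degree rotation", {
  img <- fixture_image()
  rot <- t(img)[ncol(img):1, ]  # 90 deg counterclockwise
  fa <- detect_features(img)
  fb <- detect_features(rot)
  m <- match_descriptors(fa, fb, ratio = 0.8)
  expect_gte(nrow(m), 0.5 * n_features(fa) * 0.5)  # enough candidates matched
  # known ground-truth map: (row, col) -> (nrow - col + 1... ) in rotated frame
  p <- fa$keypoints[m$roi_index, c("row", "col"), drop = FALSE]
  q <- fb$keypoints[m$target_index, c("row", "col"), drop = FALSE]
  pred_row <- ncol(img) - p[, "col"] + 1
  pred_col <- p[, "row"]
  err <- sqrt((q[, "row"] - pred_row)^2 + (q[, "col"] - pred_col)^2)
  expect_gte(mean(err < 2), 0.5)
  expect_gte(sum(err < 2), 0.5 * n_features(fa) * 0.3)
})

test_that("cropping preserves interior keypoint positions", {
  img <- fixture_image()
  # crop origin on the pyramid sampling grid (multiple of 2^octaves)
  r0 <- 129L; c0 <- 129L; sz <- 256L
  crop <- img[r0:(r0 + sz - 1L), c0:(c0 + sz - 1L)]
  fc <- detect_features(crop)
  ff <- detect_features(img)
  kp <- fc$keypoints
  margin <- 20
  interior <- kp[, "row"] > margin & kp[, "row"] < sz - margin &
    kp[, "col"] > margin & kp[, "col"] < sz - margin
  expect_gte(sum(interior), 10L)
  shifted <- cbind(kp[interior, "row"] + (r0 - 1L), kp[interior, "col"] + (c0 - 1L))
  full <- ff$keypoints[, c("row", "col")]
  nearest <- vapply(seq_len(nrow(shifted)), function(i) {
    min(sqrt((full[, 1] - shifted[i, 1])^2 + (full[, 2] - shifted[i, 2])^2))
  }, numeric(1))
  expect_gte(mean(nearest <= 1.5), 0.8)
})

test_that("ratio-test matching agrees with a brute-force oracle", {
  for (seed in c(1L, 2L, 3L)) {
    a <- random_feature_set(20, seed)
    # target: noisy copies of the queries (matchable) plus pure decoys
    b <- random_feature_set(30, seed + 50L)
    b$descriptors[1:20, ] <- a$descriptors +
      with_seed(seed + 100L, matrix(rnorm(20 * 128, 0, 2), 20, 128))
    got <- match_descriptors(a, b, ratio = 0.8)
    want <- oracle_match(a$descriptors, b$descriptors, ratio = 0.8)
    expect_gte(nrow(want), 15L)  # the planted copies are found
    expect_identical(got$roi_index, want$roi_index)
    expect_identical(got$target_index, want$target_index)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
    # absolute threshold prunes long matches
    thr <- stats::median(want$distance)
    got2 <- match_descriptors(a, b, ratio = 0.8, abs_threshold = thr)
    want2 <- oracle_match(a$descriptors, b$descriptors, 0.8, thr)
    expect_identical(got2$target_index, want2$target_index)
    expect_lt(nrow(got2), nrow(got))
  }
})

test_that("ratio rule accepts and rejects per the 0.8 cutoff", {
  # target descriptors at distances 1 and 2 from the query: ratio 0.5 < 0.8
  q <- structure(list(keypoints = cbind(row = 1, col = 1, scale = 1, orientation = 0),
                      descriptors = matrix(0, 1, 128), image_id = "q",
                      dim = c(2L, 2L)), class = "feature_set")
  tgt <- random_feature_set(2, 9L)
  tgt$descriptors[] <- 0
  tgt$descriptors[1, 1] <- 1  # distance 1
  tgt$descriptors[2, 1] <- 2  # distance 2
  m <- match_descriptors(q, tgt, ratio = 0.8)
  expect_identical(nrow(m), 1L)
  expect_identical(m$target_index, 1L)
  # distances 1.8 and 2.0: ratio 0.9 >= 0.8, rejected
  tgt$descriptors[1, 1] <- 1.8
  expect_identical(nrow(match_descriptors(q, tgt, ratio = 0.8)), 0L)
  expect_error(match_descriptors(q, random_feature_set(1, 1L)),
               "at least 2 descriptors")
})

test_that("ratio 1 with no absolute threshold is nearest-neighbor assignment", {
  a <- random_feature_set(15, 4L)
  b <- random_feature_set(25, 5L)
  m <- match_descriptors(a, b, ratio = 1)
  expect_identical(nrow(m), 15L)
  nn <- vapply(seq_len(15), function(i) {
    which.min(colSums((t(b$descriptors) - a$descriptors[i, ])^2))
  }, integer(1))
  expect_identical(m$target_index[order(m$roi_index)], unname(nn))
})

test_that("matching is invariant to target permutation", {
  a <- random_feature_set(20, 6L)
  b <- random_feature_set(30, 7L)
  m1 <- match_descriptors(a, b, ratio = 0.8)
  perm <- with_seed(8L, sample(30))
  b2 <- b
  b2$descriptors <- b$descriptors[perm, ]
  b2$keypoints <- b$keypoints[perm, ]
  m2 <- match_descriptors(a, b2, ratio = 0.8)
  expect_identical(m1$roi_index, m2$roi_index)
  expect_identical(m1$target_index, perm[m2$target_index])
})

test_that("features match themselves at distance zero beside a decoy", {
  a <- random_feature_set(10, 12L)
  decoy <- random_feature_set(1, 99L)
  decoy$descriptors[] <- 1e6
  tgt <- a
  tgt$descriptors <- rbind(a$descriptors, decoy$descriptors)
  tgt$keypoints <- rbind(a$keypoints, decoy$keypoints)
  m <- match_descriptors(a, tgt, ratio = 0.8)
  expect_identical(m$roi_index, 1:10)
  expect_identical(m$target_index, 1:10)
  expect_true(all(m$distance == 0))
})

test_that("feature sets serialize to CSV", {
  fs <- random_feature_set(5, 21L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fs, f)
  back <- read.csv(f)
  expect_identical(dim(back), c(5L, 132L))
  expect_identical(names(back)[1:4], c("row", "col", "scale", "orientation"))
})

test_that("grayscale image files round-trip through PNG", {
  img <- fixture_image()[1:64, 1:64]
  f <- withr::local_tempfile(fileext = ".png")
  write_gray(img, f)
  back <- read_gray(f)
  expect_equal(back, img, tolerance = 1 / 255, ignore_attr = TRUE)
})
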
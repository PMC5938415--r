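# Shared fixtures, built once per test run. Sizes are kept small so the
# default suite stays fast; the acceptance tests build their own full-size
# inputs.

fixture_image <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_image(seed = 3L)
    cache
  }
})

fixture_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- detect_features(fixture_image(), "fixture")
    cache
  }
})

# brute-force nearest/second-nearest ratio-test matcher, independent of the
# packaged implementation
oracle_match <- function(A, B, ratio = 0.8, abs_threshold = Inf) {
  out <- NULL
  for (i in seq_len(nrow(A))) {
    d <- sqrt(colSums((t(B) - A[i, ])^2))
    o <- order(d)
    d1 <- d[o[1]]; d2 <- d[o[2]]
    ok <- d1 < abs_threshold && (d1 == 0 || (d2 > 0 && d1 / d2 < ratio))
    if (ok) {
      out <- rbind(out, data.frame(roi_index = i, target_index = o[1],
                                   distance = d1))
    }
  }
  if (is.null(out)) {
    out <- data.frame(roi_index = integer(), target_index = integer(),
                      distance = numeric())
  }
  out
}

write_temp_registry <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("group,level,z_mm", lines), f)
  f
}

random_feature_set <- function(n, seed, id = "rand") {
  kp <- with_seed(seed, cbind(row = runif(n, 1, 100), col = runif(n, 1, 100),
                              scale = runif(n, 1, 4),
                              orientation = runif(n, 0, 2 * pi)))
  de <- with_seed(seed + 1000L, matrix(runif(n * 128, 0, 100), n, 128))
  structure(list(keypoints = kp, descriptors = de, image_id = id,
                 dim = c(100L, 100L)), class = "feature_set")
}

# absolute-tolerance comparison (testthat's tolerance is relative)
expect_abs_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
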
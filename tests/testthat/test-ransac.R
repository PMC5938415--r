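test_that("four-point fits are exact for identity and translation", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fit_homography(sq, sq), diag(3), tolerance = 1e-9)
  Ht <- fit_homography(sq, sweep(sq, 2, c(5, 3), "+"))
  expect_equal(Ht[, 3], c(5, 3, 1), tolerance = 1e-9)
  expect_equal(Ht[1:2, 1:2], diag(2), tolerance = 1e-9)
})

test_that("seeded projective maps are recovered exactly from clean points", {
  Hg <- matrix(c(1.1, 0.2, -0.1, 0.05, 0.9, 0.3, 1e-4, -2e-4, 1),
               3, 3, byrow = TRUE)
  for (seed in c(5L, 6L, 7L)) {
    p <- with_seed(seed, matrix(runif(12, 0, 100), 6, 2))
    q <- apply_homography(Hg, p)
    Hf <- fit_homography(p, q)
    expect_lt(max(reprojection_error(Hf, p, q)), 1e-6)
    expect_equal(Hf / Hf[3, 3], Hg, tolerance = 1e-6)
  }
  # exact minimal sample
  p4 <- with_seed(9L, matrix(runif(8, 0, 100), 4, 2))
  q4 <- apply_homography(Hg, p4)
  expect_lt(max(reprojection_error(fit_homography(p4, q4), p4, q4)), 1e-6)
})

test_that("degenerate minimal samples are rejected", {
  coll <- rbind(c(0, 0), c(1, 1), c(2, 2), c(5, 1))  # three collinear
  expect_error(fit_homography(coll, coll), "degenerate")
  rep_pt <- rbind(c(0, 0), c(0, 0), c(1, 2), c(3, 1))
  expect_error(fit_homography(rep_pt, rep_pt), "degenerate")
  expect_error(fit_homography(rbind(c(0, 0), c(1, 1), c(2, 2)),
                              rbind(c(0, 0), c(1, 1), c(2, 2))), "nrow")
})

test_that("reprojection error is the Euclidean reprojection distance", {
  expect_identical(reprojection_error(diag(3), c(10, 10), c(10, 10)), 0)
  expect_identical(reprojection_error(diag(3), c(0, 0), c(3, 4)), 5)
  # perturbation of known norm under a seeded projective map
  Hg <- matrix(c(1.02, -0.05, 3, 0.04, 0.97, -2, 5e-5, 1e-5, 1),
               3, 3, byrow = TRUE)
  p <- with_seed(13L, matrix(runif(10, 0, 200), 5, 2))
  q <- apply_homography(Hg, p)
  q[1, ] <- q[1, ] + c(0.6, -0.8)
  expect_equal(reprojection_error(Hg, p, q)[1], 1.0, tolerance = 1e-9)
  # mapping to the plane at infinity gives infinite error
  Hinf <- diag(3); Hinf[3, ] <- c(1, 0, 0)
  expect_identical(reprojection_error(Hinf, c(0, 5), c(1, 1)), Inf)
})

test_that("consensus search recovers planted inlier sets across seeds", {
  Hg <- matrix(c(1.1, 0.2, -0.1, 0.05, 0.9, 0.3, 1e-4, -2e-4, 1),
               3, 3, byrow = TRUE)
  for (seed in 1:20) {
    dat <- with_seed(seed, {
      p <- matrix(runif(80, 0, 500), 40, 2)
      q <- apply_homography(Hg, p)
      out_idx <- sample(40, 12)
      q[out_idx, ] <- matrix(runif(24, 0, 500), 12, 2)
      list(p = p, q = q, out_idx = out_idx)
    })
    # an outlier that lands within threshold by chance is a genuine inlier
    planted <- !(seq_len(40) %in% dat$out_idx) |
      reprojection_error(Hg, dat$p, dat$q) < 10
    r <- ransac_homography(dat$p, dat$q, seed = seed)
    expect_identical(r$inlier_flags, unname(planted))
    expect_identical(r$inlier_count, sum(planted))
  }
})

test_that("small and exact match sets behave per contract", {
  p <- with_seed(3L, matrix(runif(40, 0, 100), 20, 2))
  r <- ransac_homography(p, p, seed = 1)
  expect_identical(r$inlier_count, 20L)
  expect_true(all(r$inlier_flags))
  r3 <- ransac_homography(p[1:3, ], p[1:3, ])
  expect_identical(r3$inlier_count, 0L)
  expect_null(r3$homography)
  r0 <- ransac_homography(p[0, ], p[0, ])
  expect_identical(r0$inlier_count, 0L)
})

test_that("inliers are exactly the matches strictly inside the threshold", {
  # the fifth source point repeats the first with its target offset by 10 px,
  # so every valid minimal sample yields a near-exact map under which the twin
  # pair errs by 10 px (up to ~1e-14 fit noise)
  p <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100), c(0, 0))
  q <- p
  q[5, ] <- q[5, ] + c(10, 0)
  below <- ransac_homography(p, q, inlier_threshold_px = 10 - 1e-6, seed = 2)
  expect_identical(below$inlier_count, 4L)
  expect_false(below$inlier_flags[5])
  above <- ransac_homography(p, q, inlier_threshold_px = 10 + 1e-6, seed = 2)
  expect_identical(above$inlier_count, 5L)
  # flags are the strict comparison of reprojection error with the threshold:
  # checked away from the boundary where both sides compute stably
  r <- ransac_homography(p[1:4, ], q[1:4, ], inlier_threshold_px = 10, seed = 2)
  e <- reprojection_error(r$homography, p[1:4, ], q[1:4, ])
  expect_identical(r$inlier_flags, unname(e < 10))
})

test_that("duplicating an inlier raises the count by exactly one", {
  p <- with_seed(4L, matrix(runif(40, 0, 100), 20, 2))
  q <- p
  r1 <- ransac_homography(p, q, seed = 5)
  r2 <- ransac_homography(rbind(p, p[1, ]), rbind(q, q[1, ]), seed = 5)
  expect_identical(r2$inlier_count, r1$inlier_count + 1L)
})

test_that("results are bit-reproducible for a fixed seed", {
  Hg <- matrix(c(1.05, 0.1, 2, -0.02, 0.95, 1, 1e-5, 0, 1), 3, 3, byrow = TRUE)
  p <- with_seed(10L, matrix(runif(60, 0, 400), 30, 2))
  q <- apply_homography(Hg, p)
  q[1:8, ] <- with_seed(11L, matrix(runif(16, 0, 400), 8, 2))
  a <- ransac_homography(p, q, seed = 42)
  b <- ransac_homography(p, q, seed = 42)
  expect_identical(a, b)
  # refit never loses inliers
  c0 <- ransac_homography(p, q, seed = 42, refit = TRUE)
  expect_gte(c0$inlier_count, a$inlier_count)
})
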
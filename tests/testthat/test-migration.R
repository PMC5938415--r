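test_that("anisotropic scaling applies the published factors and inverts", {
  pts <- data.frame(case_label = "p", tag = "a", x_mm = 1.0, y_mm = 1.0)
  sc <- scale_points(pts, scale_spec())
  expect_equal(sc$x_mm, 1.39)
  expect_equal(sc$y_mm, 1.61)
  ident <- scale_points(pts, list(sx = 1, sy = 1))
  expect_identical(ident, pts)
  set.seed(1)
  rnd <- data.frame(case_label = letters[1:5], tag = "a",
                    x_mm = runif(5, -1, 1), y_mm = runif(5, -1, 1))
  round_trip <- scale_points(scale_points(rnd, scale_spec()),
                             list(sx = 1 / 1.39, sy = 1 / 1.61))
  expect_equal(round_trip$x_mm, rnd$x_mm, tolerance = 1e-9)
  expect_equal(round_trip$y_mm, rnd$y_mm, tolerance = 1e-9)
  expect_error(scale_spec(sx = -1), "sx > 0")
})

test_that("correction vectors reproduce published example rows", {
  # row a of the first migration pair
  v <- error_vector(cbind(-0.12776, -0.11052), cbind(-0.12456, -0.34712))
  expect_abs_equal(v$ab_x, 0.00320, 1e-9)
  expect_abs_equal(v$ab_y, 0.23660, 1e-9)
  expect_abs_equal(v$ab, 0.236622, 1e-6)
  expect_abs_equal(v$phi_deg, 89.225, 1e-3)
  # row k
  v2 <- error_vector(cbind(0.31640, -0.18180), cbind(0.55008, -0.50312))
  expect_abs_equal(v2$ab_x, 0.23368, 1e-9)
  expect_abs_equal(v2$ab_y, 0.32132, 1e-9)
  expect_abs_equal(v2$ab, 0.397307, 1e-6)
  expect_abs_equal(v2$phi_deg, 53.973, 1e-3)
  # null correction: zero vector, direction 0 by convention
  v3 <- error_vector(cbind(0.5, -0.5), cbind(0.5, -0.5))
  expect_identical(unlist(v3), c(dx = 0, dy = 0, ab_x = 0, ab_y = 0,
                                 ab = 0, phi_deg = 0))
})

test_that("vector magnitude obeys the component inequalities", {
  set.seed(7)
  A <- matrix(runif(60, -1, 1), 30)
  B <- matrix(runif(60, -1, 1), 30)
  v <- error_vector(A, B)
  expect_true(all(v$ab >= pmax(v$ab_x, v$ab_y) - 1e-12))
  expect_true(all(v$ab <= v$ab_x + v$ab_y + 1e-12))
  # mean of magnitudes dominates magnitude of the mean vector
  expect_gte(mean(v$ab), sqrt(mean(v$dx)^2 + mean(v$dy)^2))
})

test_that("record joining reports unmatched labels and rejects duplicates", {
  a <- data.frame(case_label = c("x", "y"), tag = "a",
                  x_mm = c(0.1, 0.2), y_mm = c(0.1, 0.2))
  b <- data.frame(case_label = c("y", "z"), tag = "a",
                  x_mm = c(0.3, 0.4), y_mm = c(0.3, 0.4))
  expect_warning(rec <- migration_records(a, b), "unmatched")
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$case_label, "y")
  b2 <- transform(b, case_label = c("q", "z"))
  expect_warning(migration_records(a, b2), "unmatched")
  disjoint <- suppressWarnings(migration_records(a, b2))
  expect_identical(nrow(disjoint), 0L)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rbind(a, a), f, row.names = FALSE)
  expect_error(read_points(f), "duplicate")
})

test_that("points outside the 2 x 2 mm workspace warn but load", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(case_label = "x", tag = "a", x_mm = 1.5, y_mm = 0),
            f, row.names = FALSE)
  expect_warning(pts <- read_points(f), "workspace")
  expect_identical(nrow(pts), 1L)
})

test_that("summary statistics are column means with sd/sqrt(n) errors", {
  rec <- migration_records(table7_points("A")[1:2, ], table7_points("B")[1:2, ])
  two_same <- rbind(rec[1, ], rec[1, ])
  s <- summarize_migration(two_same)
  expect_true(all(s["sem", ] == 0))
  expect_error(summarize_migration(rec[1, , drop = FALSE]), "fewer than 2")
})

test_that("bundled migration dataset reproduces every published error row", {
  rec <- migration_records(table7_points("A"), table7_points("B"))
  expect_identical(nrow(rec), 24L)
  key <- paste(rec$pair, rec$case_label, rec$tag)
  want <- published_migration_errors
  i <- match(paste(want$pair, want$case_label, want$tag), key)
  expect_false(anyNA(i))
  expect_abs_equal(rec$ab_x[i], want$ab_x, 1e-6)
  expect_abs_equal(rec$ab_y[i], want$ab_y, 1e-6)
  expect_abs_equal(rec$ab[i], want$ab, 1e-6)
  expect_abs_equal(rec$phi_deg[i], want$phi_deg, 1e-3)
  s <- summarize_migration(rec)
  m <- published_migration_mean
  # printed means carry 5-6 decimals; compare at their rounding resolution
  expect_abs_equal(s["mean", "ab"], m[["AB"]], 1e-6)
  expect_abs_equal(s["mean", "phi_deg"], m[["phi"]], 1e-3)
  expect_abs_equal(s["mean", "ab_x"], m[["ABx"]], 5.1e-6)
  expect_abs_equal(s["mean", "ab_y"], m[["ABy"]], 5.1e-6)
  expect_abs_equal(s["mean", "Ax"], m[["Ax"]], 5.1e-6)
  expect_abs_equal(s["mean", "Ay"], m[["Ay"]], 5.1e-6)
  expect_abs_equal(s["mean", "Bx"], m[["Bx"]], 5.1e-6)
  expect_abs_equal(s["mean", "By"], m[["By"]], 5.1e-6)
})

test_that("planted constant shifts are recovered exactly without noise", {
  ds <- make_point_dataset(n_points = 50, planted_shift = c(0.25, -0.15),
                           noise_sd = 0, seed = 11)
  rec <- migration_records(ds$A, ds$B)
  expect_equal(rec$dx, rep(0.25, 50), tolerance = 1e-12)
  expect_equal(rec$dy, rep(-0.15, 50), tolerance = 1e-12)
  expect_equal(rec$ab, rep(sqrt(0.25^2 + 0.15^2), 50), tolerance = 1e-12)
  s <- summarize_migration(rec)
  expect_equal(s["mean", "dx"], 0.25, tolerance = 1e-12)
  expect_equal(s["mean", "dy"], -0.15, tolerance = 1e-12)
})

test_that("migrate_dataset runs the staged pipeline end to end", {
  # stage 1 only: scaled transfer, no vectors
  r1 <- migrate_dataset(table7_points("A"), scale = NULL)
  expect_null(r1$records)
  expect_identical(nrow(r1$points), 24L)
  # both stages with report files
  dir <- withr::local_tempdir()
  r2 <- migrate_dataset(table7_points("A"), table7_points("B"))
  files <- write_migration_csv(r2, dir)
  expect_true(all(file.exists(files)))
  rep_csv <- read.csv(files[1])
  expect_identical(nrow(rep_csv), 24L)
  q <- quiver_svg(r2$records, file.path(dir, "corrections.svg"))
  expect_match(readLines(q, n = 1L), "<svg")
})
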
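#' Anisotropic scaling specification
#'
#' The Swanson (S) atlas template grid maps onto the Paxinos-Watson (PW)
#' stereotaxic grid under axis-specific magnification: 139% horizontally and
#' 161% vertically (`scale_S_to_PW`). An alternative workflow scales both
#' axes of PW by 139.5% after applying those factors to S (`normalize_both`);
#' the two differ by a fraction of a percent and both are provided.
#'
#' @param mode `"scale_S_to_PW"` (default) or `"normalize_both"`.
#' @param sx,sy horizontal and vertical scale factors; defaults 1.39 and 1.61.
#' @param normalize_factor the both-axes factor used by `normalize_both`
#'   (default 1.395).
#' @return list of class `scale_spec` with effective `sx`, `sy`.
#' @export
scale_spec <- function(mode = c("scale_S_to_PW", "normalize_both"),
                       sx = 1.39, sy = 1.61, normalize_factor = 1.395) {
  mode <- match.arg(mode)
  stopifnot(sx > 0, sy > 0, normalize_factor > 0)
  eff <- if (mode == "scale_S_to_PW") c(sx, sy) else
    c(sx / normalize_factor, sy / normalize_factor)
  structure(list(mode = mode, sx = eff[1], sy = eff[2]), class = "scale_spec")
}

#' Read a point-source dataset
#'
#' CSV schema `case_label,tag,x_mm,y_mm`, optionally preceded by a `pair`
#' column naming the migration (source level > destination level). Positions
#' are mediolateral (x) and dorsoventral (y) distances in mm from the origin
#' of the 2 x 2 mm Cartesian workspace built on the destination atlas
#' quadrant. Points outside that workspace are kept with a warning (other
#' datasets may legitimately use larger quadrants).
#'
#' @param path CSV file.
#' @return data frame `pair, case_label, tag, x_mm, y_mm` (`pair` is `NA`
#'   when absent from the file).
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"pair" %in% names(df)) df$pair <- NA_character_
  need <- c("case_label", "tag", "x_mm", "y_mm")
  if (!all(need %in% names(df))) {
    stop("point CSV must have columns case_label,tag,x_mm,y_mm (optional pair): ",
         path)
  }
  df <- df[, c("pair", need)]
  if (!is.numeric(df$x_mm) || !is.numeric(df$y_mm) ||
      anyNA(df$x_mm) || anyNA(df$y_mm)) {
    stop("non-numeric coordinates in ", path)
  }
  key <- paste(df$pair, df$case_label, df$tag)
  if (anyDuplicated(key)) {
    stop("duplicate (pair, case_label, tag) keys in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  out_of_ws <- abs(df$x_mm) > 1 | abs(df$y_mm) > 1
  if (any(out_of_ws)) {
    warning(sum(out_of_ws), " point(s) outside the 2 x 2 mm workspace in ",
            basename(path))
  }
  df
}

#' Bundled point-source fixture (uncorrected and corrected positions)
#'
#' The package's transcription of the published 24-site migration dataset:
#' stage `"A"` holds positions after anisotropic-scaling migration into S
#' space but before expert review, stage `"B"` the positions after
#' expert-guided relocation. Three coordinate cells of the printed source are
#' typographic errors (their printed error columns and column means identify
#' the intended values); the fixture carries the corrected values, documented
#' in the package vignette.
#'
#' @param stage `"A"` (pre-expert) or `"B"` (post-expert).
#' @return data frame as from [read_points()].
#' @export
table7_points <- function(stage = c("A", "B")) {
  stage <- match.arg(stage)
  read_points(system.file("extdata", paste0("table7_", stage, ".csv"),
                          package = "ratlas", mustWork = TRUE))
}

#' Scale point positions about the workspace origin
#'
#' @param points data frame with `x_mm`, `y_mm` columns.
#' @param spec a [scale_spec()] (or any list with positive `sx`, `sy`).
#' @return `points` with scaled coordinates.
#' @export
scale_points <- function(points, spec = scale_spec()) {
  stopifnot(is.data.frame(points), spec$sx > 0, spec$sy > 0)
  points$x_mm <- points$x_mm * spec$sx
  points$y_mm <- points$y_mm * spec$sy
  points
}

#' Correction vector between migrated and expert-relocated positions
#'
#' Given uncorrected positions A and expert-corrected positions B (mm), the
#' correction is summarized per the published convention: per-axis error
#' magnitudes `ab_x = |Bx - Ax|` and `ab_y = |Ay - By|`, vector magnitude
#' `ab = sqrt(ab_x^2 + ab_y^2)`, and direction `phi_deg` from the
#' two-argument arctangent of `(ab_y, ab_x)` in degrees (0 along the
#' mediolateral axis, 90 along the dorsoventral axis; A = B gives 0 by
#' convention). Signed components `dx = Bx - Ax` and `dy = By - Ay` are also
#' returned for analyses that need direction on the page rather than error
#' magnitude.
#'
#' @param A,B two-column matrices or data frames of (x, y) positions in mm;
#'   rows are paired.
#' @return data frame `dx, dy, ab_x, ab_y, ab, phi_deg`.
#' @export
error_vector <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == 2L, ncol(B) == 2L, nrow(A) == nrow(B),
            all(is.finite(A)), all(is.finite(B)))
  dx <- B[, 1L] - A[, 1L]
  dy <- B[, 2L] - A[, 2L]
  ab_x <- abs(dx)
  ab_y <- abs(dy)
  data.frame(dx = dx, dy = dy, ab_x = ab_x, ab_y = ab_y,
             ab = sqrt(ab_x^2 + ab_y^2),
             phi_deg = atan2(ab_y, ab_x) * 180 / pi)
}

#' Join uncorrected and corrected point sets into migration records
#'
#' Records are joined on (pair, case_label, tag); labels present in only one
#' stage are reported in the `unmatched` attribute with a warning.
#'
#' @param points_a uncorrected (stage A) points, as from [read_points()].
#' @param points_b expert-corrected (stage B) points.
#' @return data frame of class `migration_records` with the identity columns,
#'   `Ax, Ay, Bx, By`, and the [error_vector()] columns.
#' @export
migration_records <- function(points_a, points_b) {
  for (df in list(points_a, points_b)) {
    stopifnot(all(c("case_label", "tag", "x_mm", "y_mm") %in% names(df)))
  }
  if (is.null(points_a$pair)) points_a$pair <- NA_character_
  if (is.null(points_b$pair)) points_b$pair <- NA_character_
  ka <- paste(points_a$pair, points_a$case_label, points_a$tag)
  kb <- paste(points_b$pair, points_b$case_label, points_b$tag)
  common <- intersect(ka, kb)
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmatched) > 0L) {
    warning(length(unmatched), " unmatched label(s) between stages: ",
            paste(unmatched, collapse = "; "))
  }
  a <- points_a[match(common, ka), , drop = FALSE]
  b <- points_b[match(common, kb), , drop = FALSE]
  ev <- error_vector(cbind(a$x_mm, a$y_mm), cbind(b$x_mm, b$y_mm))
  out <- data.frame(pair = a$pair, case_label = a$case_label, tag = a$tag,
                    Ax = a$x_mm, Ay = a$y_mm, Bx = b$x_mm, By = b$y_mm, ev,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, unmatched = unmatched,
            class = c("migration_records", "data.frame"))
}

#' Column means and standard errors of migration records
#'
#' Means and SEMs (sample standard deviation over sqrt(n)) of the positions,
#' error magnitudes, vector magnitude, direction, and signed components.
#'
#' @param records a `migration_records` data frame with at least two rows.
#' @return data frame of class `migration_summary` with one row per
#'   statistic (`mean`, `sem`) and one column per quantity; `attr(, "n")`
#'   carries the record count.
#' @export
summarize_migration <- function(records) {
  stopifnot(is.data.frame(records))
  cols <- c("Ax", "Ay", "Bx", "By", "ab_x", "ab_y", "ab", "phi_deg", "dx", "dy")
  stopifnot(all(cols %in% names(records)))
  n <- nrow(records)
  if (n < 2L) stop("SEM is undefined for fewer than 2 records")
  m <- vapply(records[cols], mean, numeric(1))
  s <- vapply(records[cols], stats::sd, numeric(1)) / sqrt(n)
  out <- as.data.frame(rbind(mean = m, sem = s))
  attr(out, "n") <- n
  class(out) <- c("migration_summary", "data.frame")
  out
}

#' Migrate a point-source dataset between atlas frames
#'
#' Stage 1 applies the anisotropic scaling to the uncorrected positions.
#' When expert-corrected positions are supplied, stage 2 joins the two sets
#' and quantifies the expert's corrections as vectors. The expert relocation
#' itself is always an input, never computed.
#'
#' @param points_a uncorrected positions (data frame or CSV path). When
#'   `scale` is non-`NULL` these are treated as source-frame coordinates and
#'   scaled; pass `scale = NULL` for positions already in the destination
#'   frame (as in the bundled fixture).
#' @param points_b optional expert-corrected positions (data frame or CSV
#'   path), already in the destination frame.
#' @param scale a [scale_spec()] applied to `points_a`, or `NULL`.
#' @return list of class `migration_report`: `points` (migrated stage-A
#'   positions), and when `points_b` is given, `records` and `summary`.
#' @export
migrate_dataset <- function(points_a, points_b = NULL, scale = NULL) {
  if (is.character(points_a)) points_a <- read_points(points_a)
  if (is.character(points_b)) points_b <- read_points(points_b)
  migrated <- if (is.null(scale)) points_a else scale_points(points_a, scale)
  out <- list(points = migrated, scale = scale)
  if (!is.null(points_b)) {
    out$records <- migration_records(migrated, points_b)
    if (nrow(out$records) >= 2L) out$summary <- summarize_migration(out$records)
  }
  structure(out, class = "migration_report")
}

#' @export
print.migration_report <- function(x, ...) {
  cat("Migration report: ", nrow(x$points), " point(s)", sep = "")
  if (!is.null(x$scale)) {
    cat(sprintf(" scaled by (%.3f, %.3f)", x$scale$sx, x$scale$sy))
  }
  cat("\n")
  if (!is.null(x$records)) {
    s <- x$summary
    cat(sprintf("  %d correction vector(s): mean |AB| = %.6f mm, mean phi = %.3f deg\n",
                nrow(x$records), s["mean", "ab"], s["mean", "phi_deg"]))
  }
  invisible(x)
}

#' Write a migration report to CSV files
#'
#' Emits `migration_report.csv` (one row per record, positions to 5 decimal
#' places, phi to 3) and `migration_summary.csv` in `dir`.
#'
#' @param report a `migration_report` with records.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_migration_csv <- function(report, dir) {
  stopifnot(inherits(report, "migration_report"), !is.null(report$records))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- report$records
  fmt <- function(x) sprintf("%.5f", x)
  df <- data.frame(pair = r$pair, case_label = r$case_label, tag = r$tag,
                   Ax = fmt(r$Ax), Ay = fmt(r$Ay), Bx = fmt(r$Bx), By = fmt(r$By),
                   ABx = fmt(r$ab_x), ABy = fmt(r$ab_y),
                   AB = sprintf("%.6f", r$ab),
                   phi_deg = sprintf("%.3f", r$phi_deg))
  f1 <- file.path(dir, "migration_report.csv")
  utils::write.csv(df, f1, row.names = FALSE, quote = FALSE)
  files <- f1
  if (!is.null(report$summary)) {
    f2 <- file.path(dir, "migration_summary.csv")
    s <- report$summary
    sdf <- data.frame(statistic = rownames(s),
                      lapply(s, function(v) sprintf("%.6f", v)))
    utils::write.csv(sdf, f2, row.names = FALSE, quote = FALSE)
    files <- c(files, f2)
  }
  invisible(files)
}

#' Quiver plot of correction vectors (SVG)
#'
#' Draws each correction vector inside a unit circle: origin at the medial
#' point, mediolateral x axis, dorsoventral y axis, one arrow per record from
#' (0,0) along the signed correction (dx, dy).
#'
#' @param records a `migration_records` data frame.
#' @param path output `.svg` file.
#' @param size canvas size in pixels.
#' @return `path`, invisibly.
#' @export
quiver_svg <- function(records, path, size = 400) {
  stopifnot(is.data.frame(records), all(c("dx", "dy") %in% names(records)))
  c0 <- size / 2
  rad <- size / 2 - 10
  scale <- rad / max(1, max(sqrt(records$dx^2 + records$dy^2)))
  el <- c(sprintf('<circle cx="%g" cy="%g" r="%g" fill="none" stroke="black"/>', c0, c0, rad),
          sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="gray"/>',
                  c0 - rad, c0, c0 + rad, c0),
          sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="gray"/>',
                  c0, c0 - rad, c0, c0 + rad),
          sprintf('<line x1="%g" y1="%g" x2="%.2f" y2="%.2f" stroke="red" stroke-width="1.5"/>',
                  c0, c0, c0 + records$dx * scale, c0 - records$dy * scale))
  svg_write(el, path, size, size)
}
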
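# Synthetic test imagery and point datasets. Real atlas photomicrographs are
# copyrighted, so the matching pipeline is exercised on generated textures
# with the statistical structure the algorithms assume: blob-scale contrast
# (cells/nuclei analogue), band-limited background noise, and smooth
# level-to-level morphing across a stack.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so generators are pure functions of their spec.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.render_blobs <- function(h, w, blobs) {
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(blobs))) {
    r0 <- blobs$r[i]; c0 <- blobs$c[i]; s <- blobs$sigma[i]
    rs <- max(1L, floor(r0 - 3 * s)):min(h, ceiling(r0 + 3 * s))
    cs <- max(1L, floor(c0 - 3 * s)):min(w, ceiling(c0 + 3 * s))
    if (length(rs) == 0L || length(cs) == 0L) next
    patch <- blobs$amp[i] *
      exp(-outer((rs - r0)^2, (cs - c0)^2, "+") / (2 * s^2))
    img[rs, cs] <- img[rs, cs] + patch
  }
  img
}

.bandlimited_noise <- function(h, w, smooth_sigma = 2) {
  wn <- matrix(rnorm(h * w), h, w)
  fr <- (seq_len(h) - 1) / h
  fc <- (seq_len(w) - 1) / w
  fr <- pmin(fr, 1 - fr)
  fc <- pmin(fc, 1 - fc)
  g <- exp(-2 * pi^2 * smooth_sigma^2 * outer(fr^2, fc^2, "+"))
  sm <- Re(stats::fft(stats::fft(wn) * g, inverse = TRUE)) / (h * w)
  sm / stats::sd(sm)
}

.sample_blobs <- function(n, h, w) {
  data.frame(r = runif(n, 1, h), c = runif(n, 1, w),
             sigma = runif(n, 2, 15),
             amp = sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.3, 1))
}

.finish_image <- function(img) {
  rng <- range(img)
  if (diff(rng) < 1e-12) return(matrix(0.5, nrow(img), ncol(img)))
  round((img - rng[1]) / diff(rng) * 255) / 255  # quantize to 8 bit
}

#' Generate a textured histology-like test image
#'
#' Sum of seeded Gaussian blobs of varying size, sign and intensity plus
#' band-limited background noise, rescaled and quantized to 8-bit gray in
#' `[0, 1]`. With the default spec the image carries well over a hundred
#' detectable keypoints. Bit-identical for a fixed spec.
#'
#' @param width,height image size in pixels.
#' @param n_blobs number of Gaussian blobs.
#' @param noise_scale standard deviation of the band-limited noise relative
#'   to unit blob amplitude (0 disables noise).
#' @param seed integer seed.
#' @return numeric matrix in `[0, 1]` with the spec in `attr(, "spec")`.
#' @export
make_image <- function(width = 512L, height = 512L, n_blobs = 400L,
                       noise_scale = 0.15, seed = 1L) {
  stopifnot(width >= 1L, height >= 1L, n_blobs >= 0L, noise_scale >= 0)
  img <- with_seed(seed, {
    base <- if (n_blobs > 0L) {
      .render_blobs(height, width, .sample_blobs(n_blobs, height, width))
    } else {
      matrix(0, height, width)
    }
    if (noise_scale > 0) {
      base <- base + noise_scale * .bandlimited_noise(height, width)
    }
    base
  })
  structure(.finish_image(img),
            spec = list(width = width, height = height, n_blobs = n_blobs,
                        noise_scale = noise_scale, seed = seed))
}

#' Generate an ordered stack of morphing plate images
#'
#' Emulates the anteroposterior continuity of sequential atlas plates: each
#' level is the previous one with a fraction `morph_step` of blobs
#' re-sampled at new positions and a small smooth positional drift applied
#' to the rest, so structural similarity decays monotonically with level
#' distance. `morph_step = 0` yields identical levels.
#'
#' @param n_levels number of plates (>= 2).
#' @param morph_step fraction of blobs re-sampled between adjacent levels;
#'   also sets the smooth positional drift (8 px per unit step) and the
#'   autoregressive turnover of the fine noise texture.
#' @param seed integer seed.
#' @param width,height,n_blobs,noise_scale as in [make_image()]; the noise
#'   field evolves between levels as an AR(1) process with correlation
#'   `1 - morph_step`, so fine texture decorrelates at the same rate as the
#'   blob content.
#' @return list of image matrices (class `plate_stack`), each with the blob
#'   table in `attr(, "blobs")`.
#' @export
make_stack <- function(n_levels = 40L, morph_step = 0.15, seed = 1L,
                       width = 512L, height = 512L, n_blobs = 400L,
                       noise_scale = 0.15) {
  stopifnot(n_levels >= 2L, morph_step >= 0, morph_step <= 1)
  with_seed(seed, {
    blobs <- .sample_blobs(n_blobs, height, width)
    noise <- if (noise_scale > 0) {
      .bandlimited_noise(height, width)
    } else {
      matrix(0, height, width)
    }
    rho <- 1 - morph_step
    out <- vector("list", n_levels)
    for (i in seq_len(n_levels)) {
      img <- .render_blobs(height, width, blobs) + noise_scale * noise
      out[[i]] <- structure(.finish_image(img), blobs = blobs, level = i)
      if (i < n_levels) {
        resample <- runif(n_blobs) < morph_step
        if (any(resample)) {
          blobs[resample, ] <- .sample_blobs(sum(resample), height, width)
        }
        # smooth drift: affine-in-position displacement field
        drift_sd <- 8 * morph_step
        if (drift_sd > 0) {
          co <- matrix(rnorm(6, 0, drift_sd), 3, 2)
          u <- cbind(1, blobs$r / height, blobs$c / width)
          blobs$r <- pmin(pmax(blobs$r + u %*% co[, 1L], 1), height)
          blobs$c <- pmin(pmax(blobs$c + u %*% co[, 2L], 1), width)
        }
        if (noise_scale > 0 && morph_step > 0) {
          noise <- rho * noise +
            sqrt(1 - rho^2) * .bandlimited_noise(height, width)
        }
      }
    }
    class(out) <- "plate_stack"
    out
  })
}

# Gaussian-RBF displacement field evaluated at n x 2 (x, y) points
.warp_field <- function(pts, centers, disp, bw) {
  out <- matrix(0, nrow(pts), 2L)
  for (k in seq_len(nrow(centers))) {
    wgt <- exp(-((pts[, 1L] - centers[k, 1L])^2 +
                 (pts[, 2L] - centers[k, 2L])^2) / (2 * bw^2))
    out <- out + cbind(wgt * disp[k, 1L], wgt * disp[k, 2L])
  }
  out
}

.bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  inside <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
  # clamp the just-on-the-border case
  edge <- x >= 1 & x <= w & y >= 1 & y <= h & !inside
  if (any(inside)) {
    i00 <- (x0[inside] - 1) * h + y0[inside]
    v00 <- img[i00]; v01 <- img[i00 + h]
    v10 <- img[i00 + 1]; v11 <- img[i00 + h + 1]
    val[inside] <- (1 - fy[inside]) * ((1 - fx[inside]) * v00 + fx[inside] * v01) +
      fy[inside] * ((1 - fx[inside]) * v10 + fx[inside] * v11)
  }
  if (any(edge)) {
    val[edge] <- img[cbind(pmin(pmax(round(y[edge]), 1), h),
                           pmin(pmax(round(x[edge]), 1), w))]
  }
  val
}

#' Crop, rotate, and smoothly warp a region of interest
#'
#' Reproduces the standard query perturbation for plate-matching tests:
#' crops a rectangle, rotates it about its center (default 155 degrees), and
#' applies a slight random scattered-control-point warp (Gaussian radial
#' basis displacements bounded by `max_displacement_px`). The exact forward
#' transform (full-image pixel coordinates to output coordinates) and its
#' numerical inverse are returned so tests can verify geometry.
#'
#' @param image source image matrix.
#' @param crop_rect `c(row, col, height, width)`, 1-based, inside the image.
#' @param rotation_deg rotation angle in degrees; default 155.
#' @param n_control_points number of warp control points.
#' @param max_displacement_px maximum warp displacement ("slight" default 5;
#'   0 disables the warp).
#' @param seed integer seed.
#' @return list of class `roi_perturbation`: `image` (the perturbed ROI),
#'   `transform` / `inverse` (functions on n x 2 (x, y) = (col, row)
#'   matrices), `crop_rect`, `rotation_deg`.
#' @export
perturb_roi <- function(image, crop_rect, rotation_deg = 155,
                        n_control_points = 8L, max_displacement_px = 5,
                        seed = 1L) {
  stopifnot(length(crop_rect) == 4L)
  r0 <- crop_rect[1L]; c0 <- crop_rect[2L]
  ch <- crop_rect[3L]; cw <- crop_rect[4L]
  if (r0 < 1L || c0 < 1L || ch < 1L || cw < 1L ||
      r0 + ch - 1L > nrow(image) || c0 + cw - 1L > ncol(image)) {
    stop("crop_rect lies outside the image")
  }
  crop <- image[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  oh <- ceiling(abs(ch * cos(th)) + abs(cw * sin(th)))
  ow <- ceiling(abs(cw * cos(th)) + abs(ch * sin(th)))
  cc <- c((cw + 1) / 2, (ch + 1) / 2)   # (x, y) center of crop
  co <- c((ow + 1) / 2, (oh + 1) / 2)
  warp <- with_seed(seed, {
    if (max_displacement_px > 0 && n_control_points > 0L) {
      centers <- cbind(runif(n_control_points, 1, ow),
                       runif(n_control_points, 1, oh))
      ang <- runif(n_control_points, 0, 2 * pi)
      rad <- max_displacement_px * sqrt(runif(n_control_points))
      disp <- cbind(rad * cos(ang), rad * sin(ang))
      bw <- max(oh, ow) / 4
      # rescale so the realized field never exceeds max_displacement_px
      gx <- as.matrix(expand.grid(x = seq(1, ow, length.out = 40),
                                  y = seq(1, oh, length.out = 40)))
      mag <- sqrt(rowSums(.warp_field(gx, centers, disp, bw)^2))
      sc <- if (max(mag) > max_displacement_px) max_displacement_px / max(mag) else 1
      list(centers = centers, disp = disp * sc, bw = bw)
    } else {
      NULL
    }
  })
  rot_fwd <- function(p) sweep(sweep(p, 2L, cc) %*% t(R), 2L, co, "+")
  rot_inv <- function(p) sweep(sweep(p, 2L, co) %*% R, 2L, cc, "+")
  w_fwd <- function(p) {
    if (is.null(warp)) p else p + .warp_field(p, warp$centers, warp$disp, warp$bw)
  }
  w_inv <- function(p) {
    if (is.null(warp)) return(p)
    x <- p
    for (i in 1:40) x <- p - .warp_field(x, warp$centers, warp$disp, warp$bw)
    x
  }
  full_to_crop <- function(p) sweep(p, 2L, c(c0 - 1, r0 - 1))
  crop_to_full <- function(p) sweep(p, 2L, c(c0 - 1, r0 - 1), "+")
  transform <- function(p) w_fwd(rot_fwd(full_to_crop(as.matrix(p))))
  inverse <- function(p) crop_to_full(rot_inv(w_inv(as.matrix(p))))
  # resample the output canvas through the inverse map
  grid <- as.matrix(expand.grid(x = seq_len(ow), y = seq_len(oh)))
  src <- rot_inv(w_inv(grid))
  out <- matrix(.bilinear(crop, src[, 1L], src[, 2L]), oh, ow, byrow = TRUE)
  structure(list(image = out, transform = transform, inverse = inverse,
                 crop = crop, crop_rect = crop_rect,
                 rotation_deg = rotation_deg),
            class = "roi_perturbation")
}

#' Generate a synthetic point-source dataset with a planted correction
#'
#' Stage-A positions are uniform in the 2 x 2 mm Cartesian workspace; stage-B
#' positions are A plus a planted constant shift plus seeded Gaussian noise.
#' Used for parameter-recovery tests of the migration summary.
#'
#' @param n_points number of points (>= 2).
#' @param planted_shift `c(dx, dy)` in mm added to every point.
#' @param noise_sd per-axis Gaussian noise sd in mm (0 for exact shifts).
#' @param seed integer seed.
#' @return list with data frames `A` and `B` in the point-CSV schema.
#' @export
make_point_dataset <- function(n_points = 200L, planted_shift = c(0.1, -0.4),
                               noise_sd = 0.05, seed = 1L) {
  stopifnot(n_points >= 2L, length(planted_shift) == 2L, noise_sd >= 0)
  with_seed(seed, {
    A <- data.frame(pair = "synthetic",
                    case_label = sprintf("case_%04d", seq_len(n_points)),
                    tag = letters[(seq_len(n_points) - 1L) %% 26L + 1L],
                    x_mm = runif(n_points, -1, 1),
                    y_mm = runif(n_points, -1, 1))
    B <- A
    B$x_mm <- A$x_mm + planted_shift[1L] + rnorm(n_points, 0, noise_sd)
    B$y_mm <- A$y_mm + planted_shift[2L] + rnorm(n_points, 0, noise_sd)
    list(A = A, B = B)
  })
}

#' Write a point dataset to CSV
#'
#' @param points data frame in the point schema.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
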
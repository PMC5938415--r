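#' Alignment configuration
#'
#' The registration classes compare two Bregma coordinates: *fully in
#' register* means exact equality, *narrowly in register* means a nonzero
#' separation of at most `narrow_threshold_um` (50 um by default -- on the
#' order of typical probe and injector-cannula diameters, so two plates this
#' close are interchangeable targets for most stereotaxic work), and *not in
#' register* means anything farther.
#'
#' @param narrow_threshold_um positive integer threshold in micrometers.
#' @return a list of class `alignment_config`.
#' @export
alignment_config <- function(narrow_threshold_um = 50L) {
  narrow_threshold_um <- as.integer(narrow_threshold_um)
  stopifnot(length(narrow_threshold_um) == 1L, !is.na(narrow_threshold_um),
            narrow_threshold_um > 0L)
  structure(list(narrow_threshold_um = narrow_threshold_um),
            class = "alignment_config")
}

.register_classes <- c("fully", "narrowly", "not")

#' Classify a pair of Bregma coordinates by register
#'
#' Symmetric in its arguments; a separation exactly equal to the threshold
#' counts as narrowly in register (the rule is `<= 50 um`, inclusive).
#'
#' @param z_a,z_b Bregma coordinates in integer micrometers (vectorized).
#' @param config an [alignment_config()].
#' @return factor with levels `fully`, `narrowly`, `not`.
#' @export
classify_register <- function(z_a, z_b, config = alignment_config()) {
  stopifnot(inherits(config, "alignment_config"),
            all(is.finite(z_a)), all(is.finite(z_b)))
  d <- abs(as.integer(z_a) - as.integer(z_b))
  cls <- ifelse(d == 0L, "fully",
                ifelse(d <= config$narrow_threshold_um, "narrowly", "not"))
  factor(cls, levels = .register_classes)
}

.group_levels <- function(registry, group) {
  sub <- registry[registry$group == group, c("level", "z_um"), drop = FALSE]
  if (nrow(sub) == 0L) stop("no levels for group ", group, " in registry")
  if (anyDuplicated(sub$level)) {
    stop("group ", group, " has duplicate level indices; reload the registry ",
         "with on_duplicate = \"first\"")
  }
  sub[order(sub$level), , drop = FALSE]
}

#' Align every level of one atlas group to its nearest level in another
#'
#' For each source level, finds the destination level(s) at minimal |dz| and
#' classifies the pair. Equidistant destination levels are all reported
#' (ordered by level index), since the craniometric rule alone cannot break
#' such a tie. The exhaustive fully- and narrowly-in-register pair sets (the
#' published table contents) are attached as attributes `fully` and
#' `narrowly` and are also available directly via [fully_in_register()] and
#' [narrowly_table()].
#'
#' @param registry an `atlas_registry`.
#' @param source_group,dest_group atlas group names.
#' @param config an [alignment_config()].
#' @return data frame of class `alignment_pairs` with columns `source_group`,
#'   `source_level`, `source_z_um`, `dest_group`, `dest_level`, `dest_z_um`,
#'   `delta_z_um`, `class`.
#' @export
cross_align <- function(registry, source_group, dest_group,
                        config = alignment_config()) {
  stopifnot(inherits(registry, "atlas_registry"))
  src <- .group_levels(registry, source_group)
  dst <- .group_levels(registry, dest_group)
  rows <- lapply(seq_len(nrow(src)), function(i) {
    d <- abs(src$z_um[i] - dst$z_um)
    j <- which(d == min(d))
    data.frame(source_group = source_group, source_level = src$level[i],
               source_z_um = src$z_um[i], dest_group = dest_group,
               dest_level = dst$level[j], dest_z_um = dst$z_um[j],
               delta_z_um = d[j])
  })
  out <- do.call(rbind, rows)
  out$class <- classify_register(out$source_z_um, out$dest_z_um, config)
  rownames(out) <- NULL
  structure(out,
            fully = .pairs_within(src, dst, source_group, dest_group, 0L, 0L),
            narrowly = .pairs_within(src, dst, source_group, dest_group, 1L,
                                     config$narrow_threshold_um),
            config = config,
            class = c("alignment_pairs", "data.frame"))
}

.pairs_within <- function(src, dst, source_group, dest_group, lo, hi) {
  out <- lapply(seq_len(nrow(src)), function(i) {
    d <- abs(src$z_um[i] - dst$z_um)
    j <- which(d >= lo & d <= hi)
    if (length(j) == 0L) return(NULL)
    data.frame(source_group = source_group, source_level = src$level[i],
               source_z_um = src$z_um[i], dest_group = dest_group,
               dest_level = dst$level[j], dest_z_um = dst$z_um[j],
               delta_z_um = d[j])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(source_group = character(), source_level = integer(),
                      source_z_um = integer(), dest_group = character(),
                      dest_level = integer(), dest_z_um = integer(),
                      delta_z_um = integer())
  }
  rownames(out) <- NULL
  out
}

#' Exhaustive fully-in-register pairs between two groups
#'
#' All (source, dest) level pairs whose Bregma coordinates are exactly equal.
#'
#' @inheritParams cross_align
#' @return data frame with the same columns as [narrowly_table()].
#' @export
fully_in_register <- function(registry, source_group, dest_group) {
  stopifnot(inherits(registry, "atlas_registry"))
  .pairs_within(.group_levels(registry, source_group),
                .group_levels(registry, dest_group),
                source_group, dest_group, 0L, 0L)
}

#' Exhaustive narrowly-in-register pairs between two groups
#'
#' All (source, dest) level pairs separated by more than zero but no more
#' than the threshold, with |dz| in micrometers. A source level with two
#' destination neighbors inside the threshold contributes two rows.
#'
#' @inheritParams cross_align
#' @return data frame `source_group, source_level, source_z_um, dest_group,
#'   dest_level, dest_z_um, delta_z_um`.
#' @export
narrowly_table <- function(registry, source_group, dest_group,
                           config = alignment_config()) {
  stopifnot(inherits(registry, "atlas_registry"))
  .pairs_within(.group_levels(registry, source_group),
                .group_levels(registry, dest_group),
                source_group, dest_group, 1L, config$narrow_threshold_um)
}

#' Dot-plot dataset for the cross-atlas alignment chart
#'
#' One row per atlas level, laid out as a Cleveland dot plot: each group gets
#' a horizontal track (a rank on a dummy y axis) and every level is a dot at
#' its Bregma coordinate, color-coded by its best register class against the
#' comparison space. PW tracks are compared against S; the S track is
#' compared against the union of the PW groups included in `groups`.
#'
#' @param registry an `atlas_registry`.
#' @param groups which groups to plot, in track order (top to bottom).
#' @param config an [alignment_config()].
#' @return data frame `group, track, level, z_mm, class` of class
#'   `atlas_dotplot`.
#' @export
dotplot_data <- function(registry, groups = c("PW1", "PW2", "PW3", "S"),
                         config = alignment_config()) {
  stopifnot(inherits(registry, "atlas_registry"), all(groups %in% .atlas_groups))
  pw <- setdiff(groups, "S")
  rows <- lapply(seq_along(groups), function(k) {
    g <- groups[k]
    sub <- .group_levels(registry, g)
    if (g == "S") {
      if (length(pw) == 0L) stop("dot plot needs at least one PW group to compare S against")
      ref <- registry$z_um[registry$group %in% pw]
    } else {
      ref <- registry$z_um[registry$group == "S"]
    }
    best <- vapply(sub$z_um, function(z) min(abs(z - ref)), numeric(1))
    cls <- ifelse(best == 0, "fully",
                  ifelse(best <= config$narrow_threshold_um, "narrowly", "not"))
    data.frame(group = g, track = k, level = sub$level, z_mm = sub$z_um / 1000,
               class = factor(cls, levels = .register_classes))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("atlas_dotplot", "data.frame")
  out
}

#' Render a dot-plot dataset to SVG
#'
#' Minimal standalone SVG rendering of [dotplot_data()]: one track per group,
#' dots placed along the Bregma axis, filled black for fully in register,
#' open for narrowly, red for not.
#'
#' @param dots output of [dotplot_data()].
#' @param path output `.svg` file.
#' @param width,height canvas size in pixels.
#' @return `path`, invisibly.
#' @export
dotplot_svg <- function(dots, path, width = 1000, height = 260) {
  stopifnot(inherits(dots, "atlas_dotplot"))
  zr <- range(dots$z_mm)
  pad <- 50
  xs <- pad + (zr[2] - dots$z_mm) / (zr[2] - zr[1]) * (width - 2 * pad)
  tracks <- sort(unique(dots$track))
  ys <- 40 + (match(dots$track, tracks) - 1) * (height - 80) / max(1, length(tracks) - 1)
  fill <- c(fully = "black", narrowly = "white", not = "red")[as.character(dots$class)]
  el <- c(
    sprintf('<line x1="%.1f" y1="20" x2="%.1f" y2="20" stroke="black"/>', pad, width - pad),
    vapply(unique(dots$track), function(tk) {
      g <- dots$group[dots$track == tk][1]
      y <- 40 + (match(tk, tracks) - 1) * (height - 80) / max(1, length(tracks) - 1)
      sprintf('<text x="5" y="%.1f" font-size="12">%s</text>', y + 4, g)
    }, character(1)),
    sprintf('<circle cx="%.1f" cy="%.1f" r="3" fill="%s" stroke="black" stroke-width="0.6"/>',
            xs, ys, fill))
  svg_write(el, path, width, height)
}

#' Write alignment pairs to CSV
#'
#' Emits `source_group,source_level,dest_group,dest_level,delta_z_um,class`.
#'
#' @param pairs an `alignment_pairs` data frame (or a pair table from
#'   [fully_in_register()] / [narrowly_table()], in which case `class` is
#'   derived).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_csv <- function(pairs, path) {
  df <- as.data.frame(pairs)
  if (is.null(df$class)) {
    df$class <- classify_register(df$source_z_um, df$dest_z_um)
  }
  utils::write.csv(df[, c("source_group", "source_level", "dest_group",
                          "dest_level", "delta_z_um", "class")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
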
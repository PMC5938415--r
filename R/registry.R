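#' Load a craniometric registry of atlas levels
#'
#' Reads a CSV with columns `group,level,z_mm` into an `atlas_registry`.
#' Each row is one atlas plate, identified by its atlas group (`PW1` for the
#' 1982/86/97 Paxinos-Watson editions, `PW2` for 1998, `PW3` for 2005/07/14,
#' `S` for all Swanson editions), its plate number, and its anteroposterior
#' distance from Bregma in mm (positive anterior). The z coordinate is stored
#' internally as integer micrometers so that "fully in register" comparisons
#' (exact z equality) and the 50 um threshold are exact, never floating-point.
#'
#' @param path path to a registry CSV (`group,level,z_mm`; `#` lines ignored).
#' @param on_duplicate what to do with repeated `(group, level)` keys:
#'   `"error"` (default) aborts; `"first"` keeps the first printed occurrence
#'   and records the dropped rows in `attr(, "duplicates")`; `"keep"` retains
#'   every row as printed (useful for running [validate_monotonicity()] on a
#'   verbatim transcription).
#' @param provenance free-text source identifier stored on the result.
#' @return a data frame of class `atlas_registry` with columns `group`
#'   (factor), `level` (integer), `z_um` (integer).
#' @seealso [ratlas_registry()] for the bundled reference table,
#'   [z_of()], [validate_monotonicity()], [write_registry()].
#' @export
load_registry <- function(path, on_duplicate = c("error", "first", "keep"),
                          provenance = basename(path)) {
  on_duplicate <- match.arg(on_duplicate)
  raw <- readLines(path, encoding = "UTF-8")
  raw_keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(raw_keep)
  raw <- raw[raw_keep]
  if (length(raw) == 0L) stop("empty registry file: ", path)
  header <- strsplit(raw[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(header), c("group", "level", "z_mm"))) {
    stop("registry CSV must have header 'group,level,z_mm', got: ", raw[1L])
  }
  if (length(raw) == 1L) stop("registry has a header but no rows: ", path)
  body <- raw[-1L]
  lineno <- lineno[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    stop("malformed registry row at line ", lineno[which(nf != 3L)[1L]],
         ": expected 3 fields, got ", nf[which(nf != 3L)[1L]])
  }
  m <- matrix(trimws(unlist(parts)), ncol = 3L, byrow = TRUE)
  group <- m[, 1L]
  bad_group <- !(group %in% .atlas_groups)
  if (any(bad_group)) {
    i <- which(bad_group)[1L]
    stop("unknown atlas group '", group[i], "' at line ", lineno[i],
         " (expected one of ", paste(.atlas_groups, collapse = ", "), ")")
  }
  level <- suppressWarnings(as.integer(m[, 2L]))
  z_mm <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- is.na(level) | level <= 0L | !is.finite(z_mm)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("malformed registry row at line ", lineno[i], ": '", body[i], "'")
  }
  # round half away from zero at the 1 um place
  z_um <- as.integer(sign(z_mm) * floor(abs(z_mm) * 1000 + 0.5))
  if (any(z_um %% 10L != 0L)) {
    warning("z values finer than 0.01 mm present (not multiples of 10 um)")
  }
  reg <- data.frame(group = factor(group, levels = .atlas_groups),
                    level = level, z_um = z_um)
  key <- paste(group, level)
  dup <- duplicated(key)
  dropped <- NULL
  if (any(dup)) {
    if (on_duplicate == "error") {
      stop("duplicate (group, level) keys in registry: ",
           paste(unique(key[dup]), collapse = "; "))
    }
    if (on_duplicate == "first") {
      dropped <- reg[dup, , drop = FALSE]
      reg <- reg[!dup, , drop = FALSE]
    }
  }
  rownames(reg) <- NULL
  structure(reg,
            provenance = provenance,
            duplicates = dropped,
            class = c("atlas_registry", "data.frame"))
}

#' Write a registry back to CSV
#'
#' Inverse of [load_registry()]: emits `group,level,z_mm` with z printed to
#' 0.01 mm, UTF-8, Unix newlines.
#'
#' @param registry an `atlas_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "atlas_registry"))
  lines <- c("group,level,z_mm",
             sprintf("%s,%d,%.2f", as.character(registry$group),
                     registry$level, registry$z_um / 1000))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Bundled Bregma registry of the 11 source atlases
#'
#' Loads the package's transcription of the published cross-atlas alignment
#' table: every Paxinos-Watson (PW1/PW2/PW3) and Swanson (S) atlas level with
#' its anteroposterior Bregma coordinate. The transcription is verbatim,
#' including the anomalies present in the printed source (repeated PW3 level
#' indices 117-119 and S indices 52-53 near z = -11 mm, where the printed
#' column evidently reprints earlier indices in place of PW3 125-127 / S 56-57,
#' and one z row, -11.28 mm, whose level cell is blank and therefore cannot be
#' transcribed). Use [validate_monotonicity()] to list the affected rows.
#'
#' @param on_duplicate passed to [load_registry()]; the default `"first"`
#'   keeps the first printed occurrence of each repeated level index (the
#'   occurrences corroborated by the published distance tables) and stores the
#'   rest in `attr(, "duplicates")`.
#' @return an `atlas_registry`.
#' @export
ratlas_registry <- function(on_duplicate = "first") {
  path <- system.file("extdata", "table1_registry.csv", package = "ratlas",
                      mustWork = TRUE)
  load_registry(path, on_duplicate = on_duplicate,
                provenance = "bundled cross-atlas Bregma table")
}

#' Look up the Bregma coordinate of an atlas level
#'
#' @param registry an `atlas_registry`.
#' @param group atlas group (`"PW1"`, `"PW2"`, `"PW3"`, `"S"`).
#' @param level plate number(s); `group` is recycled to match.
#' @return integer z in micrometers (positive anterior to Bregma).
#' @export
z_of <- function(registry, group, level) {
  stopifnot(inherits(registry, "atlas_registry"))
  n <- max(length(group), length(level))
  group <- rep_len(as.character(group), n)
  level <- rep_len(as.integer(level), n)
  key <- paste(group, level)
  rkey <- paste(as.character(registry$group), registry$level)
  if (anyDuplicated(rkey[rkey %in% key])) {
    stop("ambiguous lookup: registry contains duplicate keys; reload with ",
         "on_duplicate = \"first\"")
  }
  i <- match(key, rkey)
  if (anyNA(i)) {
    stop("no such atlas level: ", paste(key[is.na(i)], collapse = "; "))
  }
  registry$z_um[i]
}

#' Flag non-monotone level sequences in a registry
#'
#' Atlas plates are numbered from anterior to posterior, so within a group z
#' should strictly decrease as the level index increases. This advisory check
#' lists every adjacent pair (ordered by level index, then by row order for
#' repeated indices) that violates that expectation -- either z fails to
#' decrease, or the same level index occurs more than once. Data are reported,
#' never corrected.
#'
#' @param registry an `atlas_registry` (load with `on_duplicate = "keep"` to
#'   audit a verbatim transcription).
#' @return data frame `group,level_a,level_b,description`; zero rows if clean.
#' @export
validate_monotonicity <- function(registry) {
  stopifnot(inherits(registry, "atlas_registry"))
  out <- list()
  for (g in levels(registry$group)) {
    sub <- registry[registry$group == g, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$level), , drop = FALSE]
    a <- sub[-nrow(sub), ]
    b <- sub[-1L, ]
    dup <- a$level == b$level
    nonmono <- !dup & b$z_um >= a$z_um
    if (any(dup)) {
      out[[length(out) + 1L]] <- data.frame(
        group = g, level_a = a$level[dup], level_b = b$level[dup],
        description = sprintf("level %d occurs more than once (z %.2f and %.2f mm)",
                              a$level[dup], a$z_um[dup] / 1000, b$z_um[dup] / 1000))
    }
    if (any(nonmono)) {
      out[[length(out) + 1L]] <- data.frame(
        group = g, level_a = a$level[nonmono], level_b = b$level[nonmono],
        description = sprintf("z does not decrease from level %d (%.2f mm) to level %d (%.2f mm)",
                              a$level[nonmono], a$z_um[nonmono] / 1000,
                              b$level[nonmono], b$z_um[nonmono] / 1000))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(group = character(), level_a = integer(),
                      level_b = integer(), description = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count physically distinct atlas plates in a registry
#'
#' The PW1 plates are the same tissue sections as their PW2 counterparts
#' (the 1998 edition re-publishes the earlier tissue set with two added
#' plates and renumbered levels), so the number of physically distinct plates
#' is the number of PW2, PW3, and S entries. On the bundled verbatim
#' transcription this is 311; the source states 312, the difference being the
#' single printed row (z = -11.28 mm) whose level cell is blank and so cannot
#' be carried by a transcription.
#'
#' @param registry an `atlas_registry`.
#' @return integer count of distinct physical plates.
#' @export
n_unique_levels <- function(registry) {
  stopifnot(inherits(registry, "atlas_registry"))
  dupes <- attr(registry, "duplicates")
  n <- sum(registry$group != "PW1")
  if (!is.null(dupes)) n <- n + sum(dupes$group != "PW1")
  n
}

#' @export
print.atlas_registry <- function(x, ...) {
  cat("Atlas level registry (", attr(x, "provenance"), ")\n", sep = "")
  tab <- table(x$group)
  cat(sprintf("  %d entries: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  z range: %+.2f to %+.2f mm from Bregma\n",
              max(x$z_um) / 1000, min(x$z_um) / 1000))
  if (!is.null(attr(x, "duplicates"))) {
    cat(sprintf("  %d duplicate-key row(s) dropped at load; see attr(, \"duplicates\")\n",
                nrow(attr(x, "duplicates"))))
  }
  invisible(x)
}
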
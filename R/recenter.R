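# Class-average-guided re-centering.
#
# During 2D classification each particle is aligned to its class average by
# an in-plane translation (origin_x, origin_y) and an in-plane rotation
# psi (degrees).  A region of interest clicked on the class average at
# offset (dx, dy) from the average's center therefore sits, in the
# micrograph frame, at the particle coordinate minus the alignment origin
# plus the offset rotated back through psi:
#
#   x_new = x - origin_x + dx * cos(psi * pi/180) + dy * sin(psi * pi/180)
#   y_new = y - origin_y + dy * cos(psi * pi/180) - dx * sin(psi * pi/180)
#
# The transform is applied per particle; re-extraction at (x_new, y_new)
# with a smaller box isolates the region for segmented refinement.

# Vectorized core of the transform; angles in degrees.
.recenter_coords <- function(x, y, origin_x, origin_y, psi, dx, dy) {
  a <- psi * pi / 180
  ca <- cos(a); sa <- sin(a)
  list(x = x - origin_x + dx * ca + dy * sa,
       y = y - origin_y + dy * ca - dx * sa)
}

#' Construct a class offset
#'
#' The displacement of a region of interest relative to the center of a 2D
#' class average, in class-average pixels (x right, y down).
#'
#' @param class_id positive integer class number.
#' @param dx,dy offset in pixels.
#' @param label free-text region name (e.g. `"head"`, `"neck"`, `"legs"`).
#' @return A list of class `class_offset`.
#' @export
class_offset <- function(class_id, dx, dy, label = "") {
  class_id <- as.integer(class_id)
  if (is.na(class_id) || class_id < 1L)
    stop("class_offset: class_id must be a positive integer")
  if (!is.finite(dx) || !is.finite(dy))
    stop("class_offset: dx and dy must be finite")
  structure(list(class_id = class_id, dx = as.numeric(dx),
                 dy = as.numeric(dy), label = as.character(label)),
            class = "class_offset")
}

#' Re-center a single particle on a class-average region
#'
#' Applies the in-plane alignment inverse to a region-of-interest offset:
#' the offset recorded on the class average is rotated through the
#' particle's psi angle and added to the origin-corrected coordinate.
#'
#' @param particle list or one-row data frame with `coordinate_x`,
#'   `coordinate_y`, `origin_x`, `origin_y`, `angle_psi`, `class_id`.
#' @param offset a [class_offset] for the particle's class.
#' @return Named numeric vector `c(x_new, y_new)` in micrograph pixels.
#' @export
recenter_particle <- function(particle, offset) {
  stopifnot(inherits(offset, "class_offset"))
  pc <- as.list(particle)
  if (!is.na(pc$class_id) && pc$class_id != offset$class_id)
    stop(sprintf(
      "recenter_particle: offset is for class %d but particle is in class %d",
      offset$class_id, pc$class_id))
  r <- .recenter_coords(pc$coordinate_x, pc$coordinate_y,
                        pc$origin_x, pc$origin_y, pc$angle_psi,
                        offset$dx, offset$dy)
  c(x_new = r$x, y_new = r$y)
}

#' Re-center a particle set
#'
#' Every particle whose class has an offset gets new coordinates; its
#' alignment is consumed (origin and psi reset to 0) since re-extraction at
#' the new center starts a fresh alignment. Particles in classes without an
#' offset are excluded and counted as skipped. When `micrograph_extent` and
#' `new_box` are given, particles whose new box
#' `[x_new - box/2, x_new + box/2)` (likewise in y) leaves the micrograph
#' are dropped (not clamped) and counted.
#'
#' @param particles a [particle_set].
#' @param offsets list of [class_offset], at most one per class.
#' @param micrograph_extent optional `c(width, height)` in pixels.
#' @param new_box optional new extraction box size in pixels.
#' @param scale scale factor applied to offsets when class averages were
#'   computed from binned images (offset pixels times `scale` gives
#'   extraction-image pixels); default 1.
#' @return List with `particles` (re-centered [particle_set]) and `report`
#'   (counts `n_input`, `n_written`, `n_dropped_out_of_bounds`,
#'   `n_skipped_no_offset`).
#' @export
recenter_set <- function(particles, offsets, micrograph_extent = NULL,
                         new_box = NULL, scale = 1) {
  stopifnot(inherits(particles, "particle_set"))
  if (inherits(offsets, "class_offset")) offsets <- list(offsets)
  ids <- vapply(offsets, `[[`, integer(1), "class_id")
  if (anyDuplicated(ids))
    stop("recenter_set: duplicate class_id in offsets: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  p <- particles$particles
  n_input <- nrow(p)
  if (n_input > 0L && all(is.na(p$class_id)) && length(offsets) > 0L)
    stop("recenter_set: particle set has no class assignments")

  has_offset <- p$class_id %in% ids
  kept <- p[has_offset, , drop = FALSE]
  n_skipped <- n_input - nrow(kept)

  if (nrow(kept) > 0L) {
    idx <- match(kept$class_id, ids)
    dx <- vapply(offsets, `[[`, numeric(1), "dx")[idx] * scale
    dy <- vapply(offsets, `[[`, numeric(1), "dy")[idx] * scale
    r <- .recenter_coords(kept$coordinate_x, kept$coordinate_y,
                          kept$origin_x, kept$origin_y, kept$angle_psi,
                          dx, dy)
    kept$coordinate_x <- r$x
    kept$coordinate_y <- r$y
    kept$origin_x <- 0
    kept$origin_y <- 0
    kept$angle_psi <- 0
  }

  n_dropped <- 0L
  if (!is.null(micrograph_extent) && !is.null(new_box) && nrow(kept) > 0L) {
    half <- new_box / 2
    inb <- kept$coordinate_x - half >= 0 &
           kept$coordinate_x + half <= micrograph_extent[1L] &
           kept$coordinate_y - half >= 0 &
           kept$coordinate_y + half <= micrograph_extent[2L]
    n_dropped <- sum(!inb)
    kept <- kept[inb, , drop = FALSE]
  }

  report <- list(n_input = n_input, n_written = nrow(kept),
                 n_dropped_out_of_bounds = n_dropped,
                 n_skipped_no_offset = n_skipped)
  stopifnot(report$n_input == report$n_written +
              report$n_dropped_out_of_bounds + report$n_skipped_no_offset)
  out <- particles
  out$particles <- kept
  list(particles = out, report = report)
}

#' Read a class-offsets file
#'
#' Delimited text (comma or whitespace), optional header, columns
#' `class_id, dx, dy[, label]`. One row per class.
#'
#' @param path path to the offsets file.
#' @return List of [class_offset].
#' @export
read_offsets <- function(path) {
  if (!file.exists(path)) stop("read_offsets: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) return(list())
  toks <- lapply(lines, function(l)
    strsplit(trimws(l), "\\s*,\\s*|\\s+")[[1L]])
  # header row: first token not numeric
  if (suppressWarnings(is.na(as.numeric(toks[[1L]][1L])))) {
    toks <- toks[-1L]
    if (length(toks) == 0L) return(list())
  }
  offsets <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    t <- toks[[i]]
    if (length(t) < 3L)
      stop(sprintf("read_offsets: row %d has %d fields, need class_id,dx,dy",
                   i, length(t)))
    num <- suppressWarnings(as.numeric(t[1:3]))
    if (anyNA(num))
      stop(sprintf("read_offsets: non-numeric class_id/dx/dy at row %d", i))
    offsets[[i]] <- class_offset(num[1L], num[2L], num[3L],
                                 label = if (length(t) >= 4L) t[4L] else "")
  }
  ids <- vapply(offsets, `[[`, integer(1), "class_id")
  if (anyDuplicated(ids))
    stop("read_offsets: duplicate class_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  offsets
}
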
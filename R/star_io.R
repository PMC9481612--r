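# STAR particle-table I/O (RELION dialects).
#
# Two dialects are supported:
#   * legacy_single_table: one loop_ data block, origins in pixels
#     (rlnOriginX / rlnOriginY);
#   * optics_grouped: a data_optics block carrying rlnImagePixelSize plus a
#     data_particles block with origins in Angstrom
#     (rlnOriginXAngst / rlnOriginYAngst).
# Origins are always converted to pixels on read so the re-centering
# arithmetic works in one unit; on write the source dialect is restored.

.STAR_COORD_COLS <- c("rlnCoordinateX", "rlnCoordinateY")
.STAR_ORIGIN_PX  <- c("rlnOriginX", "rlnOriginY")
.STAR_ORIGIN_ANG <- c("rlnOriginXAngst", "rlnOriginYAngst")

#' Construct a particle set
#'
#' A `particle_set` holds one row per particle with the five alignment
#' quantities used for re-centering (micrograph coordinates, alignment
#' origin in pixels, in-plane psi angle in degrees), an optional class
#' assignment, and every other STAR column preserved verbatim as character.
#'
#' @param particles data frame with numeric columns `coordinate_x`,
#'   `coordinate_y`, `origin_x`, `origin_y`, `angle_psi` and (optionally)
#'   integer `class_id`; any further columns are carried as extra fields.
#' @param dialect `"legacy_single_table"` or `"optics_grouped"`.
#' @param pixel_size pixel size in Angstrom per pixel, or `NA`.
#' @param optics_block character vector of raw optics-block lines (kept for
#'   round-trip writing), or `NULL`.
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(particles,
                         dialect = c("legacy_single_table", "optics_grouped"),
                         pixel_size = NA_real_,
                         optics_block = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(particles))
  need <- c("coordinate_x", "coordinate_y", "origin_x", "origin_y", "angle_psi")
  miss <- setdiff(need, names(particles))
  if (length(miss) > 0L)
    stop("particle_set: missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(particles$angle_psi)))
    stop("particle_set: angle_psi must be finite")
  if (!all(is.finite(particles$coordinate_x) & particles$coordinate_x >= 0 &
           is.finite(particles$coordinate_y) & particles$coordinate_y >= 0))
    stop("particle_set: coordinates must be finite and non-negative")
  if (!is.na(pixel_size) && pixel_size <= 0)
    stop("particle_set: pixel_size must be > 0")
  if (!"class_id" %in% names(particles))
    particles$class_id <- rep(NA_integer_, nrow(particles))
  structure(
    list(particles = particles, dialect = dialect,
         pixel_size = pixel_size, optics_block = optics_block),
    class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("particle_set: %d particles, dialect %s, pixel size %s A/px\n",
              nrow(x$particles), x$dialect,
              ifelse(is.na(x$pixel_size), "unknown", format(x$pixel_size))))
  invisible(x)
}

#' @export
length.particle_set <- function(x) nrow(x$particles)

# Split one STAR file into named data blocks of raw lines.
.star_blocks <- function(lines) {
  starts <- grep("^data_", trimws(lines))
  if (length(starts) == 0L)
    stop("STAR parse error: no data block found")
  ends <- c(starts[-1L] - 1L, length(lines))
  blocks <- list()
  for (i in seq_along(starts)) {
    nm <- sub("^data_", "", trimws(lines[starts[i]]))
    blocks[[length(blocks) + 1L]] <- list(
      name = nm, first_line = starts[i],
      lines = lines[starts[i]:ends[i]],
      offset = starts[i] - 1L)
  }
  blocks
}

# Parse one loop_ table inside a block; returns data.frame of character
# columns named by their rln tags.  Line numbers refer to the whole file.
.star_loop <- function(block) {
  lines <- block$lines
  loop_at <- which(trimws(lines) == "loop_")
  if (length(loop_at) == 0L)
    stop(sprintf("STAR parse error: no loop_ in block 'data_%s' (line %d)",
                 block$name, block$first_line))
  i <- loop_at[1L] + 1L
  tags <- character()
  while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
    tag <- sub("^_", "", strsplit(trimws(lines[i]), "[[:space:]#]+")[[1L]][1L])
    tags <- c(tags, tag)
    i <- i + 1L
  }
  if (length(tags) == 0L)
    stop(sprintf("STAR parse error: loop_ with no column tags (line %d)",
                 block$offset + loop_at[1L]))
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^#", ln)) { i <- i + 1L; next }
    toks <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(toks) != length(tags))
      stop(sprintf(
        "STAR parse error at line %d: %d fields, expected %d",
        block$offset + i, length(toks), length(tags)))
    rows[[length(rows) + 1L]] <- toks
    i <- i + 1L
  }
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(character(), nrow = 0, ncol = length(tags)),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  }
  names(df) <- tags
  df
}

# Non-loop key/value pairs of a block (used for single-row optics blocks
# written in key-value style are rare; RELION writes loop_ so we only need
# the loop path, but pixel size lookup goes through the parsed table).
.star_numeric <- function(x, tag) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) & length(x) > 0L)
    stop("STAR parse error: non-numeric value in column ", tag)
  v
}

#' Read a RELION STAR particle table
#'
#' Auto-detects the dialect: a `data_optics` block marks the optics-grouped
#' dialect (origins in Angstrom, converted to pixels using the optics
#' `rlnImagePixelSize`); otherwise the first loop-structured block is taken
#' as a legacy single-table file with pixel origins. All columns beyond the
#' five alignment columns and the class assignment are preserved verbatim.
#'
#' @param path path to a STAR file.
#' @return A [particle_set].
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("read_star: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- .star_blocks(lines)
  names(blocks) <- vapply(blocks, `[[`, "", "name")

  optics <- NULL
  pixel_size <- NA_real_
  if ("optics" %in% names(blocks)) {
    dialect <- "optics_grouped"
    optics <- blocks[["optics"]]
    otab <- .star_loop(optics)
    if ("rlnImagePixelSize" %in% names(otab))
      pixel_size <- .star_numeric(otab$rlnImagePixelSize,
                                  "rlnImagePixelSize")[1L]
    pblock <- if ("particles" %in% names(blocks)) blocks[["particles"]] else
      stop("read_star: optics-grouped file lacks a data_particles block")
  } else {
    dialect <- "legacy_single_table"
    pblock <- blocks[[1L]]
  }
  tab <- .star_loop(pblock)

  origin_cols <- if (all(.STAR_ORIGIN_ANG %in% names(tab))) .STAR_ORIGIN_ANG
                 else .STAR_ORIGIN_PX
  need <- c(.STAR_COORD_COLS, origin_cols, "rlnAnglePsi")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("read_star: schema error, missing column(s): ",
         paste(miss, collapse = ", "))

  ox <- .star_numeric(tab[[origin_cols[1L]]], origin_cols[1L])
  oy <- .star_numeric(tab[[origin_cols[2L]]], origin_cols[2L])
  origin_unit <- "px"
  if (identical(origin_cols, .STAR_ORIGIN_ANG)) {
    if (is.na(pixel_size))
      stop("read_star: Angstrom origins but no rlnImagePixelSize in optics")
    ox <- ox / pixel_size
    oy <- oy / pixel_size
    origin_unit <- "angst"
  }

  particles <- data.frame(
    coordinate_x = .star_numeric(tab$rlnCoordinateX, "rlnCoordinateX"),
    coordinate_y = .star_numeric(tab$rlnCoordinateY, "rlnCoordinateY"),
    origin_x = ox, origin_y = oy,
    angle_psi = .star_numeric(tab$rlnAnglePsi, "rlnAnglePsi"),
    stringsAsFactors = FALSE)
  particles$class_id <- if ("rlnClassNumber" %in% names(tab))
    as.integer(.star_numeric(tab$rlnClassNumber, "rlnClassNumber")) else
    rep(NA_integer_, nrow(particles))
  particles$micrograph_id <- if ("rlnMicrographName" %in% names(tab))
    tab$rlnMicrographName else rep(NA_character_, nrow(particles))

  consumed <- c(need, "rlnClassNumber", "rlnMicrographName")
  extras <- tab[setdiff(names(tab), consumed)]
  ps <- particle_set(cbind(particles, extras), dialect = dialect,
                     pixel_size = pixel_size,
                     optics_block = if (is.null(optics)) NULL else optics$lines)
  ps$origin_unit <- origin_unit
  ps$col_order <- names(tab)
  ps
}

.star_fmt <- function(x) {
  # >= 6 significant digits, no scientific notation, stable round trip
  formatC(x, format = "f", digits = 6, drop0trailing = FALSE)
}

#' Write a particle set as a STAR file
#'
#' Emits the dialect the set was read with (or constructed as): the
#' optics-grouped dialect re-emits the preserved optics block and converts
#' pixel origins back to Angstrom. Extra columns are written verbatim;
#' numeric alignment columns are written with six decimal places.
#'
#' @param particles a [particle_set].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_star <- function(particles, path) {
  stopifnot(inherits(particles, "particle_set"))
  p <- particles$particles
  origin_unit <- if (is.null(particles$origin_unit)) "px" else
    particles$origin_unit

  ox <- p$origin_x; oy <- p$origin_y
  if (origin_unit == "angst") {
    ox <- ox * particles$pixel_size
    oy <- oy * particles$pixel_size
    origin_tags <- .STAR_ORIGIN_ANG
  } else origin_tags <- .STAR_ORIGIN_PX

  core <- list(rlnCoordinateX = .star_fmt(p$coordinate_x),
               rlnCoordinateY = .star_fmt(p$coordinate_y))
  core[[origin_tags[1L]]] <- .star_fmt(ox)
  core[[origin_tags[2L]]] <- .star_fmt(oy)
  core$rlnAnglePsi <- .star_fmt(p$angle_psi)
  if (!all(is.na(p$class_id)))
    core$rlnClassNumber <- format(p$class_id)
  if (!all(is.na(p$micrograph_id)))
    core$rlnMicrographName <- p$micrograph_id
  extra_names <- setdiff(names(p),
                         c("coordinate_x", "coordinate_y", "origin_x",
                           "origin_y", "angle_psi", "class_id",
                           "micrograph_id"))
  for (nm in extra_names) core[[nm]] <- as.character(p[[nm]])

  # restore original column order where known
  tags <- names(core)
  if (!is.null(particles$col_order)) {
    known <- intersect(particles$col_order, tags)
    tags <- c(known, setdiff(tags, known))
  }

  out <- character()
  if (identical(particles$dialect, "optics_grouped")) {
    ob <- particles$optics_block
    if (is.null(ob))
      ob <- c("data_optics", "", "loop_", "_rlnOpticsGroup #1",
              "_rlnImagePixelSize #2",
              paste(1, .star_fmt(particles$pixel_size)))
    out <- c(out, ob, "")
    out <- c(out, "data_particles", "")
  } else {
    out <- c(out, "data_particles", "")
  }
  out <- c(out, "loop_",
           sprintf("_%s #%d", tags, seq_along(tags)))
  if (nrow(p) > 0L) {
    cols <- lapply(tags, function(t) format(core[[t]], justify = "none"))
    out <- c(out, do.call(paste, c(cols, sep = "\t")))
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_star: cannot write to ", path)
  invisible(path)
}
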
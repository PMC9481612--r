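# Seeded synthetic-data generators, plus the packaged published crosslink
# table, so every stage of the toolkit is testable without downloads.
#
# The STAR generator inverts the re-centering equations analytically
# (planted center, offset, psi, origin -> coordinate) rather than calling
# the recenter module, so recovery tests are not self-confirming.

# Run expr with a fixed RNG state, restoring the caller's state after.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic aligned particle table with known region centers
#'
#' Emulates the metadata of a 2D-classified particle stack: each particle
#' has a true region center planted uniformly inside the micrograph, a
#' psi angle uniform on [-180, 180), a Gaussian alignment origin, and a
#' coordinate synthesized by the analytic inverse of the re-centering
#' transform, so that re-centering with the class's true offset recovers
#' the planted center exactly.
#'
#' @param n_particles number of particles.
#' @param classes data frame with columns `class_id`, `dx`, `dy`: the true
#'   region offset per class; particles are assigned classes uniformly.
#' @param micrograph_extent `c(width, height)` in pixels (default
#'   `c(4096, 4096)`).
#' @param origin_sigma standard deviation of alignment origins in pixels
#'   (default 5).
#' @param margin minimum distance of planted centers from the micrograph
#'   edge (default 100 px); centers are redrawn up to 100 times, then the
#'   generator errors.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return List with `particles` (a [particle_set]) and `truth` (data
#'   frame `particle`, `class_id`, `center_x`, `center_y`).
#' @export
gen_star <- function(n_particles, classes,
                     micrograph_extent = c(4096, 4096),
                     origin_sigma = 5, margin = 100, seed = 1) {
  stopifnot(is.data.frame(classes),
            all(c("class_id", "dx", "dy") %in% names(classes)))
  n <- n_particles
  if (n == 0L) {
    empty <- data.frame(coordinate_x = numeric(), coordinate_y = numeric(),
                        origin_x = numeric(), origin_y = numeric(),
                        angle_psi = numeric(), class_id = integer())
    return(list(particles = particle_set(empty),
                truth = data.frame(particle = integer(), class_id = integer(),
                                   center_x = numeric(),
                                   center_y = numeric())))
  }
  .with_seed(seed, {
    ci <- sample.int(nrow(classes), n, replace = TRUE)
    dx <- classes$dx[ci]; dy <- classes$dy[ci]
    psi <- stats::runif(n, -180, 180)
    ox <- stats::rnorm(n, 0, origin_sigma)
    oy <- stats::rnorm(n, 0, origin_sigma)
    a <- psi * pi / 180
    cx <- cy <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:100) {
        cx[i] <- stats::runif(1, margin, micrograph_extent[1L] - margin)
        cy[i] <- stats::runif(1, margin, micrograph_extent[2L] - margin)
        # analytic inverse of the re-centering transform
        X <- cx[i] + ox[i] - dx[i] * cos(a[i]) - dy[i] * sin(a[i])
        Y <- cy[i] + oy[i] - dy[i] * cos(a[i]) + dx[i] * sin(a[i])
        if (X >= 0 && Y >= 0 && X <= micrograph_extent[1L] &&
            Y <= micrograph_extent[2L]) { ok <- TRUE; break }
      }
      if (!ok) stop("gen_star: could not place center inside micrograph")
    }
    X <- cx + ox - dx * cos(a) - dy * sin(a)
    Y <- cy + oy - dy * cos(a) + dx * sin(a)
    particles <- data.frame(
      coordinate_x = X, coordinate_y = Y,
      origin_x = ox, origin_y = oy, angle_psi = psi,
      class_id = classes$class_id[ci])
    list(particles = particle_set(particles),
         truth = data.frame(particle = seq_len(n),
                            class_id = classes$class_id[ci],
                            center_x = cx, center_y = cy))
  })
}

#' Generate a toy multi-chain structure with planted crosslink distances
#'
#' Builds C-alpha-only chains as straight rods (one residue per
#' `rise` Angstrom along an axis), deletes requested residue ranges
#' (emulating disordered regions absent from a cryo-EM model), and places
#' chains so that each planted crosslink achieves its target C-alpha
#' distance. PDB and mmCIF serializations describe identical coordinates.
#'
#' @param chains data frame with columns `chain`, `n_residues`, optional
#'   `rise` (default 3.8), `axis` (`"x"`, `"y"` or `"z"`, default `"x"`).
#' @param deleted_ranges optional data frame `chain`, `from`, `to`:
#'   residue intervals removed from the emitted coordinates.
#' @param planted_crosslinks optional data frame `chain1`, `res1`,
#'   `chain2`, `res2`, `distance`: chain2 is translated so the pair
#'   achieves `distance`; conflicting constraints on an already-placed
#'   chain raise a generation error if off by more than `1e-3` Angstrom.
#' @param seed RNG seed (used for placement directions).
#' @param dir optional directory; when given, `toy.pdb` and `toy.cif` are
#'   written there.
#' @return List with `coords` (data frame `chain`, `resno`, `x`, `y`,
#'   `z`, full coordinates before deletion filtering is applied to files
#'   — deleted residues are already excluded), `pdb` and `cif` (character
#'   vectors of file lines), `truth` (planted crosslinks with achieved
#'   distances), and file paths when `dir` was given.
#' @export
gen_toy_structure <- function(chains, deleted_ranges = NULL,
                              planted_crosslinks = NULL, seed = 1,
                              dir = NULL) {
  stopifnot(is.data.frame(chains),
            all(c("chain", "n_residues") %in% names(chains)))
  if (!"rise" %in% names(chains)) chains$rise <- 3.8
  if (!"axis" %in% names(chains)) chains$axis <- "x"
  axes <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))

  .with_seed(seed, {
    # initial well-separated origins on a coarse grid
    origins <- lapply(seq_len(nrow(chains)), function(i)
      c(0, (i - 1) * 500, 0))
    names(origins) <- chains$chain
    placed <- stats::setNames(rep(FALSE, nrow(chains)), chains$chain)
    placed[chains$chain[1L]] <- TRUE

    res_pos <- function(ch, r) {
      i <- match(ch, chains$chain)
      origins[[ch]] + axes[[chains$axis[i]]] * chains$rise[i] * (r - 1)
    }

    if (!is.null(planted_crosslinks)) {
      for (k in seq_len(nrow(planted_crosslinks))) {
        pc <- planted_crosslinks[k, ]
        if (!placed[[pc$chain2]]) {
          # translate chain2 so the pair sits at the target distance,
          # along a random direction
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          target <- res_pos(pc$chain1, pc$res1) + pc$distance * u
          shift <- target - res_pos(pc$chain2, pc$res2)
          origins[[pc$chain2]] <- origins[[pc$chain2]] + shift
          placed[[pc$chain2]] <- TRUE
        } else if (!placed[[pc$chain1]]) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          target <- res_pos(pc$chain2, pc$res2) + pc$distance * u
          shift <- target - res_pos(pc$chain1, pc$res1)
          origins[[pc$chain1]] <- origins[[pc$chain1]] + shift
          placed[[pc$chain1]] <- TRUE
        }
        got <- sqrt(sum((res_pos(pc$chain1, pc$res1) -
                           res_pos(pc$chain2, pc$res2))^2))
        if (abs(got - pc$distance) > 1e-3)
          stop(sprintf(
            "gen_toy_structure: infeasible planted distance %g (achieved %g) for %s:%d-%s:%d",
            pc$distance, got, pc$chain1, pc$res1, pc$chain2, pc$res2))
      }
    }

    coords <- do.call(rbind, lapply(seq_len(nrow(chains)), function(i) {
      r <- seq_len(chains$n_residues[i])
      p <- t(vapply(r, function(rr) res_pos(chains$chain[i], rr), numeric(3)))
      data.frame(chain = chains$chain[i], resno = r,
                 x = p[, 1], y = p[, 2], z = p[, 3],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(deleted_ranges)) {
      for (k in seq_len(nrow(deleted_ranges))) {
        dr <- deleted_ranges[k, ]
        coords <- coords[!(coords$chain == dr$chain &
                             coords$resno >= dr$from &
                             coords$resno <= dr$to), , drop = FALSE]
      }
      rownames(coords) <- NULL
    }

    truth <- planted_crosslinks
    if (!is.null(truth)) {
      truth$achieved <- vapply(seq_len(nrow(truth)), function(k)
        sqrt(sum((res_pos(truth$chain1[k], truth$res1[k]) -
                    res_pos(truth$chain2[k], truth$res2[k]))^2)),
        numeric(1))
    }

    pdb_file <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = pdb_file,
                     xyz = as.numeric(t(as.matrix(coords[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(coords)),
                     resno = coords$resno,
                     resid = rep("ALA", nrow(coords)),
                     eleno = seq_len(nrow(coords)),
                     elety = rep("CA", nrow(coords)),
                     chain = coords$chain,
                     o = rep(1, nrow(coords)), b = rep(0, nrow(coords)),
                     elesy = rep("C", nrow(coords)))
    pdb_lines <- readLines(pdb_file, warn = FALSE)
    unlink(pdb_file)
    cif_lines <- .toy_cif_lines(coords)

    out <- list(coords = coords, pdb = pdb_lines, cif = cif_lines,
                truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$pdb_file <- file.path(dir, "toy.pdb")
      out$cif_file <- file.path(dir, "toy.cif")
      writeLines(pdb_lines, out$pdb_file)
      writeLines(cif_lines, out$cif_file)
    }
    out
  })
}

# Minimal mmCIF atom_site serialization of CA-only coordinates.
.toy_cif_lines <- function(coords) {
  n <- nrow(coords)
  c("data_toy",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d C CA . ALA %s %d %.3f %.3f %.3f 1.00 0.00 %d %s 1",
            seq_len(n), coords$chain, coords$resno,
            coords$x, coords$y, coords$z, coords$resno, coords$chain),
    "#")
}

#' The packaged published intersubunit crosslink table
#'
#' Returns the transcription of the 33 published intersubunit DSSO
#' crosslinks of the human augmin (HAUS) octamer: subunits, peptides,
#' peptide starts, marked crosslink positions, search scores, the
#' published model C-alpha distances (28 rows; absent where a peptide is
#' not present in the deposited structure) and the unresolved flags
#' (5 rows; `a` = peptide 1 missing, `b` = peptide 2 missing).
#'
#' The published table marks each peptide with a superscript number and
#' the crosslinked amino acid in bold. The superscript is interpreted as
#' the peptide's start residue (the interpretation consistent across
#' repeated peptides); `superscript = "site"` provides the alternate
#' reading where it marks the crosslinked residue itself.
#'
#' @param superscript `"peptide_start"` (default) or `"site"`.
#' @return A [crosslink_records] table with additional columns `id`,
#'   `distance` (Angstrom, `NA` when unresolved) and `flag`.
#' @export
table1_fixture <- function(superscript = c("peptide_start", "site")) {
  superscript <- match.arg(superscript)
  path <- system.file("extdata", "augmin_intersubunit_crosslinks.csv",
                      package = "cryolink", mustWork = TRUE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  start1 <- raw$peptide1_start
  start2 <- raw$peptide2_start
  if (superscript == "site") {
    start1 <- raw$peptide1_start - raw$marked_pos1 + 1L
    start2 <- raw$peptide2_start - raw$marked_pos2 + 1L
  }
  df <- data.frame(
    protein1 = raw$protein1, peptide1 = raw$peptide1,
    peptide1_start = start1,
    site1 = mapply(map_peptide_site, raw$peptide1, start1, raw$marked_pos1),
    protein2 = raw$protein2, peptide2 = raw$peptide2,
    peptide2_start = start2,
    site2 = mapply(map_peptide_site, raw$peptide2, start2, raw$marked_pos2),
    score = raw$score,
    stringsAsFactors = FALSE)
  out <- crosslink_records(df)
  out$id <- raw$id
  out$distance <- as.numeric(raw$distance)
  out$flag <- ifelse(is.na(raw$flag) | raw$flag == "", "", raw$flag)
  out
}

#' Generate a decoy-flagged crosslink set with exact class counts
#'
#' Emits records realizing exactly the requested target-target,
#' target-decoy and decoy-decoy counts, deterministically shuffled by
#' `seed`, for exercising the FDR arithmetic.
#'
#' @param TT,TD,DD non-negative class counts.
#' @param seed RNG seed for the shuffle.
#' @return A [crosslink_records] table of `TT + TD + DD` rows.
#' @export
gen_decoy_set <- function(TT, TD, DD, seed = 1) {
  stopifnot(TT >= 0, TD >= 0, DD >= 0)
  n <- TT + TD + DD
  if (n == 0L) {
    return(crosslink_records(data.frame(
      protein1 = character(), peptide1 = character(),
      peptide1_start = integer(), site1 = integer(),
      protein2 = character(), peptide2 = character(),
      peptide2_start = integer(), site2 = integer(),
      score = numeric(), decoy1 = logical(), decoy2 = logical())))
  }
  d1 <- c(rep(FALSE, TT), rep(TRUE, TD), rep(TRUE, DD))
  d2 <- c(rep(FALSE, TT), rep(FALSE, TD), rep(TRUE, DD))
  .with_seed(seed, {
    ord <- sample.int(n)
    df <- data.frame(
      protein1 = sprintf("SU%02d", (seq_len(n) %% 8) + 1L),
      peptide1 = "AKAAAAR", peptide1_start = seq_len(n) * 10L,
      site1 = seq_len(n) * 10L + 1L,
      protein2 = sprintf("SU%02d", ((seq_len(n) + 3L) %% 8) + 1L),
      peptide2 = "LKAAVR", peptide2_start = seq_len(n) * 10L + 100L,
      site2 = seq_len(n) * 10L + 101L,
      score = round(stats::runif(n, 10, 45), 1),
      decoy1 = d1, decoy2 = d2,
      stringsAsFactors = FALSE)
    crosslink_records(df[ord, , drop = FALSE])
  })
}
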
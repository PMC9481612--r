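# Structure coordinates: load PDB/mmCIF, resolve (subunit, residue) to
# C-alpha positions through a subunit-to-chain mapping, tolerant of
# unmodeled (disordered) residues and multi-copy chains.

#' Read structure coordinates from PDB or mmCIF
#'
#' The format is auto-detected from content (an `_atom_site.` loop marks
#' mmCIF). Only the first model is kept. Alternate locations are resolved
#' to the highest-occupancy conformer, ties to the first. Residues are
#' identified by chain, author residue number and insertion code.
#'
#' @param path path to a PDB or mmCIF file.
#' @return Object of class `model_coordinates`: `atoms` (data frame with
#'   `chain`, `resno`, `insert`, `elety`, `x`, `y`, `z`, `occ`), `modeled`
#'   (per-chain sorted vector of modeled residue numbers) and `model_id`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  head_lines <- readLines(path, n = 200L, warn = FALSE)
  is_cif <- any(grepl("^\\s*_atom_site\\.", head_lines))
  atoms <- if (is_cif) .read_cif_atoms(path) else .read_pdb_atoms(path)
  if (nrow(atoms) == 0L)
    stop("read_structure: format error, no atoms parsed from ", path)
  atoms <- .resolve_altloc(atoms)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("read_structure: non-finite coordinates in ", path)
  modeled <- lapply(split(atoms$resno, atoms$chain),
                    function(r) sort(unique(r)))
  structure(list(atoms = atoms, modeled = modeled,
                 model_id = basename(path)),
            class = "model_coordinates")
}

.read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("read_structure: format error: ",
                             conditionMessage(e)))
  a <- pdb$atom
  data.frame(chain = as.character(a$chain),
             resno = as.integer(a$resno),
             insert = ifelse(is.na(a$insert), "", as.character(a$insert)),
             elety = as.character(a$elety),
             alt = ifelse(is.na(a$alt), "", as.character(a$alt)),
             x = a$x, y = a$y, z = a$z,
             occ = ifelse(is.na(a$o), 1, a$o),
             stringsAsFactors = FALSE)
}

# Minimal header-driven parser for the mmCIF _atom_site loop.  Field order
# is taken from the _atom_site.* tags, so files with any column ordering
# parse correctly; author chain/residue numbering is preferred.
.read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^\\s*_atom_site\\.", lines)
  if (length(tag_idx) == 0L)
    stop("read_structure: format error, no _atom_site loop in ", path)
  tags <- sub("^\\s*_atom_site\\.", "", trimws(lines[tag_idx]))
  first_row <- max(tag_idx) + 1L
  rows <- list()
  for (i in first_row:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(#|loop_|data_|_)", ln)) {
      if (length(rows) > 0L) break else next
    }
    toks <- scan(text = ln, what = character(), quiet = TRUE)
    if (length(toks) != length(tags))
      stop(sprintf("read_structure: mmCIF parse error at line %d: %d fields, expected %d",
                   i, length(toks), length(tags)))
    rows[[length(rows) + 1L]] <- toks
  }
  if (length(rows) == 0L)
    stop("read_structure: format error, empty _atom_site loop in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  get <- function(nm, alt = NULL) {
    if (nm %in% tags) m[, nm] else if (!is.null(alt) && alt %in% tags)
      m[, alt] else rep(NA_character_, nrow(m))
  }
  model_num <- get("pdbx_PDB_model_num")
  keep <- if (all(is.na(model_num))) rep(TRUE, nrow(m)) else
    model_num == model_num[1L]
  grp <- get("group_PDB")
  if (!all(is.na(grp))) keep <- keep & grp %in% c("ATOM", "HETATM")
  m <- m[keep, , drop = FALSE]
  blank <- function(v) ifelse(v %in% c(".", "?") | is.na(v), "", v)
  data.frame(
    chain = blank(m[, if ("auth_asym_id" %in% tags) "auth_asym_id" else
      "label_asym_id"]),
    resno = as.integer(m[, if ("auth_seq_id" %in% tags) "auth_seq_id" else
      "label_seq_id"]),
    insert = blank(if ("pdbx_PDB_ins_code" %in% tags)
      m[, "pdbx_PDB_ins_code"] else NA_character_),
    elety = m[, if ("auth_atom_id" %in% tags) "auth_atom_id" else
      "label_atom_id"],
    alt = blank(if ("label_alt_id" %in% tags) m[, "label_alt_id"] else
      NA_character_),
    x = as.numeric(m[, "Cartn_x"]),
    y = as.numeric(m[, "Cartn_y"]),
    z = as.numeric(m[, "Cartn_z"]),
    occ = if ("occupancy" %in% tags)
      ifelse(m[, "occupancy"] %in% c(".", "?"), 1,
             as.numeric(m[, "occupancy"])) else 1,
    stringsAsFactors = FALSE)
}

# Keep one conformer per (chain, resno, insert, elety): highest occupancy,
# ties to the first listed.
.resolve_altloc <- function(atoms) {
  if (all(atoms$alt == "")) { atoms$alt <- NULL; return(atoms) }
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  keep <- vapply(split(seq_len(nrow(atoms)), key)[unique(key)],
                 function(rows) rows[which.max(atoms$occ[rows])],
                 integer(1))
  out <- atoms[sort(keep), , drop = FALSE]
  out$alt <- NULL
  rownames(out) <- NULL
  out
}

#' Construct a subunit-to-chain mapping
#'
#' @param mapping named list, subunit name to character vector of chain
#'   ids. A chain may belong to at most one subunit.
#' @return Object of class `chain_map`.
#' @export
chain_map <- function(mapping) {
  stopifnot(is.list(mapping), !is.null(names(mapping)))
  chains <- unlist(mapping, use.names = FALSE)
  if (anyDuplicated(chains))
    stop("chain_map: chain id(s) mapped to two subunits: ",
         paste(unique(chains[duplicated(chains)]), collapse = ", "))
  structure(lapply(mapping, as.character), class = "chain_map")
}

#' Read a chain map from a config file
#'
#' One line per subunit: `subunit = chain[,chain...]` (or
#' whitespace-separated chains). Lines starting with `#` are comments.
#'
#' @param path path to the mapping file.
#' @return A [chain_map].
#' @export
read_chain_map <- function(path) {
  if (!file.exists(path)) stop("read_chain_map: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !grepl("^\\s*#", lines)]
  mapping <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("read_chain_map: expected 'subunit = chains' at row %d", i))
    su <- trimws(parts[1L])
    ch <- strsplit(trimws(parts[2L]), "\\s*,\\s*|\\s+")[[1L]]
    mapping[[su]] <- ch
  }
  chain_map(mapping)
}

#' Look up C-alpha positions for a residue of a subunit
#'
#' Returns the C-alpha position of `resid` in every chain the subunit maps
#' to where that residue is modeled; an empty result signals "not
#' resolved" (e.g. a disordered region absent from the map).
#'
#' @param model a `model_coordinates` object.
#' @param cmap a [chain_map].
#' @param subunit subunit name present in `cmap`.
#' @param resid author residue number.
#' @return Numeric matrix with 3 columns (x, y, z), one row per mapped
#'   chain copy in which the residue has a C-alpha; zero rows if none.
#' @export
get_ca <- function(model, cmap, subunit, resid) {
  stopifnot(inherits(model, "model_coordinates"), inherits(cmap, "chain_map"))
  if (!subunit %in% names(cmap))
    stop("get_ca: unknown subunit '", subunit, "' in chain map")
  a <- model$atoms
  sel <- a$chain %in% cmap[[subunit]] & a$resno == resid & a$elety == "CA"
  out <- as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
  rownames(out) <- a$chain[sel]
  out
}
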
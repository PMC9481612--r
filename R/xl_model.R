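# Crosslink identification data model.
#
# A crosslink record is one crosslinked peptide pair from a search engine:
# subunit names, peptides, the 1-based start of each peptide in its
# protein, the 1-based residue index of each crosslinked amino acid, the
# search score, an optional q-value, and target/decoy flags for both
# sides.  Records live in an ordinary data frame (class
# "crosslink_records") so standard subsetting applies.

.XL_COLS <- c("protein1", "peptide1", "peptide1_start", "site1",
              "protein2", "peptide2", "peptide2_start", "site2",
              "score", "q_value", "decoy1", "decoy2", "crosslinker")

#' Construct a crosslink record table
#'
#' @param df data frame with columns `protein1`, `peptide1`,
#'   `peptide1_start`, `site1`, `protein2`, `peptide2`, `peptide2_start`,
#'   `site2`, `score`; optional `q_value`, `decoy1`, `decoy2`,
#'   `crosslinker` (defaulting to `NA`, `FALSE`, `FALSE`, `"DSSO"`).
#' @return The validated data frame with class `crosslink_records`.
#' @export
crosslink_records <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"q_value" %in% names(df)) df$q_value <- rep(NA_real_, nrow(df))
  if (!"decoy1" %in% names(df)) df$decoy1 <- rep(FALSE, nrow(df))
  if (!"decoy2" %in% names(df)) df$decoy2 <- rep(FALSE, nrow(df))
  if (!"crosslinker" %in% names(df)) df$crosslinker <- rep("DSSO", nrow(df))
  miss <- setdiff(.XL_COLS, names(df))
  if (length(miss) > 0L)
    stop("crosslink_records: missing column(s): ", paste(miss, collapse = ", "))
  for (side in 1:2) {
    st <- df[[paste0("peptide", side, "_start")]]
    si <- df[[paste0("site", side)]]
    pep <- df[[paste0("peptide", side)]]
    bad <- which(si < st | si >= st + nchar(pep))
    if (length(bad) > 0L)
      stop(sprintf(
        "crosslink_records: site%d outside its peptide at row(s) %s",
        side, paste(bad, collapse = ", ")))
  }
  ok_q <- is.na(df$q_value) | (df$q_value >= 0 & df$q_value <= 1)
  if (!all(ok_q))
    stop("crosslink_records: q_value outside [0, 1] at row(s) ",
         paste(which(!ok_q), collapse = ", "))
  class(df) <- c("crosslink_records", "data.frame")
  df
}

#' Map a marked peptide position to a protein residue number
#'
#' Given the 1-based start of the peptide in the protein sequence and the
#' 1-based position of the crosslinked amino acid within the peptide,
#' returns `peptide_start + marked_pos - 1`. When the protein sequence is
#' supplied the peptide is verified against it and a mismatch is reported
#' with the offset of the first disagreement.
#'
#' @param peptide amino-acid string.
#' @param peptide_start 1-based residue index of the peptide's first
#'   residue in the protein.
#' @param marked_pos 1-based position of the crosslinked residue within
#'   the peptide.
#' @param seq optional full protein sequence for verification.
#' @return Integer residue index in the protein.
#' @export
map_peptide_site <- function(peptide, peptide_start, marked_pos, seq = NULL) {
  peptide_start <- as.integer(peptide_start)
  marked_pos <- as.integer(marked_pos)
  if (marked_pos < 1L || marked_pos > nchar(peptide))
    stop("map_peptide_site: marked_pos outside the peptide")
  if (!is.null(seq)) {
    frag <- substr(seq, peptide_start, peptide_start + nchar(peptide) - 1L)
    if (!identical(frag, peptide)) {
      pc <- strsplit(peptide, "")[[1L]]
      fc <- strsplit(frag, "")[[1L]]
      n <- min(length(pc), length(fc))
      off <- if (n == 0L) 1L else {
        d <- which(pc[seq_len(n)] != fc[seq_len(n)])
        if (length(d) > 0L) d[1L] else n + 1L
      }
      stop(sprintf(
        "map_peptide_site: peptide does not match sequence at start %d (first disagreement at peptide offset %d)",
        peptide_start, off))
    }
  }
  peptide_start + marked_pos - 1L
}

#' Classify crosslinks as inter- or intrasubunit
#'
#' A crosslink is intersubunit iff its two proteins differ; the
#' classification is symmetric in the two sides and total.
#'
#' @param records a [crosslink_records] table.
#' @return Character vector, `"intersubunit"` or `"intrasubunit"` per row.
#' @export
classify_pair_type <- function(records) {
  ifelse(records$protein1 != records$protein2,
         "intersubunit", "intrasubunit")
}

# Canonical unordered residue-pair key: (protein, site) of each side,
# lexicographically smaller side first.
.pair_key <- function(records) {
  a <- paste0(records$protein1, ":", records$site1)
  b <- paste0(records$protein2, ":", records$site2)
  swap <- b < a
  k1 <- ifelse(swap, b, a)
  k2 <- ifelse(swap, a, b)
  paste0(k1, "|", k2)
}

#' Deduplicate crosslink records by residue pair
#'
#' Records are redundant when they link the same unordered residue-level
#' pair `(protein, site)`; the highest-scoring record is kept (ties broken
#' by first appearance), in order of first appearance. Idempotent.
#'
#' @param records a [crosslink_records] table.
#' @return The deduplicated [crosslink_records] table.
#' @export
dedupe_crosslinks <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- .pair_key(records)
  ukeys <- key[!duplicated(key)]              # order of first appearance
  keep <- vapply(ukeys, function(k) {
    rows <- which(key == k)
    rows[which.max(records$score[rows])]      # which.max: first max wins ties
  }, integer(1))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a crosslink table from delimited text
#'
#' Accepts search-engine style CSV/TSV output. `column_map` names the file
#' columns holding each record field; unnamed optional fields default as in
#' [crosslink_records]. Site columns may be given directly
#' (`site1`/`site2`) or as marked positions within the peptides
#' (`marked_pos1`/`marked_pos2`), from which sites are computed via
#' [map_peptide_site].
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping record fields to file
#'   column names.
#' @param sep field separator; default `","`, use `"\t"` for TSV.
#' @return A [crosslink_records] table.
#' @export
read_crosslink_table <- function(path,
                                 column_map = c(
                                   protein1 = "protein1", peptide1 = "peptide1",
                                   peptide1_start = "peptide1_start",
                                   marked_pos1 = "marked_pos1",
                                   protein2 = "protein2", peptide2 = "peptide2",
                                   peptide2_start = "peptide2_start",
                                   marked_pos2 = "marked_pos2",
                                   score = "score"),
                                 sep = ",") {
  if (!file.exists(path)) stop("read_crosslink_table: file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", quote = "\"")
  mandatory <- c("protein1", "peptide1", "peptide1_start",
                 "protein2", "peptide2", "peptide2_start", "score")
  need_cols <- column_map[intersect(names(column_map), mandatory)]
  miss <- setdiff(unname(need_cols), names(raw))
  if (length(miss) > 0L)
    stop("read_crosslink_table: schema error, missing column(s): ",
         paste(miss, collapse = ", "))
  pick <- function(field, default = NULL) {
    if (!field %in% names(column_map)) return(default)
    col <- column_map[[field]]
    if (col %in% names(raw)) raw[[col]] else default
  }
  n <- nrow(raw)
  df <- data.frame(
    protein1 = as.character(pick("protein1")),
    peptide1 = as.character(pick("peptide1")),
    peptide1_start = as.integer(pick("peptide1_start")),
    protein2 = as.character(pick("protein2")),
    peptide2 = as.character(pick("peptide2")),
    peptide2_start = as.integer(pick("peptide2_start")),
    score = as.numeric(pick("score")),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    df$site1 <- integer(0); df$site2 <- integer(0)
    return(crosslink_records(df))
  }
  for (side in 1:2) {
    site <- pick(paste0("site", side))
    if (is.null(site)) {
      mp <- pick(paste0("marked_pos", side))
      if (is.null(mp))
        stop(sprintf(
          "read_crosslink_table: need site%d or marked_pos%d in column_map",
          side, side))
      site <- mapply(map_peptide_site,
                     df[[paste0("peptide", side)]],
                     df[[paste0("peptide", side, "_start")]],
                     as.integer(mp))
    }
    df[[paste0("site", side)]] <- as.integer(site)
  }
  qv <- pick("q_value"); if (!is.null(qv)) df$q_value <- as.numeric(qv)
  d1 <- pick("decoy1"); if (!is.null(d1)) df$decoy1 <- .as_flag(d1)
  d2 <- pick("decoy2"); if (!is.null(d2)) df$decoy2 <- .as_flag(d2)
  cl <- pick("crosslinker"); if (!is.null(cl)) df$crosslinker <- as.character(cl)
  out <- tryCatch(crosslink_records(df), error = function(e)
    stop("read_crosslink_table: ", conditionMessage(e)))
  out
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes", "decoy")
}

#' Read subunit sequences from FASTA
#'
#' @param path FASTA file; record names are taken up to the first space.
#' @return Named character vector of uppercase amino-acid sequences.
#' @export
read_subunit_sequences <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           set.attributes = FALSE)
  seqs <- toupper(unlist(fa))
  names(seqs) <- sub("\\s.*$", "", names(fa))
  if (any(nchar(seqs) == 0L))
    stop("read_subunit_sequences: empty sequence in ", path)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(bad))
    stop("read_subunit_sequences: non-standard residues in: ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Check crosslink sites against linker specificity
#'
#' DSSO/DSS are NHS esters reacting primarily with lysine; the relaxed mode
#' additionally admits Ser/Thr/Tyr, and a protein N-terminal amine (site 1)
#' is accepted regardless of side chain. Requires sequences.
#'
#' @param records a [crosslink_records] table.
#' @param sequences named sequences as from [read_subunit_sequences].
#' @param specificity `"relaxed"` (Lys/Ser/Thr/Tyr, the default) or
#'   `"strict"` (Lys only).
#' @return Logical vector, `TRUE` where both sites are admissible.
#' @export
check_site_specificity <- function(records, sequences,
                                   specificity = c("relaxed", "strict")) {
  specificity <- match.arg(specificity)
  allowed <- if (specificity == "strict") "K" else c("K", "S", "T", "Y")
  side_ok <- function(prot, site) {
    mapply(function(p, s) {
      if (!p %in% names(sequences)) return(NA)
      if (s == 1L && specificity == "relaxed") return(TRUE)  # N-terminal amine
      substr(sequences[[p]], s, s) %in% allowed
    }, prot, site, USE.NAMES = FALSE)
  }
  as.logical(side_ok(records$protein1, records$site1) &
             side_ok(records$protein2, records$site2))
}
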
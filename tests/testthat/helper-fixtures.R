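# Shared builders for small in-code fixtures.

# Write a legacy single-table STAR file; `rows` is a data frame whose
# columns become rln tags in order.
write_star_text <- function(rows, path, block = "data_particles") {
  tags <- names(rows)
  lines <- c(block, "", "loop_",
             sprintf("_%s #%d", tags, seq_along(tags)))
  if (nrow(rows) > 0L) {
    cols <- lapply(rows, function(col) format(col, trim = TRUE))
    lines <- c(lines, do.call(paste, c(cols, sep = " ")))
  }
  writeLines(lines, path)
  path
}

# Canonical five-column particle table plus class.
star_rows <- function(n = 3, psi = c(0, 90, -45), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    rlnCoordinateX = seq(1000, by = 10, length.out = n),
    rlnCoordinateY = seq(2000, by = 10, length.out = n),
    rlnOriginX = rep_len(c(0, 5, -3), n),
    rlnOriginY = rep_len(c(0, -2, 7), n),
    rlnAnglePsi = rep_len(psi, n),
    rlnClassNumber = rep_len(1:2, n))
}

# A crosslink_records table from terse per-row vectors.
xl_rows <- function(protein1, site1, protein2, site2, score = 10,
                    q_value = NA_real_, decoy1 = FALSE, decoy2 = FALSE) {
  n <- length(protein1)
  # peptide is a 5-mer starting 2 before the site so the site is inside
  start1 <- rep_len(as.integer(site1), n) - 2L
  start2 <- rep_len(as.integer(site2), n) - 2L
  crosslink_records(data.frame(
    protein1 = rep_len(protein1, n), peptide1 = rep_len("AAKAA", n),
    peptide1_start = start1, site1 = rep_len(as.integer(site1), n),
    protein2 = rep_len(protein2, n), peptide2 = rep_len("AAKAA", n),
    peptide2_start = start2, site2 = rep_len(as.integer(site2), n),
    score = rep_len(score, n), q_value = rep_len(q_value, n),
    decoy1 = rep_len(decoy1, n), decoy2 = rep_len(decoy2, n),
    stringsAsFactors = FALSE))
}

# Chain map used with the published crosslink table in export tests.
haus_chain_map <- function() {
  chain_map(list(HAUS1 = "A", HAUS2 = "B", HAUS3 = "C", HAUS4 = "D",
                 HAUS5 = "E", HAUS6 = "F", HAUS7 = "G", HAUS8 = "H"))
}
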
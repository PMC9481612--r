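# Reporting and exporters: pseudobond scripts for molecular viewers,
# xVis-style network CSV, and the JSON validation report behind the
# command-line `validate` entry point.

# First mapped chain of a subunit, for writing viewer selections.
.first_chain <- function(cmap, subunit) {
  if (!subunit %in% names(cmap))
    stop("export_pseudobonds: subunit '", subunit, "' not in chain map")
  cmap[[subunit]][1L]
}

#' Export crosslinks as a viewer pseudobond script
#'
#' One distance/pseudobond directive per resolved crosslink, colored black
#' when satisfied and light gray when violated (the usual drawing
#' convention for crosslinks on a model); unresolved crosslinks are
#' emitted as comment lines.
#'
#' @param assessments a `crosslink_assessment` table.
#' @param cmap a [chain_map]; the first mapped chain of each subunit is
#'   used in selections.
#' @param dialect `"pml"` (PyMOL distance commands) or `"chimerax_pb"`
#'   (ChimeraX pseudobond file).
#' @return Character vector of script lines.
#' @export
export_pseudobonds <- function(assessments, cmap,
                               dialect = c("pml", "chimerax_pb")) {
  dialect <- match.arg(dialect)
  header <- sprintf("%s crosslink pseudobonds: black = satisfied, light gray = violated",
                    if (dialect == "pml") "#" else ";")
  lines <- header
  if (dialect == "chimerax_pb")
    lines <- c(lines, "; halfbond = false")
  for (i in seq_len(nrow(assessments))) {
    a <- assessments[i, ]
    if (a$status == "unresolved") {
      cm <- if (dialect == "pml") "#" else ";"
      lines <- c(lines, sprintf(
        "%s unresolved: %s %d x %s %d (residue missing from model)",
        cm, a$protein1, a$site1, a$protein2, a$site2))
      next
    }
    ch1 <- .first_chain(cmap, a$protein1)
    ch2 <- .first_chain(cmap, a$protein2)
    if (dialect == "pml") {
      name <- sprintf("xl_%s%d_%s%d", a$protein1, a$site1,
                      a$protein2, a$site2)
      col <- if (a$status == "satisfied") "black" else "grey80"
      lines <- c(lines,
                 sprintf("distance %s, chain %s and resi %d and name CA, chain %s and resi %d and name CA",
                         name, ch1, a$site1, ch2, a$site2),
                 sprintf("color %s, %s", col, name))
    } else {
      col <- if (a$status == "satisfied") "black" else "light gray"
      lines <- c(lines, sprintf("/%s:%d@CA /%s:%d@CA %s",
                                ch1, a$site1, ch2, a$site2, col))
    }
  }
  lines
}

#' Export crosslinks as an xVis-compatible network CSV
#'
#' Columns `Protein1, AbsPos1, Protein2, AbsPos2, score`, one row per
#' record (intrasubunit records appear with `Protein1 == Protein2`).
#'
#' @param records a [crosslink_records] or `crosslink_assessment` table.
#' @return Character vector of CSV lines.
#' @export
export_network_csv <- function(records) {
  c("Protein1,AbsPos1,Protein2,AbsPos2,score",
    sprintf("%s,%d,%s,%d,%g", records$protein1, records$site1,
            records$protein2, records$site2, records$score))
}

#' Build a validation report
#'
#' Collects per-record assessments, status and threshold counts, the
#' per-subunit-pair network table and an optional FDR summary into one
#' list ready for JSON serialization.
#'
#' @param assessments a `crosslink_assessment` table.
#' @param fdr_summary optional `fdr_estimate` (see [compute_fdr]).
#' @param config the [validation_config] used.
#' @return List of class `validation_report`.
#' @export
validation_report <- function(assessments,
                              fdr_summary = NULL,
                              config = attr(assessments, "config")) {
  if (is.null(config)) config <- validation_config()
  stats <- assessment_stats(assessments, config)
  stopifnot(stats$n == stats$n_satisfied + stats$n_violated +
              stats$n_unresolved)
  rep <- list(
    tool = "cryolink",
    version = as.character(utils::packageVersion("cryolink")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    counts = stats,
    pairs = summarize_pairs(assessments),
    assessments = data.frame(
      protein1 = assessments$protein1, site1 = assessments$site1,
      protein2 = assessments$protein2, site2 = assessments$site2,
      score = assessments$score, distance = assessments$distance,
      status = assessments$status, stringsAsFactors = FALSE))
  if (!is.null(fdr_summary))
    rep$fdr <- list(fdr = fdr_summary$fdr, raw = fdr_summary$raw,
                    counts = fdr_summary$counts)
  class(rep) <- "validation_report"
  rep
}

#' Write a validation report as JSON
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the crosslink validation pipeline with file arguments
#'
#' The programmatic equivalent of the `validate` command-line subcommand:
#' loads crosslinks (either the packaged published table via
#' `table1_fixture = TRUE`, or a crosslink CSV plus a structure and chain
#' map), deduplicates, optionally q-value filters, assesses, and writes
#' `report.json`, `assessments.csv`, `network.csv` and optionally a
#' pseudobond script into `out_dir`.
#'
#' @param table1_fixture use the packaged published crosslink table in
#'   distance-supplied mode.
#' @param xl_table path to a crosslink CSV (see [read_crosslink_table]).
#' @param column_map column map for `xl_table`.
#' @param structure_file path to a PDB/mmCIF model.
#' @param chain_map_file path to a chain-map config.
#' @param out_dir output directory (created if needed).
#' @param q_max optional q-value cutoff applied before assessment.
#' @param config a [validation_config].
#' @param pseudobond_dialect `NULL`, `"pml"` or `"chimerax_pb"`.
#' @return Exit code, invisibly: 0 success, 1 I/O error, 2
#'   validation-content error. Errors are reported as messages.
#' @export
run_validate <- function(table1_fixture = FALSE, xl_table = NULL,
                         column_map = NULL, structure_file = NULL,
                         chain_map_file = NULL, out_dir = ".",
                         q_max = NULL, config = validation_config(),
                         pseudobond_dialect = NULL) {
  fail <- function(code, msg) {
    message("validate: ", msg)
    return(invisible(code))
  }
  # ---- load inputs -------------------------------------------------------
  cmap <- NULL
  if (table1_fixture) {
    tab <- table1_fixture()
    records <- tab
    distances <- tab$distance
    model <- NULL
  } else {
    if (is.null(xl_table) || is.null(structure_file) ||
        is.null(chain_map_file))
      return(fail(1, "need --table1-fixture or --xl + --structure + --chains"))
    for (f in c(xl_table, structure_file, chain_map_file))
      if (!file.exists(f)) return(fail(1, paste0("file not found: ", f)))
    records <- tryCatch(
      if (is.null(column_map)) read_crosslink_table(xl_table) else
        read_crosslink_table(xl_table, column_map = column_map),
      error = function(e) e)
    if (inherits(records, "error"))
      return(fail(2, conditionMessage(records)))
    model <- tryCatch(read_structure(structure_file), error = function(e) e)
    if (inherits(model, "error"))
      return(fail(2, conditionMessage(model)))
    cmap <- tryCatch(read_chain_map(chain_map_file), error = function(e) e)
    if (inherits(cmap, "error"))
      return(fail(2, conditionMessage(cmap)))
    distances <- NULL
  }
  # ---- pipeline ----------------------------------------------------------
  res <- tryCatch({
    n_before <- nrow(records)
    if (is.null(distances)) {
      records <- dedupe_crosslinks(records)
      if (!is.null(q_max)) records <- filter_by_q(records, q_max)
      assessments <- assess_crosslinks(records, model = model, cmap = cmap,
                                       config = config)
    } else {
      assessments <- assess_crosslinks(records, distances = distances,
                                       config = config)
    }
    fdr_summary <- if (!any(is.na(records$decoy1)) &&
                       any(records$decoy1 | records$decoy2)) {
      compute_fdr(count_decoy_classes(records))
    } else NULL
    report <- validation_report(assessments, fdr_summary, config)
    list(assessments = assessments, report = report)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail(2, conditionMessage(res)))
  # ---- outputs -----------------------------------------------------------
  out <- tryCatch({
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_validation_report(res$report, file.path(out_dir, "report.json"))
    utils::write.csv(res$report$assessments,
                     file.path(out_dir, "assessments.csv"),
                     row.names = FALSE)
    writeLines(export_network_csv(res$assessments),
               file.path(out_dir, "network.csv"))
    if (!is.null(pseudobond_dialect) && !is.null(cmap)) {
      ext <- if (pseudobond_dialect == "pml") "pml" else "pb"
      writeLines(export_pseudobonds(res$assessments, cmap,
                                    pseudobond_dialect),
                 file.path(out_dir, paste0("pseudobonds.", ext)))
    }
    TRUE
  }, error = function(e) e)
  if (inherits(out, "error")) return(fail(1, conditionMessage(out)))
  invisible(0L)
}
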
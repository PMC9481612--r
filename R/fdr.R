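# Target-decoy FDR arithmetic for crosslinked peptide pairs.
#
# Search engines match spectra against target and reversed/shuffled decoy
# sequences; a crosslinked pair can hit target-target (TT), target-decoy
# (TD) or decoy-decoy (DD).  The pair-level false discovery rate is
# estimated as FDR = (TD - DD) / TT: single-decoy hits estimate false
# pairs, double-decoy hits correct for doubly random matches.

#' Count target/decoy classes of a crosslink list
#'
#' @param records a [crosslink_records] table with `decoy1`/`decoy2` flags.
#' @return List of class `decoy_counts` with fields `TT` (both targets),
#'   `TD` (exactly one decoy), `DD` (both decoys).
#' @export
count_decoy_classes <- function(records) {
  d1 <- records$decoy1; d2 <- records$decoy2
  if (anyNA(d1) || anyNA(d2))
    stop("count_decoy_classes: decoy flags must be present on every record")
  n_decoy <- as.integer(d1) + as.integer(d2)
  out <- list(TT = sum(n_decoy == 0L), TD = sum(n_decoy == 1L),
              DD = sum(n_decoy == 2L))
  stopifnot(out$TT + out$TD + out$DD == nrow(records))
  structure(out, class = "decoy_counts")
}

#' Estimate the crosslink FDR from decoy counts
#'
#' Computes `(TD - DD) / TT`. A negative raw estimate (more double- than
#' single-decoy hits) is clamped to 0 in the reported `fdr`; the raw value
#' is kept for diagnostics.
#'
#' @param counts a `decoy_counts` object or list with `TT`, `TD`, `DD`.
#' @return List of class `fdr_estimate` with `fdr` (clamped), `raw`, and
#'   the input `counts`.
#' @export
compute_fdr <- function(counts) {
  TT <- counts$TT; TD <- counts$TD; DD <- counts$DD
  stopifnot(TT >= 0, TD >= 0, DD >= 0)
  if (TT == 0)
    stop("compute_fdr: undefined FDR, no target-target pairs (TT = 0)")
  raw <- (TD - DD) / TT
  structure(list(fdr = max(0, raw), raw = raw,
                 counts = list(TT = TT, TD = TD, DD = DD)),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("FDR = (TD - DD)/TT = (%d - %d)/%d = %.4g%s\n",
              x$counts$TD, x$counts$DD, x$counts$TT, x$fdr,
              if (x$raw < 0) sprintf(" (raw %.4g clamped to 0)", x$raw) else ""))
  invisible(x)
}

#' Filter crosslinks at a q-value cutoff
#'
#' Retains records with `q_value` strictly below `q_max` (the cutoff is
#' read as "below", so a record at exactly `q_max` is removed). Records
#' lacking a q-value cannot be judged: they are rejected and counted.
#'
#' @param records a [crosslink_records] table.
#' @param q_max cutoff in `(0, 1]`; default 0.01 (1\% FDR).
#' @return The filtered table, with attributes `n_rejected_no_q` (records
#'   lacking q-values) and `n_removed` (records at or above the cutoff);
#'   input order preserved.
#' @export
filter_by_q <- function(records, q_max = 0.01) {
  if (!is.numeric(q_max) || length(q_max) != 1L || q_max <= 0 || q_max > 1)
    stop("filter_by_q: q_max must lie in (0, 1]")
  no_q <- is.na(records$q_value)
  if (any(no_q))
    warning(sprintf("filter_by_q: %d record(s) lack a q-value; rejected",
                    sum(no_q)))
  keep <- !no_q & records$q_value < q_max
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected_no_q") <- sum(no_q)
  attr(out, "n_removed") <- sum(!keep) - sum(no_q)
  out
}
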
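#' Write a consensus sequence to FASTA
#'
#' Emits a single record, 60 columns per line, with `N` at every
#' non-informative position.
#'
#' @param result A `"consensus_result"`.
#' @param path Output FASTA path.
#' @param name Record name; defaults to
#'   `"<ref_name>_consensus_<mode>"`.
#' @return Invisibly, `path`.
#' @export
write_consensus <- function(result, path, name = NULL) {
  stopifnot(inherits(result, "consensus_result"))
  if (is.null(name)) {
    name <- paste0(result$ref_name, "_consensus_", result$summary$mode)
  }
  x <- Biostrings::DNAStringSet(result$sequence)
  names(x) <- name
  tryCatch(
    Biostrings::writeXStringSet(x, path, width = 60L),
    error = function(e) stop("failed to write consensus FASTA to ", path,
                             ": ", conditionMessage(e))
  )
  invisible(path)
}

# Fixed call-log header; documented in the function below.
CALL_LOG_COLUMNS <- c(
  "pos", "ref", "raw_A", "raw_C", "raw_G", "raw_T",
  "eff_A", "eff_C", "eff_G", "eff_T",
  "coverage", "eff_coverage", "support", "flag", "n_silenced",
  "call", "mode"
)

#' Write the per-base call log to TSV
#'
#' One row per reference position, with 1-based positions for human
#' consumption (every programmatic interface in the package is
#' 0-based). Columns: `pos`, `ref`, per-base raw counts (`raw_A` ..
#' `raw_T`), per-base effective counts after silencing or weighting
#' (`eff_A` .. `eff_T`), `coverage` (raw), `eff_coverage`, `support`,
#' `flag` (`CT`, `GA`, `CT+GA` or `.`), `n_silenced`, `call`, `mode`.
#'
#' @param result A `"consensus_result"`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_call_log <- function(result, path) {
  stopifnot(inherits(result, "consensus_result"))
  cl <- result$calls
  flag <- ifelse(cl$flag_ct & cl$flag_ga, "CT+GA",
          ifelse(cl$flag_ct, "CT", ifelse(cl$flag_ga, "GA", ".")))
  df <- data.frame(
    pos = cl$ref_pos + 1L, ref = cl$ref_base,
    raw_A = cl$raw_A, raw_C = cl$raw_C, raw_G = cl$raw_G, raw_T = cl$raw_T,
    eff_A = round(cl$eff_A, 4), eff_C = round(cl$eff_C, 4),
    eff_G = round(cl$eff_G, 4), eff_T = round(cl$eff_T, 4),
    coverage = cl$raw_cov, eff_coverage = round(cl$eff_cov, 4),
    support = round(cl$support, 4), flag = flag,
    n_silenced = cl$n_silenced, call = cl$call,
    mode = result$summary$mode,
    stringsAsFactors = FALSE
  )
  names(df) <- CALL_LOG_COLUMNS
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "."),
    error = function(e) stop("failed to write call log to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Write the consensus summary to JSON
#'
#' Records the per-sample totals that characterize a reconstruction:
#' mode, N count and percentage, number of flagged (putatively damaged)
#' positions, and how many of those were called N.
#'
#' @param result A `"consensus_result"`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_summary_json <- function(result, path) {
  stopifnot(inherits(result, "consensus_result"))
  s <- result$summary
  jsonlite::write_json(
    list(mode = s$mode, reference = result$ref_name,
         length = result$ref_len, n_N = s$n_N, pct_N = s$pct_N,
         n_damaged_positions = s$n_damaged_positions,
         n_N_at_damaged = s$n_N_at_damaged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
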
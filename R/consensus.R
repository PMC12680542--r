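#' Consensus-calling parameters
#'
#' Bundles the calling mode with its thresholds. A confident base call
#' requires coverage of at least `min_cov` and at least `min_support`
#' agreement for the most frequent base; positions failing either
#' threshold become the non-informative base `N`. Both thresholds are
#' inclusive, so a 2-of-3 column (66.7%) is callable at the defaults.
#'
#' Modes:
#' \describe{
#'   \item{`none`}{plain coverage/frequency calling, no damage handling.}
#'   \item{`pol_silence`}{polarization-based silencing: where the
#'     reference has a C, forward-read Ts are treated as N (reverse-read
#'     As where the reference has a G).}
#'   \item{`free_silence`}{polarization-free silencing: a position is
#'     flagged from the read stack alone — at least one forward T plus a
#'     C in any read (and the G/A mirror) — and the putatively damaged
#'     bases are silenced there.}
#'   \item{`free_weight`}{polarization-free weighting: every base keeps
#'     a vote, but damage-prone bases are down-weighted by `1 - d` and
#'     their undamaged counterparts up-weighted by `1 + d` using the
#'     sample's estimated damage profile.}
#' }
#'
#' @param mode One of `"none"`, `"pol_silence"`, `"free_silence"`,
#'   `"free_weight"`.
#' @param min_cov Minimum coverage (default 3).
#' @param min_support Minimum support fraction for the most frequent
#'   base, in (0.5, 1\] (default 0.65).
#' @param cov_basis For the silencing modes: whether the coverage gate
#'   applies to the post-silencing (`"effective"`, default) or raw
#'   (`"raw"`) entry count. Silenced bases are replaced by N, so by
#'   default they no longer count as evidence of coverage.
#' @param weight_cov For `free_weight`: gate coverage on the unweighted
#'   entry count (`"raw"`, default — weights express base-identity
#'   confidence, not molecule existence) or on total weight
#'   (`"weighted"`).
#' @return An object of class `"calling_params"`.
#' @export
calling_params <- function(mode = c("none", "pol_silence", "free_silence",
                                    "free_weight"),
                           min_cov = 3L, min_support = 0.65,
                           cov_basis = c("effective", "raw"),
                           weight_cov = c("raw", "weighted")) {
  mode <- match.arg(mode)
  stopifnot(min_cov >= 1L, min_support > 0.5, min_support <= 1)
  structure(
    list(mode = mode, min_cov = as.integer(min_cov),
         min_support = min_support,
         cov_basis = match.arg(cov_basis),
         weight_cov = match.arg(weight_cov)),
    class = "calling_params"
  )
}

#' Polarization-based damage flagging
#'
#' Flags a position as potentially damaged by comparison with the
#' reference: `flag_ct` where the reference base is C and at least one
#' forward-mapping read shows a T; `flag_ga` where the reference base is
#' G and at least one reverse-mapping read shows an A. No flag is raised
#' when the reference base is not consistent with the damage pattern,
#' which is the method's weakness on evolutionarily distant samples — a
#' true derived T looks exactly like damage.
#'
#' @param pileup A `"pileup"` object.
#' @param ref A `"reference_sequence"` (must match the pileup).
#' @return An object of class `"damage_flags"`: list with logical
#'   vectors `flag_ct`, `flag_ga` of length `ref_len` and
#'   `method = "polarized"`.
#' @export
flag_polarized <- function(pileup, ref) {
  stopifnot(inherits(pileup, "pileup"), inherits(ref, "reference_sequence"),
            pileup$ref_len == ref$length)
  L <- pileup$ref_len
  rb <- ref_bases(ref)
  has_fT <- pos_any(pileup, pileup$fwd & pileup$base == "T", L)
  has_rA <- pos_any(pileup, !pileup$fwd & pileup$base == "A", L)
  structure(
    list(flag_ct = has_fT & rb == "C",
         flag_ga = has_rA & rb == "G",
         method = "polarized"),
    class = "damage_flags"
  )
}

#' Polarization-free damage flagging
#'
#' Flags positions from the read stack alone, without consulting the
#' reference: `flag_ct` where at least one forward-mapping read shows a
#' T *and* a C is observed at the same position in any read (regardless
#' of orientation); `flag_ga` for the mirrored pattern (reverse-read A
#' plus any-orientation G). The read-internal C (or G) witnesses the
#' undamaged allele, so flagging keys on observed variation rather than
#' on reference identity.
#'
#' @param pileup A `"pileup"` object.
#' @return A `"damage_flags"` object with `method = "polarization_free"`.
#' @export
flag_polarization_free <- function(pileup) {
  stopifnot(inherits(pileup, "pileup"))
  L <- pileup$ref_len
  has_fT <- pos_any(pileup, pileup$fwd & pileup$base == "T", L)
  has_C <- pos_any(pileup, pileup$base == "C", L)
  has_rA <- pos_any(pileup, !pileup$fwd & pileup$base == "A", L)
  has_G <- pos_any(pileup, pileup$base == "G", L)
  structure(
    list(flag_ct = has_fT & has_C,
         flag_ga = has_rA & has_G,
         method = "polarization_free"),
    class = "damage_flags"
  )
}

# TRUE at every reference position holding at least one selected entry.
pos_any <- function(pileup, sel, L) {
  out <- logical(L)
  out[unique(pileup$pos[sel]) + 1L] <- TRUE
  out
}

BASES <- c("A", "C", "G", "T")

# Core per-column caller shared by call_column() and reconstruct().
# base/fwd/dist5/dist3 describe the column's entries; flag_ct/flag_ga are
# scalars for this position.
call_core <- function(base, fwd, dist5, dist3, flag_ct, flag_ga,
                      params, profile = NULL) {
  keep <- base != "N"
  base <- base[keep]; fwd <- fwd[keep]
  dist5 <- dist5[keep]; dist3 <- dist3[keep]
  raw_cov <- length(base)
  counts_raw <- c(sum(base == "A"), sum(base == "C"),
                  sum(base == "G"), sum(base == "T"))
  n_silenced <- 0L
  mode <- params$mode

  if (mode %in% c("pol_silence", "free_silence")) {
    sil <- (flag_ct & fwd & base == "T") | (flag_ga & !fwd & base == "A")
    n_silenced <- sum(sil)
    base <- base[!sil]; fwd <- fwd[!sil]
    counts_eff <- c(sum(base == "A"), sum(base == "C"),
                    sum(base == "G"), sum(base == "T"))
    eff_cov <- length(base)
    cov_gate <- if (params$cov_basis == "effective") eff_cov else raw_cov
  } else if (mode == "free_weight") {
    w <- base_weight(base, fwd, dist5, dist3, profile)
    counts_eff <- c(sum(w[base == "A"]), sum(w[base == "C"]),
                    sum(w[base == "G"]), sum(w[base == "T"]))
    eff_cov <- sum(counts_eff)
    cov_gate <- if (params$weight_cov == "raw") raw_cov else eff_cov
  } else {
    counts_eff <- counts_raw
    eff_cov <- raw_cov
    cov_gate <- raw_cov
  }

  tot <- sum(counts_eff)
  if (tot > 0) {
    top <- which.max(counts_eff)
    support <- counts_eff[top] / tot
  } else {
    top <- NA_integer_
    support <- NA_real_
  }
  # inclusive threshold with roundoff slack: weighted tallies can land one
  # ulp under an exact boundary (e.g. 2.47/3.8 vs 0.65) depending on
  # summation order
  call <- if (!is.na(support) && cov_gate >= params$min_cov &&
              support >= params$min_support - 1e-9) BASES[top] else "N"
  list(call = call, raw_cov = raw_cov, eff_cov = eff_cov,
       support = support, n_silenced = n_silenced,
       counts_raw = counts_raw, counts_eff = counts_eff,
       flagged = flag_ct || flag_ga)
}

#' Call the consensus base for one pileup column
#'
#' Applies the thresholding and damage handling selected in `params` to
#' a single position. The silencing modes need the position's damage
#' flags; the weighting mode needs a damage profile.
#'
#' @param column A `"pileup_column"` from [pileup_column()].
#' @param params A `"calling_params"` object.
#' @param flags A `"damage_flags"` object (indexed at the column's
#'   position), or a list with scalar logicals `flag_ct`, `flag_ga`.
#'   Required for the silencing modes; for `free_weight` and `none` the
#'   flags, when given, are only echoed in the result.
#' @param profile A `"damage_profile"`; required for `free_weight`.
#' @return An object of class `"consensus_call"`: list with `ref_pos`,
#'   `call`, `raw_cov`, `eff_cov`, `support` (NA when no informative
#'   base remains), `flagged`, `n_silenced`, and named per-base
#'   `counts_raw` / `counts_eff` vectors.
#' @export
call_column <- function(column, params, flags = NULL, profile = NULL) {
  stopifnot(inherits(column, "pileup_column"),
            inherits(params, "calling_params"))
  fl <- column_flags(flags, column$ref_pos, params$mode)
  if (params$mode == "free_weight" && is.null(profile)) {
    stop("mode 'free_weight' requires a damage profile")
  }
  res <- call_core(column$base, column$fwd, column$dist5, column$dist3,
                   fl$flag_ct, fl$flag_ga, params, profile)
  names(res$counts_raw) <- BASES
  names(res$counts_eff) <- BASES
  structure(c(list(ref_pos = column$ref_pos), res),
            class = "consensus_call")
}

column_flags <- function(flags, ref_pos, mode) {
  if (is.null(flags)) {
    if (mode %in% c("pol_silence", "free_silence")) {
      stop("mode '", mode, "' requires damage flags")
    }
    return(list(flag_ct = FALSE, flag_ga = FALSE))
  }
  ct <- flags$flag_ct; ga <- flags$flag_ga
  if (length(ct) > 1L) ct <- ct[ref_pos + 1L]
  if (length(ga) > 1L) ga <- ga[ref_pos + 1L]
  list(flag_ct = isTRUE(ct), flag_ga = isTRUE(ga))
}

#' Reconstruct a consensus sequence from a pileup
#'
#' Runs damage flagging appropriate to the mode, calls every reference
#' position, and assembles the consensus with per-position audit
#' records. The polarized mode flags against the reference; the
#' polarization-free modes flag from the read stack alone (the
#' reference is still used as the coordinate system and reported in the
#' call log). In mode `none` the polarization-free flags are computed
#' for reporting parity but never alter calls.
#'
#' @param pileup A `"pileup"` object.
#' @param ref The `"reference_sequence"` the pileup was built against.
#' @param params A `"calling_params"` object.
#' @param profile A `"damage_profile"`; required for mode
#'   `"free_weight"`.
#' @return An object of class `"consensus_result"`: list with
#'   `sequence` (character scalar), `calls` (data frame with one row
#'   per reference position: position, reference base, per-base raw and
#'   effective counts, coverage, support, flags, silenced count, final
#'   call), `summary` (list with `n_N`, `pct_N`,
#'   `n_damaged_positions`, `n_N_at_damaged`, `mode`), `params`,
#'   `flags`, and reference metadata.
#' @export
reconstruct <- function(pileup, ref, params, profile = NULL) {
  stopifnot(inherits(pileup, "pileup"), inherits(ref, "reference_sequence"),
            inherits(params, "calling_params"),
            pileup$ref_len == ref$length)
  if (params$mode == "free_weight" && is.null(profile)) {
    stop("mode 'free_weight' requires a damage profile")
  }
  flags <- if (params$mode == "pol_silence") flag_polarized(pileup, ref)
           else flag_polarization_free(pileup)
  L <- pileup$ref_len
  idx <- pileup_split(pileup)

  call <- character(L)
  raw_cov <- integer(L); eff_cov <- numeric(L)
  support <- numeric(L); n_sil <- integer(L)
  craw <- matrix(0, L, 4, dimnames = list(NULL, BASES))
  ceff <- matrix(0, L, 4, dimnames = list(NULL, BASES))
  for (p in seq_len(L)) {
    i <- idx[[p]]
    res <- call_core(pileup$base[i], pileup$fwd[i],
                     pileup$dist5[i], pileup$dist3[i],
                     flags$flag_ct[p], flags$flag_ga[p], params, profile)
    call[p] <- res$call
    raw_cov[p] <- res$raw_cov; eff_cov[p] <- res$eff_cov
    support[p] <- res$support; n_sil[p] <- res$n_silenced
    craw[p, ] <- res$counts_raw; ceff[p, ] <- res$counts_eff
  }

  flagged <- flags$flag_ct | flags$flag_ga
  is_N <- call == "N"
  calls <- data.frame(
    ref_pos = 0:(L - 1L), ref_base = pileup$ref_base,
    raw_A = craw[, 1], raw_C = craw[, 2], raw_G = craw[, 3], raw_T = craw[, 4],
    eff_A = ceff[, 1], eff_C = ceff[, 2], eff_G = ceff[, 3], eff_T = ceff[, 4],
    raw_cov = raw_cov, eff_cov = eff_cov, support = support,
    flag_ct = flags$flag_ct, flag_ga = flags$flag_ga,
    n_silenced = n_sil, call = call,
    stringsAsFactors = FALSE
  )
  structure(
    list(sequence = paste(call, collapse = ""),
         calls = calls,
         summary = list(n_N = sum(is_N), pct_N = 100 * sum(is_N) / L,
                        n_damaged_positions = sum(flagged),
                        n_N_at_damaged = sum(is_N & flagged),
                        mode = params$mode),
         params = params, flags = flags,
         ref_name = ref$name, ref_len = L),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<consensus_result> %s (%d bp), mode '%s'\n",
              x$ref_name, x$ref_len, s$mode))
  cat(sprintf("  non-informative: %d (%.1f%%); flagged damaged positions: %d (%d called N)\n",
              s$n_N, s$pct_N, s$n_damaged_positions, s$n_N_at_damaged))
  invisible(x)
}

#' @export
summary.consensus_result <- function(object, ...) {
  s <- object$summary
  cov <- object$calls$raw_cov
  out <- c(s, list(mean_coverage = mean(cov),
                   pct_covered_3x = 100 * mean(cov >= 3)))
  class(out) <- "summary.consensus_result"
  out
}

#' @export
print.summary.consensus_result <- function(x, ...) {
  cat(sprintf("mode: %s\n", x$mode))
  cat(sprintf("mean coverage: %.2fx (%.1f%% of positions at >=3x)\n",
              x$mean_coverage, x$pct_covered_3x))
  cat(sprintf("N calls: %d (%.2f%%)\n", x$n_N, x$pct_N))
  cat(sprintf("damaged positions: %d, of which called N: %d\n",
              x$n_damaged_positions, x$n_N_at_damaged))
  invisible(x)
}

#' Compare a consensus to the simulated truth
#'
#' Scores the reconstruction against the true genome the simulator
#' generated reads from: called (non-N) positions are classified as
#' correct or miscalled, with miscall positions listed and broken down
#' by damage-flag status.
#'
#' @param result A `"consensus_result"`.
#' @param truth A `"simulation_truth"` from [mutate_reference()] (or any
#'   list with a `true_genome` string of matching length).
#' @return A list with `n_called`, `n_correct`, `n_miscall`, `n_N`,
#'   `miscall_pos` (0-based) and `miscall_at_flagged`.
#' @export
compare_to_truth <- function(result, truth) {
  stopifnot(inherits(result, "consensus_result"))
  tg <- truth$true_genome
  if (nchar(tg) != result$ref_len) {
    stop("truth genome length (", nchar(tg), ") does not match consensus length (",
         result$ref_len, ")")
  }
  tb <- strsplit(tg, "", fixed = TRUE)[[1L]]
  cb <- strsplit(result$sequence, "", fixed = TRUE)[[1L]]
  called <- cb != "N"
  ok <- called & cb == tb
  mis <- called & cb != tb
  flagged <- result$flags$flag_ct | result$flags$flag_ga
  list(n_called = sum(called), n_correct = sum(ok), n_miscall = sum(mis),
       n_N = sum(!called), miscall_pos = which(mis) - 1L,
       miscall_at_flagged = sum(mis & flagged))
}
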
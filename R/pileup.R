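#' Build a circular-aware pileup from aligned reads
#'
#' Stacks every aligned base onto its reference position, recording for
#' each entry the read's orientation and the base's distance from each
#' alignment end. End distances drive damage-profile lookups, because
#' deamination concentrates at fragment termini. On a circular reference
#' a read overhanging the end wraps to the origin; on a linear reference
#' an overhanging read is an error (it signals that upstream mapping was
#' not circular-aware).
#'
#' @param reads An `"aligned_reads"` object from [read_alignments()] or
#'   [simulate_reads()].
#' @param ref A `"reference_sequence"`.
#' @return An object of class `"pileup"`: a list with reference metadata
#'   (`ref_name`, `ref_len`, `circular`, `ref_base` character vector)
#'   and parallel per-entry vectors `pos` (0-based reference position),
#'   `base`, `fwd`, `dist5`, `dist3`, `read_id`. `dist5` is the offset
#'   from the read's left alignment end (reference orientation), `dist3`
#'   from its right end; `dist5 + dist3 == aligned length - 1`.
#' @export
build_pileup <- function(reads, ref) {
  stopifnot(inherits(ref, "reference_sequence"))
  L <- ref$length
  span <- nchar(reads$bases)
  if (nrow(reads) > 0L && !ref$circular &&
      any(reads$ref_start + span > L)) {
    bad <- which(reads$ref_start + span > L)[1L]
    stop("read '", reads$read_id[bad], "' overhangs the end of linear ",
         "reference '", ref$name, "'; was the mapping circular-aware?")
  }
  if (nrow(reads) > 0L && any(reads$ref_start < 0L | reads$ref_start >= L)) {
    stop("read start outside reference [0, ", L, ")")
  }

  irregular <- vapply(reads$qoff, Negate(is.null), logical(1L))
  if (length(irregular) == 0L) irregular <- logical(0)

  pos <- integer(0); base <- character(0); fwd <- logical(0)
  dist5 <- integer(0); dist3 <- integer(0); rid <- character(0)

  reg <- which(!irregular)
  if (length(reg) > 0L) {
    lens <- span[reg]
    off <- sequence(lens) - 1L
    pos <- rep(reads$ref_start[reg], lens) + off
    base <- unlist(strsplit(reads$bases[reg], "", fixed = TRUE),
                   use.names = FALSE)
    fwd <- rep(reads$fwd[reg], lens)
    dist5 <- off
    dist3 <- rep(lens, lens) - 1L - off
    rid <- rep(reads$read_id[reg], lens)
  }
  for (i in which(irregular)) {
    chars <- strsplit(reads$bases[i], "", fixed = TRUE)[[1L]]
    keep <- chars != "-"
    if (!any(keep)) next
    rposs <- reads$ref_start[i] + which(keep) - 1L
    qo <- reads$qoff[[i]][keep]
    pos <- c(pos, rposs)
    base <- c(base, chars[keep])
    fwd <- c(fwd, rep(reads$fwd[i], sum(keep)))
    dist5 <- c(dist5, qo)
    dist3 <- c(dist3, reads$qlen[i] - 1L - qo)
    rid <- c(rid, rep(reads$read_id[i], sum(keep)))
  }
  if (ref$circular) pos <- pos %% L

  structure(
    list(ref_name = ref$name, ref_len = L, circular = ref$circular,
         ref_base = ref_bases(ref),
         pos = as.integer(pos), base = base, fwd = fwd,
         dist5 = as.integer(dist5), dist3 = as.integer(dist3),
         read_id = rid),
    class = "pileup"
  )
}

#' Extract one pileup column
#'
#' @param pileup A `"pileup"` object.
#' @param ref_pos 0-based reference position.
#' @return An object of class `"pileup_column"`: a list with `ref_pos`,
#'   `ref_base` and the per-entry vectors `base`, `fwd`, `dist5`,
#'   `dist3`, `read_id` restricted to that position. Raw coverage is
#'   `length(column$base)`.
#' @export
pileup_column <- function(pileup, ref_pos) {
  stopifnot(inherits(pileup, "pileup"),
            ref_pos >= 0L, ref_pos < pileup$ref_len)
  idx <- which(pileup$pos == ref_pos)
  new_pileup_column(ref_pos, pileup$ref_base[ref_pos + 1L],
                    pileup$base[idx], pileup$fwd[idx],
                    pileup$dist5[idx], pileup$dist3[idx],
                    pileup$read_id[idx])
}

new_pileup_column <- function(ref_pos, ref_base, base, fwd, dist5, dist3,
                              read_id = NULL) {
  structure(
    list(ref_pos = ref_pos, ref_base = ref_base, base = base, fwd = fwd,
         dist5 = dist5, dist3 = dist3,
         read_id = if (is.null(read_id)) rep(NA_character_, length(base))
                   else read_id),
    class = "pileup_column"
  )
}

# Per-position entry indices as a list of length ref_len (0-based order).
pileup_split <- function(pileup) {
  f <- factor(pileup$pos, levels = 0:(pileup$ref_len - 1L))
  split(seq_along(pileup$pos), f)
}

#' Per-position raw coverage of a pileup
#'
#' @param pileup A `"pileup"` object.
#' @return Integer vector of length `ref_len` (position order, 0-based).
#' @export
coverage_vector <- function(pileup) {
  tabulate(pileup$pos + 1L, nbins = pileup$ref_len)
}

#' @export
print.pileup <- function(x, ...) {
  cov <- coverage_vector(x)
  cat(sprintf("<pileup> %s (%d bp, %s): %d entries, mean coverage %.2fx\n",
              x$ref_name, x$ref_len,
              if (x$circular) "circular" else "linear",
              length(x$pos), mean(cov)))
  invisible(x)
}
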
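#' Read aligned reads from a SAM or BAM file
#'
#' Imports mapped records, dropping unmapped, secondary and supplementary
#' alignments, and applies a fragment-length filter. Ancient-DNA pipelines
#' discard very short fragments because they cannot be placed reliably;
#' the default minimum of 30 bp matches common adapter-trimming practice.
#'
#' Bases are reported in reference orientation (as stored in SAM/BAM);
#' a read's `fwd` field is `FALSE` when the reverse-strand flag is set,
#' which is what identifies the molecule's strand in single-stranded
#' libraries. CIGAR strings are projected onto the reference: inserted
#' read bases are dropped, deleted reference positions contribute no
#' base, and soft-clipped bases are excluded from the alignment.
#'
#' @param path Path to a SAM (`.sam`) or BAM file. SAM input is converted
#'   on the fly; no index is required (sequential scan).
#' @param min_len Minimum aligned fragment length in bp (default 30);
#'   shorter reads are discarded.
#' @param min_mapq Optional minimum mapping quality; `NULL` (default)
#'   applies no filter, on the assumption that mapping-quality filtering
#'   happened upstream at alignment time.
#' @param ref_name Optional reference name the records must be aligned
#'   to; a mismatch raises an error naming both the requested and the
#'   observed reference(s).
#' @return An object of class `"aligned_reads"`: a data frame with one
#'   row per read and columns `read_id`, `ref_start` (0-based), `fwd`
#'   (logical), `qlen` (aligned query length), `mapq`, `bases`
#'   (reference-projected bases, `-` marking deleted reference
#'   positions), and a list column `qoff` holding per-base query offsets
#'   for reads with indels or clipping (`NULL` for plain matches).
#' @export
read_alignments <- function(path, min_len = 30L, min_mapq = NULL,
                            ref_name = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$pos)
  if (!is.null(ref_name) && n > 0L) {
    seen <- unique(as.character(x$rname))
    if (!all(seen == ref_name)) {
      stop("alignments reference ", paste(seen, collapse = ", "),
           " but '", ref_name, "' was requested")
    }
  }
  if (n == 0L) return(empty_aligned_reads())

  seqs <- as.character(x$seq)
  cig <- x$cigar
  plain <- grepl("^[0-9]+M$", cig)

  bases <- character(n)
  qoff <- vector("list", n)
  qlen <- integer(n)
  bases[plain] <- seqs[plain]
  qlen[plain] <- nchar(seqs[plain])
  for (i in which(!plain)) {
    pr <- project_cigar(cig[i], seqs[i])
    bases[i] <- pr$bases
    qoff[[i]] <- pr$qoff
    qlen[i] <- pr$qlen
  }

  reads <- data.frame(
    read_id = x$qname,
    ref_start = x$pos - 1L,
    fwd = !bitwAnd(x$flag, 16L),
    qlen = qlen,
    mapq = x$mapq,
    bases = bases,
    stringsAsFactors = FALSE
  )
  reads$qoff <- qoff
  keep <- reads$qlen >= min_len
  if (!is.null(min_mapq)) keep <- keep & !is.na(reads$mapq) & reads$mapq >= min_mapq
  reads <- reads[keep, , drop = FALSE]
  rownames(reads) <- NULL
  class(reads) <- c("aligned_reads", "data.frame")
  reads
}

empty_aligned_reads <- function() {
  reads <- data.frame(read_id = character(), ref_start = integer(),
                      fwd = logical(), qlen = integer(), mapq = integer(),
                      bases = character(), stringsAsFactors = FALSE)
  reads$qoff <- list()
  class(reads) <- c("aligned_reads", "data.frame")
  reads
}

# Project a CIGAR onto the reference: returns the reference-spanning base
# string ("-" at deletions), query offsets of each non-deleted base, and
# the aligned query length (soft clips excluded throughout).
project_cigar <- function(cigar, seq) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  qchars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- character(0)
  offs <- integer(0)
  qpos <- 0L   # position within the full SEQ field
  apos <- 0L   # position within the aligned (non-clipped) query
  for (k in seq_along(ops)) {
    op <- ops[k]; L <- lens[k]
    if (op %in% c("M", "=", "X")) {
      out <- c(out, qchars[(qpos + 1L):(qpos + L)])
      offs <- c(offs, apos + seq_len(L) - 1L)
      qpos <- qpos + L; apos <- apos + L
    } else if (op == "I") {
      qpos <- qpos + L; apos <- apos + L
    } else if (op %in% c("D", "N")) {
      out <- c(out, rep("-", L))
      offs <- c(offs, rep(NA_integer_, L))
    } else if (op == "S") {
      qpos <- qpos + L
    } else if (op == "H" || op == "P") {
      # consume nothing
    } else {
      stop("unsupported CIGAR op '", op, "' in ", cigar)
    }
  }
  list(bases = paste(out, collapse = ""), qoff = offs, qlen = apos)
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf("<aligned_reads> %d reads (%d forward, %d reverse)\n",
              nrow(x), sum(x$fwd), sum(!x$fwd)))
  if (nrow(x) > 0L)
    cat(sprintf("  aligned length: %d-%d bp, median %g\n",
                min(x$qlen), max(x$qlen), stats::median(x$qlen)))
  invisible(x)
}
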
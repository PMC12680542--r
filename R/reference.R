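#' Read a reference sequence from a FASTA file
#'
#' Loads a single-record FASTA (the usual case for a mitochondrial
#' reference), uppercases the sequence and maps any non-ACGT character
#' (IUPAC ambiguity codes, gaps) to `N`.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param circular Logical; `TRUE` for circular genomes such as mtDNA.
#'   Circularity controls how reads spanning the origin are piled up
#'   (see [build_pileup()]).
#' @return An object of class `"reference_sequence"`: a list with fields
#'   `name`, `seq` (character scalar over A/C/G/T/N), `circular` and
#'   `length`.
#' @seealso [build_pileup()], [write_consensus()]
#' @export
read_reference <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  if (length(recs) > 1L) {
    stop("expected a single FASTA record in ", path, ", found ", length(recs))
  }
  seq <- toupper(as.character(recs[[1L]]))
  seq <- gsub("[^ACGT]", "N", seq)
  new_reference(sub("\\s.*$", "", names(recs)[1L]), seq, circular = circular)
}

#' Construct a reference sequence object from a string
#'
#' Programmatic constructor used by the simulator and in tests; performs
#' the same alphabet normalization as [read_reference()].
#'
#' @param name Sequence identifier.
#' @param seq Character scalar; uppercased, non-ACGT characters become `N`.
#' @param circular Logical.
#' @return A `"reference_sequence"` object.
#' @export
new_reference <- function(name, seq, circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  seq <- gsub("[^ACGT]", "N", toupper(seq))
  structure(
    list(name = name, seq = seq, circular = isTRUE(circular),
         length = nchar(seq)),
    class = "reference_sequence"
  )
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("<reference_sequence> %s: %d bp (%s)\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

# Split the reference into a character vector of single bases (cached use).
ref_bases <- function(ref) strsplit(ref$seq, "", fixed = TRUE)[[1L]]
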
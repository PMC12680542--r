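#' Chromosome read counts
#'
#' @param name Chromosome name.
#' @param mapped_reads Number of mapped reads (>= 0).
#' @param length Chromosome length in bp (> 0).
#' @return An object of class `"chrom_counts"`.
#' @export
chrom_counts <- function(name, mapped_reads, length) {
  stopifnot(length > 0, mapped_reads >= 0)
  structure(list(name = name, mapped_reads = as.numeric(mapped_reads),
                 length = as.numeric(length)),
            class = "chrom_counts")
}

#' Infer genetic sex from X-vs-autosome read densities
#'
#' In XY systems a male carries one X against two autosome copies, so
#' the length-normalized ChrX:autosome read-count ratio is expected
#' near 0.5; a female's is expected near 1. The comparison autosome
#' should be similar in size to X (horse Chr3 is the conventional
#' choice) and the reference X must be present — this method does not
#' use the Y, which is absent from female reference assemblies.
#'
#' Band boundaries are policy, not measurements: the defaults are
#' symmetric, non-overlapping windows around the two expectations, and
#' anything outside both bands (or below `min_reads` total) is reported
#' as undetermined rather than forced into a class.
#'
#' @param x `"chrom_counts"` for the X chromosome.
#' @param autosome `"chrom_counts"` for the comparison autosome.
#' @param male_band,female_band Numeric length-2 intervals (inclusive)
#'   classified as male / female; defaults `c(0.35, 0.65)` and
#'   `c(0.8, 1.2)`. Must be disjoint.
#' @param min_reads Minimum total mapped reads across both chromosomes
#'   to attempt classification (default 100).
#' @return An object of class `"sex_result"`: list with `ratio`,
#'   `classification` (`"male"`, `"female"` or `"undetermined"`), a
#'   `reason` when undetermined, and the inputs echoed.
#' @export
infer_sex <- function(x, autosome, male_band = c(0.35, 0.65),
                      female_band = c(0.8, 1.2), min_reads = 100L) {
  stopifnot(inherits(x, "chrom_counts"), inherits(autosome, "chrom_counts"),
            length(male_band) == 2L, length(female_band) == 2L,
            min_reads >= 1L)
  if (max(male_band[1], female_band[1]) <= min(male_band[2], female_band[2])) {
    stop("male_band and female_band must be disjoint")
  }
  total <- x$mapped_reads + autosome$mapped_reads
  mk <- function(ratio, classification, reason = NA_character_) {
    structure(list(ratio = ratio, classification = classification,
                   reason = reason, x = x, autosome = autosome,
                   male_band = male_band, female_band = female_band,
                   min_reads = min_reads),
              class = "sex_result")
  }
  if (autosome$mapped_reads == 0) {
    return(mk(NA_real_, "undetermined", "no reads mapped to the autosome"))
  }
  ratio <- (x$mapped_reads / x$length) / (autosome$mapped_reads / autosome$length)
  if (total < min_reads) {
    return(mk(ratio, "undetermined",
              sprintf("only %g total reads (min_reads = %d)", total, min_reads)))
  }
  cls <- if (ratio >= male_band[1] && ratio <= male_band[2]) "male"
         else if (ratio >= female_band[1] && ratio <= female_band[2]) "female"
         else "undetermined"
  mk(ratio, cls,
     if (cls == "undetermined") "ratio outside both bands" else NA_character_)
}

#' @export
print.sex_result <- function(x, ...) {
  cat(sprintf("<sex_result> %s:%s ratio = %s -> %s\n",
              x$x$name, x$autosome$name,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              x$classification))
  if (!is.na(x$reason)) cat("  reason: ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Read an idxstats-style chromosome count table
#'
#' Four tab-separated columns without header: chromosome name, length,
#' mapped reads, unmapped reads (the `samtools idxstats` layout).
#'
#' @param path TSV path.
#' @return Data frame with columns `name`, `length`, `mapped`,
#'   `unmapped`.
#' @export
read_idxstats <- function(path) {
  if (!file.exists(path)) stop("idxstats table not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = FALSE,
                      col.names = c("name", "length", "mapped", "unmapped"),
                      colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) {
      data.frame(name = character(), length = numeric(),
                 mapped = numeric(), unmapped = numeric())
    })
  df
}

#' Sex inference straight from an idxstats table
#'
#' @param path idxstats-style TSV (see [read_idxstats()]).
#' @param x_name,autosome_name Chromosome names to compare.
#' @param ... Passed to [infer_sex()].
#' @return A `"sex_result"`; undetermined (with reason) when the table
#'   is empty.
#' @export
infer_sex_from_idxstats <- function(path, x_name, autosome_name, ...) {
  df <- read_idxstats(path)
  if (nrow(df) == 0L) {
    return(structure(list(ratio = NA_real_, classification = "undetermined",
                          reason = "empty idxstats table",
                          x = NULL, autosome = NULL),
                     class = "sex_result"))
  }
  pick <- function(nm) {
    i <- match(nm, df$name)
    if (is.na(i)) {
      stop("chromosome '", nm, "' not in table; available: ",
           paste(df$name, collapse = ", "))
    }
    chrom_counts(df$name[i], df$mapped[i], df$length[i])
  }
  infer_sex(pick(x_name), pick(autosome_name), ...)
}
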
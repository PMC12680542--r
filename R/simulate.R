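#' Simulation configuration for single-stranded-library ancient reads
#'
#' Defaults emulate deep-time shotgun data from non-UDG single-stranded
#' libraries: very short fragments (mean 34 bp, minimum 30 bp after
#' trimming) and heavy terminal cytosine deamination (72% C-to-T at the
#' molecule's 5' terminus, decaying exponentially into the read). The
#' 3' amplitude is freely configurable; single-stranded libraries show
#' elevated damage at both ends, and its default here (0.40) is a
#' package choice, not a measured value.
#'
#' @param seed Integer seed; mandatory, drives all randomness.
#' @param target_cov Target fold-coverage (expected total bases =
#'   `target_cov * genome length`).
#' @param frag_mean Mean fragment length in bp after truncation at
#'   `min_len` (default 34).
#' @param frag_shape Lognormal shape (sdlog) of the length distribution
#'   (default 0.25).
#' @param min_len Minimum fragment length in bp (default 30).
#' @param damage_amp5,damage_amp3 Terminal deamination probabilities at
#'   the molecule's 5' and 3' ends (defaults 0.72 and 0.40).
#' @param damage_decay Exponential decay scale of positional damage, in
#'   read positions (default 3.0).
#' @param damage_baseline Residual deamination probability at interior
#'   positions (default 0.02).
#' @param seq_error Per-base uniform, strand-symmetric sequencing-error
#'   probability (default 0.001).
#' @param p_forward Probability a molecule maps in forward orientation
#'   (default 0.5).
#' @param n_variants Number of true differences to introduce between
#'   reference and simulated genome (default 0).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed, target_cov = 10, frag_mean = 34,
                              frag_shape = 0.25, min_len = 30L,
                              damage_amp5 = 0.72, damage_amp3 = 0.40,
                              damage_decay = 3.0, damage_baseline = 0.02,
                              seq_error = 0.001, p_forward = 0.5,
                              n_variants = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            target_cov > 0, frag_shape > 0, min_len >= 1L,
            damage_decay > 0)
  probs <- c(damage_amp5, damage_amp3, damage_baseline, seq_error, p_forward)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (frag_mean <= min_len) {
    stop("frag_mean (", frag_mean, ") must exceed min_len (", min_len,
         "): the truncated length distribution cannot attain that mean")
  }
  structure(
    list(seed = as.integer(seed), target_cov = target_cov,
         frag_mean = frag_mean, frag_shape = frag_shape,
         min_len = as.integer(min_len),
         damage_amp5 = damage_amp5, damage_amp3 = damage_amp3,
         damage_decay = damage_decay, damage_baseline = damage_baseline,
         seq_error = seq_error, p_forward = p_forward,
         n_variants = as.integer(n_variants)),
    class = "simulation_config"
  )
}

#' Introduce true variants into a reference
#'
#' Picks `n_variants` distinct positions and substitutes a uniformly
#' chosen different base at each, producing the true genome that reads
#' are simulated from. This is what makes variant-recovery tests
#' meaningful: a true C-to-T difference from the reference looks
#' exactly like damage to a polarized caller.
#'
#' @param ref A `"reference_sequence"`.
#' @param n_variants Number of substitutions (0 allowed).
#' @param seed Integer seed.
#' @return An object of class `"simulation_truth"`: list with
#'   `true_genome` (string), `variants` (data frame: `pos` 0-based,
#'   `ref_base`, `true_base`) and reference metadata.
#' @export
mutate_reference <- function(ref, n_variants, seed) {
  stopifnot(inherits(ref, "reference_sequence"))
  n_variants <- as.integer(n_variants)
  if (n_variants > ref$length) {
    stop("n_variants (", n_variants, ") exceeds reference length (",
         ref$length, ")")
  }
  set.seed(as.integer(seed))
  tb <- ref_bases(ref)
  if (n_variants > 0L) {
    pos <- sample.int(ref$length, n_variants)  # 1-based internally
    old <- tb[pos]
    new <- vapply(old, function(b) sample(setdiff(BASES, b), 1L), "")
    tb[pos] <- new
    variants <- data.frame(pos = sort(pos) - 1L,
                           ref_base = old[order(pos)],
                           true_base = new[order(pos)],
                           stringsAsFactors = FALSE)
  } else {
    variants <- data.frame(pos = integer(), ref_base = character(),
                           true_base = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(ref_name = ref$name, ref_len = ref$length, circular = ref$circular,
         true_genome = paste(tb, collapse = ""), variants = variants),
    class = "simulation_truth"
  )
}

# Solve for the lognormal meanlog whose min_len-truncated mean equals the
# requested fragment mean.
lnorm_meanlog_for_truncated_mean <- function(frag_mean, sdlog, min_len) {
  la <- log(min_len)
  tmean <- function(mu) {
    exp(mu + sdlog^2 / 2) * stats::pnorm((mu + sdlog^2 - la) / sdlog) /
      stats::pnorm((mu - la) / sdlog) - frag_mean
  }
  stats::uniroot(tmean, c(la - 8, log(frag_mean) + 4), tol = 1e-9)$root
}

# Draw fragment lengths (integer, >= min_len) by rejection.
draw_lengths <- function(n, config) {
  mu <- lnorm_meanlog_for_truncated_mean(config$frag_mean, config$frag_shape,
                                         config$min_len)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(max(2L * (n - length(out)), 16L), mu, config$frag_shape)
    out <- c(out, x[x >= config$min_len])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Simulate single-stranded-library ancient-DNA reads with known truth
#'
#' Draws molecules uniformly from the (circular) true genome with
#' lognormal lengths, assigns each a mapping orientation, deaminates
#' molecule-strand cytosines to thymines with probability
#' `min(1, amp5 * exp(-i/decay) + amp3 * exp(-j/decay) + baseline)`
#' where `i` and `j` are the distances from the molecule's 5' and 3'
#' ends, overlays uniform sequencing errors, and logs every damage
#' event. Reverse-mapping molecules are emitted in reference
#' orientation, so their deamination appears as G-to-A — the hallmark
#' asymmetry of single-stranded libraries that the calling modes key
#' on.
#'
#' @param truth A `"simulation_truth"` from [mutate_reference()].
#' @param config A `"simulation_config"`.
#' @return A list of class `"sim_reads"` with `reads` (an
#'   `"aligned_reads"` data frame, directly pileable or writable with
#'   [write_sam()]), `events` (data frame: `read_id`, `offset`
#'   (molecule 5'-anchored), `type` `"CT"` for forward reads / `"GA"`
#'   for reverse), and the `config`.
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- truth$ref_len
  target_bases <- config$target_cov * L

  # draw lengths until the coverage target is met
  lens <- integer(0)
  repeat {
    need <- max(16L, ceiling((target_bases - sum(lens)) / config$frag_mean))
    lens <- c(lens, draw_lengths(need, config))
    cs <- cumsum(as.numeric(lens))
    if (cs[length(cs)] >= target_bases) {
      lens <- lens[seq_len(which(cs >= target_bases)[1L])]
      break
    }
  }
  n <- length(lens)
  if (truth$circular) {
    starts <- sample.int(L, n, replace = TRUE) - 1L
  } else {
    if (any(lens > L)) stop("fragment longer than linear reference")
    starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L, 1L)
  }
  fwd <- stats::runif(n) < config$p_forward
  rid <- sprintf("sim_%06d", seq_len(n))

  tb <- strsplit(truth$true_genome, "", fixed = TRUE)[[1L]]
  ri <- rep(seq_len(n), lens)
  k <- sequence(lens) - 1L                     # offset within read, ref orientation
  refpos <- (rep(starts, lens) + k) %% L
  char <- tb[refpos + 1L]
  lrep <- rep(lens, lens)
  frep <- rep(fwd, lens)
  i <- ifelse(frep, k, lrep - 1L - k)          # molecule 5' distance
  j <- lrep - 1L - i                           # molecule 3' distance

  p <- pmin(1, config$damage_amp5 * exp(-i / config$damage_decay) +
               config$damage_amp3 * exp(-j / config$damage_decay) +
               config$damage_baseline)
  target <- (frep & char == "C") | (!frep & char == "G")
  dam <- target & stats::runif(length(char)) < p
  char[dam & frep] <- "T"
  char[dam & !frep] <- "A"
  events <- data.frame(read_id = rid[ri[dam]], offset = i[dam],
                       type = ifelse(frep[dam], "CT", "GA"),
                       stringsAsFactors = FALSE)

  err <- stats::runif(length(char)) < config$seq_error
  if (any(err)) {
    char[err] <- vapply(char[err],
                        function(b) sample(setdiff(BASES, b), 1L), "")
  }

  bases <- vapply(split(char, factor(ri, levels = seq_len(n))),
                  paste, "", collapse = "")
  reads <- data.frame(read_id = rid, ref_start = starts, fwd = fwd,
                      qlen = lens, mapq = 37L, bases = unname(bases),
                      stringsAsFactors = FALSE)
  reads$qoff <- vector("list", n)
  class(reads) <- c("aligned_reads", "data.frame")
  structure(list(reads = reads, events = events, config = config),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("<sim_reads> %d reads, %d logged damage events\n",
              nrow(x$reads), nrow(x$events)))
  invisible(x)
}

#' Write aligned reads to a SAM file
#'
#' Emits a valid header plus one ungapped record per read with correct
#' reverse-strand flags. Reads wrapping the origin of a circular
#' reference are written as single records whose alignment extends past
#' the stated reference length; [build_pileup()] interprets the
#' overhang as a wrap, so a round trip through
#' [read_alignments()] preserves placements exactly.
#'
#' @param reads An `"aligned_reads"` object (ungapped, as produced by
#'   the simulator).
#' @param ref The `"reference_sequence"`.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, ref, path) {
  stopifnot(inherits(ref, "reference_sequence"))
  if (any(vapply(reads$qoff, Negate(is.null), logical(1L)))) {
    stop("write_sam only supports ungapped alignments")
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length))
  if (nrow(reads) > 0L) {
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                   reads$read_id, ifelse(reads$fwd, 0L, 16L), ref$name,
                   reads$ref_start + 1L,
                   ifelse(is.na(reads$mapq), 255L, reads$mapq),
                   nchar(reads$bases), reads$bases)
  } else rec <- character(0)
  tryCatch(writeLines(c(hdr, rec), path),
           error = function(e) stop("failed to write SAM to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Write simulation truth tables
#'
#' Writes the true genome as FASTA plus TSV tables of introduced
#' variants and logged damage events, so any downstream evaluation can
#' run without access to the R objects.
#'
#' @param truth A `"simulation_truth"`.
#' @param sim A `"sim_reads"` result (for the damage-event table); may
#'   be `NULL` to write the genome and variants only.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the paths written.
#' @export
write_truth <- function(truth, sim = NULL, dir) {
  stopifnot(inherits(truth, "simulation_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(truth$true_genome)
  names(g) <- paste0(truth$ref_name, "_truth")
  fa <- file.path(dir, "truth_genome.fasta")
  Biostrings::writeXStringSet(g, fa, width = 60L)
  va <- file.path(dir, "truth_variants.tsv")
  utils::write.table(truth$variants, va, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- list(genome = fa, variants = va)
  if (!is.null(sim)) {
    ev <- file.path(dir, "truth_damage_events.tsv")
    utils::write.table(sim$events, ev, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$events <- ev
  }
  invisible(out)
}
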
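# Shared fixture builders: everything is generated in code at test time.

random_ref <- function(len, seed = 1L, name = "mt", circular = TRUE) {
  set.seed(seed)
  new_reference(name, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                            collapse = ""),
                circular = circular)
}

# Hand-build an aligned_reads frame (reference-orientation bases, 0-based
# starts), bypassing file I/O.
mk_reads <- function(ref_start, bases, fwd = TRUE, read_id = NULL,
                     mapq = 37L) {
  n <- length(bases)
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  df <- data.frame(read_id = read_id,
                   ref_start = as.integer(rep_len(ref_start, n)),
                   fwd = rep_len(fwd, n),
                   qlen = nchar(bases),
                   mapq = rep_len(as.integer(mapq), n),
                   bases = bases,
                   stringsAsFactors = FALSE)
  df$qoff <- vector("list", n)
  class(df) <- c("aligned_reads", "data.frame")
  df
}

# Hand-build a single pileup column. Default end distances put every
# entry mid-read (dist 10 from both ends of a 21 bp read).
mk_col <- function(bases, fwd = TRUE, dist5 = 10L, dist3 = 10L,
                   ref_base = "A", ref_pos = 0L) {
  n <- length(bases)
  paleomito:::new_pileup_column(as.integer(ref_pos), ref_base, bases,
                                rep_len(fwd, n),
                                as.integer(rep_len(dist5, n)),
                                as.integer(rep_len(dist3, n)))
}

# Flat damage profile: constant frequency d at every distance, both
# substitution classes and ends.
flat_profile <- function(d, window = 25L, baseline = d) {
  damage_profile(ct5 = rep(d, window), baseline_ct = baseline,
                 baseline_ga = baseline)
}

# Draw one random pileup column (used by property-style tests).
random_column <- function(max_entries = 8L, allow_n = TRUE) {
  n <- sample.int(max_entries, 1L)
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  d5 <- sample(0:30, n, replace = TRUE)
  mk_col(sample(alphabet, n, replace = TRUE),
         fwd = sample(c(TRUE, FALSE), n, replace = TRUE),
         dist5 = d5, dist3 = sample(0:30, n, replace = TRUE),
         ref_base = sample(c("A", "C", "G", "T"), 1L))
}

# Polarization-free flags of a single column, computed from its entries.
col_flags_free <- function(col) {
  list(flag_ct = any(col$fwd & col$base == "T") && any(col$base == "C"),
       flag_ga = any(!col$fwd & col$base == "A") && any(col$base == "G"))
}

# Polarized flags of a single column given its reference base.
col_flags_pol <- function(col) {
  list(flag_ct = col$ref_base == "C" && any(col$fwd & col$base == "T"),
       flag_ga = col$ref_base == "G" && any(!col$fwd & col$base == "A"))
}

# Terminal misincorporation rate implied by the simulator's damage model
# at the molecule's 5' end (the 3'-amplitude contribution at the far end
# of a >=30 bp fragment is negligible but included).
model_terminal_rate <- function(config) {
  min(1, config$damage_amp5 +
         config$damage_amp3 * exp(-(config$min_len - 1) / config$damage_decay) +
         config$damage_baseline)
}
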
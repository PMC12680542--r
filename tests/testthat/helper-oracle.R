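# Brute-force consensus caller, written as a plain entry-by-entry loop,
# independent of the package's vectorized implementation. Takes explicit
# scalar flags; profile lookups re-derive the weight rules from first
# principles.

oracle_profile_d <- function(fwd, d5, d3, profile) {
  W <- profile$window
  if (profile$anchor == "five_prime" || d5 <= d3) {
    dist <- d5
    curve <- if (fwd) profile$ct5 else profile$ga5
  } else {
    dist <- d3
    curve <- if (fwd) profile$ct3 else profile$ga3
  }
  if (dist < W) curve[dist + 1] else if (fwd) profile$baseline_ct else profile$baseline_ga
}

oracle_call <- function(col, mode, flag_ct, flag_ga, profile = NULL,
                        min_cov = 3, min_support = 0.65,
                        cov_basis = "effective", weight_cov = "raw") {
  tally <- c(A = 0, C = 0, G = 0, T = 0)
  raw <- 0L
  surviving <- 0L
  for (e in seq_along(col$base)) {
    b <- col$base[e]
    if (b == "N") next
    raw <- raw + 1L
    f <- col$fwd[e]
    if (mode == "pol_silence" || mode == "free_silence") {
      if (flag_ct && f && b == "T") next
      if (flag_ga && !f && b == "A") next
      surviving <- surviving + 1L
      tally[b] <- tally[b] + 1
    } else if (mode == "free_weight") {
      d <- oracle_profile_d(f, col$dist5[e], col$dist3[e], profile)
      w <- 1
      if (f && b == "T") w <- max(1 - d, 1e-9)
      if (f && b == "C") w <- 1 + d
      if (!f && b == "A") w <- max(1 - d, 1e-9)
      if (!f && b == "G") w <- 1 + d
      tally[b] <- tally[b] + w
    } else {
      tally[b] <- tally[b] + 1
    }
  }
  gate <- if (mode %in% c("pol_silence", "free_silence")) {
    if (cov_basis == "effective") surviving else raw
  } else if (mode == "free_weight" && weight_cov == "weighted") {
    sum(tally)
  } else raw
  tot <- sum(tally)
  if (tot == 0 || gate < min_cov) return("N")
  support <- max(tally) / tot
  if (support < min_support - 1e-9) return("N")  # same roundoff slack as the caller

  names(tally)[which.max(tally)]
}
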
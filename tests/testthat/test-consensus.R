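test_that("polarized flagging requires the matching reference base", {
  ref <- new_reference("r", "CAG", circular = FALSE)
  reads <- mk_reads(c(0L, 0L, 0L, 0L),
                    c("TAA", "CAA", "ATA", "AAA"),
                    fwd = c(TRUE, TRUE, TRUE, FALSE))
  # last read reverse with A over the reference G at position 2
  p <- build_pileup(reads, ref)
  fl <- flag_polarized(p, ref)
  expect_true(fl$flag_ct[1])    # ref C with a forward T
  expect_false(fl$flag_ct[2])   # ref A: no flag even though a fwd T is present
  expect_true(fl$flag_ga[3])    # ref G with a reverse A
  expect_equal(fl$method, "polarized")
})

test_that("forward As never trigger the G>A flag under polarization", {
  ref <- new_reference("r", "G", circular = FALSE)
  p <- build_pileup(mk_reads(0L, c("A", "A"), fwd = c(TRUE, TRUE)), ref)
  expect_false(flag_polarized(p, ref)$flag_ga[1])
  p2 <- build_pileup(mk_reads(0L, c("A", "A"), fwd = c(FALSE, TRUE)), ref)
  expect_true(flag_polarized(p2, ref)$flag_ga[1])
})

test_that("polarization-free flagging keys on observed variation only", {
  ref <- new_reference("r", "AAAA", circular = FALSE)  # reference never consulted
  # pos 0: fwd T + rev C -> CT flag; pos 1: three Ts, no C -> no flag
  # pos 2: rev A + fwd G -> GA flag; pos 3: nothing
  reads <- mk_reads(c(0L, 0L, 0L),
                    c("TTGA", "TTAA", "CTAA"),
                    fwd = c(TRUE, TRUE, FALSE))
  p <- build_pileup(reads, ref)
  fl <- flag_polarization_free(p)
  expect_true(fl$flag_ct[1])
  expect_false(fl$flag_ct[2])
  expect_true(fl$flag_ga[3])
  expect_false(fl$flag_ct[4] || fl$flag_ga[4])
  expect_equal(fl$method, "polarization_free")
})

test_that("support thresholding is inclusive at the 2-of-3 boundary", {
  params <- calling_params("none")
  col <- mk_col(c("A", "A", "T"))
  res <- call_column(col, params)
  expect_equal(res$call, "A")
  expect_equal(res$support, 2 / 3)
  # coverage below 3 gives N no matter how clean
  expect_equal(call_column(mk_col(c("A", "A")), params)$call, "N")
  # support below 65% gives N
  expect_equal(call_column(mk_col(c("A", "A", "T", "T")), params)$call, "N")
})

test_that("silencing removes flagged damage-pattern bases before thresholds", {
  params <- calling_params("free_silence")
  col <- mk_col(c("C", "T", "T"), fwd = TRUE)
  res <- call_column(col, params, flags = list(flag_ct = TRUE, flag_ga = FALSE))
  expect_equal(res$n_silenced, 2L)
  expect_equal(res$eff_cov, 1)
  expect_equal(res$call, "N")  # post-silencing coverage 1 < 3
  # with the raw-coverage variant the surviving C is callable
  raw_params <- calling_params("free_silence", cov_basis = "raw")
  res2 <- call_column(col, raw_params, flags = list(flag_ct = TRUE, flag_ga = FALSE))
  expect_equal(res2$call, "C")
})

test_that("weighted calling recovers the C drowned out by damage", {
  prof <- flat_profile(0.7)
  params <- calling_params("free_weight")
  col <- mk_col(c("T", "T", "C"), fwd = TRUE, dist5 = 0L, dist3 = 30L)
  res <- call_column(col, params, profile = prof)
  expect_equal(unname(res$counts_eff["T"]), 0.6)
  expect_equal(unname(res$counts_eff["C"]), 1.7)
  expect_equal(res$support, 1.7 / 2.3, tolerance = 1e-12)
  expect_equal(res$call, "C")
  # with zero damage the same column behaves exactly like plain counting
  res0 <- call_column(col, params, profile = flat_profile(0))
  expect_equal(res0$call, call_column(col, calling_params("none"))$call)
  expect_equal(res0$call, "T")
})

test_that("missing flags or profile are configuration errors", {
  col <- mk_col(c("A", "A", "A"))
  expect_error(call_column(col, calling_params("free_weight")), "profile")
  expect_error(call_column(col, calling_params("pol_silence")), "flags")
  expect_error(call_column(col, calling_params("free_silence")), "flags")
})

test_that("entries with base N count nowhere", {
  params <- calling_params("none")
  res <- call_column(mk_col(c("A", "A", "A", "N")), params)
  expect_equal(res$raw_cov, 3L)
  expect_equal(res$call, "A")
  expect_equal(call_column(mk_col(c("A", "A", "N")), params)$call, "N")
})

test_that("free-weight calls equal plain calls under an all-zero profile", {
  set.seed(7)
  zero <- flat_profile(0)
  none <- calling_params("none")
  weight <- calling_params("free_weight")
  for (k in 1:1000) {
    col <- random_column()
    expect_identical(call_column(col, weight, profile = zero)$call,
                     call_column(col, none)$call)
  }
})

test_that("argmax ties always fall below the support threshold", {
  set.seed(13)
  for (k in 1:500) {
    col <- random_column(max_entries = 6L)
    res <- call_column(col, calling_params("none"))
    ce <- res$counts_eff
    if (sum(ce) > 0 && sum(ce == max(ce)) > 1 && res$raw_cov >= 2L) {
      expect_lte(res$support, 0.5)
      expect_equal(res$call, "N")
    }
  }
})

test_that("N calls are monotone in the support threshold", {
  ref <- random_ref(800, seed = 17)
  cfg <- simulation_config(seed = 41, target_cov = 8, n_variants = 10L)
  truth <- mutate_reference(ref, 10L, 41)
  sim <- simulate_reads(truth, cfg)
  p <- build_pileup(sim$reads, ref)
  prof <- estimate_profile(p)
  for (mode in c("none", "pol_silence", "free_silence", "free_weight")) {
    nn <- vapply(c(0.55, 0.65, 0.75, 0.9), function(ms) {
      params <- calling_params(mode, min_support = ms)
      reconstruct(p, ref, params, prof)$summary$n_N
    }, 0L)
    expect_true(all(diff(nn) >= 0), info = mode)
  }
})

test_that("silencing only ever changes calls at flagged positions", {
  ref <- random_ref(800, seed = 19)
  cfg <- simulation_config(seed = 43, target_cov = 8)
  sim <- simulate_reads(mutate_reference(ref, 0L, 43), cfg)
  p <- build_pileup(sim$reads, ref)
  base <- reconstruct(p, ref, calling_params("none"))
  for (mode in c("pol_silence", "free_silence")) {
    res <- reconstruct(p, ref, calling_params(mode))
    flagged <- res$flags$flag_ct | res$flags$flag_ga
    b <- strsplit(base$sequence, "")[[1]]
    s <- strsplit(res$sequence, "")[[1]]
    expect_true(all(b[!flagged] == s[!flagged]), info = mode)
  }
})

test_that("clean deep data reproduce the truth exactly in every mode", {
  ref <- random_ref(600, seed = 23)
  cfg <- simulation_config(seed = 47, target_cov = 20,
                           damage_amp5 = 0, damage_amp3 = 0,
                           damage_baseline = 0, seq_error = 0)
  truth <- mutate_reference(ref, 0L, 47)
  sim <- simulate_reads(truth, cfg)
  p <- build_pileup(sim$reads, ref)
  prof <- estimate_profile(p)
  for (mode in c("none", "pol_silence", "free_silence", "free_weight")) {
    res <- reconstruct(p, ref, calling_params(mode), prof)
    expect_equal(res$sequence, truth$true_genome, info = mode)
    expect_equal(res$summary$n_N, 0L, info = mode)
    cmp <- compare_to_truth(res, truth)
    expect_equal(cmp$n_miscall, 0L)
    expect_equal(cmp$n_called, ref$length)
  }
})

test_that("uncovered regions are counted as N and pct_N is exact", {
  ref <- new_reference("lin", strrep("A", 50), circular = FALSE)
  p <- build_pileup(mk_reads(c(0L, 0L, 0L), rep(strrep("A", 30), 3)), ref)
  res <- reconstruct(p, ref, calling_params("none"))
  expect_equal(substr(res$sequence, 31, 50), strrep("N", 20))
  expect_equal(res$summary$n_N, 20L)
  expect_equal(res$summary$pct_N, 100 * 20 / 50)
  s <- res$summary
  expect_equal(s$n_N, lengths(regmatches(res$sequence, gregexpr("N", res$sequence))))
  expect_lte(s$n_N_at_damaged, min(s$n_N, s$n_damaged_positions))
})

test_that("comparison to truth pinpoints miscalls", {
  ref <- random_ref(300, seed = 29)
  cfg <- simulation_config(seed = 53, target_cov = 20,
                           damage_amp5 = 0, damage_amp3 = 0,
                           damage_baseline = 0, seq_error = 0)
  truth <- mutate_reference(ref, 3L, 53)
  sim <- simulate_reads(truth, cfg)
  res <- reconstruct(build_pileup(sim$reads, ref), ref, calling_params("none"))
  expect_equal(compare_to_truth(res, truth)$n_miscall, 0L)
  # corrupt one call and it must be reported at the right position
  bad <- res
  sq <- strsplit(bad$sequence, "")[[1]]
  pos <- 42L
  sq[pos + 1L] <- setdiff(c("A", "C", "G", "T"), sq[pos + 1L])[1]
  bad$sequence <- paste(sq, collapse = "")
  cmp <- compare_to_truth(bad, truth)
  expect_equal(cmp$n_miscall, 1L)
  expect_equal(cmp$miscall_pos, pos)
  # length mismatch is an error, not a silent misalignment
  expect_error(compare_to_truth(res, list(true_genome = "ACGT")), "length")
})
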
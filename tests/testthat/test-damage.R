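test_that("profile cells are direct mismatch frequencies", {
  # one forward read carrying T over a reference C at its 5' terminus
  ref <- new_reference("r", paste0("C", strrep("A", 9)), circular = FALSE)
  p <- build_pileup(mk_reads(0L, "TAAAA"), ref)
  prof <- estimate_profile(p, window = 5L)
  expect_equal(prof$ct5[1], 1.0)
  # a clean alignment yields all-zero frequencies
  p2 <- build_pileup(mk_reads(0L, "CAAAA"), ref)
  prof2 <- estimate_profile(p2, window = 5L)
  expect_true(all(c(prof2$ct5, prof2$ct3, prof2$ga5, prof2$ga3) == 0))
  expect_equal(prof2$baseline_ct, 0)
})

test_that("empty pileups cannot be profiled", {
  ref <- new_reference("r", "ACGT", circular = FALSE)
  p <- build_pileup(paleomito:::empty_aligned_reads(), ref)
  expect_error(estimate_profile(p), "empty")
})

test_that("damage_frequency looks up the nearer alignment end", {
  prof <- damage_profile(ct5 = c(0.7, 0.5, rep(0.1, 23)),
                         ct3 = c(0.6, 0.4, rep(0.1, 23)),
                         ga5 = c(0.3, rep(0.1, 24)),
                         ga3 = c(0.2, 0.15, rep(0.1, 23)),
                         baseline_ct = 0.05, baseline_ga = 0.04)
  expect_equal(damage_frequency(TRUE, 0L, 33L, prof), 0.7)
  expect_equal(damage_frequency(TRUE, 33L, 1L, prof), 0.4)   # nearer 3' end
  expect_equal(damage_frequency(FALSE, 30L, 1L, prof), 0.15) # reverse: ga3
  expect_equal(damage_frequency(FALSE, 0L, 20L, prof), 0.3)  # reverse: ga5
  # read middle beyond the window falls back to the baseline
  expect_equal(damage_frequency(TRUE, 27L, 12L, prof), 0.1)  # in-window 3'
  expect_equal(damage_frequency(TRUE, 26L, 30L, prof), 0.05) # beyond window
})

test_that("a five-prime-only anchor ignores the 3' curves", {
  prof <- damage_profile(ct5 = rep(0.6, 5), ct3 = rep(0.2, 5),
                         baseline_ct = 0.01, anchor = "five_prime")
  expect_equal(damage_frequency(TRUE, 1L, 0L, prof), 0.6)
  expect_equal(damage_frequency(TRUE, 7L, 0L, prof), 0.01)
})

test_that("base weights follow the damage/counterpart rule", {
  prof <- flat_profile(0.7)
  expect_equal(base_weight("T", TRUE, 0L, 20L, prof), 0.3)
  expect_equal(base_weight("C", TRUE, 0L, 20L, prof), 1.7)
  expect_equal(base_weight("A", FALSE, 0L, 20L, prof), 0.3)
  expect_equal(base_weight("G", FALSE, 0L, 20L, prof), 1.7)
  # only the stated damaged/counterpart pairs are reweighted
  expect_equal(base_weight("T", FALSE, 0L, 20L, prof), 1)
  expect_equal(base_weight("A", TRUE, 0L, 20L, prof), 1)
  expect_equal(base_weight("G", TRUE, 0L, 20L, prof), 1)
  expect_equal(base_weight("C", FALSE, 0L, 20L, prof), 1)
  # zero damage degenerates to plain counting
  z <- flat_profile(0)
  expect_true(all(base_weight(c("A", "C", "G", "T"), TRUE, 0L, 9L, z) == 1))
})

test_that("weights stay in (0, 2] and balanced pairs keep their mass", {
  set.seed(42)
  for (k in 1:200) {
    prof <- flat_profile(runif(1))
    b <- sample(c("A", "C", "G", "T"), 1)
    f <- sample(c(TRUE, FALSE), 1)
    w <- base_weight(b, f, sample(0:40, 1), sample(0:40, 1), prof)
    expect_gt(w, 0)
    expect_lte(w, 2)
  }
  # probabilistic equilibrium: a T/C pair at one end distance weighs 2
  prof <- flat_profile(0.63)
  wT <- base_weight("T", TRUE, 2L, 30L, prof)
  wC <- base_weight("C", TRUE, 2L, 30L, prof)
  expect_equal(wT + wC, 2)
  wA <- base_weight("A", FALSE, 5L, 30L, prof)
  wG <- base_weight("G", FALSE, 5L, 30L, prof)
  expect_equal(wA + wG, 2)
})

test_that("fragment statistics summarize read lengths", {
  reads <- mk_reads(0L, c(strrep("A", 30), strrep("A", 34), strrep("A", 38)))
  fs <- fragment_stats(reads)
  expect_equal(fs$mean_len, 34)
  expect_equal(fs$median_len, 34)
  expect_equal(sum(fs$hist), 3L)
  one <- fragment_stats(mk_reads(0L, strrep("A", 31)))
  expect_equal(one$mean_len, 31)
  expect_error(fragment_stats(paleomito:::empty_aligned_reads()), "empty")
})

test_that("the estimator recovers the simulator's terminal damage rate", {
  ref <- random_ref(4000, seed = 8)
  cfg <- simulation_config(seed = 31, target_cov = 40)  # ~4,700 reads
  sim <- simulate_reads(mutate_reference(ref, 0L, 31), cfg)
  prof <- estimate_profile(build_pileup(sim$reads, ref))
  r0 <- model_terminal_rate(cfg)
  n <- prof$n_obs[1, "ct5"]
  se <- sqrt(r0 * (1 - r0) / n)
  expect_lt(abs(prof$ct5[1] - r0), 3 * se)
  # the reverse-strand mirror appears on the right-end G>A curve
  n_ga <- prof$n_obs[1, "ga3"]
  expect_lt(abs(prof$ga3[1] - r0), 3 * sqrt(r0 * (1 - r0) / n_ga))
})

test_that("terminal C>T frequency increases with the deamination amplitude", {
  ref <- random_ref(2000, seed = 12)
  mean_ct0 <- function(amp) {
    vals <- vapply(1:3, function(s) {
      cfg <- simulation_config(seed = 100 + s, target_cov = 15,
                               damage_amp5 = amp)
      sim <- simulate_reads(mutate_reference(ref, 0L, 100 + s), cfg)
      estimate_profile(build_pileup(sim$reads, ref))$ct5[1]
    }, 0)
    mean(vals)
  }
  expect_lt(mean_ct0(0.1), mean_ct0(0.4))
  expect_lt(mean_ct0(0.4), mean_ct0(0.7))
})

test_that("profiles survive a TSV round trip", {
  ref <- random_ref(1000, seed = 5)
  cfg <- simulation_config(seed = 77, target_cov = 10)
  sim <- simulate_reads(mutate_reference(ref, 0L, 77), cfg)
  prof <- estimate_profile(build_pileup(sim$reads, ref))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, tsv)
  back <- read_profile(tsv)
  for (f in c("window", "ct5", "ct3", "ga5", "ga3",
              "baseline_ct", "baseline_ga", "anchor")) {
    expect_equal(back[[f]], prof[[f]], tolerance = 1e-12)
  }
  expect_equal(unname(back$n_obs), unname(prof$n_obs))
})

test_that("sparse window cells inherit the baseline", {
  # single short forward read: distances beyond its length have no data
  ref <- new_reference("r", strrep("C", 50), circular = FALSE)
  p <- build_pileup(mk_reads(0L, paste0("T", strrep("C", 9))), ref)
  prof <- estimate_profile(p, window = 25L)
  # cells 11..25 have zero denominator -> baseline
  expect_true(all(prof$ct5[12:25] == prof$baseline_ct))
})
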
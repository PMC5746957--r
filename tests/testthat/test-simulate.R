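# Simulator: protocol-step behaviour, configured-rate fidelity, truth
# bookkeeping, emission round-trips.

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(pull_down_rate = 1.5), "probabilities")
  expect_error(sim_config(truncation_prob = 0.7,
                          offtarget_truncation_prob = 0.4), "> 1")
  expect_error(sim_config(size_min = 140, size_max = 140), "size_min")
})

test_that("fragment lengths follow the configured normal distribution", {
  withr::with_seed(61, {
    len <- fragment_lengths(1e4)
  })
  expect_true(all(len >= 1))
  # 3 MC standard errors around the configured mean and sd
  expect_lt(abs(mean(len) - 165), 3 * 50 / sqrt(1e4))
  expect_lt(abs(sd(len) - 50), 3 * 50 / sqrt(2 * 1e4))
})

test_that("transcript abundances drive fragment sampling", {
  tx <- data.frame(chrom = c("c1", "c1"), start = c(0L, 10000L),
                   end = c(5000L, 15000L), strand = "+",
                   abundance = c(9, 1))
  withr::with_seed(62, {
    fr <- sample_fragments(tx, 1e4)
  })
  n1 <- sum(fr$start < 5000)
  expect_lt(abs(n1 / 1e4 - 0.9), 3 * sqrt(0.9 * 0.1 / 1e4))
  expect_true(all(fr$end <= ifelse(fr$start < 5000, 5000, 15000)))
})

test_that("pull-down keeps overlapping fragments at the configured rate", {
  regions <- data.frame(chrom = "c1", start = 500L, end = 508L,
                        strand = "+", region = 1L)
  frags <- data.frame(chrom = "c1", start = rep(c(400L, 2000L), each = 5000),
                      end = rep(c(600L, 2200L), each = 5000),
                      strand = "+", len = 200L)
  withr::with_seed(63, {
    kept_full <- pull_down(frags, regions, rate = 1.0)
    kept_half <- pull_down(frags, regions, rate = 0.5)
  })
  expect_equal(nrow(kept_full), 5000L)       # every overlapping fragment
  expect_true(all(kept_full$start == 400L))  # non-overlapping never selected
  expect_lt(abs(nrow(kept_half) / 5000 - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("reverse transcription truncates at the configured rates", {
  regions <- data.frame(chrom = "c1", start = 500L, end = 508L,
                        strand = "+", region = 1L)
  crosslinks <- data.frame(chrom = "c1", pos = 503L, strand = "+",
                           region = 1L)
  n <- 2e4
  frags <- data.frame(chrom = "c1", start = 450L, end = 550L, strand = "+",
                      len = 100L, region = 1L)[rep(1, n), ]
  # certain truncation with a single in-fragment crosslink
  withr::with_seed(64, {
    rt1 <- reverse_transcribe(frags, crosslinks, sim_config(),
                              truncation_prob = 1,
                              offtarget_truncation_prob = 0)
  })
  expect_true(all(rt1$pos == 503L))
  expect_true(all(rt1$trunc == "at_crosslink"))
  # default rates: 0.7 / 0.1 within 3 MC standard errors
  withr::with_seed(65, {
    rt <- reverse_transcribe(frags, crosslinks, sim_config())
  })
  f_cl <- mean(rt$trunc == "at_crosslink")
  f_ot <- mean(rt$trunc == "off_target")
  expect_lt(abs(f_cl - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  expect_lt(abs(f_ot - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # both probabilities zero: the start stays at the 5' end
  withr::with_seed(66, {
    rt0 <- reverse_transcribe(frags, crosslinks, sim_config(),
                              truncation_prob = 0,
                              offtarget_truncation_prob = 0)
  })
  expect_true(all(rt0$pos == 450L))
  expect_true(all(rt0$trunc == "none"))
  # crosslink outside the fragment: the branch falls through to untruncated
  far <- data.frame(chrom = "c1", start = 600L, end = 700L, strand = "+",
                    len = 100L, region = 1L)
  withr::with_seed(67, {
    rtf <- reverse_transcribe(far, crosslinks, sim_config(),
                              truncation_prob = 1,
                              offtarget_truncation_prob = 0)
  })
  expect_equal(rtf$trunc, "none")
  expect_equal(rtf$pos, 600L)
  # minus-strand 5' end is the rightmost base
  mfrag <- data.frame(chrom = "c1", start = 450L, end = 550L, strand = "-",
                      len = 100L, region = 1L)
  rtm <- reverse_transcribe(mfrag, crosslinks, sim_config(),
                            truncation_prob = 0,
                            offtarget_truncation_prob = 0)
  expect_equal(rtm$pos, 549L)
})

test_that("size selection keeps 30-140 nt fragments inclusively", {
  reads <- data.frame(len = c(29L, 30L, 100L, 140L, 141L))
  kept <- size_select(reads)
  expect_equal(kept$len, c(30L, 100L, 140L))
  expect_equal(nrow(size_select(reads[0, , drop = FALSE])), 0L)
})

test_that("the full simulation keeps its bookkeeping invariants", {
  cs <- c(chrA = 60000L, chrB = 40000L)
  sim <- simulate_clip(cs, n_fragments = 2e4, n_regions = 10,
                       n_bg_regions = 3, seed = 68)
  # truth labels partition the reads
  expect_true(all(sim$reads$origin %in% c("target", "background", "noise")))
  # every at-crosslink target read start coincides with a truth crosslink
  tgt <- sim$reads[sim$reads$origin == "target" &
                     sim$reads$trunc == "at_crosslink", ]
  key_cl <- paste(sim$crosslinks$chrom, sim$crosslinks$strand,
                  sim$crosslinks$pos)
  expect_true(all(paste(tgt$chrom, tgt$strand, tgt$pos) %in% key_cl))
  # crosslink positions lie inside their regions
  for (r in seq_len(nrow(sim$crosslinks))) {
    reg <- sim$regions[sim$regions$region == sim$crosslinks$region[r], ]
    expect_true(sim$crosslinks$pos[r] >= reg$start &&
                  sim$crosslinks$pos[r] < reg$end)
  }
  # tracks tally the reads exactly
  expect_equal(sum(vapply(sim$tracks, function(tr) sum(tr$counts),
                          numeric(1))), nrow(sim$reads))
  # determinism under a fixed seed
  sim2 <- simulate_clip(cs, n_fragments = 2e4, n_regions = 10,
                        n_bg_regions = 3, seed = 68)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$crosslinks, sim2$crosslinks)
})

test_that("noise reads appear at the configured fraction", {
  cs <- c(chrA = 80000L)
  # wide size window so no noise read is lost to size selection
  cfg <- sim_config(noise_fraction = 0.01, size_min = 1L, size_max = 10000L)
  sim <- simulate_clip(cs, n_fragments = 1e5, n_regions = 5,
                       cfg = cfg, seed = 69)
  expect_equal(sum(sim$reads$origin == "noise"), 1000L)
  # a pure target dataset has no background and no noise
  cfg0 <- sim_config(noise_fraction = 0)
  sim0 <- simulate_clip(cs, n_fragments = 1e4, n_regions = 5,
                        cfg = cfg0, seed = 70)
  expect_true(all(sim0$reads$origin == "target"))
})

test_that("emitted files round-trip through read-start extraction", {
  cs <- c(chrA = 50000L, chrB = 30000L)
  sim <- simulate_clip(cs, n_fragments = 1e4, n_regions = 8, seed = 71)
  prefix <- file.path(tempfile("sim"), "run")
  dir.create(dirname(prefix))
  paths <- emit_sim(sim, prefix)
  # bedGraph round-trip
  back <- tracks_from_bedgraph(paths$bedgraph[["+"]],
                               paths$bedgraph[["-"]], cs)
  for (key in names(sim$tracks))
    expect_equal(back[[key]]$counts, sim$tracks[[key]]$counts)
  # SAM -> BAM -> extraction reproduces the in-memory tracks
  bam <- Rsamtools::asBam(paths$sam, sub("\\.sam$", "", paths$sam),
                          overwrite = TRUE, indexDestination = TRUE)
  extracted <- extract_read_starts(bam, cs)
  for (key in names(sim$tracks))
    expect_equal(extracted[[key]]$counts, sim$tracks[[key]]$counts)
  # truth crosslinks lie inside truth regions (as written to BED)
  cl <- read.table(paths$crosslinks, sep = "\t")
  reg <- read.table(paths$regions, sep = "\t")
  for (i in seq_len(nrow(cl))) {
    rr <- reg[reg$V4 == cl$V4[i], ]
    expect_true(any(cl$V2[i] >= rr$V2 & cl$V3[i] <= rr$V3))
  }
  expect_true(file.exists(paths$manifest))
})
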
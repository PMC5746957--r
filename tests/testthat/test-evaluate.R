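# Evaluation statistics against brute-force matching oracles.

test_that("motif-anchored precision classifies by distance to motif starts", {
  motifs <- data.frame(chrom = "c1", start = c(100L, 200L), strand = "+")
  sites <- data.frame(chrom = "c1", pos = c(100L, 102L, 203L, 150L),
                      strand = "+", score = c(5, 4, 3, 2))
  curve <- precision_vs_motif(sites, motifs, tol = 2)
  # at the loosest threshold: 100 (d=0) and 102 (d=2) are TP; 203 (d=3)
  # and 150 are FP
  expect_equal(tail(curve$n_called, 1), 4L)
  expect_equal(tail(curve$n_tp, 1), 2L)
  expect_equal(tail(curve$precision, 1), 0.5)
  # perfect calls: precision 1 at every threshold
  perfect <- data.frame(chrom = "c1", pos = c(100L, 200L), strand = "+",
                        score = c(2, 1))
  expect_true(all(precision_vs_motif(perfect, motifs)$precision == 1))
  expect_error(precision_vs_motif(sites, motifs[0, , drop = FALSE]),
               "empty")
  # strand-aware brute force on random instances
  withr::with_seed(81, {
    ms <- data.frame(chrom = sample(c("c1", "c2"), 40, TRUE),
                     start = sample(0:500, 40), strand = sample(c("+", "-"), 40, TRUE))
    ss <- data.frame(chrom = sample(c("c1", "c2"), 200, TRUE),
                     pos = sample(0:500, 200, TRUE),
                     strand = sample(c("+", "-"), 200, TRUE),
                     score = runif(200))
  })
  curve_r <- precision_vs_motif(ss, ms, tol = 2)
  brute_tp <- sum(vapply(seq_len(nrow(ss)), function(i) {
    d <- abs(ss$pos[i] - ms$start[ms$chrom == ss$chrom[i] &
                                    ms$strand == ss$strand[i]])
    length(d) > 0 && min(d) <= 2
  }, logical(1)))
  expect_equal(tail(curve_r$n_tp, 1), brute_tp)
})

test_that("splice-site positioning uses the strand-aware 7-15 nt window", {
  ss <- data.frame(chrom = "c1", pos = 1000L, strand = "+")
  sites <- data.frame(chrom = "c1",
                      pos = 1000L - c(11L, 7L, 15L, 6L, 16L),
                      strand = "+", score = 5:1)
  curve <- precision_vs_splice_sites(sites, ss)
  expect_equal(tail(curve$n_tp, 1), 3L)       # 11, 7 and 15 nt upstream
  # minus strand: upstream means larger coordinates
  ssm <- data.frame(chrom = "c1", pos = 1000L, strand = "-")
  sm <- data.frame(chrom = "c1", pos = c(1011L, 989L), strand = "-",
                   score = c(2, 1))
  curve_m <- precision_vs_splice_sites(sm, ssm)
  expect_equal(tail(curve_m$n_tp, 1), 1L)
})

test_that("simulation precision/recall matches exact-position truth", {
  truth <- list(
    crosslinks = data.frame(chrom = "c1", pos = c(50L, 60L, 70L),
                            strand = "+", region = c(1L, 1L, 2L)),
    regions = data.frame(chrom = "c1", start = c(45L, 65L),
                         end = c(62L, 75L), strand = "+",
                         region = c(1L, 2L)))
  # calls identical to the truth: everything is 1
  calls <- data.frame(chrom = "c1", pos = c(50L, 60L, 70L), strand = "+",
                      score = c(3, 2, 1))
  pr <- sim_precision_recall(calls, truth)
  expect_equal(tail(pr$site_curve$precision, 1), 1)
  expect_equal(tail(pr$site_curve$recall, 1), 1)
  expect_equal(tail(pr$region_curve$precision, 1), 1)
  expect_equal(tail(pr$region_curve$recall, 1), 1)
  # one nucleotide off and outside any region: both levels count a FP
  off <- data.frame(chrom = "c1", pos = 41L, strand = "+", score = 1)
  pr_off <- sim_precision_recall(off, truth)
  expect_equal(tail(pr_off$site_curve$precision, 1), 0)
  expect_equal(tail(pr_off$region_curve$precision, 1), 0)
  # random call sets against brute-force matching
  withr::with_seed(82, {
    rc <- data.frame(chrom = "c1", pos = sample(40:80, 30, TRUE),
                     strand = "+", score = runif(30))
  })
  pr_r <- sim_precision_recall(rc, truth)
  brute_site <- sum(rc$pos %in% truth$crosslinks$pos)
  brute_reg <- sum(vapply(rc$pos, function(p)
    any(p >= truth$regions$start & p < truth$regions$end), logical(1)))
  expect_equal(tail(pr_r$site_curve$n_tp, 1), brute_site)
  expect_equal(tail(pr_r$region_curve$n_tp, 1), brute_reg)
})

test_that("replicate agreement counts exact-position overlap in top-x sets", {
  rep1 <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L, 40L),
                     strand = "+", score = c(4, 3, 2, 1))
  # identical replicates, no filters: agreement 1 everywhere (flagged raw)
  expect_warning(agr <- replicate_agreement(rep1, rep1), "raw")
  expect_true(all(agr$agreement == 1))
  # disjoint replicates: zero
  rep2 <- data.frame(chrom = "c1", pos = c(15L, 25L, 35L, 45L),
                     strand = "+", score = c(4, 3, 2, 1))
  expect_warning(agr0 <- replicate_agreement(rep1, rep2), "raw")
  expect_true(all(agr0$agreement == 0))
  # brute-force per-x set intersection on random replicates
  withr::with_seed(83, {
    r1 <- data.frame(chrom = "c1", pos = sample(0:200, 50), strand = "+",
                     score = runif(50))
    r2 <- data.frame(chrom = "c1", pos = sample(0:200, 60), strand = "+",
                     score = runif(60))
  })
  suppressWarnings(agr_r <- replicate_agreement(r1, r2))
  o1 <- r1[order(-r1$score, r1$chrom, r1$pos), ]
  o2 <- r2[order(-r2$score, r2$chrom, r2$pos), ]
  for (x in c(1, 10, 25, 50)) {
    expect_equal(agr_r$agreement[agr_r$x == x],
                 mean(o1$pos[1:x] %in% o2$pos[seq_len(min(x, 60))]))
  }
})

test_that("replicate-agreement bias filters exclude the right sites", {
  rep1 <- data.frame(chrom = "c1", pos = c(10L, 300L, 600L, 900L),
                     strand = "+", score = c(4, 3, 2, 1))
  rep2 <- rep1
  # background region at [250, 350) pre-extended by 200 swallows pos 300;
  # a CL motif at [598, 604) swallows pos 600
  bg <- data.frame(chrom = "c1", start = 250L, end = 350L)
  cl <- data.frame(chrom = "c1", start = 598L, end = 604L)
  enr <- c(2, 2, 2, -5)                    # pos 900 fails the quantile filter
  agr <- replicate_agreement(rep1, rep2, enrichment = enr,
                             enrichment_quantile = 0.5,
                             background = bg, cl_motifs = cl)
  # only pos 10 survives the filters and it is present in rep2
  expect_equal(nrow(agr), 1L)
  expect_equal(agr$agreement, 1)
  expect_true(attr(agr, "corrected"))
})
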
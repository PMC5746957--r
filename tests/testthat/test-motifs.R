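# CL-motif score track construction: discovery windows, MEME parsing,
# PWM scanning with exact null p-values, FIMO ingestion, best-score
# reduction.

meme_fixture <- function(rows, id = "M1", bg = rep(0.25, 4)) {
  path <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    sprintf("A %.4f C %.4f G %.4f T %.4f", bg[1], bg[2], bg[3], bg[4]),
    "",
    paste("MOTIF", id),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 1e-5",
            nrow(rows)),
    apply(rows, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))),
    path)
  path
}

test_that("MEME motif files parse into normalised PWMs", {
  rows <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1), c(0.5, 0.5, 0, 0),
                c(0, 0, 1, 0), c(0, 1, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  motifs <- read_meme_motifs(meme_fixture(rows))
  expect_length(motifs, 1)
  expect_equal(motifs[[1]]$id, "M1")
  expect_equal(dim(motifs[[1]]$pwm), c(4L, 6L))
  expect_equal(colSums(motifs[[1]]$pwm), rep(1, 6), tolerance = 1e-12)
  expect_true(all(motifs[[1]]$pwm > 0))      # pseudocount applied
})

test_that("discovery windows follow the centre +/- 5 / +/- 20 layout", {
  genome <- toy_genome(c(chrM = 2000L), seed = 2)
  sites <- data.frame(chrom = "chrM", pos = 1000L, strand = "+")
  win <- make_dreme_windows(sites, genome)
  expect_equal(as.character(win$positive[[1]]),
               as.character(Biostrings::subseq(genome[["chrM"]], 996, 1005)))
  expect_equal(as.character(win$control[[1]]),
               as.character(Biostrings::subseq(genome[["chrM"]], 976, 985)))
  expect_equal(as.character(win$control[[2]]),
               as.character(Biostrings::subseq(genome[["chrM"]], 1016, 1025)))
  # near-edge site is dropped and counted
  win2 <- make_dreme_windows(
    data.frame(chrom = "chrM", pos = 3L, strand = "+"), genome)
  expect_length(win2$positive, 0)
  expect_gte(win2$dropped, 1)
  # minus-strand site: reverse-complemented window
  win3 <- make_dreme_windows(
    data.frame(chrom = "chrM", pos = 50L, strand = "-"), genome)
  expect_equal(as.character(win3$positive[[1]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(genome[["chrM"]], 46, 55))))
})

test_that("PWM scanning finds exact-consensus occurrences with FIMO semantics", {
  # near-deterministic PWM for the 6-mer TTCGAT
  cons <- c("T", "T", "C", "G", "A", "T")
  rows <- t(vapply(cons, function(b) {
    r <- rep(0, 4); r[match(b, c("A", "C", "G", "T"))] <- 1; r
  }, numeric(4)))
  motifs <- read_meme_motifs(meme_fixture(rows), pseudocount = 1e-3)
  seq <- paste0(strrep("A", 40), "TTCGAT", strrep("C", 30), "TTCGAT",
                strrep("G", 18))
  genome <- Biostrings::DNAStringSet(c(chrZ = seq))
  hits <- scan_motifs(motifs, genome, thresh = 1e-3)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(40L, 76L))
  expect_equal(hits$end, c(46L, 82L))
  expect_true(all(hits$strand == "+"))
  # occurrence probability under the background: p-value ~ (1/4)^6 per
  # window (matches the exact null)
  expect_lt(max(hits$pvalue), 1e-3)
  # a uniform PWM scores zero everywhere: no hit passes
  uni <- read_meme_motifs(meme_fixture(matrix(0.25, 6, 4)))
  expect_equal(nrow(scan_motifs(uni, genome, thresh = 0.01)), 0L)
})

test_that("FIMO TSV ingestion reproduces the scanner's own hits", {
  cons_rows <- rbind(c(0, 0, 0, 1), c(0, 0, 0, 1), c(0, 1, 0, 0),
                     c(0, 0, 1, 0))
  motifs <- read_meme_motifs(meme_fixture(cons_rows, id = "TTCG"))
  genome <- Biostrings::DNAStringSet(
    c(c1 = paste0(strrep("A", 25), "TTCG", strrep("A", 25))))
  hits <- scan_motifs(motifs, genome, thresh = 1e-2)
  tsv <- tempfile(fileext = ".tsv")
  write.table(
    data.frame(motif_id = hits$motif_id, motif_alt_id = "",
               sequence_name = hits$chrom, start = hits$start + 1L,
               stop = hits$end, strand = hits$strand, score = hits$score,
               `p-value` = hits$pvalue, `q-value` = NA,
               matched_sequence = "", check.names = FALSE),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_fimo_tsv(tsv)
  cs <- c(c1 = 54L)
  tr1 <- best_score_track(hits, cs)
  tr2 <- best_score_track(back, cs)
  expect_equal(tr1, tr2, tolerance = 1e-9)
})

test_that("best-score reduction takes the position-wise maximum", {
  cs <- c(cQ = 40L)
  hits <- data.frame(chrom = "cQ", start = c(10L, 14L), end = c(20L, 24L),
                     strand = "+", motif = c(1L, 2L), motif_id = c("a", "b"),
                     score = c(5.1, 7.3), pvalue = 1e-3)
  tr <- best_score_track(hits, cs)
  expect_equal(tr$cQ$score[15:20], rep(7.3, 6))    # overlap: higher wins
  expect_equal(tr$cQ$score[11:14], rep(5.1, 4))
  expect_equal(tr$cQ$index[15:20], rep(2L, 6))
  expect_true(all(tr$cQ$score[c(1:10, 25:40)] == 0))
  # no hits: all-zero track
  tr0 <- best_score_track(hits[0, , drop = FALSE], cs)
  expect_true(all(tr0$cQ$score == 0))
  # ties go to the lower motif index
  hits_tie <- data.frame(chrom = "cQ", start = c(5L, 5L), end = c(8L, 8L),
                         strand = "+", motif = c(2L, 1L),
                         motif_id = c("b", "a"), score = 3, pvalue = 1e-3)
  expect_equal(best_score_track(hits_tie, cs)$cQ$index[6:8], rep(1L, 3))

  # brute-force position-wise maximum on random hit sets
  withr::with_seed(51, {
    rh <- data.frame(chrom = "cQ",
                     start = sample(0:30, 25, replace = TRUE))
    rh$end <- rh$start + sample(3:8, 25, replace = TRUE)
    rh$strand <- "+"
    rh$motif <- sample(1:3, 25, replace = TRUE)
    rh$motif_id <- letters[rh$motif]
    rh$score <- round(runif(25, 0.5, 9), 3)
    rh$pvalue <- 1e-3
  })
  tr_r <- best_score_track(rh, cs)
  for (p0 in 0:39) {
    over <- rh[rh$start <= p0 & rh$end > p0, ]
    if (nrow(over) == 0L) {
      expect_equal(tr_r$cQ$score[p0 + 1], 0)
    } else {
      expect_equal(tr_r$cQ$score[p0 + 1], max(over$score))
      expect_equal(tr_r$cQ$index[p0 + 1],
                   min(over$motif[over$score == max(over$score)]))
    }
  }
})
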
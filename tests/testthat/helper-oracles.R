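# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own computational paths.

# Brute-force forward-backward: exhaustive enumeration over all S^T paths.
fb_brute_force <- function(log_emis, trans, init) {
  T <- nrow(log_emis); S <- ncol(log_emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  logp <- apply(paths, 1, function(st) {
    lp <- log(init[st[1]]) + log_emis[1, st[1]]
    if (T > 1)
      for (t in 2:T)
        lp <- lp + log(trans[st[t - 1], st[t]]) + log_emis[t, st[t]]
    lp
  })
  m <- max(logp)
  w <- exp(logp - m)
  loglik <- m + log(sum(w))
  w <- w / sum(w)
  gamma <- matrix(0, T, S)
  for (t in seq_len(T))
    for (s in seq_len(S))
      gamma[t, s] <- sum(w[paths[, t] == s])
  list(gamma = gamma, loglik = loglik)
}

# Zero-truncated binomial pmf by direct enumeration and renormalisation.
ztb_enum <- function(k, n, p) {
  pk <- dbinom(seq_len(n), n, p)
  (pk / sum(pk))[k]
}

# Write a toy SAM file and return the BAM path (via Rsamtools::asBam).
# reads: data.frame with chrom, pos0 (0-based leftmost), len, strand.
toy_bam <- function(reads, chrom_sizes, dir = tempfile("sam")) {
  dir.create(dir)
  sam <- file.path(dir, "toy.sam")
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (chrom in names(chrom_sizes))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_sizes[[chrom]]),
               con)
  o <- order(reads$chrom, reads$pos0)
  writeLines(sprintf("r%03d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                     seq_len(nrow(reads))[o],
                     ifelse(reads$strand == "+", 0L, 16L)[o],
                     reads$chrom[o], reads$pos0[o] + 1L, reads$len[o]),
             con)
  close(con)
  Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# A small random genome as a named DNAStringSet.
toy_genome <- function(sizes, seed = 1) {
  withr::with_seed(seed, {
    seqs <- vapply(sizes, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), "")
  })
  Biostrings::DNAStringSet(setNames(seqs, names(sizes)))
}

# True four-state parameters used by several model-based tests.
toy_true_params <- function(tp = 0.5) {
  list(
    transition = matrix(c(0.95, 0.01, 0.03, 0.01,
                          0.05, 0.85, 0.05, 0.05,
                          0.04, 0.01, 0.90, 0.05,
                          0.02, 0.03, 0.05, 0.90), 4, 4, byrow = TRUE),
    init = rep(0.25, 4),
    emission = clipHMM:::new_emission_params(
      mu = c(2, 6), lambda = c(2, 4), p = c(0.01, 0.2), tp = tp))
}
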
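## iCLIP/eCLIP read simulation with ground truth. The workflow mirrors the
## bench protocol: fragmentation of transcripts (normal fragment lengths),
## planting of binding regions with 1-4 crosslink sites each, pull-down of
## region-overlapping fragments, reverse transcription with truncation at
## crosslink sites (and occasional off-target truncation), and size
## selection. Background-protein regions run through the same machinery with
## per-region randomised rates, and a small fraction of untruncated random
## RNA-seq-like reads is added as noise. A synthetic transcriptome replaces
## real RNA-seq input so the whole method is testable without any download.

#' Simulation configuration
#'
#' Defaults are the protocol-level rates used throughout: fragment lengths
#' Normal(165, 50), truncation probability 0.7, off-target truncation 0.1,
#' size selection keeping fragments of 30-140 nt inclusive, 1-4 crosslink
#' sites per binding region, pull-down rate 1.0 and 1 % random noise reads.
#' Background regions draw per-region pull-down rates from
#' `bg_pull_range` and truncation probabilities from `bg_trunc_range`.
#'
#' @param frag_mean,frag_sd fragment-length distribution (bp).
#' @param pull_down_rate probability a region-overlapping fragment is kept.
#' @param truncation_prob probability the read start moves to a crosslink
#'   site of the overlapped region.
#' @param offtarget_truncation_prob probability of truncation at a random
#'   other in-fragment position.
#' @param size_min,size_max inclusive fragment-length window kept by size
#'   selection.
#' @param max_crosslinks crosslink sites per region are uniform on
#'   `{1, ..., max_crosslinks}`.
#' @param noise_fraction fraction of the fragment pool added as untruncated
#'   noise reads.
#' @param bg_pull_range,bg_trunc_range per-region uniform ranges for
#'   background simulation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(frag_mean = 165, frag_sd = 50,
                       pull_down_rate = 1.0,
                       truncation_prob = 0.7,
                       offtarget_truncation_prob = 0.1,
                       size_min = 30L, size_max = 140L,
                       max_crosslinks = 4L,
                       noise_fraction = 0.01,
                       bg_pull_range = c(0.1, 0.5),
                       bg_trunc_range = c(0.2, 0.7)) {
  cfg <- list(frag_mean = frag_mean, frag_sd = frag_sd,
              pull_down_rate = pull_down_rate,
              truncation_prob = truncation_prob,
              offtarget_truncation_prob = offtarget_truncation_prob,
              size_min = as.integer(size_min),
              size_max = as.integer(size_max),
              max_crosslinks = as.integer(max_crosslinks),
              noise_fraction = noise_fraction,
              bg_pull_range = bg_pull_range,
              bg_trunc_range = bg_trunc_range)
  probs <- c(cfg$pull_down_rate, cfg$truncation_prob,
             cfg$offtarget_truncation_prob, cfg$noise_fraction)
  if (any(probs < 0 | probs > 1))
    stop("sim_config: probabilities must lie in [0, 1]")
  if (cfg$truncation_prob + cfg$offtarget_truncation_prob > 1)
    stop("sim_config: truncation_prob + offtarget_truncation_prob > 1")
  if (cfg$size_min >= cfg$size_max)
    stop("sim_config: size_min must be below size_max")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic transcriptome
#'
#' Places non-overlapping transcripts with log-normal abundances on a toy
#' genome; fragments are later sampled proportional to abundance with
#' uniform start positions inside the transcript. This stands in for
#' aligned RNA-seq data as the fragment-coverage source.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_transcripts number of transcripts.
#' @param len_range transcript length range (uniform).
#' @param abundance_sdlog sd of the log-normal abundance distribution.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `abundance`.
#' @export
synth_transcriptome <- function(chrom_sizes, n_transcripts = 20L,
                                len_range = c(1500L, 4000L),
                                abundance_sdlog = 1) {
  stopifnot(n_transcripts >= 1)
  out <- list()
  occupied <- lapply(chrom_sizes, function(x) cbind(numeric(0), numeric(0)))
  for (i in seq_len(n_transcripts)) {
    for (attempt in 1:200) {
      chrom <- sample(names(chrom_sizes), 1L,
                      prob = as.numeric(chrom_sizes))
      len <- sample(len_range[1]:len_range[2], 1L)
      if (chrom_sizes[[chrom]] <= len) next
      start <- sample.int(chrom_sizes[[chrom]] - len, 1L) - 1L
      occ <- occupied[[chrom]]
      if (nrow(occ) > 0 &&
          any(start < occ[, 2] & start + len > occ[, 1])) next
      occupied[[chrom]] <- rbind(occ, c(start, start + len))
      out[[i]] <- data.frame(chrom = chrom, start = start,
                             end = start + len,
                             strand = sample(c("+", "-"), 1L))
      break
    }
  }
  tx <- do.call(rbind, out)
  tx$abundance <- stats::rlnorm(nrow(tx), meanlog = 0,
                                sdlog = abundance_sdlog)
  tx
}

#' Simulate fragment lengths
#'
#' iid Normal(`frag_mean`, `frag_sd`) rounded to integers, resampled while
#' below 1.
#'
#' @param n number of lengths.
#' @param cfg a [sim_config()].
#' @return integer vector of lengths (all >= 1).
#' @export
fragment_lengths <- function(n, cfg = sim_config()) {
  stopifnot(n >= 1)
  len <- round(stats::rnorm(n, cfg$frag_mean, cfg$frag_sd))
  while (any(len < 1))
    len[len < 1] <- round(stats::rnorm(sum(len < 1), cfg$frag_mean,
                                       cfg$frag_sd))
  as.integer(len)
}

#' Sample a fragment pool from a transcriptome
#'
#' Transcripts are chosen proportional to abundance; fragment lengths come
#' from [fragment_lengths()] (clamped to the transcript) and start positions
#' are uniform within the transcript.
#'
#' @param tx transcriptome data.frame from [synth_transcriptome()].
#' @param n number of fragments.
#' @param cfg a [sim_config()].
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `len`.
#' @export
sample_fragments <- function(tx, n, cfg = sim_config()) {
  ti <- sample.int(nrow(tx), n, replace = TRUE, prob = tx$abundance)
  len <- fragment_lengths(n, cfg)
  txlen <- tx$end[ti] - tx$start[ti]
  len <- pmin(len, txlen)
  slack <- txlen - len
  start <- tx$start[ti] + floor(stats::runif(n) * (slack + 1))
  data.frame(chrom = tx$chrom[ti], start = start, end = start + len,
             strand = tx$strand[ti], len = len)
}

#' Plant binding regions and crosslink sites in a transcriptome
#'
#' Fixed-width regions at random transcript positions with a minimum
#' spacing; within each region the number of crosslink sites is uniform on
#' `{1, ..., max_crosslinks}` and their positions are drawn uniformly
#' without replacement.
#'
#' @param tx transcriptome data.frame.
#' @param n_regions number of binding regions.
#' @param width region width (nt).
#' @param min_spacing minimum start-to-start distance between regions on the
#'   same transcript.
#' @param cfg a [sim_config()].
#' @return list with `regions` (data.frame `chrom`, `start`, `end`,
#'   `strand`, `region`) and `crosslinks` (data.frame `chrom`, `pos`,
#'   `strand`, `region`).
#' @export
plant_binding_regions <- function(tx, n_regions, width = 8L,
                                  min_spacing = 300L, cfg = sim_config()) {
  regions <- list(); crosslinks <- list()
  placed <- data.frame(chrom = character(0), start = numeric(0))
  rid <- 0L
  for (i in seq_len(n_regions)) {
    for (attempt in 1:200) {
      ti <- sample.int(nrow(tx), 1L, prob = tx$abundance)
      lo <- tx$start[ti]; hi <- tx$end[ti] - width
      if (hi <= lo) next
      start <- lo + sample.int(hi - lo, 1L) - 1L
      near <- placed$chrom == tx$chrom[ti] &
        abs(placed$start - start) < min_spacing
      if (any(near)) next
      rid <- rid + 1L
      placed <- rbind(placed,
                      data.frame(chrom = tx$chrom[ti], start = start))
      regions[[rid]] <- data.frame(chrom = tx$chrom[ti], start = start,
                                   end = start + width,
                                   strand = tx$strand[ti], region = rid)
      n_cl <- sample.int(cfg$max_crosslinks, 1L)
      pos <- start + sample.int(width, n_cl) - 1L
      crosslinks[[rid]] <- data.frame(chrom = tx$chrom[ti], pos = sort(pos),
                                      strand = tx$strand[ti], region = rid)
      break
    }
  }
  list(regions = do.call(rbind, regions),
       crosslinks = do.call(rbind, crosslinks))
}

## first overlapping region per fragment (same chrom and strand), 0 if none
.overlap_region <- function(frags, regions) {
  hit <- integer(nrow(frags))
  for (r in seq_len(nrow(regions))) {
    sel <- hit == 0L &
      frags$chrom == regions$chrom[r] &
      frags$strand == regions$strand[r] &
      frags$start < regions$end[r] & frags$end > regions$start[r]
    hit[sel] <- regions$region[r]
  }
  hit
}

#' Pull down region-overlapping fragments
#'
#' Each fragment overlapping a binding region is kept independently with
#' probability `rate`; fragments overlapping no region are never selected
#' here.
#'
#' @param frags fragment data.frame from [sample_fragments()].
#' @param regions binding-region data.frame.
#' @param rate pull-down rate in (0, 1].
#' @return the kept fragments with an added `region` column.
#' @export
pull_down <- function(frags, regions, rate) {
  stopifnot(rate > 0, rate <= 1)
  reg <- .overlap_region(frags, regions)
  sel <- reg > 0L & stats::runif(nrow(frags)) <= rate
  out <- frags[sel, , drop = FALSE]
  out$region <- reg[sel]
  rownames(out) <- NULL
  out
}

#' Reverse transcription: truncation of read starts
#'
#' For each pulled-down fragment, with probability `truncation_prob` the
#' read start moves to a uniformly chosen crosslink site of its region that
#' lies inside the fragment (label `at_crosslink`); with probability
#' `offtarget_truncation_prob` it moves to a uniform other in-fragment
#' position (`off_target`); otherwise it stays at the fragment 5' end
#' (`none`). If the crosslink branch fires but no crosslink of the region
#' lies inside the fragment, the read is left untruncated and labelled
#' `none` (resampling would distort the pull-down fraction).
#'
#' @param frags fragments with a `region` column (from [pull_down()]).
#' @param crosslinks crosslink data.frame (`chrom`, `pos`, `strand`,
#'   `region`).
#' @param cfg a [sim_config()]; `truncation_prob` /
#'   `offtarget_truncation_prob` may be overridden per call.
#' @param truncation_prob,offtarget_truncation_prob optional overrides
#'   (vectors of length 1 or `nrow(frags)`).
#' @return data.frame of reads: fragment columns plus `pos` (the 0-based
#'   read-start position) and `trunc` label.
#' @export
reverse_transcribe <- function(frags, crosslinks, cfg = sim_config(),
                               truncation_prob = NULL,
                               offtarget_truncation_prob = NULL) {
  n <- nrow(frags)
  tp <- rep(if (is.null(truncation_prob)) cfg$truncation_prob
            else truncation_prob, length.out = n)
  op <- rep(if (is.null(offtarget_truncation_prob))
    cfg$offtarget_truncation_prob else offtarget_truncation_prob,
    length.out = n)
  five_prime <- ifelse(frags$strand == "+", frags$start, frags$end - 1L)
  pos <- five_prime
  lab <- rep("none", n)
  u <- stats::runif(n)
  cl_by_region <- split(crosslinks$pos, crosslinks$region)
  for (i in seq_len(n)) {
    if (u[i] < tp[i]) {
      cl <- cl_by_region[[as.character(frags$region[i])]]
      cl <- cl[cl >= frags$start[i] & cl < frags$end[i]]
      if (length(cl) > 0L) {
        pos[i] <- if (length(cl) == 1L) cl else sample(cl, 1L)
        lab[i] <- "at_crosslink"
      }
    } else if (u[i] < tp[i] + op[i]) {
      cand <- setdiff(frags$start[i]:(frags$end[i] - 1L), five_prime[i])
      if (length(cand) > 0L) {
        pos[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
        lab[i] <- "off_target"
      }
    }
  }
  out <- frags
  out$pos <- pos
  out$trunc <- lab
  out
}

#' Size selection
#'
#' Keeps reads whose underlying fragment length lies between `size_min` and
#' `size_max` inclusive.
#'
#' @param reads read data.frame with a `len` column.
#' @param cfg a [sim_config()].
#' @return the retained reads.
#' @export
size_select <- function(reads, cfg = sim_config()) {
  out <- reads[reads$len >= cfg$size_min & reads$len <= cfg$size_max, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full iCLIP/eCLIP simulation
#'
#' Orchestrates the protocol steps for the target signal, the
#' background-protein signal (same machinery, per-region randomised
#' pull-down and truncation rates) and the random noise reads, then tallies
#' read starts into per-(chromosome, strand) tracks. A single RNG stream is
#' used; the draw order is: transcriptome, target regions, fragment pool,
#' target pull-down/truncation, background regions, background
#' pull-down/truncation, noise sampling.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_fragments size of the RNA fragment pool.
#' @param n_regions number of target binding regions.
#' @param n_bg_regions number of background-protein regions (0 for a pure
#'   target dataset).
#' @param cfg a [sim_config()].
#' @param tx optional pre-built transcriptome (then no transcriptome draw).
#' @param seed optional integer seed.
#' @return object of class `clip_sim`: `reads` (with `origin` and `trunc`
#'   labels), `regions`, `crosslinks`, `bg_regions`, `tracks`, `tx`, `cfg`.
#' @export
simulate_clip <- function(chrom_sizes, n_fragments = 5e4, n_regions = 30L,
                          n_bg_regions = 0L, cfg = sim_config(), tx = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tx)) tx <- synth_transcriptome(chrom_sizes)
  planted <- plant_binding_regions(tx, n_regions, cfg = cfg)
  frags <- sample_fragments(tx, n_fragments, cfg)

  pulled <- pull_down(frags, planted$regions, cfg$pull_down_rate)
  target <- reverse_transcribe(pulled, planted$crosslinks, cfg)
  target <- size_select(target, cfg)
  if (nrow(target) > 0L) target$origin <- "target"

  bg_regions <- NULL
  bg <- NULL
  if (n_bg_regions > 0L) {
    bg_planted <- plant_binding_regions(tx, n_bg_regions, cfg = cfg)
    # avoid region-id collisions and flag overlaps with target regions
    bg_planted$regions$region <- bg_planted$regions$region + n_regions
    bg_planted$crosslinks$region <- bg_planted$crosslinks$region + n_regions
    ov <- .overlap_region(bg_planted$regions, planted$regions)
    bg_planted$regions$overlaps_target <- ov > 0L
    bg_regions <- bg_planted$regions
    rates <- stats::runif(n_bg_regions, cfg$bg_pull_range[1],
                          cfg$bg_pull_range[2])
    truncs <- stats::runif(n_bg_regions, cfg$bg_trunc_range[1],
                           cfg$bg_trunc_range[2])
    reg_hit <- .overlap_region(frags, bg_planted$regions)
    keep <- reg_hit > 0L &
      stats::runif(nrow(frags)) <= rates[pmax(reg_hit - n_regions, 1L)]
    bgf <- frags[keep, , drop = FALSE]
    bgf$region <- reg_hit[keep]
    bg <- reverse_transcribe(bgf, bg_planted$crosslinks, cfg,
                             truncation_prob =
                               truncs[bgf$region - n_regions])
    bg <- size_select(bg, cfg)
    if (nrow(bg) > 0L) bg$origin <- "background"
  }

  noise <- NULL
  n_noise <- round(cfg$noise_fraction * n_fragments)
  if (n_noise > 0L) {
    ni <- sample.int(n_fragments, n_noise)
    noise <- frags[ni, , drop = FALSE]
    noise$region <- 0L
    noise$pos <- ifelse(noise$strand == "+", noise$start, noise$end - 1L)
    noise$trunc <- "none"
    noise <- size_select(noise, cfg)
    if (nrow(noise) > 0L) noise$origin <- "noise"
  }

  reads <- do.call(rbind, Filter(Negate(is.null), list(target, bg, noise)))
  rownames(reads) <- NULL

  tracks <- list()
  for (chrom in names(chrom_sizes)) {
    for (st in c("+", "-")) {
      sel <- reads$chrom == chrom & reads$strand == st
      counts <- as.numeric(tabulate(reads$pos[sel] + 1L,
                                    nbins = chrom_sizes[[chrom]]))
      tracks[[track_key(chrom, st)]] <- read_start_track(chrom, st, counts)
    }
  }
  structure(list(reads = reads, regions = planted$regions,
                 crosslinks = planted$crosslinks, bg_regions = bg_regions,
                 tracks = tracks, tx = tx, cfg = cfg,
                 chrom_sizes = chrom_sizes, seed = seed),
            class = "clip_sim")
}

#' @export
print.clip_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "<clip_sim> %d reads (%s), %d target regions, %d crosslink sites\n"),
    nrow(x$reads),
    paste(names(table(x$reads$origin)), table(x$reads$origin),
          sep = ": ", collapse = ", "),
    nrow(x$regions), nrow(x$crosslinks)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits per-strand read-start bedGraph tracks, truth BED files (binding
#' regions and crosslink sites), a plain-text SAM file of the simulated
#' reads (all-match CIGAR, suitable for `samtools`/`asBam` conversion) and a
#' JSON manifest echoing the configuration. The bedGraph tracks are
#' identical to what [extract_read_starts()] produces from the equivalent
#' BAM.
#'
#' @param sim a `clip_sim` object.
#' @param prefix output path prefix.
#' @return invisibly, a named list of the written paths.
#' @export
emit_sim <- function(sim, prefix) {
  paths <- list()
  paths$bedgraph <- write_bedgraph(sim$tracks, prefix, what = "counts")
  reg_bed <- paste0(prefix, ".regions.bed")
  utils::write.table(
    data.frame(sim$regions$chrom, sim$regions$start, sim$regions$end,
               paste0("region_", sim$regions$region), 0,
               sim$regions$strand),
    reg_bed, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  paths$regions <- reg_bed
  cl_bed <- paste0(prefix, ".crosslinks.bed")
  utils::write.table(
    data.frame(sim$crosslinks$chrom, sim$crosslinks$pos,
               sim$crosslinks$pos + 1L,
               paste0("region_", sim$crosslinks$region), 0,
               sim$crosslinks$strand),
    cl_bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths$crosslinks <- cl_bed
  paths$sam <- write_sim_sam(sim, paste0(prefix, ".sam"))
  manifest <- paste0(prefix, ".manifest.json")
  jsonlite::write_json(
    list(config = unclass(sim$cfg), chrom_sizes = as.list(sim$chrom_sizes),
         n_reads = nrow(sim$reads), seed = sim$seed),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$manifest <- manifest
  invisible(paths)
}

#' Write simulated reads as a SAM file
#'
#' Reads span from the read-start position to the 3' end of the underlying
#' fragment (all-match CIGAR); only the 5'-most base position is meaningful
#' for downstream read-start extraction.
#'
#' @param sim a `clip_sim` object.
#' @param path output SAM path.
#' @return invisibly, `path`.
#' @export
write_sim_sam <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (chrom in names(sim$chrom_sizes))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom,
                       sim$chrom_sizes[[chrom]]), con)
  r <- sim$reads
  plus <- r$strand == "+"
  rlen <- ifelse(plus, pmax(r$end - r$pos, 1L), pmax(r$pos - r$start + 1L, 1L))
  aln_start <- ifelse(plus, r$pos, r$pos - rlen + 1L)    # 0-based
  o <- order(r$chrom, aln_start)
  lines <- sprintf("read%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                   seq_len(nrow(r))[o], ifelse(plus, 0L, 16L)[o],
                   r$chrom[o], aln_start[o] + 1L, rlen[o])
  writeLines(lines, con)
  invisible(path)
}
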
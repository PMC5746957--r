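## Observed-signal layer: per-(chromosome, strand) read-start count tracks,
## kernel-smoothed pulled-down fragment densities, surrogate trial counts and
## the decomposition of the genome into covered intervals. All coordinates are
## 0-based half-open internally; BED/bedGraph conversion happens at the I/O
## boundary.

#' Construct a read-start count track
#'
#' A track holds, for one chromosome and one strand, the number of reads whose
#' truncation-indicating end maps to each position. In iCLIP/eCLIP the
#' reverse transcriptase frequently stops at the protein-RNA crosslink, so
#' pile-ups of read 5' ends mark crosslink sites at nucleotide resolution.
#'
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param counts non-negative integer vector, one entry per position
#'   (position `p`, 0-based, is `counts[p + 1]`).
#' @return an object of class `read_start_track`.
#' @export
read_start_track <- function(chrom, strand, counts) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            strand %in% c("+", "-"),
            is.numeric(counts), all(counts >= 0))
  structure(list(chrom = chrom, strand = strand, counts = as.numeric(counts)),
            class = "read_start_track")
}

#' @export
print.read_start_track <- function(x, ...) {
  cat(sprintf("<read_start_track> %s(%s): %d positions, %s read starts\n",
              x$chrom, x$strand, length(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

track_key <- function(chrom, strand) paste0(chrom, ":", strand)

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with chromosome name and length.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$size, tab$chrom)
}

#' Extract per-position read-start counts from a BAM file
#'
#' Tallies, per chromosome and strand, the positions of the
#' truncation-indicating read ends. For iCLIP-style data this is the 5' end of
#' the (single-end) read; for eCLIP the second mate of the pair corresponds to
#' the 3' end of the sequenced fragment and its 5' end marks the truncation,
#' selected with `which_end = "mate_three_prime"`. No upstream shift is
#' applied: the model calls the truncation-accumulation position itself.
#'
#' Unmapped, secondary and supplementary records are skipped (tallied in the
#' `skipped` attribute). Alignments on chromosomes absent from `chrom_sizes`
#' are an error.
#'
#' @param bam path to a coordinate-sorted, indexed, deduplicated BAM file.
#' @param chrom_sizes named vector of chromosome lengths
#'   (see [read_chrom_sizes()]).
#' @param which_end `"five_prime"` (iCLIP, use every read) or
#'   `"mate_three_prime"` (eCLIP, use only second-in-pair mates).
#' @return named list of [read_start_track()] objects keyed `"chrom:strand"`.
#' @export
extract_read_starts <- function(bam, chrom_sizes,
                                which_end = c("five_prime", "mate_three_prime")) {
  which_end <- match.arg(which_end)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isSecondMateRead = if (which_end == "mate_three_prime") TRUE else NA)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag))
  # records dropped by the flag filter
  n_total <- Rsamtools::countBam(bam)$records
  skipped <- n_total - length(ga)

  chroms <- as.character(GenomicAlignments::seqnames(ga))
  unknown <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(unknown) > 0L)
    stop("alignments on chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  strand <- as.character(GenomicAlignments::strand(ga))
  if (any(strand == "*"))
    stop("alignments without strand information are not supported")
  # 5'-most mapped base: start on '+', end on '-' (1-based -> 0-based)
  pos0 <- ifelse(strand == "+",
                 GenomicAlignments::start(ga) - 1L,
                 GenomicAlignments::end(ga) - 1L)

  tracks <- list()
  for (chrom in names(chrom_sizes)) {
    for (st in c("+", "-")) {
      sel <- chroms == chrom & strand == st
      counts <- numeric(chrom_sizes[[chrom]])
      if (any(sel)) {
        tab <- tabulate(pos0[sel] + 1L, nbins = chrom_sizes[[chrom]])
        counts <- as.numeric(tab)
      }
      tracks[[track_key(chrom, st)]] <- read_start_track(chrom, st, counts)
    }
  }
  attr(tracks, "skipped") <- skipped
  tracks
}

#' Read read-start count tracks from a pair of bedGraph files
#'
#' One file per strand, one line per nonzero position (or run of positions).
#'
#' @param plus_file,minus_file bedGraph paths; either may be `NULL`.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return named list of [read_start_track()] objects.
#' @export
tracks_from_bedgraph <- function(plus_file, minus_file, chrom_sizes) {
  tracks <- list()
  for (chrom in names(chrom_sizes)) {
    for (st in c("+", "-")) {
      tracks[[track_key(chrom, st)]] <-
        read_start_track(chrom, st, numeric(chrom_sizes[[chrom]]))
    }
  }
  fill <- function(file, st) {
    gr <- rtracklayer::import(file, format = "bedGraph")
    chroms <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(chroms), names(chrom_sizes))
    if (length(unknown) > 0L)
      stop("bedGraph chromosome(s) absent from chrom_sizes: ",
           paste(unknown, collapse = ", "))
    for (i in seq_along(gr)) {
      key <- track_key(chroms[i], st)
      idx <- GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]  # 1-based
      tracks[[key]]$counts[idx] <<- gr$score[i]
    }
  }
  if (!is.null(plus_file)) fill(plus_file, "+")
  if (!is.null(minus_file)) fill(minus_file, "-")
  tracks
}

#' Write per-strand bedGraph files for a set of tracks
#'
#' @param tracks list of tracks (read-start or density), each with `chrom`,
#'   `strand` and a numeric vector named by `what`.
#' @param prefix output path prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @param what name of the per-position field to export (`"counts"` or
#'   `"density"`).
#' @return invisibly, the two file paths.
#' @export
write_bedgraph <- function(tracks, prefix, what = "counts") {
  paths <- c(`+` = paste0(prefix, ".plus.bedgraph"),
             `-` = paste0(prefix, ".minus.bedgraph"))
  chroms <- unique(vapply(tracks, `[[`, "", "chrom"))
  for (st in c("+", "-")) {
    rows <- list()
    for (tr in tracks) {
      if (tr$strand != st) next
      v <- tr[[what]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tr$chrom, start = starts[keep], end = ends[keep],
        score = r$values[keep])
    }
    tab <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), score = numeric(0))
    gr <- GenomicRanges::GRanges(
      factor(tab$chrom, levels = chroms),
      IRanges::IRanges(tab$start, tab$end), score = tab$score)
    rtracklayer::export(gr, paths[[st]], format = "bedGraph")
  }
  invisible(paths)
}

#' Kernel-smoothed pulled-down fragment density
#'
#' Position-wise read counts in truncation-based CLIP data are dominated by
#' truncation pile-ups, so local fragment coverage is instead estimated by a
#' Gaussian kernel density over the read-start counts:
#' `c_t = (1/h) * sum_{i = t-4h}^{t+4h} k_i * K((t - i)/h)` with `K` the
#' standard normal density. Positions beyond the chromosome contribute zero;
#' the kernel is truncated at four bandwidths, losing < 1e-4 of the mass.
#'
#' @param track a [read_start_track()].
#' @param h kernel bandwidth in positions (integer >= 1; default 50).
#' @return a `fragment_density_track`: the input track plus a `density`
#'   numeric vector and the bandwidth `h`.
#' @export
kde_smooth <- function(track, h = 50L) {
  stopifnot(inherits(track, "read_start_track") || is.list(track),
            h >= 1, h == round(h))
  k <- track$counts
  L <- length(k)
  r <- 4L * as.integer(h)
  kern <- stats::dnorm((-r):r / h) / h
  if (L == 0L) {
    dens <- numeric(0)
  } else if (sum(k) == 0) {
    dens <- numeric(L)
  } else {
    # full (zero-padded) convolution, trimmed to the chromosome
    full <- stats::convolve(k, kern, type = "open")
    dens <- full[(r + 1L):(r + L)]
    dens[dens < 0] <- 0  # FFT round-off can produce tiny negatives
  }
  out <- track
  out$density <- dens
  out$h <- as.integer(h)
  class(out) <- c("fragment_density_track", "read_start_track")
  out
}

#' @export
print.fragment_density_track <- function(x, ...) {
  cat(sprintf(
    "<fragment_density_track> %s(%s): %d positions, h = %d, max density %.3g\n",
    x$chrom, x$strand, length(x$counts), x$h,
    if (length(x$density)) max(x$density) else 0))
  invisible(x)
}

#' Surrogate trial counts from the fragment density
#'
#' The number of fragments overlapping a position (the binomial trial count of
#' the read-start model) is not directly observed; it is approximated by
#' rescaling the smoothed density: `n_hat_t = max(k_t, round(c_t * s))`.
#' Because the kernel conserves mass, `c_t` is a per-position read-start rate
#' and multiplying by the bandwidth approximates the number of fragments
#' contributing locally. Flooring at the observed count keeps the
#' zero-truncated binomial well defined (`k <= n_hat`).
#'
#' @param track a `fragment_density_track` from [kde_smooth()].
#' @param rescale rescale factor `s`; defaults to the track's bandwidth.
#' @return the track with an added integer vector `n_hat`.
#' @export
derive_n_hat <- function(track, rescale = NULL) {
  stopifnot(inherits(track, "fragment_density_track"))
  s <- if (is.null(rescale)) track$h else rescale
  track$n_hat <- pmax(track$counts, round(track$density * s))
  track$rescale <- s
  track
}

#' Decompose a density track into covered intervals
#'
#' Positions with density above the truncation point `tp` are grouped into
#' maximal runs; runs separated by a gap shorter than `min_gap` are merged.
#' Each interval is processed as an independent HMM chain. Provided
#' `tp < min(density at positions with a read start)`, every position with at
#' least one read start lies inside some interval.
#'
#' @param track a `fragment_density_track`.
#' @param tp density threshold (the left-truncation point of the gamma
#'   emission).
#' @param min_gap gaps strictly shorter than this are merged.
#' @return data.frame with 0-based half-open `start`, `end` per interval.
#' @export
covered_intervals <- function(track, tp, min_gap = 1L) {
  stopifnot(tp >= 0)
  above <- track$density > tp
  if (!any(above)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(above)
  ends1 <- cumsum(r$lengths)            # 1-based inclusive
  starts1 <- ends1 - r$lengths + 1L
  starts1 <- starts1[r$values]
  ends1 <- ends1[r$values]
  # merge runs whose separating gap is < min_gap
  if (length(starts1) > 1L && min_gap > 0L) {
    out_s <- integer(0); out_e <- integer(0)
    cur_s <- starts1[1L]; cur_e <- ends1[1L]
    for (i in 2L:length(starts1)) {
      gap <- starts1[i] - cur_e - 1L
      if (gap < min_gap) {
        cur_e <- ends1[i]
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        cur_s <- starts1[i]; cur_e <- ends1[i]
      }
    }
    out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
    starts1 <- out_s; ends1 <- out_e
  }
  data.frame(start = starts1 - 1L, end = ends1)   # 0-based half-open
}

#' Truncation point of the fragment-density emission
#'
#' The left-truncated gamma is fitted only to positions carrying at least one
#' read start; its truncation point is fixed ahead of EM at just below the
#' minimum density observed at such positions (a one-sided relative nudge of
#' 1e-6 keeps all of them strictly inside the open support).
#'
#' @param tracks list of `fragment_density_track` objects.
#' @return scalar truncation point.
#' @export
density_truncation_point <- function(tracks) {
  mins <- vapply(tracks, function(tr) {
    sel <- tr$counts >= 1
    if (!any(sel)) return(Inf)
    min(tr$density[sel])
  }, numeric(1))
  m <- min(mins)
  if (!is.finite(m)) stop("no position with a read start in any track")
  m * (1 - 1e-6)
}
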
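## Evaluation statistics: motif-anchored precision, 3'-splice-site
## positioning precision, simulation precision/recall and bias-corrected
## replicate agreement. All curves are computed over descending score
## thresholds with ties in score broken by (chrom, pos) for stable top-x
## sets.

order_sites <- function(sites) {
  sites[order(-sites$score, sites$chrom, sites$pos), , drop = FALSE]
}

precision_curve <- function(sites, is_tp) {
  o <- order(-sites$score, sites$chrom, sites$pos)
  sc <- sites$score[o]
  tp <- cumsum(is_tp[o])
  called <- seq_along(sc)
  # collapse ties: one curve point per distinct threshold (closed threshold)
  last <- !duplicated(sc, fromLast = TRUE)
  data.frame(threshold = sc[last], n_called = called[last],
             n_tp = tp[last], precision = tp[last] / called[last])
}

#' Precision of called sites against motif occurrences
#'
#' A called site is a true positive if its distance to the closest motif
#' start position (same strand) is at most `tol` (default 2 nt). Returns
#' the precision curve over descending score thresholds.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `strand`, `score`.
#' @param motifs data.frame of motif occurrences with `chrom`, `start`
#'   (0-based), `strand`.
#' @param tol maximum distance (nt).
#' @return data.frame with `threshold`, `n_called`, `n_tp`, `precision`.
#' @export
precision_vs_motif <- function(sites, motifs, tol = 2L) {
  if (nrow(motifs) == 0L) stop("precision_vs_motif: empty motif set")
  is_tp <- logical(nrow(sites))
  for (gr in split(seq_len(nrow(sites)),
                   paste(sites$chrom, sites$strand))) {
    key <- paste(sites$chrom[gr[1]], sites$strand[gr[1]])
    ms <- motifs$start[paste(motifs$chrom, motifs$strand) == key]
    if (length(ms) == 0L) next
    ms <- sort(ms)
    p <- sites$pos[gr]
    i <- findInterval(p, ms)
    d_lo <- ifelse(i >= 1L, p - ms[pmax(i, 1L)], Inf)
    d_hi <- ifelse(i < length(ms), ms[pmin(i + 1L, length(ms))] - p, Inf)
    is_tp[gr] <- pmin(d_lo, d_hi) <= tol
  }
  precision_curve(sites, is_tp)
}

#' Precision of called sites against 3' splice sites
#'
#' A called site is a true positive if it lies 11 +/- 4 nt (i.e. 7-15 nt)
#' upstream of a 3' splice site, strand-aware: upstream of a splice site at
#' position `s` means `s - pos` on the plus strand and `pos - s` on the
#' minus strand.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`, `score`.
#' @param splice_sites data.frame with `chrom`, `pos` (0-based position of
#'   the 3' splice site), `strand`.
#' @param window upstream distance window (inclusive).
#' @return precision curve data.frame.
#' @export
precision_vs_splice_sites <- function(sites, splice_sites,
                                      window = c(7L, 15L)) {
  is_tp <- logical(nrow(sites))
  for (r in seq_len(nrow(sites))) {
    ss <- splice_sites[splice_sites$chrom == sites$chrom[r] &
                         splice_sites$strand == sites$strand[r], ]
    if (nrow(ss) == 0L) next
    d <- if (sites$strand[r] == "+") ss$pos - sites$pos[r]
         else sites$pos[r] - ss$pos
    is_tp[r] <- any(d >= window[1] & d <= window[2])
  }
  precision_curve(sites, is_tp)
}

#' Site- and region-level precision/recall against simulation truth
#'
#' Site level: a called crosslink site is a true positive if a target
#' crosslink site was simulated at exactly the same position (chromosome,
#' strand and nucleotide). Region level: a target binding region counts as
#' recovered if it contains at least one called site, and the region-level
#' precision is the fraction of called sites lying inside target binding
#' regions.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`, `score`.
#' @param truth a `clip_sim` object (or list with `crosslinks` and
#'   `regions`).
#' @return list with `site_curve` and `region_curve` precision curves, each
#'   carrying an additional `recall` column (fraction of truth crosslinks /
#'   regions recovered at that threshold).
#' @export
sim_precision_recall <- function(sites, truth) {
  cl_key <- paste(truth$crosslinks$chrom, truth$crosslinks$strand,
                  truth$crosslinks$pos)
  site_key <- paste(sites$chrom, sites$strand, sites$pos)
  site_tp <- site_key %in% cl_key

  in_region <- integer(nrow(sites))   # region id containing each site, 0 if none
  for (r in seq_len(nrow(truth$regions))) {
    sel <- in_region == 0L &
      sites$chrom == truth$regions$chrom[r] &
      sites$strand == truth$regions$strand[r] &
      sites$pos >= truth$regions$start[r] &
      sites$pos < truth$regions$end[r]
    in_region[sel] <- truth$regions$region[r]
  }

  o <- order(-sites$score, sites$chrom, sites$pos)
  sc <- sites$score[o]
  last <- !duplicated(sc, fromLast = TRUE)

  site_curve <- precision_curve(sites, site_tp)
  matched <- ifelse(site_tp[o], site_key[o], NA)
  n_cl_rec <- cumsum(!is.na(matched) & !duplicated(matched))
  site_curve$recall <- (n_cl_rec / length(cl_key))[last]

  region_curve <- precision_curve(sites, in_region > 0L)
  reg_seq <- in_region[o]
  first_hit <- reg_seq > 0L & !duplicated(reg_seq)
  region_curve$recall <-
    (cumsum(first_hit) / nrow(truth$regions))[last]
  list(site_curve = site_curve, region_curve = region_curve)
}

#' Bias-corrected agreement of called sites between replicates
#'
#' For each number of called sites `x` in replicate 1, the fraction of its
#' top-`x` sites (after the bias filters) that are called at exactly the
#' same nucleotide position within the top-`x` sites of replicate 2 (the
#' larger-library reference). Filters, each optional: (1) sufficient
#' enrichment over the input signal, applied as a quantile threshold on the
#' per-site log-fold enrichment; (2) exclusion of common background regions,
#' pre-extended by 200 bp; (3) exclusion of CL-motif occurrences (all
#' matches with a score > 0). With no filters supplied the raw agreement is
#' computed and flagged.
#'
#' @param rep1,rep2 site data.frames (`chrom`, `pos`, `strand`, `score`);
#'   `rep2` should be the larger-library replicate.
#' @param enrichment optional numeric vector of per-site log-fold
#'   enrichment for `rep1` sites (same order), e.g.
#'   `log(target_density / input_density)`.
#' @param enrichment_quantile quantile of `enrichment` below which sites
#'   are excluded (default 0.5).
#' @param background optional data.frame of background regions (`chrom`,
#'   `start`, `end`); they are extended by `extend` on both sides.
#' @param cl_motifs optional data.frame of CL-motif occurrences (`chrom`,
#'   `start`, `end`) with positive scores.
#' @param extend background-region extension (bp).
#' @param x_values site counts at which to evaluate; default every filtered
#'   rep1 site count.
#' @return data.frame with `x` and `agreement`, plus attribute
#'   `"corrected"` (FALSE when no filter was applied).
#' @export
replicate_agreement <- function(rep1, rep2, enrichment = NULL,
                                enrichment_quantile = 0.5,
                                background = NULL, cl_motifs = NULL,
                                extend = 200L, x_values = NULL) {
  corrected <- !is.null(enrichment) || !is.null(background) ||
    !is.null(cl_motifs)
  if (!corrected)
    warning("replicate_agreement: no filter inputs; ",
            "raw (uncorrected) agreement computed")
  keep <- rep(TRUE, nrow(rep1))
  if (!is.null(enrichment)) {
    thr <- stats::quantile(enrichment, enrichment_quantile, na.rm = TRUE)
    keep <- keep & !is.na(enrichment) & enrichment >= thr
  }
  in_any <- function(sites, regions, ext) {
    hit <- logical(nrow(sites))
    for (r in seq_len(nrow(regions))) {
      hit <- hit | (sites$chrom == regions$chrom[r] &
                      sites$pos >= regions$start[r] - ext &
                      sites$pos < regions$end[r] + ext)
    }
    hit
  }
  if (!is.null(background) && nrow(background) > 0L)
    keep <- keep & !in_any(rep1, background, extend)
  if (!is.null(cl_motifs) && nrow(cl_motifs) > 0L)
    keep <- keep & !in_any(rep1, cl_motifs, 0L)

  r1 <- order_sites(rep1[keep, , drop = FALSE])
  r2 <- order_sites(rep2)
  key1 <- paste(r1$chrom, r1$strand, r1$pos)
  key2 <- paste(r2$chrom, r2$strand, r2$pos)
  if (is.null(x_values)) x_values <- seq_len(nrow(r1))
  agreement <- vapply(x_values, function(x) {
    if (x < 1L || nrow(r1) == 0L) return(NA_real_)
    x1 <- min(x, nrow(r1))
    mean(key1[seq_len(x1)] %in% key2[seq_len(min(x, length(key2)))])
  }, numeric(1))
  out <- data.frame(x = x_values, agreement = agreement)
  attr(out, "corrected") <- corrected
  out
}
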
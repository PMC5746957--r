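## The user-facing model: clip_hmm() assembles the observed signals, fixes
## the truncation point, decomposes the genome into covered intervals, runs
## Baum-Welch and returns a classed fit with the usual accessor methods.
## predict() performs posterior decoding into crosslink sites and merged
## binding regions.

#' Fit the crosslink-site HMM
#'
#' Fits the four-state (non-)homogeneous hidden Markov model to
#' read-start-count tracks. Per (chromosome, strand) track the pulled-down
#' fragment density is estimated by Gaussian-kernel smoothing of the read
#' starts, surrogate binomial trial counts are derived by rescaling, the
#' genome is decomposed into independently processed covered intervals, and
#' Baum-Welch (with numerically optimised M-steps) learns the transition
#' matrix and the emission parameters: a left-truncated gamma on the density
#' for the enrichment dimension and a zero-truncated binomial on the counts
#' for the crosslink dimension.
#'
#' Optionally, an input-control experiment turns the enrichment emission
#' into a gamma GLM (log link) on the log input fragment density, and a
#' CL-motif score track turns the crosslink emission into per-motif logistic
#' regressions -- both reduce to the basic model exactly when their
#' coefficients are zero.
#'
#' @param tracks named list of [read_start_track()] objects (keyed
#'   `"chrom:strand"`), e.g. from [extract_read_starts()] or
#'   [simulate_clip()].
#' @param input_tracks optional input-control tracks in the same layout.
#' @param motif_track optional per-chromosome best-motif score track from
#'   [best_score_track()].
#' @param n_motifs number of CL motifs (inferred from `motif_track` when
#'   supplied).
#' @param h kernel bandwidth (positions; default 50).
#' @param rescale surrogate-trial rescale factor; defaults to `h`.
#' @param tp truncation point of the density emission; default: just below
#'   the minimum density at positions with a read start
#'   ([density_truncation_point()]).
#' @param min_gap covered-interval merge gap (see [covered_intervals()]).
#' @param train_chroms optional character vector: learn parameters only on
#'   these chromosomes, then apply transcriptome-wide (default: all).
#' @param max_iter,tol Baum-Welch convergence controls.
#' @param verbose print the EM log-likelihood trace.
#' @return an object of class `clip_hmm`.
#' @seealso [predict.clip_hmm()], [simulate.clip_hmm()], [coef.clip_hmm()]
#' @export
clip_hmm <- function(tracks, input_tracks = NULL, motif_track = NULL,
                     n_motifs = NULL, h = 50L, rescale = NULL, tp = NULL,
                     min_gap = 1L, train_chroms = NULL, max_iter = 50L,
                     tol = 1e-3, verbose = FALSE) {
  stopifnot(length(tracks) >= 1)
  dens <- lapply(tracks, function(tr) derive_n_hat(kde_smooth(tr, h),
                                                   rescale))
  if (is.null(tp)) tp <- density_truncation_point(dens)
  inp <- NULL
  if (!is.null(input_tracks)) {
    inp <- lapply(input_tracks, function(tr)
      input_covariate(kde_smooth(tr, h)))
  }
  if (!is.null(motif_track) && is.null(n_motifs))
    n_motifs <- max(0L, unlist(lapply(motif_track,
                                      function(x) x$index)))

  build_chains <- function(keys) {
    chains <- list()
    meta <- list()
    for (key in keys) {
      tr <- dens[[key]]
      iv <- covered_intervals(tr, tp, min_gap)
      for (r in seq_len(nrow(iv))) {
        ix <- (iv$start[r] + 1L):iv$end[r]          # 1-based slice
        ch <- list(c = tr$density[ix], k = tr$counts[ix],
                   n_hat = tr$n_hat[ix])
        if (!is.null(inp) && key %in% names(inp)) {
          ch$b <- inp[[key]]$b[ix]
          ch$b_mask <- inp[[key]]$mask[ix]
        }
        if (!is.null(motif_track) && tr$chrom %in% names(motif_track)) {
          ch$motif_i <- motif_track[[tr$chrom]]$index[ix]
          ch$motif_x <- motif_track[[tr$chrom]]$score[ix]
        }
        chains[[length(chains) + 1L]] <- ch
        meta[[length(meta) + 1L]] <- list(chrom = tr$chrom,
                                          strand = tr$strand,
                                          start = iv$start[r],
                                          end = iv$end[r])
      }
    }
    list(chains = chains, meta = meta)
  }

  all_keys <- names(dens)
  train_keys <- all_keys
  if (!is.null(train_chroms)) {
    train_keys <- all_keys[vapply(dens, function(tr)
      tr$chrom %in% train_chroms, logical(1))]
    if (length(train_keys) == 0L)
      stop("train_chroms matches no track")
  }
  train <- build_chains(train_keys)
  if (length(train$chains) == 0L)
    stop("no covered interval to train on (is the data empty?)")

  init <- init_hmm_params(train$chains, tp,
                          n_motifs = if (is.null(n_motifs)) 0L else n_motifs)
  par <- baum_welch(train$chains, init, max_iter = max_iter, tol = tol,
                    verbose = verbose)

  full <- if (identical(train_keys, all_keys)) train else
    build_chains(all_keys)

  structure(list(
    params = list(transition = par$transition, init = par$init,
                  emission = par$emission),
    loglik_trace = par$loglik_trace,
    iterations = par$iterations,
    converged = par$converged,
    chains = full$chains,
    chain_meta = full$meta,
    config = list(h = as.integer(h),
                  rescale = if (is.null(rescale)) as.integer(h) else rescale,
                  tp = tp, min_gap = min_gap,
                  train_chroms = train_chroms,
                  max_iter = max_iter, tol = tol,
                  has_input = !is.null(input_tracks),
                  n_motifs = if (is.null(n_motifs)) 0L else n_motifs)),
    class = "clip_hmm")
}

#' @export
print.clip_hmm <- function(x, ...) {
  em <- x$params$emission
  cat("Crosslink-site HMM fit\n")
  cat(sprintf("  chains: %d covered intervals, %s positions\n",
              length(x$chains),
              format(sum(vapply(x$chains, function(ch) length(ch$c),
                                numeric(1))), big.mark = ",")))
  cat(sprintf("  EM: %d iterations, %sconverged, loglik %.2f\n",
              x$iterations, if (x$converged) "" else "NOT ",
              utils::tail(x$loglik_trace, 1)))
  cat(sprintf("  enrichment (LTG): mu = (%.3g, %.3g), lambda = (%.3g, %.3g), tp = %.3g\n",
              exp(em$alpha0[1]), exp(em$alpha0[2]),
              em$lambda[1], em$lambda[2], em$tp))
  cat(sprintf("  crosslink (ZTB): p = (%.3g, %.3g)\n",
              stats::plogis(em$beta0[1]), stats::plogis(em$beta0[2])))
  if (x$config$has_input)
    cat(sprintf("  input GLM slopes: alpha1 = (%.3g, %.3g)\n",
                em$alpha1[1], em$alpha1[2]))
  if (x$config$n_motifs > 0L)
    cat(sprintf("  CL-motif slopes (crosslink state): %s\n",
                paste(signif(em$beta_slopes[2, ], 3), collapse = ", ")))
  invisible(x)
}

#' @export
summary.clip_hmm <- function(object, ...) {
  structure(list(fit = object), class = "summary.clip_hmm")
}

#' @export
print.summary.clip_hmm <- function(x, ...) {
  print(x$fit)
  cat("\nTransition matrix (rows: from, order ne.nc ne.cl en.nc en.cl):\n")
  tm <- x$fit$params$transition
  dimnames(tm) <- list(STATE_LABELS, STATE_LABELS)
  print(round(tm, 4))
  cat("\nLog-likelihood trace:\n")
  print(signif(x$fit$loglik_trace, 8))
  invisible(x)
}

#' Extract fitted HMM parameters
#'
#' @param object a `clip_hmm` fit.
#' @param ... unused.
#' @return named list: LTG means and shapes per enrichment state, ZTB
#'   probabilities per crosslink state, GLM coefficients, motif slopes,
#'   truncation point and the transition matrix.
#' @export
coef.clip_hmm <- function(object, ...) {
  em <- object$params$emission
  list(mu = exp(em$alpha0), lambda = em$lambda,
       p = stats::plogis(em$beta0),
       alpha0 = em$alpha0, alpha1 = em$alpha1,
       beta0 = em$beta0, beta_slopes = em$beta_slopes,
       tp = em$tp, transition = object$params$transition)
}

#' @export
logLik.clip_hmm <- function(object, ...) {
  ll <- utils::tail(object$loglik_trace, 1)
  n_par <- 4 * 3 + 2 * (2 + object$config$has_input) +
    2 * (1 + object$config$n_motifs)
  structure(ll, df = n_par, class = "logLik")
}

#' Call crosslink sites (and binding regions) from a fitted model
#'
#' Runs forward-backward with the fitted parameters over every covered
#' interval, posterior-decodes each position, and returns the positions
#' whose most likely state is enriched + crosslink, scored with the log
#' posterior ratio of the two most likely states. Positions without read
#' starts are never called.
#'
#' @param object a `clip_hmm` fit.
#' @param merge_distance if `> 0` the result carries the merged binding
#'   regions in attribute `"regions"` (default 8).
#' @param ... unused.
#' @return data.frame of sites: `chrom`, `pos` (0-based), `strand`,
#'   `score`, `posterior`, sorted by (chrom, strand, pos).
#' @export
predict.clip_hmm <- function(object, merge_distance = 8L, ...) {
  out <- list()
  for (i in seq_along(object$chains)) {
    ch <- object$chains[[i]]
    meta <- object$chain_meta[[i]]
    le <- log_emission_matrix(ch$c, ch$k, ch$n_hat, object$params$emission,
                              b = ch$b, b_mask = ch$b_mask,
                              motif_i = ch$motif_i, motif_x = ch$motif_x)
    fb <- forward_backward(le, object$params$transition, object$params$init)
    sites <- posterior_decode_and_score(fb$gamma, ch$k)
    if (nrow(sites) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = meta$chrom, pos = meta$start + sites$index - 1L,
      strand = meta$strand, score = sites$score,
      posterior = sites$posterior)
  }
  sites <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = integer(0),
               strand = character(0), score = numeric(0),
               posterior = numeric(0))
  sites <- sites[order(sites$chrom, sites$strand, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  if (merge_distance > 0L)
    attr(sites, "regions") <- merge_sites(sites, merge_distance)
  sites
}

#' Simulate observations from a fitted model
#'
#' Draws a state path from the fitted Markov chain and observations from
#' the fitted emission distributions (basic model; covariate effects are
#' not resimulated).
#'
#' @param object a `clip_hmm` fit.
#' @param nsim number of positions to simulate.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return list with `state`, `c`, `k`, `n_hat` (see
#'   [simulate_hmm_observations()]).
#' @export
simulate.clip_hmm <- function(object, nsim = 1e4, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_hmm_observations(object$params, nsim,
                            rescale = object$config$rescale)
}

#' Plot a fitted crosslink-site HMM
#'
#' Two base-graphics panels: the EM log-likelihood trace and the fitted
#' state-conditional left-truncated gamma densities over the histogram of
#' observed fragment densities at positions with read starts.
#'
#' @param x a `clip_hmm` fit.
#' @param ... passed to `hist()`.
#' @export
plot.clip_hmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
                 xlab = "EM iteration", ylab = "total log-likelihood",
                 main = "EM trace")
  cc <- unlist(lapply(x$chains, function(ch) ch$c[ch$k >= 1]))
  em <- x$params$emission
  graphics::hist(cc, breaks = 60, freq = FALSE,
                 main = "fragment density emissions",
                 xlab = "pulled-down fragment density", ...)
  xs <- seq(em$tp, max(cc), length.out = 400)[-1]
  graphics::lines(xs, exp(ltg_logpdf(xs, exp(em$alpha0[1]), em$lambda[1],
                                     em$tp)), col = "steelblue", lwd = 2)
  graphics::lines(xs, exp(ltg_logpdf(xs, exp(em$alpha0[2]), em$lambda[2],
                                     em$tp)), col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("non-enriched", "enriched"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}

#' Write called sites as BED6+1
#'
#' Column 5 carries the log-posterior-ratio score scaled by 100 and capped
#' at 1000 (browser convention); column 7 repeats the raw score.
#'
#' @param sites data.frame from [predict.clip_hmm()].
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
write_sites_bed <- function(sites, path) {
  bed_score <- pmin(round(sites$score * 100), 1000)
  utils::write.table(
    data.frame(sites$chrom, sites$pos, sites$pos + 1L, "en.cl",
               bed_score, sites$strand, sites$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write merged binding regions as BED6
#'
#' @param regions data.frame from [merge_sites()].
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, regions$start, regions$end,
               paste0("region_", seq_len(nrow(regions))),
               pmin(round(regions$score * 100), 1000), regions$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6(+1) site file back into a site data.frame
#'
#' @param path BED path written by [write_sites_bed()].
#' @return data.frame with `chrom`, `pos`, `strand`, `score`.
#' @export
read_sites_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = tab[[1]], pos = tab[[2]], strand = tab[[6]],
             score = if (ncol(tab) >= 7) tab[[7]] else tab[[5]] / 100)
}
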
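## Four-state HMM machinery: forward-backward (compiled core), Baum-Welch
## with numerically optimised M-steps, posterior decoding with the
## log-posterior-ratio site score, and merging of called sites into binding
## regions. State order throughout: (0,0), (0,1), (1,0), (1,1) as
## (enrichment, crosslink); the target state is (1,1), flat index 4.

STATE_LABELS <- c("ne.nc", "ne.cl", "en.nc", "en.cl")

#' Forward-backward smoothing for one chain
#'
#' Exact smoothed posteriors, summed pairwise transition expectations and the
#' chain log-likelihood, computed with per-position scaling (numerically
#' equivalent to log-sum-exp).
#'
#' @param log_emissions T x 4 matrix of log emission probabilities; `-Inf`
#'   entries are allowed provided each row has at least one finite entry.
#' @param transition 4 x 4 row-stochastic matrix.
#' @param init length-4 initial state distribution.
#' @return list with `gamma` (T x 4 posteriors), `xi` (4 x 4 expected
#'   transition counts summed over the chain) and `loglik`.
#' @export
forward_backward <- function(log_emissions, transition,
                             init = rep(0.25, 4)) {
  stopifnot(is.matrix(log_emissions), ncol(log_emissions) == 4,
            nrow(log_emissions) >= 1,
            all(abs(rowSums(transition) - 1) < 1e-9),
            all(transition >= 0), length(init) == 4)
  .fb_cpp(log_emissions, transition, init)
}

## Permutations of the flat state index under a label swap of one dimension.
.perm_s1 <- c(3L, 4L, 1L, 2L)   # swap enrichment labels
.perm_s2 <- c(2L, 1L, 4L, 3L)   # swap crosslink labels

permute_states <- function(params, perm) {
  params$transition <- params$transition[perm, perm, drop = FALSE]
  params$init <- params$init[perm]
  params
}

#' Default initial parameters for Baum-Welch
#'
#' Positions are split at the weighted median of the density into provisional
#' non-enriched/enriched sets for a method-of-moments gamma start;
#' `p0 = 0.01`, `p1 = 0.2`; transitions start at 0.9 self / 0.1/3
#' off-diagonal; the initial state distribution is uniform (intervals start
#' at low-coverage boundaries, so no stationary solve is needed).
#'
#' @param chains list of chains as passed to [baum_welch()].
#' @param tp truncation point of the density emission.
#' @param n_motifs number of CL motifs (0 for the basic model).
#' @return list with `transition`, `init`, `emission`.
#' @export
init_hmm_params <- function(chains, tp, n_motifs = 0L) {
  cc <- unlist(lapply(chains, function(ch) ch$c[ch$k >= 1]))
  if (length(cc) < 4L) stop("too few positions with read starts to initialise")
  med <- stats::median(cc)
  lo <- cc[cc <= med]; hi <- cc[cc > med]
  if (length(hi) < 2L) { hi <- lo }  # extremely flat data; start symmetric
  mom <- function(x) {
    m <- mean(x); v <- stats::var(x)
    if (!is.finite(v) || v <= 0) v <- m^2
    c(m, m^2 / v)
  }
  m0 <- mom(lo); m1 <- mom(hi)
  if (m1[1] <= m0[1]) m1[1] <- m0[1] * 2
  trans <- matrix(0.1 / 3, 4, 4); diag(trans) <- 0.9
  list(transition = trans,
       init = rep(0.25, 4),
       emission = new_emission_params(
         mu = c(m0[1], m1[1]),
         lambda = pmin(pmax(c(m0[2], m1[2]), 0.05), 100),
         p = c(0.01, 0.2), tp = tp, n_motifs = n_motifs))
}

#' Baum-Welch training of the four-state model
#'
#' Iterates the E-step (forward-backward over all chains) and the M-step
#' (transition re-estimation from expected counts; weighted maximum-likelihood
#' refits of the left-truncated gamma / zero-truncated binomial emissions, or
#' their covariate GLM generalisations) until the change in total
#' log-likelihood drops below `tol` or `max_iter` is reached. Emission
#' distributions are fitted only to positions carrying at least one read
#' start. Label switching is prevented by reordering states after each M-step
#' so that `mu1 > mu0` and `p1 > p0`. Transitions and the uniform initial
#' distribution are shared across all chains.
#'
#' @param chains list of chains; each a list with numeric vectors `c`, `k`,
#'   `n_hat` and optionally `b`, `b_mask` (input covariate) and `motif_i`,
#'   `motif_x` (CL-motif covariate).
#' @param init initial parameters from [init_hmm_params()] (or a previous
#'   fit).
#' @param max_iter,tol convergence controls (absolute change in total
#'   log-likelihood).
#' @param min_motif_sites motifs observed at fewer weighted sites keep a
#'   zero slope.
#' @param verbose print the log-likelihood trace.
#' @return list with `transition`, `init`, `emission`, `loglik_trace`,
#'   `iterations`, `converged`.
#' @export
baum_welch <- function(chains, init, max_iter = 50L, tol = 1e-3,
                       min_motif_sites = 10, verbose = FALSE) {
  stopifnot(length(chains) >= 1)
  par <- init
  has_b <- any(vapply(chains, function(ch) !is.null(ch$b), logical(1)))
  has_motif <- any(vapply(chains, function(ch) !is.null(ch$motif_i),
                          logical(1))) && ncol(par$emission$beta_slopes) > 0L
  # concatenated observation vectors (fixed across iterations)
  cc <- unlist(lapply(chains, `[[`, "c"))
  kk <- unlist(lapply(chains, `[[`, "k"))
  nn <- unlist(lapply(chains, `[[`, "n_hat"))
  bb <- if (has_b) unlist(lapply(chains, function(ch) {
    if (is.null(ch$b)) rep(NA_real_, length(ch$c)) else ch$b
  })) else NULL
  bm <- if (has_b) unlist(lapply(chains, function(ch) {
    if (is.null(ch$b_mask)) rep(!is.null(ch$b), length(ch$c)) else ch$b_mask
  })) & !is.na(bb) else NULL
  mi <- if (has_motif) unlist(lapply(chains, function(ch) {
    if (is.null(ch$motif_i)) rep(0L, length(ch$c)) else ch$motif_i
  })) else NULL
  mx <- if (has_motif) unlist(lapply(chains, function(ch) {
    if (is.null(ch$motif_x)) rep(0, length(ch$c)) else ch$motif_x
  })) else NULL

  pos1 <- which(kk >= 1)           # positions entering the emission fits
  trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    ## E-step
    total_ll <- 0
    xi_sum <- matrix(0, 4, 4)
    gam <- matrix(0, length(cc), 4)
    off <- 0L
    for (ch in chains) {
      T <- length(ch$c)
      le <- log_emission_matrix(ch$c, ch$k, ch$n_hat, par$emission,
                                b = ch$b, b_mask = ch$b_mask,
                                motif_i = ch$motif_i, motif_x = ch$motif_x)
      fb <- forward_backward(le, par$transition, par$init)
      total_ll <- total_ll + fb$loglik
      xi_sum <- xi_sum + fb$xi
      gam[(off + 1L):(off + T), ] <- fb$gamma
      off <- off + T
    }
    trace <- c(trace, total_ll)
    if (verbose)
      message(sprintf("EM iter %d: loglik = %.4f", iter, total_ll))
    if (iter > 1L && abs(total_ll - trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }

    ## M-step: transitions
    rs <- rowSums(xi_sum)
    new_trans <- par$transition
    ok <- rs > 0
    new_trans[ok, ] <- xi_sum[ok, , drop = FALSE] / rs[ok]
    par$transition <- new_trans

    ## M-step: enrichment emissions (LTG / gamma GLM), fitted at k >= 1
    em <- par$emission
    for (s1 in 0:1) {
      w <- (gam[, 2 * s1 + 1] + gam[, 2 * s1 + 2])[pos1]
      if (sum(w) <= 0) {
        warning("enrichment state ", s1,
                " received zero posterior mass; parameters kept")
        next
      }
      vals <- cc[pos1]
      if (has_b) {
        fit <- tryCatch(
          fit_gamma_glm(vals, bb[pos1], w, em$tp, mask = bm[pos1],
                        init = c(em$alpha0[s1 + 1], em$alpha1[s1 + 1],
                                 em$lambda[s1 + 1])),
          error = function(e) stop("gamma GLM fit failed at EM iteration ",
                                   iter, ", enrichment state ", s1, ": ",
                                   conditionMessage(e)))
        em$alpha0[s1 + 1] <- fit$alpha0
        em$alpha1[s1 + 1] <- fit$alpha1
        em$lambda[s1 + 1] <- fit$lambda
      } else {
        fit <- tryCatch(
          ltg_fit(vals, w, em$tp,
                  init = c(exp(em$alpha0[s1 + 1]), em$lambda[s1 + 1])),
          error = function(e) stop("LTG fit failed at EM iteration ", iter,
                                   ", enrichment state ", s1, ": ",
                                   conditionMessage(e)))
        em$alpha0[s1 + 1] <- log(fit$mu)
        em$lambda[s1 + 1] <- fit$lambda
      }
    }

    ## M-step: crosslink emissions (ZTB / per-motif logistic), at k >= 1
    for (s2 in 0:1) {
      w <- (gam[, s2 + 1] + gam[, s2 + 3])[pos1]
      if (sum(w) <= 0) {
        warning("crosslink state ", s2,
                " received zero posterior mass; parameters kept")
        next
      }
      zero_x <- if (has_motif) mi[pos1] == 0L else rep(TRUE, length(pos1))
      if (sum(w[zero_x]) > 0) {
        fit <- tryCatch(
          ztb_fit(kk[pos1][zero_x], nn[pos1][zero_x], w[zero_x]),
          error = function(e) stop("ZTB fit failed at EM iteration ", iter,
                                   ", crosslink state ", s2, ": ",
                                   conditionMessage(e)))
        em$beta0[s2 + 1] <- stats::qlogis(fit$p)
      }
      if (has_motif) {
        sl <- fit_logistic_slopes(kk[pos1], nn[pos1], mi[pos1], mx[pos1], w,
                                  beta0 = em$beta0[s2 + 1],
                                  n_motifs = ncol(em$beta_slopes),
                                  min_sites = min_motif_sites)
        em$beta_slopes[s2 + 1, ] <- sl
      }
    }

    ## ordering constraints: mu1 > mu0 (baseline mean) and p1 > p0
    if (em$alpha0[2] < em$alpha0[1]) {
      em$alpha0 <- rev(em$alpha0); em$alpha1 <- rev(em$alpha1)
      em$lambda <- rev(em$lambda)
      par <- permute_states(par, .perm_s1)
    }
    if (em$beta0[2] < em$beta0[1]) {
      em$beta0 <- rev(em$beta0)
      em$beta_slopes <- em$beta_slopes[2:1, , drop = FALSE]
      par <- permute_states(par, .perm_s2)
    }
    par$emission <- em
  }
  par$loglik_trace <- trace
  par$iterations <- length(trace)
  par$converged <- converged
  par
}

#' Posterior decoding and site scoring
#'
#' Selects the most likely state at each position (ties broken toward the
#' lower flat state index) and returns every position decoded as
#' enriched + crosslink, scored with the log posterior probability ratio of
#' the first and second most likely state. At positions with no read start
#' the crosslink dimension carries no information and the decoded state is
#' forced to non-crosslink (mass of `(s1, 1)` is moved to `(s1, 0)` before
#' the argmax), so such positions are never called.
#'
#' @param gamma T x 4 posterior matrix from [forward_backward()].
#' @param k read-start counts for the same positions (used for the `k = 0`
#'   convention); pass `NULL` to decode the posteriors as-is.
#' @return data.frame with `index` (1-based position within the chain),
#'   `posterior` (of the called state) and `score` for every called site.
#' @export
posterior_decode_and_score <- function(gamma, k = NULL) {
  g <- gamma
  if (!is.null(k)) {
    z <- k == 0
    if (any(z)) {
      g[z, 1] <- g[z, 1] + g[z, 2]; g[z, 2] <- 0
      g[z, 3] <- g[z, 3] + g[z, 4]; g[z, 4] <- 0
    }
  }
  best <- max.col(g, ties.method = "first")
  called <- which(best == 4L)
  if (length(called) == 0L)
    return(data.frame(index = integer(0), posterior = numeric(0),
                      score = numeric(0)))
  p1 <- g[called, 4]
  p2 <- apply(g[called, 1:3, drop = FALSE], 1, max)
  data.frame(index = called, posterior = p1, score = log(p1 / p2))
}

#' Merge crosslink sites into binding regions
#'
#' Single-linkage merge of same-chromosome, same-strand sites whose
#' positional gap is at most `d` (default 8). A region's score is the
#' maximum score among its member sites.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `strand`, `score`,
#'   sorted by (chrom, strand, pos).
#' @param d maximum gap between consecutive member sites.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `n_sites`, `score`.
#' @export
merge_sites <- function(sites, d = 8L) {
  if (nrow(sites) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_sites = integer(0), score = numeric(0)))
  o <- order(sites$chrom, sites$strand, sites$pos)
  sites <- sites[o, , drop = FALSE]
  grp <- paste(sites$chrom, sites$strand)
  new_region <- c(TRUE, diff(sites$pos) > d | grp[-1] != grp[-nrow(sites)])
  region_id <- cumsum(new_region)
  out <- do.call(rbind, lapply(split(seq_len(nrow(sites)), region_id),
    function(ix) {
      data.frame(chrom = sites$chrom[ix[1]],
                 start = min(sites$pos[ix]),
                 end = max(sites$pos[ix]) + 1L,
                 strand = sites$strand[ix[1]],
                 n_sites = length(ix),
                 score = max(sites$score[ix]))
    }))
  rownames(out) <- NULL
  out
}

#' Simulate observations from the four-state model itself
#'
#' Draws a state path from the Markov chain, densities from the
#' state-conditional left-truncated gamma (by rejection), trial counts by the
#' surrogate rescale `n_hat = max(1, round(c * s))` and read-start counts
#' from the zero-truncated binomial via inverse-cdf conditioning. Used for
#' parameter-recovery checks and by the `simulate()` method of fitted models.
#'
#' @param params list with `transition`, `init`, `emission`.
#' @param T number of positions.
#' @param rescale surrogate-trial rescale factor `s`.
#' @return list with vectors `state` (flat index 1..4), `c`, `k`, `n_hat`.
#' @export
simulate_hmm_observations <- function(params, T, rescale = 50) {
  em <- params$emission
  A <- params$transition
  state <- integer(T)
  state[1] <- sample.int(4L, 1L, prob = params$init)
  for (t in 2:T) state[t] <- sample.int(4L, 1L, prob = A[state[t - 1L], ])
  s1 <- (state - 1L) %/% 2L          # 0 or 1
  s2 <- (state - 1L) %% 2L
  mu <- exp(em$alpha0)[s1 + 1L]
  lam <- em$lambda[s1 + 1L]
  # left-truncated gamma via inverse cdf above the truncation mass
  u0 <- stats::pgamma(em$tp, shape = lam, rate = lam / mu)
  u <- u0 + stats::runif(T) * (1 - u0)
  c_val <- stats::qgamma(u, shape = lam, rate = lam / mu)
  n_hat <- pmax(1, round(c_val * rescale))
  p <- stats::plogis(em$beta0)[s2 + 1L]
  v0 <- stats::pbinom(0, n_hat, p)
  v <- v0 + stats::runif(T) * (1 - v0)
  k <- stats::qbinom(v, n_hat, p)
  k <- pmax(k, 1)                    # guard qbinom edge round-off
  list(state = state, c = c_val, k = k, n_hat = n_hat)
}
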
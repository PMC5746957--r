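## Non-homogeneous emissions. The input-control fragment density enters the
## enrichment dimension through a left-truncated gamma GLM with log link
## (position-specific mean, constant shape per state); CL-motif match scores
## enter the crosslink dimension through one logistic regression per motif,
## with the intercept pinned to the basic-model fit on motif-free positions.

#' Weighted left-truncated gamma GLM fit
#'
#' Maximises the weighted truncated-gamma log-likelihood with
#' `log(mu_t) = alpha0 + alpha1 * b_t` and a constant shape `lambda`, by
#' bounded quasi-Newton over `(alpha0, alpha1, log lambda)` (gradient
#' tolerance 1e-6), warm-started from the previous EM iterate. Positions
#' where the covariate is masked (input density at or below its own
#' truncation point, so the log is undefined or extrapolating) contribute
#' through the covariate-free mean `exp(alpha0)`.
#'
#' @param values density values, all `> tp`.
#' @param b covariate (log input fragment density); may contain `NA` at
#'   masked positions.
#' @param weights non-negative weights (posterior responsibilities).
#' @param tp truncation point.
#' @param mask logical, `TRUE` where the covariate is valid; defaults to
#'   `!is.na(b)`.
#' @param init `c(alpha0, alpha1, lambda)` warm start.
#' @return list with `alpha0`, `alpha1`, `lambda`, `loglik`, `converged`.
#' @export
fit_gamma_glm <- function(values, b, weights, tp = 0, mask = NULL,
                          init = NULL) {
  stopifnot(length(values) == length(b), length(weights) == length(values))
  if (sum(weights) <= 0) {
    warning("fit_gamma_glm: all-zero weights; parameters kept")
    return(list(alpha0 = init[1], alpha1 = init[2], lambda = init[3],
                loglik = NA_real_, converged = FALSE))
  }
  if (is.null(mask)) mask <- !is.na(b)
  b2 <- ifelse(mask, b, 0)
  bv <- b2[mask & weights > 0]
  degenerate <- length(bv) < 2L || stats::var(bv) < 1e-12
  if (degenerate)
    warning("fit_gamma_glm: covariate constant or fully masked; ",
            "slope pinned to 0")
  if (is.null(init)) {
    m <- sum(weights * values) / sum(weights)
    v <- sum(weights * (values - m)^2) / sum(weights)
    init <- c(log(m), 0, max(m^2 / max(v, 1e-12), 0.05))
  }
  nll <- function(theta) {
    a0 <- theta[1]
    a1 <- if (degenerate) 0 else theta[2]
    lam <- exp(theta[3])
    mu <- exp(a0 + a1 * b2)
    mu[!mask] <- exp(a0)
    -sum(weights * ltg_logpdf(values, mu, lam, tp))
  }
  theta0 <- c(init[1], init[2], log(init[3]))
  fit <- stats::optim(theta0, nll, method = "L-BFGS-B",
                      lower = c(-20, -20, log(1e-3)),
                      upper = c(20, 20, log(1e4)),
                      control = list(pgtol = 1e-6))
  if (fit$convergence != 0) {
    warning("fit_gamma_glm: optimizer did not converge (code ",
            fit$convergence, "); previous iterate kept")
    return(list(alpha0 = init[1], alpha1 = init[2], lambda = init[3],
                loglik = NA_real_, converged = FALSE))
  }
  list(alpha0 = fit$par[1],
       alpha1 = if (degenerate) 0 else fit$par[2],
       lambda = exp(fit$par[3]),
       loglik = -fit$value, converged = TRUE)
}

#' Per-motif logistic slope fits for the crosslink emission
#'
#' With the intercept `beta0` fixed (estimated on motif-free positions via
#' the basic zero-truncated binomial fit), each motif's slope maximises the
#' weighted ZTB log-likelihood over the positions whose best-scoring motif it
#' is, independently of the other motifs, by Brent's method on `[-10, 10]`
#' (tolerance 1e-5). A motif with too little weighted data keeps a zero
#' slope.
#'
#' @param k read-start counts (all >= 1).
#' @param n_hat trial counts.
#' @param motif_i best-motif index per position (0 = no match).
#' @param motif_x best-motif score per position.
#' @param weights non-negative weights.
#' @param beta0 fixed intercept for this crosslink state.
#' @param n_motifs number of motifs.
#' @param min_sites minimum total weight required to fit a slope.
#' @return numeric vector of `n_motifs` slopes.
#' @export
fit_logistic_slopes <- function(k, n_hat, motif_i, motif_x, weights, beta0,
                                n_motifs, min_sites = 10) {
  slopes <- numeric(n_motifs)
  for (i in seq_len(n_motifs)) {
    sel <- which(motif_i == i & motif_x > 0)
    if (length(sel) == 0L) next
    w <- weights[sel]
    if (sum(w) < min_sites) {
      warning("motif ", i, ": fewer than ", min_sites,
              " weighted sites; slope pinned to 0")
      next
    }
    ki <- k[sel]; ni <- n_hat[sel]; xi <- motif_x[sel]
    obj <- function(beta)
      sum(w * ztb_logpmf(ki, ni, stats::plogis(beta0 + beta * xi)))
    slopes[i] <- stats::optimize(obj, interval = c(-10, 10),
                                 maximum = TRUE, tol = 1e-5)$maximum
  }
  slopes
}

#' Build the input-control covariate track
#'
#' The covariate is the log of the input experiment's smoothed fragment
#' density, computed with the same kernel bandwidth as the target (50 bp by
#' default). Positions where the input density does not exceed its own
#' truncation point are masked: there the GLM would extrapolate far below
#' its support, so the basic (covariate-free) emission is used instead.
#'
#' @param input_track a `fragment_density_track` of the input experiment.
#' @param tp_input input-density threshold below which the covariate is
#'   masked; defaults to the smallest positive density.
#' @return list with `b` (log density, `NA` where masked) and `mask`.
#' @export
input_covariate <- function(input_track, tp_input = NULL) {
  d <- input_track$density
  if (is.null(tp_input)) {
    pos <- d[d > 0]
    tp_input <- if (length(pos)) min(pos) * (1 - 1e-6) else Inf
  }
  mask <- d > tp_input
  b <- ifelse(mask, log(pmax(d, .Machine$double.xmin)), NA_real_)
  list(b = b, mask = mask, tp_input = tp_input)
}
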
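## Emission families of the four-state model: a left-truncated gamma (LTG) on
## the pulled-down fragment density for the enrichment dimension, and a
## zero-truncated binomial (ZTB) on the read-start counts for the crosslink
## dimension. Both are fitted by weighted maximum likelihood inside EM.

#' Left-truncated gamma log density
#'
#' Ordinary gamma density with mean `mu` and shape `lambda`, renormalised to
#' the open support `(tp, Inf)`:
#' `f(c) = dgamma(c; shape = lambda, rate = lambda/mu) / P(C > tp)`.
#' Values at or below `tp` get `-Inf` (outside the support; callers mask).
#'
#' @param c density values (vectorised).
#' @param mu mean (> 0); may be a vector of position-specific means (GLM).
#' @param lambda shape (> 0).
#' @param tp truncation point (>= 0).
#' @return log density values.
#' @export
ltg_logpdf <- function(c, mu, lambda, tp = 0) {
  stopifnot(all(mu > 0), all(lambda > 0), tp >= 0)
  rate <- lambda / mu
  out <- stats::dgamma(c, shape = lambda, rate = rate, log = TRUE) -
    stats::pgamma(tp, shape = lambda, rate = rate,
                  lower.tail = FALSE, log.p = TRUE)
  out[c <= tp] <- -Inf
  out
}

#' Weighted maximum-likelihood fit of the left-truncated gamma
#'
#' Maximises `sum(w * ltg_logpdf(values; mu, lambda, tp))` over
#' `(log mu, log lambda)` by bounded quasi-Newton (`L-BFGS-B`, gradient
#' tolerance 1e-6), initialised from weighted method-of-moments on the
#' untruncated model. In EM the weights are the posterior responsibilities of
#' one enrichment state.
#'
#' @param values density values, all `> tp`.
#' @param weights non-negative weights, `sum(weights) > 0`.
#' @param tp truncation point.
#' @param init optional `c(mu, lambda)` warm start.
#' @return list with elements `mu`, `lambda`, `loglik`.
#' @export
ltg_fit <- function(values, weights = rep(1, length(values)), tp = 0,
                    init = NULL) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  if (length(values) == 0L || sum(weights) <= 0)
    stop("ltg_fit: no data (empty input or all-zero weights)")
  if (any(values <= tp))
    stop("ltg_fit: values at or below the truncation point")
  wsum <- sum(weights)
  m <- sum(weights * values) / wsum
  v <- sum(weights * (values - m)^2) / wsum
  if (v <= .Machine$double.eps * m^2)
    stop("ltg_fit: degenerate input (weighted variance ~ 0); ",
         "shape would diverge")
  if (is.null(init)) init <- c(m, m^2 / v)
  # the weighted truncated-gamma log-likelihood depends on the data only
  # through three sufficient statistics, so each objective call is O(1)
  W <- wsum
  T1 <- sum(weights * log(values))
  T2 <- sum(weights * values)
  nll <- function(theta) {
    mu <- exp(theta[1]); lambda <- exp(theta[2])
    logS <- stats::pgamma(tp, shape = lambda, rate = lambda / mu,
                          lower.tail = FALSE, log.p = TRUE)
    -((lambda - 1) * T1 - (lambda / mu) * T2 +
        W * (lambda * log(lambda / mu) - lgamma(lambda) - logS))
  }
  fit <- stats::optim(log(init), nll, method = "L-BFGS-B",
                      lower = log(c(1e-8, 1e-3)), upper = log(c(1e8, 1e4)),
                      control = list(pgtol = 1e-6))
  list(mu = exp(fit$par[1]), lambda = exp(fit$par[2]), loglik = -fit$value)
}

# log(1 - exp(x)) for x < 0, stable near 0 and -Inf
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

#' Zero-truncated binomial log pmf
#'
#' `P(K = k | K >= 1)` for `K ~ Binomial(n_hat, p)`:
#' `choose(n,k) p^k (1-p)^(n-k) / (1 - (1-p)^n)`. `k = 0` has probability
#' zero under both crosslink states; `k > n_hat` (possible only if the
#' surrogate-trial rescale underestimates) is clamped to `-Inf`.
#'
#' @param k observed read-start counts (vectorised).
#' @param n_hat surrogate trial counts (>= 1 where evaluated).
#' @param p per-trial start probability in (0, 1); may be position-specific.
#' @return log probabilities.
#' @export
ztb_logpmf <- function(k, n_hat, p) {
  stopifnot(all(p > 0), all(p < 1))
  out <- stats::dbinom(k, n_hat, p, log = TRUE) -
    log1mexp(n_hat * log1p(-p))
  out[k == 0 | k > n_hat] <- -Inf
  out
}

#' Weighted maximum-likelihood fit of the zero-truncated binomial
#'
#' One-dimensional maximisation of the weighted ZTB log-likelihood in `p`,
#' solved by Brent's method (`optimize`, absolute tolerance 1e-6) on
#' `(1e-6, 1 - 1e-6)`. A fit on the boundary is flagged with a warning.
#'
#' @param k read-start counts, all >= 1.
#' @param n_hat trial counts, `k <= n_hat` elementwise.
#' @param weights non-negative weights.
#' @return list with elements `p`, `loglik`.
#' @export
ztb_fit <- function(k, n_hat, weights = rep(1, length(k))) {
  if (length(k) == 0L) stop("ztb_fit: empty input")
  stopifnot(all(k >= 1), all(k <= n_hat), length(k) == length(n_hat),
            length(weights) == length(k))
  if (sum(weights) <= 0) stop("ztb_fit: all-zero weights")
  eps <- 1e-6
  # sufficient statistics: the objective needs only sum(w*k), sum(w*(n-k))
  # and, for the truncation normaliser, the total weight per distinct n
  const <- sum(weights * lchoose(n_hat, k))
  sk <- sum(weights * k)
  snk <- sum(weights * (n_hat - k))
  nw <- rowsum(weights, n_hat)
  n_lev <- as.numeric(rownames(nw))
  obj <- function(p) {
    const + sk * log(p) + snk * log1p(-p) -
      sum(nw * log1mexp(n_lev * log1p(-p)))
  }
  fit <- stats::optimize(obj, interval = c(eps, 1 - eps),
                         maximum = TRUE, tol = 1e-6)
  if (fit$maximum > 1 - 2 * eps || fit$maximum < 2 * eps)
    warning("ztb_fit: estimate on the boundary (p = ",
            signif(fit$maximum, 4), ")")
  list(p = fit$maximum, loglik = fit$objective)
}

## ---- joint emissions -------------------------------------------------------

## Internal parameter container shared by the basic and covariate models.
## The basic model is the special case alpha1 = 0, all motif slopes = 0, so
## both run through exactly the same code path:
##   mu_{s1,t}  = exp(alpha0[s1] + alpha1[s1] * b_t)
##   p_{s2,t}   = plogis(beta0[s2] + beta[s2, i_t] * x_t)
new_emission_params <- function(mu, lambda, p, tp,
                                alpha1 = c(0, 0), beta_slopes = NULL,
                                n_motifs = 0L) {
  stopifnot(length(mu) == 2, length(lambda) == 2, length(p) == 2)
  if (is.null(beta_slopes))
    beta_slopes <- matrix(0, nrow = 2, ncol = n_motifs)
  structure(list(
    alpha0 = log(mu), alpha1 = alpha1, lambda = lambda,
    beta0 = stats::qlogis(p), beta_slopes = beta_slopes, tp = tp),
    class = "clip_emission_params")
}

#' Position-specific gamma-GLM mean
#'
#' `mu_{s1,t} = exp(alpha0 + alpha1 * b_t)` (log link). With `alpha1 = 0` this
#' reduces exactly to the constant mean of the basic model.
#'
#' @param b covariate values (log input fragment density).
#' @param alpha0,alpha1 intercept and slope for one enrichment state.
#' @return position-specific means.
#' @export
glm_mu <- function(b, alpha0, alpha1) exp(alpha0 + alpha1 * b)

#' Position-specific crosslink probability from CL-motif scores
#'
#' `p_{s2,t} = plogis(beta0 + beta_i * x_t)` where `i` is the position's
#' best-scoring motif. At `x = 0` (no motif match) this is exactly
#' `plogis(beta0)`, the basic-model probability.
#'
#' @param x motif match score (>= 0).
#' @param beta0 intercept for one crosslink state.
#' @param beta_i slope of the matched motif.
#' @return probabilities in (0, 1).
#' @export
logistic_p <- function(x, beta0, beta_i) stats::plogis(beta0 + beta_i * x)

#' Joint log emission matrix for the four hidden states
#'
#' The joint emission factorises as
#' `P(c, k | s1, s2) = LTG(c; mu_s1, lambda_s1, tp) * ZTB(k; n_hat, p_s2)`
#' because the trial count is deduced from `c` itself. States are ordered
#' `(0,0), (0,1), (1,0), (1,1)` as (enrichment, crosslink). At positions with
#' `k = 0` only the enrichment dimension is informative: the ZTB factor is
#' dropped (log factor 0 for both crosslink states) and decoding forces the
#' non-crosslink state there. Positions where the density does not exceed
#' `tp` (possible inside merged interval gaps) evaluate the LTG at the edge
#' of its support. When a covariate mask is supplied, masked positions fall
#' back to the covariate-free mean for the enrichment dimension.
#'
#' @param c fragment density values.
#' @param k read-start counts.
#' @param n_hat surrogate trial counts.
#' @param par a `clip_emission_params` object.
#' @param b optional input-control covariate (log input density).
#' @param b_mask optional logical; `TRUE` where the covariate is valid.
#' @param motif_i,motif_x optional per-position best-motif index (0 = none)
#'   and score.
#' @return `length(c)` x 4 matrix of log emission probabilities.
#' @export
log_emission_matrix <- function(c, k, n_hat, par, b = NULL, b_mask = NULL,
                                motif_i = NULL, motif_x = NULL) {
  T <- length(c)
  stopifnot(length(k) == T, length(n_hat) == T,
            inherits(par, "clip_emission_params"))
  ce <- pmax(c, par$tp * (1 + 1e-12) + 1e-300)  # clamp to the open support
  le <- matrix(0, nrow = T, ncol = 4)
  # enrichment factor (columns 1,2 share s1 = 0; columns 3,4 share s1 = 1)
  for (s1 in 0:1) {
    a0 <- par$alpha0[s1 + 1]; a1 <- par$alpha1[s1 + 1]
    if (is.null(b) || a1 == 0) {
      mu <- exp(a0)
    } else {
      mu <- glm_mu(b, a0, a1)
      if (!is.null(b_mask)) mu[!b_mask] <- exp(a0)
    }
    lf <- ltg_logpdf(ce, mu, par$lambda[s1 + 1], par$tp)
    le[, 2 * s1 + 1] <- le[, 2 * s1 + 1] + lf
    le[, 2 * s1 + 2] <- le[, 2 * s1 + 2] + lf
  }
  # crosslink factor (columns 1,3 share s2 = 0; columns 2,4 share s2 = 1)
  pos <- which(k >= 1)
  if (length(pos) > 0L) {
    for (s2 in 0:1) {
      b0 <- par$beta0[s2 + 1]
      eta <- rep(b0, length(pos))
      if (!is.null(motif_i) && ncol(par$beta_slopes) > 0L) {
        mi <- motif_i[pos]
        hit <- which(mi > 0L)
        if (length(hit) > 0L)
          eta[hit] <- b0 + par$beta_slopes[s2 + 1, mi[hit]] * motif_x[pos][hit]
      }
      zf <- ztb_logpmf(k[pos], n_hat[pos], stats::plogis(eta))
      le[pos, s2 + 1] <- le[pos, s2 + 1] + zf
      le[pos, s2 + 3] <- le[pos, s2 + 3] + zf
    }
  }
  le
}

#' Joint log emission for a single observation and state
#'
#' Convenience scalar wrapper around [log_emission_matrix()].
#'
#' @param c,k,n_hat one observation.
#' @param state length-2 vector `c(s1, s2)` with entries in `{0, 1}`.
#' @param par a `clip_emission_params` object.
#' @inheritParams log_emission_matrix
#' @return scalar log emission probability.
#' @export
joint_log_emission <- function(c, k, n_hat, state, par, b = NULL,
                               motif_i = NULL, motif_x = NULL) {
  stopifnot(length(state) == 2, all(state %in% 0:1))
  le <- log_emission_matrix(c, k, n_hat, par, b = b,
                            motif_i = motif_i, motif_x = motif_x)
  le[1, 2 * state[1] + state[2] + 1]
}

#' Serialise emission and transition parameters to a key=value file
#'
#' Values are written with full double precision (`%.17g`) so that
#' `read_params(write_params(x))` round-trips exactly.
#'
#' @param params list as stored in a fitted model (`transition`, `init`,
#'   `emission` of class `clip_emission_params`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_params <- function(params, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = ",")
  em <- params$emission
  lines <- c(
    paste0("transition=", num(params$transition)),
    paste0("init=", num(params$init)),
    paste0("alpha0=", num(em$alpha0)),
    paste0("alpha1=", num(em$alpha1)),
    paste0("lambda=", num(em$lambda)),
    paste0("beta0=", num(em$beta0)),
    paste0("beta_slopes=", num(em$beta_slopes)),
    paste0("n_motifs=", ncol(em$beta_slopes)),
    paste0("tp=", num(em$tp)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter file written by [write_params()]
#'
#' @param path parameter file.
#' @return list with `transition`, `init` and `emission`.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) as.numeric(strsplit(x[2], ",")[[1]])),
    vapply(kv, `[[`, "", 1))
  m <- as.integer(vals$n_motifs)
  em <- structure(list(
    alpha0 = vals$alpha0, alpha1 = vals$alpha1, lambda = vals$lambda,
    beta0 = vals$beta0,
    beta_slopes = matrix(vals$beta_slopes, nrow = 2, ncol = m),
    tp = vals$tp), class = "clip_emission_params")
  list(transition = matrix(vals$transition, 4, 4),
       init = vals$init, emission = em)
}
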
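#' E-step responsibilities for the zero-inflated Gaussian mixture
#'
#' Posterior probability that an exact zero of the transformed response
#' is structural: `p / (p + (1 - p) * phi(0; mu, sigma2))` at exact
#' zeros, and 0 elsewhere. Both supported transformations (log2(C+1) and
#' arcsine square root) map zero abundance to exactly zero, so the rule
#' keys on zero raw abundance.
#'
#' @param y transformed responses.
#' @param p zero-inflation probabilities.
#' @param mu Gaussian conditional means.
#' @param sigma2 Gaussian residual variance.
#' @return responsibility vector in \[0, 1\].
#' @export
zig_e_step <- function(y, p, mu, sigma2) {
  stopifnot(sigma2 > 0)
  p <- rep_len(p, length(y))
  mu <- rep_len(mu, length(y))
  xi <- numeric(length(y))
  z <- y == 0
  if (any(z)) {
    dens <- dnorm(0, mean = mu[z], sd = sqrt(sigma2))
    xi[z] <- p[z] / (p[z] + (1 - p[z]) * dens)
  }
  xi
}

# observed-data log-likelihood of the ZIG model
zig_obs_loglik <- function(y, p, mu, sigma2) {
  p <- rep_len(p, length(y))
  z <- y == 0
  ll <- numeric(length(y))
  if (any(z))
    ll[z] <- log(p[z] + (1 - p[z]) * dnorm(0, mu[z], sqrt(sigma2)))
  if (any(!z))
    ll[!z] <- log(1 - p[!z]) + dnorm(y[!z], mu[!z], sqrt(sigma2), log = TRUE)
  sum(ll)
}

#' Fit a zero-inflated Gaussian mixed model
#'
#' EM on the transformed response: the E-step is [zig_e_step()]; the
#' M-step fits the zero part with [m_step_zero()] and the Gaussian part
#' by [fit_weighted_lmm()] with prior weights `1 - xi`, after which the
#' residual variance is refreshed EM-consistently as the weighted
#' residual sum of squares divided by `sum(1 - xi)`. With no exact zeros
#' in the response the mixture is degenerate and the fit is exactly the
#' unit-weight linear mixed model.
#'
#' The response in `design` must already be transformed (the screening
#' wrapper applies log2(C+1) to counts and arcsine square root to
#' proportions); the design's offset is on the same scale (log2 totals
#' for counts, none for proportions — [build_design()] rejects an offset
#' for proportion data).
#'
#' @inheritParams fit_nbmm
#' @return a `taxamix_fit` with `dispersion` holding the Gaussian
#'   residual variance and `loglik_trace` the observed-data
#'   log-likelihood after each EM iteration (exact for models without
#'   random effects; conditional on the predicted random effects
#'   otherwise).
#' @export
fit_zigmm <- function(design, control = taxamix_control()) {
  stopifnot(inherits(design, "taxamix_design"))
  y <- design$y
  if (all(y == 0)) stop("response is all zero; the model is unfittable")
  n <- length(y)

  if (!any(y == 0)) {
    # degenerate reduction: plain weighted LMM with unit weights
    lfit <- fit_weighted_lmm(y, design$X, design$groups,
                             offset = design$offset, slope = design$slope,
                             correlation = design$correlation,
                             method = control$lmm_method)
    wt <- wald_table(lfit, ref = control$wald)
    return(new_fit(method = "zig", count = wt, zero = NULL,
                   vc = list(count = lfit$psi, zero = NULL),
                   dispersion = lfit$sigma2, sigma2 = lfit$sigma2,
                   rho = lfit$rho, converged = TRUE, n_iter = 1L,
                   warnings = lfit$warnings,
                   extra = list(mu = lfit$fitted, xi = numeric(n),
                                lfit = lfit)))
  }

  Z <- design$Z
  if (is.null(Z)) Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  zi_groups <- if (!is.null(design$zi_random)) design$groups else NULL
  warns <- character()

  # init: unit-weight LMM, empirical zero fraction for p
  lfit <- withCallingHandlers(
    fit_weighted_lmm(y, design$X, design$groups, offset = design$offset,
                     slope = design$slope, correlation = design$correlation,
                     method = control$lmm_method),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  mu <- lfit$fitted
  sigma2 <- max(mean((y - mu)^2), 1e-10)
  p <- rep(min(max(mean(y == 0), control$p_clip[1L]), control$p_clip[2L]), n)
  alpha <- NULL
  zstep <- NULL
  trace <- numeric()
  converged <- FALSE
  it <- 0L
  for (it in seq_len(control$em_max_iter)) {
    old <- c(lfit$beta, if (is.null(alpha)) NULL else alpha, sigma2)
    xi <- zig_e_step(y, p, mu, sigma2)
    zstep <- withCallingHandlers(
      m_step_zero(xi, Z, groups = zi_groups, p_clip = control$p_clip),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    alpha <- zstep$alpha
    p <- zstep$p
    w <- pmax(1 - xi, 1e-8)
    lfit <- withCallingHandlers(
      fit_weighted_lmm(y, design$X, design$groups, weights = w,
                       offset = design$offset, slope = design$slope,
                       correlation = design$correlation,
                       method = control$lmm_method),
      warning = function(w2) {
        warns <<- c(warns, conditionMessage(w2)); invokeRestart("muffleWarning")
      })
    mu <- lfit$fitted
    sigma2 <- max(sum(w * (y - mu)^2) / sum(w), 1e-10)
    trace <- c(trace, zig_obs_loglik(y, p, mu, sigma2))
    new <- c(lfit$beta, alpha, sigma2)
    if (length(old) == length(new) &&
        max(abs(new - old)) < control$em_tol) { converged <- TRUE; break }
  }
  wt <- wald_table(lfit, ref = control$wald)
  zero_tab <- data.frame(term = names(zstep$alpha),
                         estimate = unname(zstep$alpha),
                         se = unname(zstep$se),
                         pvalue = unname(zstep$pvalues),
                         stringsAsFactors = FALSE)
  new_fit(method = "zig", count = wt, zero = zero_tab,
          vc = list(count = lfit$psi, zero = zstep$phi),
          dispersion = sigma2, sigma2 = sigma2, rho = lfit$rho,
          converged = converged, n_iter = it, warnings = unique(warns),
          loglik_trace = trace,
          extra = list(mu = mu, xi = zig_e_step(y, p, mu, sigma2), p = p,
                       lfit = lfit))
}
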
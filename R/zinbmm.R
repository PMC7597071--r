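#' Probability of a zero count under the negative binomial
#'
#' `(theta / (theta + mu))^theta`, the NB mass at zero; approaches
#' `exp(-mu)` as `theta` grows (Poisson limit) and 1 as `mu` shrinks.
#'
#' @param mu positive mean(s).
#' @param theta positive dispersion.
#' @return probability vector.
#' @export
nb_zero_probability <- function(mu, theta) {
  stopifnot(all(mu > 0), all(theta > 0))
  exp(theta * (log(theta) - log(theta + mu)))
}

#' E-step responsibilities for the zero-inflated NB mixture
#'
#' Posterior probability that an observed zero is structural:
#' `p / (p + (1 - p) * P(NB = 0))` at zeros, and exactly 0 at positive
#' counts.
#'
#' @param y counts.
#' @param p zero-inflation probabilities.
#' @param mu NB means.
#' @param theta NB dispersion.
#' @return responsibility vector in \[0, 1\].
#' @export
zinb_e_step <- function(y, p, mu, theta) {
  p <- rep_len(p, length(y))
  mu <- rep_len(mu, length(y))
  xi <- numeric(length(y))
  z <- y == 0
  if (any(z)) {
    p0 <- nb_zero_probability(mu[z], theta)
    xi[z] <- p[z] / (p[z] + (1 - p[z]) * p0)
  }
  xi
}

#' M-step for the zero-inflation part
#'
#' Fits a binomial model with the fractional responsibilities as
#' response, by IWLS for a fixed-effects logistic regression or by a
#' short PQL loop (working response/weights fed to [fit_weighted_lmm()])
#' when a zero-part random intercept is requested. Quasi-separation is
#' handled by a small ridge penalty on the coefficients, with a warning.
#'
#' @param xi responsibilities in \[0, 1\].
#' @param Z zero-part design matrix.
#' @param groups optional grouping factor; when supplied a random
#'   intercept is added to the zero part.
#' @param p_clip admissible range for fitted probabilities.
#' @param ridge penalty used on fallback.
#' @return list with `alpha` (coefficients), `se`, `pvalues`, `phi`
#'   (random-intercept covariance or `NULL`), `p` (fitted, conditional,
#'   clipped probabilities) and `warnings`.
#' @export
m_step_zero <- function(xi, Z, groups = NULL, p_clip = c(1e-6, 1 - 1e-6),
                        ridge = 1e-4) {
  Z <- as.matrix(Z)
  stopifnot(all(xi >= 0), all(xi <= 1), nrow(Z) == length(xi))
  warns <- character()
  clip <- function(p) pmin(pmax(p, p_clip[1L]), p_clip[2L])

  lo <- qlogis(p_clip[1L]); hi <- qlogis(p_clip[2L])

  if (is.null(groups)) {
    alpha <- numeric(ncol(Z))
    alpha[1L] <- qlogis(clip(mean(xi)))
    A <- NULL
    used_ridge <- FALSE
    for (it in seq_len(100L)) {
      # clamp the linear predictor at the probability clip bounds so a
      # degenerate zero part (xi ~ 0 or ~ 1 everywhere) saturates there
      eta <- pmin(pmax(drop(Z %*% alpha), lo), hi)
      pr <- clip(plogis(eta))
      w <- pr * (1 - pr)
      zz <- eta + (xi - pr) / w
      A <- crossprod(Z, w * Z)
      b <- crossprod(Z, w * zz)
      step <- tryCatch(drop(solve(A, b)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step)) || max(abs(step)) > 30) {
        used_ridge <- TRUE
        A <- A + diag(ridge, ncol(Z))
        step <- drop(solve(A, b + 0))  # ridge shrinks toward zero
      }
      delta <- max(abs(step - alpha))
      alpha <- step
      if (delta < 1e-10) break
    }
    if (used_ridge)
      warns <- c(warns, "separation in zero-part logistic fit; ridge applied")
    cov_a <- solve(A)
    se <- sqrt(pmax(diag(cov_a), 0))
    stat <- ifelse(se > 0, alpha / se, 0)
    res <- list(alpha = setNames(alpha, colnames(Z)),
                se = setNames(se, colnames(Z)),
                pvalues = setNames(2 * pnorm(-abs(stat)), colnames(Z)),
                phi = NULL, p = clip(plogis(drop(Z %*% alpha))),
                warnings = warns)
    return(res)
  }

  # logistic mixed model by PQL
  alpha <- numeric(ncol(Z))
  alpha[1L] <- qlogis(clip(mean(xi)))
  eta <- drop(Z %*% alpha)
  lfit <- NULL
  for (it in seq_len(25L)) {
    pr <- clip(plogis(eta))
    w <- pr * (1 - pr)
    zz <- eta + (xi - pr) / w
    lfit <- withCallingHandlers(
      fit_weighted_lmm(zz, Z, groups, weights = w),
      warning = function(w2) {
        warns <<- c(warns, conditionMessage(w2))
        invokeRestart("muffleWarning")
      })
    eta_new <- pmin(pmax(lfit$fitted, lo), hi)
    if (max(abs(eta_new - eta)) < 1e-6) { eta <- eta_new; break }
    eta <- eta_new
  }
  wt <- wald_table(lfit)
  list(alpha = setNames(wt$estimate, wt$term),
       se = setNames(wt$se, wt$term),
       pvalues = setNames(wt$pvalue, wt$term),
       phi = lfit$psi, p = clip(plogis(eta)), warnings = unique(warns))
}

# observed-data log-likelihood of the ZINB model at current parameters
zinb_obs_loglik <- function(y, p, mu, theta) {
  p <- rep_len(p, length(y))
  z <- y == 0
  ll <- numeric(length(y))
  if (any(z))
    ll[z] <- log(p[z] + (1 - p[z]) * nb_zero_probability(mu[z], theta))
  if (any(!z))
    ll[!z] <- log(1 - p[!z]) +
      dnbinom(y[!z], size = theta, mu = mu[!z], log = TRUE)
  sum(ll)
}

#' Fit a zero-inflated negative binomial mixed model
#'
#' EM-IWLS: the E-step computes posterior structural-zero
#' responsibilities via [zinb_e_step()]; the M-step refits the zero part
#' with [m_step_zero()] and the count part by a short run of the NB PQL
#' loop with prior observation weights `1 - xi` multiplying the IWLS
#' weights, followed by a responsibility-weighted dispersion update.
#' Iteration stops when every linear-scale parameter moves less than
#' `control$em_tol`.
#'
#' A response without zeros (or `control$force_zero_p = TRUE`) collapses
#' the model onto the plain NBMM and [fit_nbmm()] is called directly, so
#' the nested model is reproduced exactly.
#'
#' @inheritParams fit_nbmm
#' @return a `taxamix_fit` with both `count` and `zero` coefficient
#'   blocks, plus `loglik_trace`, the observed-data log-likelihood after
#'   each EM iteration.
#' @export
fit_zinbmm <- function(design, control = taxamix_control()) {
  stopifnot(inherits(design, "taxamix_design"))
  y <- design$y
  if (all(y == 0)) stop("response is all zero; the model is unfittable")
  if (control$force_zero_p) return(fit_nbmm(design, control))
  if (!any(y == 0)) {
    warning("response has no zeros; falling back to the NB mixed model",
            call. = FALSE)
    fit <- fit_nbmm(design, control)
    fit$warnings <- c(fit$warnings, "no zeros: NB fallback")
    return(fit)
  }
  Z <- design$Z
  if (is.null(Z)) Z <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  zi_groups <- if (!is.null(design$zi_random)) design$groups else NULL

  warns <- character()
  # init: count part from a short plain NBMM run; p from the zero fraction
  core <- nbmm_core(design, control, max_sweeps = control$inner_sweeps)
  mu <- core$mu; theta <- core$theta
  p <- rep(min(max(mean(y == 0), control$p_clip[1L]), control$p_clip[2L]),
           length(y))
  alpha <- NULL
  zstep <- NULL
  trace <- numeric()
  converged <- FALSE
  it <- 0L
  for (it in seq_len(control$em_max_iter)) {
    old <- c(core$beta, if (is.null(alpha)) NULL else alpha, log(theta))
    xi <- zinb_e_step(y, p, mu, theta)
    zstep <- withCallingHandlers(
      m_step_zero(xi, Z, groups = zi_groups, p_clip = control$p_clip),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    alpha <- zstep$alpha
    p <- zstep$p
    core <- nbmm_core(design, control, prior_w = pmax(1 - xi, 1e-8),
                      init = list(mu = mu, theta = theta, beta = core$beta),
                      max_sweeps = control$inner_sweeps)
    mu <- core$mu; theta <- core$theta
    warns <- c(warns, core$warnings)
    trace <- c(trace, zinb_obs_loglik(y, p, mu, theta))
    new <- c(core$beta, alpha, log(theta))
    if (length(old) == length(new) &&
        max(abs(new - old)) < control$em_tol) { converged <- TRUE; break }
  }
  wt <- wald_table(core$lfit, ref = control$wald)
  zero_tab <- data.frame(term = names(zstep$alpha),
                         estimate = unname(zstep$alpha),
                         se = unname(zstep$se),
                         pvalue = unname(zstep$pvalues),
                         stringsAsFactors = FALSE)
  new_fit(method = "zinb", count = wt, zero = zero_tab,
          vc = list(count = core$lfit$psi, zero = zstep$phi),
          dispersion = theta, sigma2 = core$lfit$sigma2,
          rho = core$lfit$rho, converged = converged, n_iter = it,
          warnings = unique(warns), loglik_trace = trace,
          extra = list(mu = mu, xi = zinb_e_step(y, p, mu, theta),
                       p = p, lfit = core$lfit))
}
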
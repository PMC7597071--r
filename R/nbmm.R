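#' Working response and weights for the NB log link
#'
#' One IWLS linearisation step of the negative binomial model with log
#' link: the working response is `(eta - offset) + (y - mu)/mu` and the
#' working weight is `mu^2 / V(mu)` with `V(mu) = mu + mu^2/theta`, i.e.
#' `mu * theta / (theta + mu)`.
#'
#' @param y observed counts.
#' @param eta current linear predictor (offset included).
#' @param mu current fitted means, `exp(eta)`.
#' @param theta current NB dispersion.
#' @param offset known offset.
#' @return list with components `z` (working response) and `w` (weights).
#' @export
nb_working_response_and_weights <- function(y, eta, mu, theta, offset = 0) {
  stopifnot(all(mu > 0), theta > 0)
  list(z = (eta - offset) + (y - mu) / mu,
       w = mu * theta / (theta + mu))
}

# conditional NB log-likelihood in theta at fixed means (y! term dropped)
nb_theta_loglik <- function(theta, y, mu, weights) {
  sum(weights * (lgamma(y + theta) - lgamma(theta) + theta * log(theta) -
                   (y + theta) * log(theta + mu) +
                   ifelse(y > 0, y * log(mu), 0)))
}

#' Newton-Raphson update of the NB dispersion
#'
#' Maximises the conditional negative binomial log-likelihood in the
#' dispersion `theta` holding the fitted means fixed, by Newton-Raphson
#' on the digamma score, in the spirit of the classical `glm.nb` theta
#' update. The estimate is clipped to `clip`; if the score or curvature
#' is non-finite or the curvature has the wrong sign, a bracketed
#' golden-section search on the log-likelihood over `log(theta)` is used
#' instead, with a warning.
#'
#' @param y observed counts.
#' @param mu fitted means.
#' @param theta0 starting value.
#' @param weights optional non-negative per-observation weights
#'   (responsibility weights in EM fits).
#' @param clip admissible range for theta.
#' @return the updated dispersion estimate.
#' @export
update_theta_newton <- function(y, mu, theta0, weights = NULL,
                                clip = c(1e-3, 1e5)) {
  stopifnot(all(mu > 0), theta0 > 0)
  if (is.null(weights)) weights <- rep(1, length(y))
  score <- function(th)
    sum(weights * (digamma(y + th) - digamma(th) + log(th) + 1 -
                     log(th + mu) - (y + th) / (th + mu)))
  dscore <- function(th)
    sum(weights * (trigamma(y + th) - trigamma(th) + 1 / th -
                     2 / (th + mu) + (y + th) / (th + mu)^2))
  th <- min(max(theta0, clip[1L]), clip[2L])
  ok <- TRUE
  for (it in seq_len(50L)) {
    u <- score(th); du <- dscore(th)
    if (!is.finite(u) || !is.finite(du) || du >= 0) { ok <- FALSE; break }
    step <- u / du
    th_new <- th - step
    if (!is.finite(th_new) || th_new <= 0) th_new <- th / 2
    th_new <- min(max(th_new, clip[1L]), clip[2L])
    if (abs(th_new - th) < 1e-8 * (th + 1e-8)) { th <- th_new; break }
    th <- th_new
  }
  if (!ok) {
    warning("Newton update for theta unstable; using bracketed search",
            call. = FALSE)
    opt <- optimize(function(lt) nb_theta_loglik(exp(lt), y, mu, weights),
                    interval = log(clip), maximum = TRUE, tol = 1e-8)
    th <- exp(opt$maximum)
  }
  # boundary handling: if the score is still positive at the upper clip the
  # likelihood is increasing (near-Poisson data) and the clip is returned
  min(max(th, clip[1L]), clip[2L])
}

# one PQL run of the NB working model; shared by fit_nbmm and the ZINB M-step
nbmm_core <- function(design, control, prior_w = NULL, init = NULL,
                      max_sweeps = control$max_iter, update_theta = TRUE) {
  y <- design$y
  n <- length(y)
  if (is.null(prior_w)) prior_w <- rep(1, n)
  warns <- character()

  if (is.null(init)) {
    g0 <- tryCatch(
      suppressWarnings(glm.fit(x = design$X, y = y, weights = prior_w,
                               offset = design$offset, family = poisson())),
      error = function(e) NULL)
    mu <- if (is.null(g0)) pmax(y, 0) + 0.5 else pmax(g0$fitted.values, 1e-4)
    excess <- sum(prior_w * ((y - mu)^2 - mu))
    theta <- if (excess <= 0) 100 else sum(prior_w * mu^2) / excess
    theta <- min(max(theta, 1e-2), 1e3)
    beta <- rep(0, ncol(design$X))
  } else {
    mu <- init$mu; theta <- init$theta; beta <- init$beta
  }
  mu <- pmin(pmax(mu, control$mu_clip[1L]), control$mu_clip[2L])
  eta <- log(mu)

  lfit <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_sweeps)) {
    beta_old <- beta; theta_old <- theta
    zw <- nb_working_response_and_weights(y, eta, mu, theta, design$offset)
    lfit <- withCallingHandlers(
      fit_weighted_lmm(zw$z, design$X, design$groups,
                       weights = zw$w * prior_w, slope = design$slope,
                       correlation = design$correlation,
                       method = control$lmm_method),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    eta <- lfit$fitted + design$offset
    mu <- pmin(pmax(exp(eta), control$mu_clip[1L]), control$mu_clip[2L])
    eta <- log(mu)
    if (update_theta)
      theta <- update_theta_newton(y, mu, theta, weights = prior_w,
                                   clip = control$theta_clip)
    beta <- rep(0, ncol(design$X))
    names(beta) <- colnames(design$X)
    beta[names(lfit$beta)] <- lfit$beta
    if (length(beta_old) == length(beta)) {
      delta <- max(abs(beta - beta_old) / pmax(abs(beta_old), 1e-4),
                   abs(log(theta) - log(theta_old)))
      if (is.finite(delta) && delta < control$tol) { converged <- TRUE; break }
    }
  }
  list(lfit = lfit, beta = lfit$beta, mu = mu, eta = eta, theta = theta,
       n_iter = it, converged = converged, warnings = unique(warns))
}

#' Fit a negative binomial mixed model
#'
#' Fits the NBMM `C ~ NB(mu, theta)`, `log mu = offset + X beta + G b`,
#' `b ~ N(0, Psi)` by penalised quasi-likelihood: the model is repeatedly
#' linearised to a weighted linear mixed model (solved by the
#' [fit_weighted_lmm()] engine) and the dispersion is refreshed by
#' [update_theta_newton()] once per sweep, until the coefficients and
#' log-dispersion stabilise. Standard errors are taken from the final
#' working mixed model, as usual for PQL.
#'
#' @param design a `taxamix_design` from [build_design()] holding the
#'   count response.
#' @param control a [taxamix_control()].
#' @return an object of class `taxamix_fit`: lists `coef`, `se`,
#'   `pvalues` (component `count`), `vc` (random-effect covariance),
#'   `dispersion` (theta), `sigma2` (working-model residual variance),
#'   `rho`, `converged`, `n_iter`, `warnings`, `method`.
#' @export
fit_nbmm <- function(design, control = taxamix_control()) {
  stopifnot(inherits(design, "taxamix_design"))
  y <- design$y
  if (any(y < 0)) stop("negative counts")
  if (all(y == 0))
    stop("response is all zero; NBMM cannot be fitted - consider the ",
         "zero-inflated models for sparse taxa")
  if (any(abs(y - round(y)) > 1e-8))
    warning("non-integer counts supplied; proceeding via the NB ",
            "mean-variance relation", call. = FALSE)
  core <- nbmm_core(design, control)
  wt <- wald_table(core$lfit, ref = control$wald)
  new_fit(method = "nb", count = wt, zero = NULL,
          vc = list(count = core$lfit$psi, zero = NULL),
          dispersion = core$theta, sigma2 = core$lfit$sigma2,
          rho = core$lfit$rho, converged = core$converged,
          n_iter = core$n_iter, warnings = core$warnings,
          extra = list(mu = core$mu, eta = core$eta, lfit = core$lfit))
}

# shared FitResult constructor
new_fit <- function(method, count, zero, vc, dispersion, sigma2, rho,
                    converged, n_iter, warnings, extra = list(),
                    loglik_trace = NULL) {
  coefs <- list(count = setNames(count$estimate, count$term))
  ses <- list(count = setNames(count$se, count$term))
  ps <- list(count = setNames(count$pvalue, count$term))
  if (!is.null(zero)) {
    coefs$zero <- setNames(zero$estimate, zero$term)
    ses$zero <- setNames(zero$se, zero$term)
    ps$zero <- setNames(zero$pvalue, zero$term)
  }
  structure(c(list(coef = coefs, se = ses, pvalues = ps, vc = vc,
                   dispersion = dispersion, sigma2 = sigma2, rho = rho,
                   converged = converged, n_iter = n_iter,
                   warnings = warnings, method = method,
                   loglik_trace = loglik_trace), extra),
            class = "taxamix_fit")
}

#' @export
print.taxamix_fit <- function(x, ...) {
  cat(sprintf("taxamix %s fit (%s, %d iterations)\n", toupper(x$method),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  for (part in names(x$coef)) {
    cat(part, "part:\n")
    print(data.frame(estimate = x$coef[[part]], se = x$se[[part]],
                     pvalue = signif(x$pvalues[[part]], 4)))
  }
  lab <- if (x$method == "zig") "sigma2" else "theta"
  cat(sprintf("%s = %.4g\n", lab, x$dispersion))
  invisible(x)
}
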
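#' Fit a weighted linear mixed model
#'
#' The inner solver used by every outer algorithm in the package: a
#' Gaussian linear mixed model with a subject random intercept (optionally
#' plus one random slope), per-row prior weights, a known offset and an
#' optional AR(1) or compound-symmetry within-subject residual
#' correlation. Fitting is delegated to [nlme::lme()] with the prior
#' weights expressed as a fixed variance function (residual variance
#' proportional to `1/weights`). When every group is a singleton and no
#' correlation is requested the random intercept is unidentifiable and
#' the model collapses to weighted least squares, which is solved in
#' closed form.
#'
#' @param y numeric response vector.
#' @param X fixed-effects design matrix (including an intercept column if
#'   wanted). Aliased columns are dropped with a warning.
#' @param groups factor of subject membership per row; rows must be
#'   contiguous by group.
#' @param weights positive prior weights per row (default all 1).
#' @param offset known offset per row, subtracted from `y` before fitting
#'   and added back to the fitted values.
#' @param slope optional numeric vector giving the random-slope covariate.
#' @param correlation `"none"`, `"ar1"` or `"cs"` on observation order
#'   within group.
#' @param method `"REML"` (default) or `"ML"`.
#' @return a list of class `taxamix_lmm` with elements `beta`, `beta_cov`,
#'   `psi` (random-effect covariance), `sigma2`, `rho`, `loglik`,
#'   `fitted` (conditional means, offset included), `residuals`,
#'   `converged`, `warnings`, `n`, `n_groups`, `rank`, `dropped`.
#' @export
fit_weighted_lmm <- function(y, X, groups, weights = NULL, offset = NULL,
                             slope = NULL, correlation = c("none", "ar1", "cs"),
                             method = c("REML", "ML")) {
  correlation <- match.arg(correlation)
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(groups) == n)
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(offset)) offset <- rep(0, n)
  if (any(weights <= 0)) stop("weights must be strictly positive")
  warns <- character()

  # drop aliased columns once, so every solver sees a full-rank design
  qx <- qr(X)
  dropped <- character()
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    warns <- c(warns, paste("dropped aliased column(s):",
                            paste(dropped, collapse = ", ")))
    warning(warns[length(warns)], call. = FALSE)
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  p <- ncol(X)
  yo <- y - offset

  finish <- function(beta, beta_cov, psi, sigma2, rho, loglik, fitted_off,
                     converged) {
    structure(list(beta = beta, beta_cov = beta_cov, psi = psi,
                   sigma2 = sigma2, rho = rho, loglik = loglik,
                   fitted = fitted_off + offset,
                   residuals = y - (fitted_off + offset),
                   converged = converged, warnings = warns, n = n,
                   n_groups = nlevels(groups), rank = p, dropped = dropped,
                   method = method),
              class = "taxamix_lmm")
  }

  wls <- function(extra_warn = NULL) {
    if (!is.null(extra_warn)) warns <<- c(warns, extra_warn)
    A <- crossprod(X, weights * X)
    b <- crossprod(X, weights * yo)
    beta <- drop(solve(A, b))
    names(beta) <- colnames(X)
    fit0 <- drop(X %*% beta)
    dfres <- max(n - p, 1L)
    sigma2 <- sum(weights * (yo - fit0)^2) / dfres
    beta_cov <- sigma2 * solve(A)
    dimnames(beta_cov) <- list(colnames(X), colnames(X))
    q <- 1L + !is.null(slope)
    psi <- matrix(0, q, q)
    ll <- -0.5 * (n * log(2 * pi * sigma2) - sum(log(weights)) +
                    sum(weights * (yo - fit0)^2) / sigma2)
    finish(beta, beta_cov, psi, sigma2, NA_real_, ll, fit0,
           converged = is.null(extra_warn))
  }

  singleton <- all(tabulate(groups) == 1L)
  if (singleton && correlation == "none") return(wls())

  nm <- paste0(".x", seq_len(p))
  df <- data.frame(.y = yo, .g = groups, .iw = 1 / weights,
                   check.names = FALSE)
  for (j in seq_len(p)) df[[nm[j]]] <- X[, j]
  if (!is.null(slope)) df$.slope <- slope
  fixed <- as.formula(paste(".y ~ 0 +", paste(nm, collapse = " + ")))
  random <- if (is.null(slope)) ~ 1 | .g else ~ 1 + .slope | .g
  cs <- switch(correlation,
               none = NULL,
               ar1 = nlme::corAR1(form = ~ 1 | .g),
               cs = nlme::corCompSymm(form = ~ 1 | .g))
  vf <- if (length(unique(weights)) > 1L) nlme::varFixed(~.iw) else NULL
  ctrl <- nlme::lmeControl(opt = "optim", maxIter = 100, msMaxIter = 100,
                           niterEM = 25, returnObject = TRUE)
  fit <- tryCatch(
    withCallingHandlers(
      nlme::lme(fixed = fixed, random = random, data = df, weights = vf,
                correlation = cs, method = method, control = ctrl),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(wls(paste("lme failed, fell back to WLS:", conditionMessage(fit))))

  beta <- nlme::fixef(fit)
  names(beta) <- colnames(X)
  beta_cov <- as.matrix(vcov(fit))
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  psi <- tryCatch(unclass(nlme::getVarCov(fit)),
                  error = function(e) {
                    vc <- nlme::VarCorr(fit)
                    diag(as.numeric(vc[-nrow(vc), "Variance"]),
                         nrow = nrow(vc) - 1L)
                  })
  psi <- as.matrix(psi)
  rho <- if (is.null(cs)) NA_real_ else
    as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))[1L]
  fit0 <- as.numeric(fitted(fit))
  finish(beta, beta_cov, psi, fit$sigma^2, rho, as.numeric(logLik(fit)),
         fit0, converged = length(warns) == 0L || all(!grepl(
           "iteration|converg", warns, ignore.case = TRUE)))
}

#' Wald coefficient table
#'
#' Estimates, standard errors, statistics and two-sided p-values for the
#' fixed effects of a fitted model. The default reference distribution is
#' the standard normal; `ref = "t"` uses a Student t with denominator
#' degrees of freedom `n - n_groups - rank + 1`, a containment-style
#' approximation.
#'
#' @param fit a `taxamix_lmm` object from [fit_weighted_lmm()].
#' @param ref `"z"` or `"t"`.
#' @return data frame with columns `term`, `estimate`, `se`, `statistic`,
#'   `pvalue`.
#' @export
wald_table <- function(fit, ref = c("z", "t")) {
  ref <- match.arg(ref)
  est <- fit$beta
  se <- sqrt(pmax(diag(as.matrix(fit$beta_cov)), 0))
  stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  if (any(se == 0 & est != 0))
    warning("zero standard error with nonzero estimate; p-value set to 0")
  p <- if (ref == "z") 2 * pnorm(-abs(stat)) else {
    df <- max(fit$n - fit$n_groups - fit$rank + 1, 1)
    2 * pt(-abs(stat), df = df)
  }
  p[se == 0 & est == 0] <- 1
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             statistic = unname(stat), pvalue = unname(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' AR(1) within-subject correlation matrix
#'
#' Entry (j, k) equals `rho^|pos_j - pos_k|` where positions are the
#' within-subject observation order implied by `times_or_order` (ties keep
#' input order).
#'
#' @param times_or_order numeric vector of observation times or indices
#'   for one subject.
#' @param rho autoregressive parameter, `|rho| < 1`.
#' @return correlation matrix.
#' @export
ar1_correlation_matrix <- function(times_or_order, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  pos <- rank(times_or_order, ties.method = "first")
  rho^abs(outer(pos, pos, "-"))
}
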
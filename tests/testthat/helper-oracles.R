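# Independent oracles used across tests. These deliberately avoid the
# package's own fitting paths: direct likelihood maximisation with optim,
# Gauss-Hermite quadrature for the random-intercept marginal likelihood,
# and explicit per-subject multivariate normal likelihoods for the LMM.

# direct-likelihood NB GLM (log link, known offset)
nb_glm_oracle <- function(y, X, offset) {
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    theta <- exp(par[ncol(X) + 1L])
    mu <- exp(offset + drop(X %*% beta))
    -sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  }
  start <- c(qr.solve(X, log(y + 0.5) - offset), 0)
  o <- optim(start, nll, method = "BFGS", control = list(maxit = 1000))
  list(beta = o$par[seq_len(ncol(X))], theta = exp(o$par[ncol(X) + 1L]),
       nll = o$value, convergence = o$convergence)
}

# Gauss-Hermite nodes/weights by Golub-Welsch
gh_rule <- function(k) {
  i <- seq_len(k - 1L)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1L, ]^2)
}

# marginal likelihood of a random-intercept NB model by quadrature,
# maximised over (beta, log theta, log sd); quadrature recentred at the
# per-subject conditional mode (adaptive in the usual sense)
nb_ri_marginal_oracle <- function(y, X, offset, groups, nodes = 64) {
  gh <- gh_rule(nodes)
  glev <- unique(groups)
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    theta <- exp(par[ncol(X) + 1L])
    s <- exp(par[ncol(X) + 2L])
    eta0 <- offset + drop(X %*% beta)
    ll <- 0
    for (g in glev) {
      idx <- which(groups == g)
      lk <- vapply(seq_along(gh$x), function(k) {
        b <- sqrt(2) * s * gh$x[k]
        sum(dnbinom(y[idx], size = theta, mu = exp(eta0[idx] + b), log = TRUE))
      }, 0)
      m <- max(lk)
      ll <- ll + m + log(sum(gh$w / sqrt(pi) * exp(lk - m)))
    }
    if (!is.finite(ll)) 1e10 else -ll
  }
  start <- c(qr.solve(X, log(y + 0.5) - offset), 0, log(0.5))
  o <- optim(start, nll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-10))
  list(beta = o$par[seq_len(ncol(X))], theta = exp(o$par[ncol(X) + 1L]),
       sd = exp(o$par[ncol(X) + 2L]))
}

# explicit marginal Gaussian ML for a random-intercept LMM with optional
# AR(1)/CS residual correlation and prior weights, small instances only
lmm_ml_oracle <- function(y, X, groups, weights = rep(1, length(y)),
                          correlation = "none") {
  glev <- unique(groups)
  p <- ncol(X)
  nll <- function(par) {
    beta <- par[seq_len(p)]
    s2 <- exp(par[p + 1L])
    psi <- exp(par[p + 2L])
    rho <- if (correlation == "none") 0 else tanh(par[p + 3L])
    ll <- 0
    for (g in glev) {
      idx <- which(groups == g)
      k <- length(idx)
      R <- switch(correlation,
                  none = diag(k),
                  ar1 = rho^abs(outer(seq_len(k), seq_len(k), "-")),
                  cs = matrix(rho, k, k) + diag(1 - rho, k))
      sw <- 1 / sqrt(weights[idx])
      V <- psi + s2 * (sw %o% sw) * R
      r <- y[idx] - drop(X[idx, , drop = FALSE] %*% beta)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      z <- backsolve(ch, r, transpose = TRUE)
      ll <- ll - 0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
    }
    if (!is.finite(ll)) 1e10 else -ll
  }
  np <- p + 2L + (correlation != "none")
  start <- c(qr.solve(X, y), log(var(y) / 2 + 1e-3), log(var(y) / 2 + 1e-3),
             if (correlation != "none") 0)
  o <- optim(start, nll, method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-12))
  o <- optim(o$par, nll, method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-12))
  list(beta = o$par[seq_len(p)], sigma2 = exp(o$par[p + 1L]),
       psi = exp(o$par[p + 2L]), nll = o$value)
}

# small longitudinal metadata for hand-built designs
toy_meta <- function(n_subjects = 8, k = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = paste0("s", seq_len(n_subjects * k)),
    subject = rep(paste0("S", seq_len(n_subjects)), each = k),
    group = rep(rbinom(n_subjects, 1, 0.5), each = k),
    time = rep(seq_len(k) - 1, n_subjects) / max(k - 1, 1),
    age = rep(rnorm(n_subjects), each = k),
    total_reads = runif(n_subjects * k, 5e3, 5e4),
    stringsAsFactors = FALSE)
}
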
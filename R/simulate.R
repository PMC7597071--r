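#' Generating truth for a synthetic longitudinal microbiome dataset
#'
#' Collects every parameter of the generative models in one validated
#' object. The default covariate design mirrors a typical case-control
#' longitudinal study: a subject-level binary group, a sample-level time
#' covariate scaled to \[0, 1\], and a subject-level continuous nuisance
#' covariate (`age`), with per-sample sequencing totals drawn uniformly
#' from `total_reads_range` and unbalanced panel sizes drawn uniformly
#' from `samples_per_subject`.
#'
#' @param n_subjects number of subjects.
#' @param samples_per_subject integer range `c(lo, hi)`; each subject's
#'   sample count is drawn uniformly from it (equal values give a
#'   balanced design).
#' @param beta count-part fixed effects, named `intercept` and `group`.
#' @param beta_time,beta_age additional fixed effects (default 0).
#' @param theta NB dispersion.
#' @param sd_intercept,sd_slope random intercept / random time-slope
#'   standard deviations.
#' @param alpha zero-part fixed effects on the logit scale, named
#'   `intercept` (and optionally `group`), used by the zero-inflated
#'   generators; alternatively supply a constant `p_zero`.
#' @param p_zero constant zero-inflation probability (overrides `alpha`).
#' @param sigma Gaussian residual SD (ZIG generator).
#' @param rho AR(1) correlation of Gaussian residuals within subject
#'   (ZIG generator), `|rho| < 1`.
#' @param total_reads_range range of per-sample totals.
#' @param m number of taxa to simulate (independent given the shared
#'   design).
#' @param seed integer seed; every generator is fully reproducible from
#'   it.
#' @return a list of class `sim_truth`.
#' @export
sim_truth <- function(n_subjects = 100, samples_per_subject = c(5, 5),
                      beta = c(intercept = 1.0, group = 0.5),
                      beta_time = 0, beta_age = 0, theta = 2,
                      sd_intercept = 0.5, sd_slope = 0, alpha = NULL,
                      p_zero = NULL, sigma = 0.6, rho = 0,
                      total_reads_range = c(5e3, 5e4), m = 1, seed = 1) {
  stopifnot(n_subjects >= 2, length(samples_per_subject) == 2,
            samples_per_subject[1] >= 1,
            samples_per_subject[2] >= samples_per_subject[1],
            theta > 0, sd_intercept >= 0, sd_slope >= 0, sigma >= 0,
            abs(rho) < 1, total_reads_range[1] > 0,
            total_reads_range[2] >= total_reads_range[1], m >= 1)
  if (!is.null(p_zero)) stopifnot(p_zero >= 0, p_zero < 1)
  structure(list(n_subjects = n_subjects,
                 samples_per_subject = samples_per_subject, beta = beta,
                 beta_time = beta_time, beta_age = beta_age, theta = theta,
                 sd_intercept = sd_intercept, sd_slope = sd_slope,
                 alpha = alpha, p_zero = p_zero, sigma = sigma, rho = rho,
                 total_reads_range = total_reads_range, m = m,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

# shared design draw: subjects, panel sizes, covariates, totals, random effects
sim_design <- function(truth) {
  ni <- if (truth$samples_per_subject[1] == truth$samples_per_subject[2])
    rep(truth$samples_per_subject[1], truth$n_subjects)
  else
    sample(seq(truth$samples_per_subject[1], truth$samples_per_subject[2]),
           truth$n_subjects, replace = TRUE)
  subject <- rep(paste0("S", seq_len(truth$n_subjects)), times = ni)
  group_subj <- rbinom(truth$n_subjects, 1, 0.5)
  age_subj <- rnorm(truth$n_subjects)
  idx <- rep(seq_len(truth$n_subjects), times = ni)
  time <- unlist(lapply(ni, function(k) if (k == 1) 0 else (seq_len(k) - 1) / (k - 1)))
  n <- length(subject)
  meta <- data.frame(sample_id = paste0("s", seq_len(n)),
                     subject = subject,
                     group = group_subj[idx],
                     time = time,
                     age = age_subj[idx],
                     total_reads = runif(n, truth$total_reads_range[1],
                                         truth$total_reads_range[2]),
                     stringsAsFactors = FALSE)
  list(meta = meta, idx = idx, ni = ni, n = n)
}

sim_linpred <- function(truth, d, b0, b1 = NULL) {
  meta <- d$meta
  eta <- truth$beta[["intercept"]] + truth$beta[["group"]] * meta$group +
    truth$beta_time * meta$time + truth$beta_age * meta$age +
    b0[d$idx]
  if (!is.null(b1)) eta <- eta + b1[d$idx] * meta$time
  eta
}

sim_pzero <- function(truth, meta) {
  if (!is.null(truth$p_zero)) return(rep(truth$p_zero, nrow(meta)))
  if (is.null(truth$alpha)) return(rep(0, nrow(meta)))
  eta <- truth$alpha[["intercept"]] +
    if ("group" %in% names(truth$alpha)) truth$alpha[["group"]] * meta$group else 0
  plogis(eta)
}

#' Simulate counts from the NB mixed model
#'
#' Draws subject random effects, covariates and per-sample totals, then
#' counts `C ~ NB(mu, theta)` with
#' `log mu = log T + Xb + b0 (+ b1 * time)`. Fully reproducible from
#' `truth$seed`.
#'
#' @param truth a [sim_truth()].
#' @return list with `table` (a [taxa_table()]), `meta` (metadata data
#'   frame) and `truth` (the input, echoed).
#' @export
simulate_nbmm <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed)
  d <- sim_design(truth)
  counts <- matrix(0, d$n, truth$m)
  for (h in seq_len(truth$m)) {
    b0 <- rnorm(truth$n_subjects, 0, truth$sd_intercept)
    b1 <- if (truth$sd_slope > 0) rnorm(truth$n_subjects, 0, truth$sd_slope)
    eta <- log(d$meta$total_reads) + sim_linpred(truth, d, b0, b1)
    counts[, h] <- rnbinom(d$n, size = truth$theta, mu = exp(eta))
  }
  colnames(counts) <- paste0("taxon", seq_len(truth$m))
  rownames(counts) <- d$meta$sample_id
  list(table = taxa_table(counts), meta = d$meta, truth = truth)
}

#' Simulate counts from the zero-inflated NB mixed model
#'
#' As [simulate_nbmm()], then independently replaces each count by zero
#' with probability `p_ij` (a constant `p_zero` or
#' `plogis(Z alpha)`). The latent structural-zero indicators are
#' returned for E-step unit tests.
#'
#' @inheritParams simulate_nbmm
#' @return list with `table`, `meta`, `truth` and `latent` (samples x
#'   taxa 0/1 matrix of structural-zero indicators).
#' @export
simulate_zinbmm <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  sim <- simulate_nbmm(truth)
  d_meta <- sim$meta
  p <- sim_pzero(truth, d_meta)
  counts <- sim$table$counts
  latent <- matrix(0L, nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  for (h in seq_len(ncol(counts))) {
    z <- rbinom(nrow(counts), 1, p)
    latent[, h] <- z
    counts[z == 1, h] <- 0
  }
  list(table = taxa_table(counts), meta = d_meta, truth = truth,
       latent = latent)
}

#' Simulate transformed responses from the zero-inflated Gaussian model
#'
#' Responses are exactly zero with probability `p`, otherwise Gaussian
#' around `Xb + b0 (+ b1 * time)` with residual SD `sigma` and optional
#' AR(1) correlation `rho` within subject.
#'
#' @inheritParams simulate_nbmm
#' @return list with `y` (samples x taxa matrix of transformed-scale
#'   responses; Gaussian draws may be negative, only structural zeros
#'   are exactly zero), `meta`, `truth` and `latent`.
#' @export
simulate_zigmm <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed)
  d <- sim_design(truth)
  p <- sim_pzero(truth, d$meta)
  ymat <- matrix(0, d$n, truth$m)
  latent <- matrix(0L, d$n, truth$m)
  for (h in seq_len(truth$m)) {
    b0 <- rnorm(truth$n_subjects, 0, truth$sd_intercept)
    b1 <- if (truth$sd_slope > 0) rnorm(truth$n_subjects, 0, truth$sd_slope)
    mu <- sim_linpred(truth, d, b0, b1)
    eps <- if (abs(truth$rho) > 0) {
      unlist(lapply(seq_along(d$ni), function(i) {
        k <- d$ni[i]
        R <- ar1_correlation_matrix(seq_len(k), truth$rho)
        drop(t(chol(R)) %*% rnorm(k)) * truth$sigma
      }))
    } else rnorm(d$n, 0, truth$sigma)
    y <- mu + eps
    z <- rbinom(d$n, 1, p)
    latent[, h] <- z
    # a continuous Gaussian draw is almost surely nonzero, so exact zeros
    # mark the structural component only
    y[z == 1] <- 0
    ymat[, h] <- y
  }
  colnames(ymat) <- paste0("taxon", seq_len(truth$m))
  rownames(ymat) <- d$meta$sample_id
  list(y = ymat, meta = d$meta, truth = truth, latent = latent)
}
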
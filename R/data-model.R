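#' Construct a taxa abundance table
#'
#' A `taxa_table` stores abundances as a samples x taxa numeric matrix,
#' together with a flag saying whether entries are counts (possibly
#' fractional, as some pipelines emit) or proportions in \[0, 1\].
#'
#' @param counts numeric matrix, samples in rows, taxa in columns. Must be
#'   non-negative. Row and column names are used as sample and taxon
#'   identifiers when `sample_ids`/`taxon_ids` are not given.
#' @param taxon_ids character vector of unique taxon identifiers.
#' @param sample_ids character vector of unique sample identifiers.
#' @param is_proportion logical; `TRUE` when entries are proportions
#'   (every entry must then be in \[0, 1\]).
#' @return an object of class `taxa_table`.
#' @export
taxa_table <- function(counts, taxon_ids = colnames(counts),
                       sample_ids = rownames(counts),
                       is_proportion = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(counts)))
  taxon_ids <- as.character(taxon_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxon_ids) != ncol(counts))
    stop("taxon_ids length must equal the number of columns of counts")
  if (length(sample_ids) != nrow(counts))
    stop("sample_ids length must equal the number of rows of counts")
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon identifiers: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(counts)) stop("abundance table contains missing values")
  if (any(counts < 0)) stop("abundance table contains negative entries")
  if (is_proportion && any(counts > 1))
    stop("is_proportion = TRUE but entries exceed 1; rescale the table ",
         "(e.g. read with scale = 0.01 for percentages)")
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(list(counts = counts, taxon_ids = taxon_ids,
                 sample_ids = sample_ids, is_proportion = is_proportion),
            class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("taxa_table: %d samples x %d taxa (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$is_proportion) "proportions" else "counts"))
  invisible(x)
}

#' @export
dim.taxa_table <- function(x) dim(x$counts)

#' Read a taxa abundance table from delimited text
#'
#' Reads a TSV or CSV file whose first column holds identifiers, in either
#' orientation, and returns a [taxa_table()] oriented samples x taxa.
#' Entries are multiplied by `scale` on the way in (use e.g. `scale = 100`
#' to rescale fractions, or `scale = 0.01` to turn percentages into
#' proportions); no rescaling is ever applied silently.
#'
#' @param path file path to a delimited text file with a header row.
#' @param orientation `"samples_by_taxa"` (rows are samples) or
#'   `"taxa_by_samples"` (rows are taxa; the table is transposed).
#' @param scale positive multiplier applied to every entry.
#' @param sep field separator; defaults to `","` for `.csv` files and tab
#'   otherwise.
#' @inheritParams taxa_table
#' @return a [taxa_table()].
#' @export
read_taxa_table <- function(path,
                            orientation = c("samples_by_taxa", "taxa_by_samples"),
                            scale = 1, is_proportion = FALSE, sep = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (ncol(raw) < 2L) stop("expected an identifier column plus data columns in ", path)
  ids <- as.character(raw[[1L]])
  dat <- raw[, -1L, drop = FALSE]
  for (j in seq_along(dat)) {
    v <- dat[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                     v[bad[1L]], ids[bad[1L]], names(dat)[j], path))
      v <- vn
    }
    dat[[j]] <- v
  }
  mat <- as.matrix(dat) * scale
  rownames(mat) <- ids
  if (orientation == "taxa_by_samples") mat <- t(mat)
  taxa_table(mat, is_proportion = is_proportion)
}

#' log2(x + 1) transformation for counts
#'
#' Maps zero to exactly zero and is monotone non-decreasing.
#'
#' @param x non-negative numeric vector of counts.
#' @return `log2(x + 1)`.
#' @export
log2_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("log2_transform requires non-negative input")
  log2(x + 1)
}

#' Arcsine square root transformation for proportions
#'
#' Computes `asin(sqrt(x / totals))`, the variance-stabilising
#' transformation for proportion data; zero maps to exactly zero and the
#' range is \[0, pi/2\].
#'
#' @param x non-negative numeric vector (counts, or proportions with
#'   `totals = 1`).
#' @param totals positive totals, recycled against `x`; every `x` must be
#'   at most its total.
#' @return transformed vector.
#' @export
arcsine_sqrt_transform <- function(x, totals = 1) {
  if (any(x < 0, na.rm = TRUE)) stop("arcsine_sqrt_transform requires non-negative input")
  if (any(totals <= 0, na.rm = TRUE)) stop("totals must be positive")
  frac <- x / totals
  if (any(frac > 1 + 1e-12, na.rm = TRUE))
    stop("count exceeds its total in arcsine_sqrt_transform")
  asin(sqrt(pmin(frac, 1)))
}

#' Per-taxon proportion of nonzero samples
#'
#' @param table a [taxa_table()].
#' @return named numeric vector of length `m`, the fraction of strictly
#'   positive entries for each taxon.
#' @export
nonzero_proportions <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  if (nrow(table$counts) == 0L) stop("empty table")
  colMeans(table$counts > 0)
}

#' Specify a per-taxon mixed model
#'
#' Collects the fixed- and random-effect formulas, optional zero-part
#' formulas, residual correlation structure, offset policy and model
#' family in one object, mirroring the call signature shared by the
#' single-taxon fitters and the screening wrapper.
#'
#' @param fixed one-sided formula for the fixed effects of the abundance
#'   part, e.g. `~ group + time + age` (the response is supplied
#'   separately, per taxon).
#' @param random one-sided formula with grouping for the random effects,
#'   e.g. `~ 1 | subject` (random intercept) or `~ 1 + time | subject`
#'   (random intercept and slope).
#' @param zi_fixed optional one-sided formula for the fixed effects of the
#'   zero-inflation part (methods `"zinb"`/`"zig"` only); intercept-only
#'   when omitted.
#' @param zi_random optional `~ 1 | subject`-style formula adding a random
#'   intercept to the zero part.
#' @param correlation within-subject residual correlation: `"none"`,
#'   `"ar1"` (first-order autoregressive on observation order) or `"cs"`
#'   (compound symmetry).
#' @param offset_policy `"log_total_reads"` to include the log library
#'   size as an offset (counts), or `"none"` (required for proportions).
#' @param method model family: `"nb"`, `"zinb"`, `"zig"` or `"lmm"`.
#' @param total_var name of the metadata column holding total reads.
#' @param time_var optional name of the metadata column used to order
#'   samples within subject when `correlation = "ar1"`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(fixed, random, zi_fixed = NULL, zi_random = NULL,
                       correlation = c("none", "ar1", "cs"),
                       offset_policy = c("log_total_reads", "none"),
                       method = c("nb", "zinb", "zig", "lmm"),
                       total_var = "total_reads", time_var = NULL) {
  correlation <- match.arg(correlation)
  offset_policy <- match.arg(offset_policy)
  method <- match.arg(method)
  stopifnot(inherits(fixed, "formula"), inherits(random, "formula"))
  if (length(fixed) != 2L)
    stop("'fixed' must be one-sided (the response is supplied per taxon)")
  if (!is.null(zi_fixed) && !method %in% c("zinb", "zig"))
    stop("zero-part formulas are only allowed for methods 'zinb' and 'zig'")
  if (!is.null(zi_random) && !method %in% c("zinb", "zig"))
    stop("zero-part formulas are only allowed for methods 'zinb' and 'zig'")
  structure(list(fixed = fixed, random = parse_random(random),
                 zi_fixed = zi_fixed,
                 zi_random = if (is.null(zi_random)) NULL else parse_random(zi_random),
                 correlation = correlation, offset_policy = offset_policy,
                 method = method, total_var = total_var, time_var = time_var),
            class = "model_spec")
}

# split "~ lhs | group" into slope variables and the grouping variable
parse_random <- function(f) {
  rhs <- f[[length(f)]]
  if (!(is.call(rhs) && identical(as.character(rhs[[1L]]), "|")))
    stop("random formula must have the form ~ terms | group")
  grp <- all.vars(rhs[[3L]])
  if (length(grp) != 1L) stop("random formula needs exactly one grouping variable")
  slope_vars <- setdiff(all.vars(rhs[[2L]]), c("1"))
  if (length(slope_vars) > 1L)
    stop("at most one random slope variable is supported")
  list(group = grp, slope = if (length(slope_vars)) slope_vars else NULL)
}

#' Build the per-taxon design bundle
#'
#' Expands the model formulas against the sample metadata for one response
#' vector: fixed-effect and zero-part design matrices, the offset implied
#' by the offset policy, the grouping factor, and the row ordering (rows
#' are grouped contiguously by subject, and ordered by `time_var` within
#' subject when the correlation is AR(1)). Rows with missing values in
#' any model variable are dropped, with the count recorded.
#'
#' @param meta data frame of per-sample metadata; must contain the
#'   grouping variable, every formula variable, and `total_var` whenever
#'   an offset is requested.
#' @param spec a [model_spec()].
#' @param response numeric response vector aligned with `meta` rows.
#' @param is_proportion logical; `TRUE` forbids a library-size offset.
#' @return a list of class `taxamix_design` with elements `y`, `X`, `Z`,
#'   `offset`, `groups`, `slope`, `correlation`, `order`, `n_dropped`,
#'   `spec`.
#' @export
build_design <- function(meta, spec, response, is_proportion = FALSE) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(meta))
  if (length(response) != nrow(meta))
    stop("response length must equal the number of metadata rows")
  if (is_proportion && spec$offset_policy != "none")
    stop("offset_policy must be 'none' for proportion responses")

  vars <- unique(c(all.vars(spec$fixed), spec$random$group, spec$random$slope,
                   if (!is.null(spec$zi_fixed)) all.vars(spec$zi_fixed),
                   if (!is.null(spec$zi_random))
                     c(spec$zi_random$group, spec$zi_random$slope),
                   if (!is.null(spec$time_var)) spec$time_var,
                   if (spec$offset_policy == "log_total_reads") spec$total_var))
  missing_vars <- setdiff(vars, names(meta))
  if (length(missing_vars))
    stop("variable(s) not found in metadata: ", paste(missing_vars, collapse = ", "))

  dat <- meta[, vars, drop = FALSE]
  # first-observed level as reference for categorical covariates
  for (v in names(dat))
    if (is.character(dat[[v]]) || is.logical(dat[[v]]))
      dat[[v]] <- factor(dat[[v]], levels = unique(dat[[v]]))
  keep <- complete.cases(dat) & !is.na(response)
  n_dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  y <- response[keep]

  if (spec$offset_policy == "log_total_reads") {
    totals <- dat[[spec$total_var]]
    if (!is.numeric(totals) || any(totals <= 0))
      stop("'", spec$total_var, "' must be positive wherever an offset is required")
    offset <- if (spec$method == "zig") log2(totals) else log(totals)
  } else {
    offset <- rep(0, nrow(dat))
  }

  subj <- dat[[spec$random$group]]
  ord <- if (spec$correlation == "ar1" && !is.null(spec$time_var))
    order(match(subj, unique(subj)), dat[[spec$time_var]])
  else
    order(match(subj, unique(subj)))
  dat <- dat[ord, , drop = FALSE]
  y <- y[ord]
  offset <- offset[ord]
  groups <- factor(dat[[spec$random$group]], levels = unique(dat[[spec$random$group]]))

  X <- model.matrix(spec$fixed, dat)
  zf <- if (is.null(spec$zi_fixed)) ~1 else spec$zi_fixed
  Z <- if (spec$method %in% c("zinb", "zig")) model.matrix(zf, dat) else NULL
  slope <- if (is.null(spec$random$slope)) NULL else dat[[spec$random$slope]]

  structure(list(y = y, X = X, Z = Z, offset = offset, groups = groups,
                 slope = slope, correlation = spec$correlation,
                 order = which(keep)[ord], n_dropped = n_dropped,
                 zi_random = spec$zi_random, spec = spec, data = dat),
            class = "taxamix_design")
}

#' Fitting control parameters
#'
#' @param tol relative-change convergence tolerance for the outer IWLS
#'   loop of the NB fitter (on coefficients and log dispersion).
#' @param max_iter maximum outer IWLS iterations.
#' @param em_tol absolute-change tolerance on all linear-scale parameters
#'   for the EM loops.
#' @param em_max_iter maximum EM iterations.
#' @param inner_sweeps IWLS sweeps of the count part per EM M-step.
#' @param theta_clip admissible range for the NB dispersion.
#' @param p_clip admissible range for zero-inflation probabilities.
#' @param mu_clip admissible range for fitted NB means.
#' @param wald reference distribution for Wald p-values: `"z"` (standard
#'   normal) or `"t"` (Student t with a containment-style denominator df).
#' @param lmm_method `"REML"` or `"ML"` for the inner linear mixed model.
#' @param force_zero_p logical; force the zero-inflation probability to
#'   zero, collapsing the ZINB fitter onto the NB fitter (testing aid).
#' @return a list of class `taxamix_control`.
#' @export
taxamix_control <- function(tol = 1e-5, max_iter = 50, em_tol = 1e-4,
                            em_max_iter = 100, inner_sweeps = 5,
                            theta_clip = c(1e-3, 1e5),
                            p_clip = c(1e-6, 1 - 1e-6),
                            mu_clip = c(1e-8, 1e8),
                            wald = c("z", "t"),
                            lmm_method = c("REML", "ML"),
                            force_zero_p = FALSE) {
  wald <- match.arg(wald)
  lmm_method <- match.arg(lmm_method)
  structure(list(tol = tol, max_iter = max_iter, em_tol = em_tol,
                 em_max_iter = em_max_iter, inner_sweeps = inner_sweeps,
                 theta_clip = theta_clip, p_clip = p_clip, mu_clip = mu_clip,
                 wald = wald, lmm_method = lmm_method,
                 force_zero_p = force_zero_p),
            class = "taxamix_control")
}
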
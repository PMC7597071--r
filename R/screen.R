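#' Fit one taxon with the family named in the model spec
#'
#' Builds the design for one response vector and dispatches to
#' [fit_nbmm()], [fit_zinbmm()], [fit_zigmm()] or a plain linear mixed
#' model. For method `"zig"` the response is transformed first:
#' log2(C+1) for count tables, arcsine square root for proportion tables.
#' Methods `"nb"`/`"zinb"` require a count table.
#'
#' @param response raw abundance vector for one taxon, aligned with
#'   `meta` rows.
#' @param meta per-sample metadata data frame.
#' @param spec a [model_spec()].
#' @param control a [taxamix_control()].
#' @param is_proportion whether `response` holds proportions.
#' @return a `taxamix_fit`.
#' @export
fit_taxon <- function(response, meta, spec, control = taxamix_control(),
                      is_proportion = FALSE) {
  y <- response
  if (spec$method == "zig") {
    y <- if (is_proportion) arcsine_sqrt_transform(response, 1)
         else log2_transform(response)
  } else if (spec$method %in% c("nb", "zinb") && is_proportion) {
    stop("methods 'nb' and 'zinb' require count data, not proportions")
  }
  design <- build_design(meta, spec, y, is_proportion = is_proportion)
  switch(spec$method,
         nb = fit_nbmm(design, control),
         zinb = fit_zinbmm(design, control),
         zig = fit_zigmm(design, control),
         lmm = {
           lfit <- fit_weighted_lmm(design$y, design$X, design$groups,
                                    offset = design$offset,
                                    slope = design$slope,
                                    correlation = design$correlation,
                                    method = control$lmm_method)
           wt <- wald_table(lfit, ref = control$wald)
           new_fit(method = "lmm", count = wt, zero = NULL,
                   vc = list(count = lfit$psi, zero = NULL),
                   dispersion = lfit$sigma2, sigma2 = lfit$sigma2,
                   rho = lfit$rho, converged = lfit$converged, n_iter = 1L,
                   warnings = lfit$warnings, extra = list(lfit = lfit))
         })
}

#' Screen many taxa with one model family
#'
#' The many-taxa wrapper: taxa whose nonzero proportion is at most
#' `min_p` are skipped as filtered; the remaining taxa are fitted
#' independently, each inside its own error handler so a failing taxon
#' is recorded and never aborts the run. With `sort = TRUE` taxa are
#' analysed in decreasing order of nonzero proportion (ties keep input
#' order).
#'
#' @param table a [taxa_table()].
#' @param meta per-sample metadata; rows aligned with the table's
#'   samples.
#' @param spec a [model_spec()].
#' @param min_p inclusion threshold: only taxa with nonzero proportion
#'   strictly greater than `min_p` are analysed. Default 0.
#' @param sort analyse (and report) in decreasing nonzero proportion.
#' @param control a [taxamix_control()].
#' @return an object of class `taxamix_screen` with elements `fits`
#'   (named list of `taxamix_fit`), `skipped` (named character vector of
#'   reasons, `"filtered"` or `"failed: <message>"`), `order` (taxon ids
#'   in analysis order), `nonzero` and `settings`.
#' @export
screen_taxa <- function(table, meta, spec, min_p = 0, sort = FALSE,
                        control = taxamix_control()) {
  stopifnot(inherits(table, "taxa_table"), inherits(spec, "model_spec"))
  if (nrow(table$counts) != nrow(meta))
    stop("table and metadata must cover the same samples")
  stopifnot(min_p >= 0, min_p <= 1)
  nzp <- nonzero_proportions(table)
  keep <- nzp > min_p
  skipped <- setNames(rep("filtered", sum(!keep)), table$taxon_ids[!keep])
  ids <- table$taxon_ids[keep]
  if (sort) ids <- ids[order(-nzp[keep])]
  if (!length(ids)) warning("no taxa pass the nonzero-proportion filter")

  fits <- list()
  for (id in ids) {
    res <- tryCatch(
      fit_taxon(table$counts[, id], meta, spec, control,
                is_proportion = table$is_proportion),
      error = function(e) e)
    if (inherits(res, "error"))
      skipped[[id]] <- paste0("failed: ", conditionMessage(res))
    else
      fits[[id]] <- res
  }
  structure(list(fits = fits, skipped = skipped,
                 order = names(fits), nonzero = nzp,
                 settings = list(spec = spec, min_p = min_p, sort = sort)),
            class = "taxamix_screen")
}

#' @export
print.taxamix_screen <- function(x, ...) {
  cat(sprintf("taxamix screen (%s): %d fitted, %d skipped (%d filtered)\n",
              x$settings$spec$method, length(x$fits), length(x$skipped),
              sum(x$skipped == "filtered")))
  invisible(x)
}

#' Long table of fixed effects across all fitted taxa
#'
#' One row per (taxon, coefficient, part), in analysis order, with part
#' `"count"` for the abundance model and `"zero"` for the
#' zero-inflation model. Failed and filtered taxa contribute no rows.
#'
#' @param result a `taxamix_screen` (or a single `taxamix_fit`, taken as
#'   one unnamed taxon).
#' @return data frame with columns `taxon`, `term`, `part`, `estimate`,
#'   `se`, `pvalue`, `converged`.
#' @export
fixed_table <- function(result) {
  if (inherits(result, "taxamix_fit"))
    result <- structure(list(fits = list(taxon = result),
                             order = "taxon"), class = "taxamix_screen")
  stopifnot(inherits(result, "taxamix_screen"))
  rows <- lapply(result$order, function(id) {
    fit <- result$fits[[id]]
    do.call(rbind, lapply(names(fit$coef), function(part) {
      data.frame(taxon = id, term = names(fit$coef[[part]]), part = part,
                 estimate = unname(fit$coef[[part]]),
                 se = unname(fit$se[[part]]),
                 pvalue = unname(fit$pvalues[[part]]),
                 converged = fit$converged, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(taxon = character(), term = character(),
                      part = character(), estimate = numeric(),
                      se = numeric(), pvalue = numeric(),
                      converged = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract one covariate's effects across taxa
#'
#' Per-taxon estimate, standard error and p-value for a single
#' coefficient, across every fitted taxon whose model contains it (a
#' taxon in which the term was dropped as aliased is omitted, with a
#' note attached to the result).
#'
#' @param result a `taxamix_screen`.
#' @param vr_name coefficient label, e.g. `"group"` or a factor contrast
#'   such as `"groupB"`.
#' @param part `"count"` or `"zero"`.
#' @return data frame with columns `taxon`, `estimate`, `se`, `pvalue`;
#'   attribute `"omitted"` lists taxa lacking the term.
#' @export
get_fixed <- function(result, vr_name, part = "count") {
  tab <- fixed_table(result)
  tab <- tab[tab$part == part, , drop = FALSE]
  avail <- unique(tab$term)
  if (!vr_name %in% avail)
    stop("term '", vr_name, "' not found; available terms: ",
         paste(avail, collapse = ", "))
  out <- tab[tab$term == vr_name, c("taxon", "estimate", "se", "pvalue")]
  rownames(out) <- NULL
  omitted <- setdiff(unique(tab$taxon), out$taxon)
  if (length(omitted))
    message("term '", vr_name, "' aliased out of: ",
            paste(omitted, collapse = ", "))
  attr(out, "omitted") <- omitted
  attr(out, "term") <- vr_name
  out
}

#' Multiplicity adjustment of screening p-values
#'
#' Adds an `adjusted` column. `"BH"` applies the Benjamini-Hochberg
#' step-up procedure separately within each (term, part) across taxa;
#' `"none"` copies the raw p-values.
#'
#' @param table a long results table from [fixed_table()].
#' @param method `"none"` or `"BH"`.
#' @return the table with an `adjusted` column appended.
#' @export
adjust_pvalues <- function(table, method = c("none", "BH")) {
  method <- match.arg(method)
  stopifnot(all(c("term", "part", "pvalue") %in% names(table)))
  table$adjusted <- if (method == "none") table$pvalue else
    ave(table$pvalue, interaction(table$term, table$part, drop = TRUE),
        FUN = function(p) p.adjust(p, method = "BH"))
  table
}
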
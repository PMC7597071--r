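# truncate taxon labels, keeping them unique
abbreviate_taxa <- function(x, width = 20) {
  out <- substr(x, 1L, width)
  make.unique(out, sep = "~")
}

#' Forest-style display of fixed effects
#'
#' Plots the point estimate and a 95% interval (estimate +/- 1.96 se)
#' for every (taxon, term) row of a screening results table, colouring
#' significant effects (p < alpha) differently from insignificant ones
#' and annotating each row with its p-value. The exact numeric table
#' that is drawn is returned, so tests can check the numbers without
#' comparing images.
#'
#' @param table long results table from [fixed_table()] (optionally
#'   after [adjust_pvalues()]; the raw `pvalue` column is used).
#' @param alpha significance threshold for display emphasis.
#' @param terms optional character vector restricting the display to a
#'   subset of coefficient names.
#' @param part model part to display (default `"count"`).
#' @param significant_only drop rows with p >= alpha before plotting.
#' @param out optional image path (`.png`, `.pdf`, `.svg`); when given
#'   the figure is written there.
#' @param width,height device size in inches when `out` is given.
#' @return (invisibly) a list with `data` (the plotted table, including
#'   `lower`/`upper`/`significant` columns) and `plot` (the ggplot).
#' @export
plot_fixed <- function(table, alpha = 0.05, terms = NULL, part = "count",
                       significant_only = FALSE, out = NULL,
                       width = 7, height = 7) {
  stopifnot(alpha > 0, alpha < 1,
            all(c("taxon", "term", "estimate", "se", "pvalue") %in% names(table)))
  df <- table[table$part == part, , drop = FALSE]
  if (!is.null(terms)) df <- df[df$term %in% terms, , drop = FALSE]
  df$lower <- df$estimate - 1.96 * df$se
  df$upper <- df$estimate + 1.96 * df$se
  df$significant <- df$pvalue < alpha
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  if (!nrow(df)) {
    warning("nothing to plot after filtering")
    return(invisible(list(data = df, plot = NULL)))
  }
  df$label <- paste(abbreviate_taxa(df$taxon), df$term, sep = " : ")
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  df$p_text <- formatC(df$pvalue, format = "g", digits = 2)
  xpos <- max(df$upper) + 0.08 * diff(range(c(df$lower, df$upper), finite = TRUE))
  g <- ggplot(df, aes(x = .data$estimate, y = .data$label,
                      colour = .data$significant)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$lower, xmax = .data$upper),
                   height = 0.25) +
    geom_point(size = 1.8) +
    geom_text(x = xpos, label = df$p_text, hjust = 0, size = 2.8,
              colour = "grey30") +
    scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                        name = sprintf("p < %.3g", alpha)) +
    coord_cartesian(clip = "off") +
    labs(x = "estimate (95% interval)", y = NULL) +
    theme_bw() +
    theme(plot.margin = margin(5.5, 60, 5.5, 5.5))
  if (!is.null(out)) ggsave(out, g, width = width, height = height)
  invisible(list(data = df[, setdiff(names(df), c("label", "p_text"))],
                 plot = g))
}

#' Signed p-value heat map across taxa and covariates
#'
#' A taxa x terms matrix of p-values coloured on the -log10 scale
#' (capped at 10), with a "+" overlay on cells whose effect is
#' significant (p < alpha) and positive. Missing (taxon, term)
#' combinations — e.g. terms aliased out of a taxon — stay missing
#' rather than being drawn as zero.
#'
#' @inheritParams plot_fixed
#' @param cap ceiling for -log10(p) in the colour scale.
#' @return (invisibly) a list with `p` (taxa x terms p-value matrix),
#'   `sign` (character matrix, `"+"` where significant and positive) and
#'   `plot` (the ggplot).
#' @export
heat_p <- function(table, alpha = 0.05, terms = NULL, part = "count",
                   cap = 10, out = NULL, width = 7, height = 7) {
  stopifnot(alpha > 0, alpha < 1)
  df <- table[table$part == part, , drop = FALSE]
  if (!is.null(terms)) df <- df[df$term %in% terms, , drop = FALSE]
  if (!nrow(df)) stop("no rows to display")
  taxa <- unique(df$taxon)
  tms <- unique(df$term)
  P <- matrix(NA_real_, length(taxa), length(tms),
              dimnames = list(taxa, tms))
  S <- matrix("", length(taxa), length(tms), dimnames = list(taxa, tms))
  for (i in seq_len(nrow(df))) {
    P[df$taxon[i], df$term[i]] <- df$pvalue[i]
    if (!is.na(df$pvalue[i]) && df$pvalue[i] < alpha && df$estimate[i] > 0)
      S[df$taxon[i], df$term[i]] <- "+"
  }
  long <- data.frame(
    taxon = factor(rep(abbreviate_taxa(taxa), times = length(tms)),
                   levels = rev(abbreviate_taxa(taxa))),
    term = factor(rep(tms, each = length(taxa)), levels = tms),
    p = as.vector(P), sign = as.vector(S), stringsAsFactors = FALSE)
  long$neglog <- pmin(-log10(long$p), cap)
  g <- ggplot(long, aes(x = .data$term, y = .data$taxon,
                        fill = .data$neglog)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = .data$sign), colour = "black", size = 4) +
    scale_fill_gradient(low = "lightyellow", high = "firebrick",
                        na.value = "grey85", limits = c(0, cap),
                        name = "-log10(p)") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
  if (!is.null(out)) ggsave(out, g, width = width, height = height)
  invisible(list(p = P, sign = S, plot = g))
}
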
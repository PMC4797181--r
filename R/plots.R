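CHROM_ORDER <- c(as.character(1:22), "X")

#' Volcano-plot coordinates
#'
#' Numeric layer behind [volcano()]: `x = log2(OR)`, `y = -log10(P)`,
#' with points below the threshold (strict) highlighted. Degenerate/separated
#' results are dropped.
#'
#' @param results An [assoc_scan()] tibble.
#' @param threshold Highlighting P threshold in `(0, 1)` (default 0.01).
#' @return Tibble `rsid, x, y, highlight`.
#' @export
volcano_data <- function(results, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ok <- results[results$status_flag == "ok", , drop = FALSE]
  if (nrow(ok) == 0) stop("no usable (ok) results to plot")
  tibble::tibble(rsid = ok$rsid, x = log2(ok$or_), y = -log10(ok$p),
                 highlight = ok$p < threshold)
}

#' Volcano plot of association significance versus fold change
#'
#' Plots `-log10(P)` against `log2(OR)` per variant, highlighting points with
#' P strictly below the threshold, in the style used for sex-stratified trait
#' association panels.
#'
#' @inheritParams volcano_data
#' @param path Output image path (extension selects the device: png/pdf/svg).
#' @return Invisibly, the ggplot object; writes `path` if non-NULL.
#' @export
volcano <- function(results, threshold = 0.01, path = NULL) {
  dat <- volcano_data(results, threshold)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight), size = 1.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::labs(x = expression(log[2] ~ "OR"),
                  y = expression(-log[10] ~ italic(P))) +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, gg, width = 5, height = 4, dpi = 150)
  invisible(gg)
}

#' Manhattan-plot coordinates for sex-differentiated P values
#'
#' Orders variants by chromosome (1..22 then X) and position and maps
#' `y = -log10(p_het)`; points with `p_het` strictly below the threshold are
#' highlighted.
#'
#' @param results A [sexdiff_scan()] tibble.
#' @param variants [variant_info()] table supplying `chrom`/`pos` per rsid.
#' @param threshold Highlighting threshold (default 0.01).
#' @return Tibble `rsid, chrom, pos, x, y, highlight` in plotting order.
#' @export
manhattan_data <- function(results, variants, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  idx <- match(results$rsid, variants$rsid)
  if (anyNA(idx)) {
    stop("missing chromosome annotation for: ",
         paste(results$rsid[is.na(idx)], collapse = ", "))
  }
  dat <- tibble::tibble(
    rsid = results$rsid,
    chrom = factor(variants$chrom[idx], levels = CHROM_ORDER),
    pos = variants$pos[idx],
    y = -log10(results$p_het),
    highlight = results$p_het < threshold
  )
  dat <- dat[order(dat$chrom, dat$pos), , drop = FALSE]
  dat$x <- seq_len(nrow(dat))
  dat
}

#' Manhattan plot of sex-differentiated P values
#'
#' @inheritParams manhattan_data
#' @param path Optional output image path.
#' @return Invisibly, the ggplot object.
#' @export
manhattan_sexdiff <- function(results, variants, threshold = 0.01, path = NULL) {
  dat <- manhattan_data(results, variants, threshold)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chrom,
                                     alpha = .data$highlight), size = 1.2) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                guide = "none") +
    ggplot2::guides(colour = "none") +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::labs(x = "variant (chromosome order)",
                  y = expression(-log[10] ~ "sex-differentiated" ~ italic(P))) +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, gg, width = 7, height = 3.5, dpi = 150)
  invisible(gg)
}

#' Female versus male minor-allele-frequency scatter
#'
#' Scatter of per-variant MAF in females against males with the panel-level
#' squared correlation annotated; the annotation equals [maf_by_sex()]'s
#' `r_squared` exactly.
#'
#' @param maf A [maf_by_sex()] result (list with `summary` and `r_squared`).
#' @param path Optional output image path.
#' @return Invisibly, the ggplot object.
#' @export
maf_scatter <- function(maf, path = NULL) {
  dat <- maf$summary[!is.na(maf$summary$maf_f) & !is.na(maf$summary$maf_m), ]
  if (nrow(dat) < 2) stop("need at least two variants with both frequencies")
  lab <- sprintf("R² = %.3f", maf$r_squared)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$maf_f, y = .data$maf_m)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 1.2, alpha = 0.7) +
    ggplot2::annotate("text", x = 0.1, y = 0.47, label = lab, hjust = 0) +
    ggplot2::labs(x = "MAF (females)", y = "MAF (males)") +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, gg, width = 4.5, height = 4.5, dpi = 150)
  invisible(gg)
}

#' Enrichment bar chart
#'
#' Percentage of significant SNP-trait associations in the protective and
#' risk directions per sex and trait, with the underlying counts atop the
#' bars.
#'
#' @param tables [enrichment_from_counts()] or per-trait
#'   [build_trait_table()] rows.
#' @param path Optional output image path.
#' @return Invisibly, the ggplot object.
#' @export
enrichment_bars <- function(tables, path = NULL) {
  long <- tidyr::pivot_longer(
    tables[, c("trait", "prot_f", "risk_f", "prot_m", "risk_m")],
    cols = -"trait", names_to = c("direction", "sex"), names_sep = "_",
    values_to = "count"
  )
  long <- dplyr::mutate(
    dplyr::group_by(long, .data$trait, .data$sex),
    # a sex with zero significant associations plots as empty bars, not NaN
    pct = if (sum(.data$count) > 0) 100 * .data$count / sum(.data$count) else 0
  )
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sex, y = .data$pct,
                                           fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count),
                       position = ggplot2::position_dodge(width = 0.9),
                       vjust = -0.3, size = 2.8) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::scale_fill_manual(values = c(prot = "steelblue4", risk = "firebrick3"),
                               labels = c(prot = "protective", risk = "risk")) +
    ggplot2::labs(x = NULL, y = "% of significant associations", fill = NULL) +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, gg, width = 7, height = 5, dpi = 150)
  invisible(gg)
}
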
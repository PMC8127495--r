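# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-phenotype result
#'
#' @param x a `cpag_result`.
#' @param ... unused.
#' @return plain tibble, one row per trait pair.
#' @method tidy cpag_result
#' @export
tidy.cpag_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a cross-phenotype run
#'
#' @param x a `cpag_result`.
#' @param ... unused.
#' @return tibble with pair counts, correction size, N_e and the number of
#'   BH-significant pairs.
#' @method glance cpag_result
#' @export
glance.cpag_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_significant = sum(x$significant),
    m = attr(x, "m"),
    fdr = attr(x, "fdr"),
    population = attr(x, "population"),
    n_e = attr(x, "n_e"),
    min_p_fisher = if (nrow(x)) exp(min(x$log_p_fisher)) else NA_real_
  )
}

#' Plot a cross-phenotype result
#'
#' Horizontal bar chart of the strongest pairs on the -log10 BH-adjusted
#' scale, filled by the direct/indirect composition of the shared blocks.
#'
#' @param object a `cpag_result`.
#' @param n_top show at most this many pairs (default 20).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cpag_result
#' @export
autoplot.cpag_result <- function(object, n_top = 20, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::arrange(.data$log_p_bh) |>
    utils::head(n_top) |>
    dplyr::mutate(
      pair = paste(.data$trait1, .data$trait2, sep = " ~ "),
      neglog10_bh = -.data$log_p_bh / log(10)) |>
    tidyr::pivot_longer(c("k_direct", "k_indirect"), names_to = "mode",
                        values_to = "blocks")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$neglog10_bh,
    y = stats::reorder(.data$pair, .data$neglog10_bh),
    fill = .data$mode)) +
    ggplot2::geom_col(data = ~ dplyr::distinct(.x, .data$pair,
                                               .keep_all = TRUE),
                      fill = "grey80") +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "fdr")),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "BH-adjusted p"), y = NULL,
                  title = "Cross-phenotype enrichment") +
    ggplot2::theme_minimal()
}

#' Tidy a colocalization result
#'
#' @param x a `coloc_result`.
#' @param ... unused.
#' @return per-SNP tibble with log ABFs and the normalized H4 contribution.
#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  x$snps
}

#' One-row summary of a colocalization result
#'
#' @param x a `coloc_result`.
#' @param ... unused.
#' @return tibble with `pp0`..`pp4`, `nsnps`, `lead_causal_snp`.
#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  x$summary
}

#' Plot a colocalization result
#'
#' Posterior probabilities of the five hypotheses, plus the per-SNP H4
#' contribution along the region.
#'
#' @param object a `coloc_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  pp <- tidyr::pivot_longer(object$summary, dplyr::all_of(paste0("pp", 0:4)),
                            names_to = "hypothesis", values_to = "posterior")
  ggplot2::ggplot(pp, ggplot2::aes(x = toupper(.data$hypothesis),
                                   y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Posterior probability",
                  title = sprintf("%s vs %s (%d SNPs; candidate %s)",
                                  object$summary$trait1,
                                  object$summary$trait2,
                                  object$summary$nsnps,
                                  object$summary$lead_causal_snp)) +
    ggplot2::theme_minimal()
}

#' Plot the prior-sensitivity curve
#'
#' @param sens output of [prior_sensitivity()].
#' @return a ggplot object: PP3 and PP4 against the shared prior `p12`.
#' @export
plot_prior_sensitivity <- function(sens) {
  df <- tidyr::pivot_longer(sens, c("pp3", "pp4"), names_to = "hypothesis",
                            values_to = "posterior")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p12, y = .data$posterior,
                                   colour = toupper(.data$hypothesis))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p12 prior", y = "Posterior", colour = NULL) +
    ggplot2::theme_minimal()
}
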
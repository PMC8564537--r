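#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a codon usage table
#'
#' @param x A `codon_usage` object.
#' @param ... Unused.
#' @return A plain tibble of the per-codon rows.
#' @method tidy codon_usage
#' @export
tidy.codon_usage <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a codon usage table
#'
#' @param x A `codon_usage` object.
#' @param ... Unused.
#' @return Tibble with `total_codons`, `dropped_nt`, `ambiguous_codons` and,
#'   when classified, `n_optimal`, `n_non_optimal`, `n_no_preference`.
#' @method glance codon_usage
#' @export
glance.codon_usage <- function(x, ...) {
  out <- tibble(total_codons = attr(x, "total_codons"),
                dropped_nt = attr(x, "dropped_nt"),
                ambiguous_codons = attr(x, "ambiguous_codons"))
  if ("class" %in% names(x)) {
    out$n_optimal <- sum(x$class == "optimal", na.rm = TRUE)
    out$n_non_optimal <- sum(x$class == "non_optimal", na.rm = TRUE)
    out$n_no_preference <- sum(x$class == "no_preference", na.rm = TRUE)
  }
  out
}

#' Tidy a supermatrix (its partition map)
#'
#' @param x A `supermatrix`.
#' @param ... Unused.
#' @return Tibble `gene`, `start`, `end`.
#' @method tidy supermatrix
#' @export
tidy.supermatrix <- function(x, ...) partition_map(x)

#' One-row summary of a supermatrix
#'
#' @param x A `supermatrix`.
#' @param ... Unused.
#' @return Tibble with `n_species`, `n_genes`, `alignment_length`.
#' @method glance supermatrix
#' @export
glance.supermatrix <- function(x, ...) {
  p <- partition_map(x)
  tibble(n_species = nrow(x), n_genes = nrow(p),
         alignment_length = if (nrow(p) > 0) max(p$end) else 0L)
}

#' RSCU bar chart per amino acid
#'
#' Stacked RSCU bars per amino acid, the standard display of codon-usage
#' bias in organelle genome reports.
#'
#' @param object A classified `codon_usage` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot codon_usage
#' @export
autoplot.codon_usage <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    filter(!is.na(.data$rscu)) %>%
    mutate(aa = ifelse(.data$aa == "*", "Stop", .data$aa))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa, y = .data$rscu,
                                   fill = .data$codon)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2,
                      show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "amino acid", y = "RSCU") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Composition and skew overview plot
#'
#' Per-class AT and GC skews by genome, as a dot plot about zero.
#'
#' @param report Output of [composition_report()].
#' @return A ggplot.
#' @export
plot_skews <- function(report) {
  df <- report %>%
    select("name", "class", "at_skew", "gc_skew") %>%
    tidyr::pivot_longer(c("at_skew", "gc_skew"),
                        names_to = "statistic", values_to = "skew") %>%
    filter(!is.na(.data$skew))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$skew,
                                   colour = .data$name,
                                   shape = .data$statistic)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 3,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "gene class", y = "skew") +
    ggplot2::theme_minimal()
}
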
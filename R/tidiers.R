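#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CCT report into its per-site table
#'
#' @param x A `cct_report` from [cct_bounds()].
#' @param ... Unused.
#' @return A tibble with one row per diagnostic site.
#' @method tidy cct_report
#' @export
tidy.cct_report <- function(x, ...) {
  as_tibble(x$sites)
}

#' One-row summary of a CCT report
#'
#' @param x A `cct_report`.
#' @param ... Unused.
#' @return A one-row tibble of the tract bounds and site counts.
#' @method glance cct_report
#' @export
glance.cct_report <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    n_homoplastic = sum(x$sites$homoplasy_flag),
    lower_bound_3prime = x$lower_bound_3prime,
    upper_bound_3prime = x$upper_bound_3prime,
    lower_bound_5prime = x$lower_bound_5prime,
    upper_bound_5prime = x$upper_bound_5prime
  )
}

#' Tidy a retroprocessing report
#'
#' @param x A `retro_report` from [retro_signature()].
#' @param ... Unused.
#' @return A tibble with one row per informative downstream edit site.
#' @method tidy retro_report
#' @export
tidy.retro_report <- function(x, ...) {
  mutate(x$states, taxon = x$taxon, .before = 1)
}

#' One-row summary of a retroprocessing report
#'
#' @param x A `retro_report`.
#' @param ... Unused.
#' @return A one-row tibble with the verdict and site tallies.
#' @method glance retro_report
#' @export
glance.retro_report <- function(x, ...) {
  tibble(
    taxon = x$taxon,
    verdict = x$verdict,
    n_informative = nrow(x$states),
    n_converted = sum(x$states$observed_state == "T")
  )
}

#' Tidy a simulated data set into its truth table
#'
#' @param x A `cox1_sim` from [simulate_locus()].
#' @param ... Unused.
#' @return The event truth table (tibble).
#' @method tidy cox1_sim
#' @export
tidy.cox1_sim <- function(x, ...) {
  as_tibble(x$truth)
}

#' Footprint map of a CCT report
#'
#' Diagnostic sites along the signed exon axis, coloured by site class,
#' homoplastic sites hollow, with the 3' minimum-tract bound and (when
#' finite) the endpoint upper bound as dashed lines.
#'
#' @param object A `cct_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cct_report
#' @export
autoplot.cct_report <- function(object, ...) {
  sites <- as_tibble(object$sites)
  p <- ggplot2::ggplot(sites, ggplot2::aes(x = .data$position, y = 0)) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$site_class, shape = .data$homoplasy_flag),
      size = 3) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 1),
      labels = c(`FALSE` = "clean", `TRUE` = "homoplastic"),
      name = NULL) +
    ggplot2::geom_vline(xintercept = object$lower_bound_3prime,
                        linetype = "dashed") +
    ggplot2::labs(x = "signed position relative to intron insertion site (bp)",
                  y = NULL, colour = "site class") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::theme_minimal()
  if (is.finite(object$upper_bound_3prime)) {
    p <- p + ggplot2::geom_vline(xintercept = object$upper_bound_3prime,
                                 linetype = "dotted")
  }
  p
}

#' Amplicon-size view of an intron survey
#'
#' @param object A tibble from [survey_introns()].
#' @param ... Unused.
#' @return A ggplot of per-taxon amplicon lengths coloured by call.
#' @export
plot_survey <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$amplicon_length,
                               y = stats::reorder(.data$taxon,
                                                  .data$amplicon_length),
                               fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "amplicon length (bp)", y = NULL,
                  fill = "intron call") +
    ggplot2::theme_minimal()
}
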
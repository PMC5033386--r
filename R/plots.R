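# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline labs
#'   geom_line geom_segment geom_errorbar theme_minimal facet_wrap
#'   geom_histogram
NULL

#' @export
ggplot2::autoplot

#' Plot a constraint fit
#'
#' Scatter of synonymous versus total pairwise divergence within a
#' lineage, with the fitted through-origin slope.
#'
#' @param object A `constraint_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.constraint_fit <- function(object, ...) {
  ggplot(object$points, aes(x = .data$d_total, y = .data$d_syn)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = object$slope, intercept = 0, colour = "firebrick") +
    labs(
      x = "total divergence (subs/site)",
      y = "synonymous divergence (subs/site)",
      title = sprintf("Functional constraint: slope = %.3f",
                      object$slope),
      subtitle = object$lineage_id
    ) +
    theme_minimal()
}

#' Plot an MCMC trace
#'
#' Trace and marginal histogram per recorded parameter.
#'
#' @param object A `posterior_trace`.
#' @param parameters Parameter names to show (default: clade ages).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.posterior_trace <- function(object, parameters = NULL, ...) {
  samples <- object$samples
  if (is.null(parameters)) {
    parameters <- setdiff(names(samples),
                          c("state", "loglik", "mean_rate"))
  }
  long <- samples |>
    select(dplyr::all_of(c("state", parameters))) |>
    tidyr::pivot_longer(-"state", names_to = "parameter")
  ggplot(long, aes(x = .data$state, y = .data$value)) +
    geom_line(linewidth = 0.2) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "generation", y = NULL) +
    theme_minimal()
}

#' Dyad divergence-time plot
#'
#' Point-and-interval display of lineage and lineage-pair TMRCAs (the
#' Fig-3 style summary).
#'
#' @param dyads Tibble from [lineage_divergence_times()] (`$dyads`).
#' @return A ggplot.
#' @export
plot_dyad_times <- function(dyads) {
  d <- dyads |> arrange(.data$mean) |>
    mutate(clade = factor(.data$clade, levels = .data$clade))
  ggplot(d, aes(x = .data$mean, y = .data$clade)) +
    geom_segment(aes(x = .data$hpd_lower, xend = .data$hpd_upper,
                     yend = .data$clade),
                 colour = "grey60", linetype = 2) +
    geom_point(colour = "firebrick", size = 2) +
    labs(x = "divergence time (My)", y = NULL,
         title = "Lineage and dyad TMRCAs (mean and 95% HPD)") +
    theme_minimal()
}

#' Per-species diversity plot
#'
#' Dot display of the per-species dN/dS with the Z-test significance.
#'
#' @param report Tibble from [diversity_report()].
#' @return A ggplot.
#' @export
plot_diversity <- function(report) {
  ggplot(report, aes(x = .data$species, y = .data$dn_ds)) +
    geom_point(aes(size = -log10(pmax(.data$p_z_full, 1e-6)))) +
    labs(x = NULL, y = "dN/dS",
         size = "-log10 p (Z-test)",
         title = "Per-species selection on the amplicon") +
    theme_minimal()
}
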
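# The functional-constraint-adjusted substitution rate: within a
# supported lineage, synonymous pairwise divergence is regressed (through
# the origin) on total pairwise divergence; the slope estimates the
# fraction of the genome-wide neutral rate at which the fragment
# accumulates synonymous change, and multiplying the slope by a neutral
# nuclear rate gives the lineage's clock rate for dating.

#' Published neutral nuclear substitution rates (per site per year)
#'
#' Whole-genome neutral rate estimates used to scale the constraint
#' slope: zebra finch 2.21e-9 and domestic chicken 1.91e-9
#' substitutions/site/year.
#'
#' @return Named numeric vector.
#' @export
neutral_rates <- function() {
  c(zebra_finch = 2.21e-9, chicken = 1.91e-9)
}

#' Functional-constraint slope of a lineage
#'
#' For every unordered pair of lineage members, computes total divergence
#' (Jukes-Cantor-corrected across the whole fragment) and synonymous
#' divergence (modified Nei-Gojobori dS) and fits dS = slope * d_total
#' through the origin by least squares.
#'
#' @param lineage_alignment Alignment of one lineage's members (>= 3).
#' @param R Transition/transversion ratio for the NG site counting; if
#'   `NULL`, estimated from the data.
#' @param frame_offset Reading-frame offset.
#' @param lineage_id Label stored with the fit.
#' @return Object of class `constraint_fit`: `points` (tibble `pair_a`,
#'   `pair_b`, `d_total`, `d_syn`), `slope`, `n_members`, `lineage_id`.
#' @export
constraint_slope <- function(lineage_alignment, R = NULL,
                             frame_offset = 0L, lineage_id = NA_character_) {
  aln <- as_allele_alignment(lineage_alignment)
  n <- nrow(aln)
  if (n < 3) abort("need >= 3 lineage members (>= 3 pairs)",
                   class = "mhctsp_error")
  if (is.null(R)) R <- estimate_ts_tv_ratio(aln)
  pts <- list()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d_tot <- pairwise_distance(aln$seq[i], aln$seq[j], "JC")$d_jc
      d_syn <- pairwise_dn_ds(aln$seq[i], aln$seq[j], R, frame_offset)$ds
      pts[[length(pts) + 1L]] <- tibble(
        pair_a = aln$allele[i], pair_b = aln$allele[j],
        d_total = d_tot, d_syn = d_syn
      )
    }
  }
  points <- bind_rows(pts)
  slope <- origin_slope(points$d_total, points$d_syn)
  structure(
    list(points = points, slope = slope, n_members = n,
         lineage_id = lineage_id, R = R),
    class = "constraint_fit"
  )
}

#' Least-squares slope through the origin
#'
#' The estimator behind [constraint_slope()]: a zero-divergence pair must
#' have zero synonymous divergence, so the regression has no intercept.
#'
#' @param x,y Numeric vectors (total and synonymous divergence).
#' @return Scalar slope; errors when all `x` are zero.
#' @export
origin_slope <- function(x, y) {
  if (all(x == 0)) {
    abort("all pairs identical: slope undefined", class = "mhctsp_error")
  }
  sum(x * y) / sum(x^2)
}

#' Adjusted substitution rate of a lineage
#'
#' Multiplies the constraint slope by a neutral nuclear rate (per site
#' per year) and converts to substitutions/site/My.
#'
#' @param fit A `constraint_fit` (or a bare slope).
#' @param neutral_rate Neutral rate in subs/site/year, or a name from
#'   [neutral_rates()] (`"zebra_finch"`, `"chicken"`).
#' @return Rate in substitutions/site/My.
#' @export
adjusted_rate <- function(fit, neutral_rate = "zebra_finch") {
  slope <- if (inherits(fit, "constraint_fit")) fit$slope else fit
  if (is.na(slope)) abort("slope undefined", class = "mhctsp_error")
  if (is.character(neutral_rate)) {
    neutral_rate <- neutral_rates()[[neutral_rate]]
  }
  slope * neutral_rate * 1e6
}

#' @export
print.constraint_fit <- function(x, ...) {
  cat("Constraint fit", if (!is.na(x$lineage_id)) x$lineage_id else "",
      ": slope", signif(x$slope, 4), "from", nrow(x$points),
      "pairs (", x$n_members, "members )\n")
  invisible(x)
}

#' @export
tidy.constraint_fit <- function(x, ...) x$points

#' @export
glance.constraint_fit <- function(x, ...) {
  tibble(
    lineage = x$lineage_id, slope = x$slope, n_members = x$n_members,
    n_pairs = nrow(x$points), ts_tv_ratio = x$R,
    adjusted_rate_zebra_finch = adjusted_rate(x, "zebra_finch"),
    adjusted_rate_chicken = adjusted_rate(x, "chicken")
  )
}

#' Constraint slopes and adjusted rates for all detected lineages
#'
#' @param alignment Allele alignment.
#' @param lineages Lineage membership from [detect_lineages()].
#' @param R Transition/transversion ratio (`NULL` = per-lineage
#'   estimate).
#' @param frame_offset Reading-frame offset.
#' @return Tibble: one row per lineage (slope, adjusted rates under both
#'   neutral rates) plus the across-lineage average rates as attribute
#'   `avg_rates`; fits stored in attribute `fits`.
#' @export
lineage_rates <- function(alignment, lineages, R = NULL,
                          frame_offset = 0L) {
  fits <- lapply(split(lineages$allele, lineages$lineage), function(ids) {
    constraint_slope(alignment |> filter(.data$allele %in% ids),
                     R = R, frame_offset = frame_offset)
  })
  for (nm in names(fits)) fits[[nm]]$lineage_id <- nm
  out <- purrr::map_dfr(fits, glance)
  attr(out, "fits") <- fits
  attr(out, "avg_rates") <- c(
    zebra_finch = mean(out$adjusted_rate_zebra_finch),
    chicken = mean(out$adjusted_rate_chicken)
  )
  out
}
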
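# Trace summaries: effective sample size by Geyer's initial monotone
# positive sequence estimator, shortest-interval HPDs, and the
# S2/S3-style per-parameter summary table.

#' Effective sample size of an MCMC trace
#'
#' Geyer's initial monotone positive sequence estimator on the lag
#' autocorrelations.
#'
#' @param x Numeric vector of (possibly autocorrelated) samples.
#' @return ESS estimate (`n` for iid input; `0 < ESS <= n`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(n)
  lag_max <- min(n - 2L, 2000L)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf
  rho <- as.numeric(ac) # rho[1] is lag 0 (= 1)
  # paired sums Gamma_k = rho(2k) + rho(2k+1), k = 0, 1, ...
  n_pairs <- floor(length(rho) / 2)
  gam <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  # truncate at the first nonpositive pair, enforce monotone decrease
  neg <- which(gam <= 0)
  stop_at <- if (length(neg)) neg[1] - 1L else n_pairs
  if (stop_at < 1) return(n)
  g <- cummin(gam[seq_len(stop_at)])
  tau <- -1 + 2 * sum(g) # integrated autocorrelation time
  tau <- max(tau, 1e-8)
  min(n, n / tau)
}

#' Highest posterior density interval
#'
#' Shortest interval containing `level` of the sorted samples.
#'
#' @param x Numeric samples.
#' @param level Mass contained (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(xs[1], xs[n]))
  widths <- xs[(m + 1):n] - xs[1:(n - m)]
  i <- which.min(widths)
  c(xs[i], xs[i + m])
}

#' Summarise an MCMC trace
#'
#' Per parameter: mean, SD, SE = SD/sqrt(ESS), ESS, and the `level` HPD
#' interval.
#'
#' @param trace A `posterior_trace` (see [mcmc_date()]) or a data frame
#'   of samples (one column per parameter).
#' @param level HPD mass (default 0.95).
#' @return Tibble with columns `parameter`, `mean`, `sd`, `se`, `ess`,
#'   `hpd_lower`, `hpd_upper`, `hpd_width`.
#' @export
trace_summary <- function(trace, level = 0.95) {
  samples <- if (inherits(trace, "posterior_trace")) trace$samples else
    as_tibble(trace)
  samples <- samples[, !names(samples) %in% "state", drop = FALSE]
  if (nrow(samples) < 100) {
    abort("need >= 100 post-burnin samples", class = "mhctsp_error")
  }
  purrr::map_dfr(names(samples), function(nm) {
    x <- samples[[nm]]
    e <- ess(x)
    h <- hpd_interval(x, level)
    s <- stats::sd(x)
    tibble(
      parameter = nm, mean = mean(x), sd = s,
      se = if (e > 0) s / sqrt(e) else NA_real_,
      ess = e, hpd_lower = h[1], hpd_upper = h[2],
      hpd_width = h[2] - h[1]
    )
  })
}
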
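# Modified Nei-Gojobori dN/dS with Jukes-Cantor correction, the codon-based
# Z-test for positive selection, Tajima's D and the entropy-based
# substitution-saturation index.

.jc_codon <- function(p) {
  suppressWarnings(ifelse(p < 0.75, -3 / 4 * log(1 - 4 * p / 3), NA_real_))
}

# per-codon-pair contributions for two codon index vectors (NA = excluded)
.ng_pair_terms <- function(idx1, idx2, syn_sites) {
  keep <- !is.na(idx1) & !is.na(idx2)
  tabs <- ng_diff_tables()
  flat <- (idx2[keep] - 1L) * 64L + idx1[keep]
  list(
    keep = keep,
    sd = tabs$sd[flat],
    nd = tabs$nd[flat],
    s = (syn_sites[idx1[keep]] + syn_sites[idx2[keep]]) / 2,
    n = 3 - (syn_sites[idx1[keep]] + syn_sites[idx2[keep]]) / 2
  )
}

codon_indices <- function(seq, frame_offset = 0L) {
  codon_index(seq_codons(seq, frame_offset))
}

#' Pairwise dN and dS by the modified Nei-Gojobori method
#'
#' Counts synonymous and nonsynonymous sites with transitions weighted `R`
#' against transversions, averages observed differences over all minimal
#' substitution pathways (pathways through stop codons excluded), and
#' applies the Jukes-Cantor correction to the proportions.
#'
#' @param s1,s2 Equal-length nucleotide strings.
#' @param R Transition/transversion ratio used in site counting.
#' @param frame_offset 5' bases to skip; the incomplete 3' codon is dropped.
#' @param codon_subset Optional integer vector of codon positions (after
#'   framing) to restrict the computation to, e.g. a PBR mask.
#' @return One-row tibble with `dn`, `ds`, `n_sites`, `s_sites`, `nd`, `sd`,
#'   `pn`, `ps` and `saturated`.
#' @export
pairwise_dn_ds <- function(s1, s2, R = 1, frame_offset = 0L,
                           codon_subset = NULL) {
  idx1 <- codon_indices(s1, frame_offset)
  idx2 <- codon_indices(s2, frame_offset)
  if (length(idx1) != length(idx2)) {
    abort("sequences must contain the same number of codons",
          class = "mhctsp_error")
  }
  if (!is.null(codon_subset)) {
    idx1 <- idx1[codon_subset]
    idx2 <- idx2[codon_subset]
  }
  if (any(idx1 %in% STOP_IDX, na.rm = TRUE) ||
      any(idx2 %in% STOP_IDX, na.rm = TRUE)) {
    abort("premature stop codon in input sequence", class = "mhctsp_error")
  }
  syn <- ng_syn_sites(R)
  tm <- .ng_pair_terms(idx1, idx2, syn)
  S <- sum(tm$s); N <- sum(tm$n)
  sd_tot <- sum(tm$sd); nd_tot <- sum(tm$nd)
  ps <- if (S > 0) sd_tot / S else 0
  pn <- if (N > 0) nd_tot / N else 0
  ds <- .jc_codon(ps)
  dn <- .jc_codon(pn)
  saturated <- is.na(ds) || is.na(dn)
  if (saturated) {
    abort(
      sprintf("dN/dS saturated (pN=%.3f, pS=%.3f)", pn, ps),
      class = "mhctsp_saturation"
    )
  }
  tibble(
    dn = dn, ds = ds, n_sites = N, s_sites = S,
    nd = nd_tot, sd = sd_tot, pn = pn, ps = ps, saturated = saturated
  )
}

#' Estimate the transition/transversion ratio from an alignment
#'
#' Mean over sequence pairs of the K2-implied ratio of transition to
#' transversion distance components. Pairs with no transversions or
#' saturated logs are skipped; returns `fallback` if nothing is estimable.
#'
#' @param alignment Allele alignment (see [as_allele_alignment()]).
#' @param fallback Value returned when no pair yields an estimate.
#' @return Positive scalar.
#' @export
estimate_ts_tv_ratio <- function(alignment, fallback = 2) {
  alignment <- as_allele_alignment(alignment)
  n <- nrow(alignment)
  if (n < 2) return(fallback)
  vals <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      r <- pairwise_distance(alignment$seq[i], alignment$seq[j],
                             model = "K2", allow_saturated = TRUE)
      if (r$saturated || r$Q == 0 || r$P == 0) next
      a1 <- 1 - 2 * r$P - r$Q
      a2 <- 1 - 2 * r$Q
      if (a1 <= 0 || a2 <= 0) next
      d_ts <- -0.5 * log(a1) + 0.25 * log(a2)
      d_tv <- -0.5 * log(a2)
      if (d_tv > 0 && d_ts > 0) vals <- c(vals, d_ts / d_tv)
    }
  }
  if (length(vals) == 0) return(fallback)
  mean(vals)
}

#' Nucleotide diversity of an alignment
#'
#' Mean over all unordered sequence pairs of the p-distance (`overall`),
#' synonymous (`dS`) or nonsynonymous (`dN`) pairwise divergence; `dS`/`dN`
#' use the modified Nei-Gojobori method. Saturated pairs are excluded; the
#' exclusion count is attached as attribute `n_excluded`.
#'
#' @param alignment Allele alignment.
#' @param mode `"overall"`, `"dS"` or `"dN"`.
#' @param R Transition/transversion ratio for the NG site counting.
#' @param frame_offset Reading-frame offset for `dS`/`dN`.
#' @return Scalar diversity with attribute `n_excluded`.
#' @export
nucleotide_diversity <- function(alignment, mode = c("overall", "dS", "dN"),
                                 R = 1, frame_offset = 0L) {
  mode <- match.arg(mode)
  alignment <- as_allele_alignment(alignment)
  n <- nrow(alignment)
  if (n < 2) abort("need at least 2 sequences", class = "mhctsp_error")
  vals <- c()
  excl <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      v <- tryCatch({
        if (mode == "overall") {
          pairwise_distance(alignment$seq[i], alignment$seq[j], "p")$p
        } else {
          r <- pairwise_dn_ds(alignment$seq[i], alignment$seq[j], R,
                              frame_offset)
          if (mode == "dS") r$ds else r$dn
        }
      }, mhctsp_saturation = function(e) NA_real_)
      if (is.na(v)) excl <- excl + 1L else vals <- c(vals, v)
    }
  }
  out <- if (length(vals)) mean(vals) else NA_real_
  attr(out, "n_excluded") <- excl
  out
}

# per-codon contribution matrices used by the Z-test bootstrap:
# rows = sequence pairs, cols = codon positions
.ng_pair_matrices <- function(codmat, codon_pos, R) {
  n <- nrow(codmat)
  pairs <- combn(n, 2)
  np <- ncol(pairs)
  nc <- length(codon_pos)
  syn <- ng_syn_sites(R)
  tabs <- ng_diff_tables()
  SD <- matrix(0, np, nc); ND <- matrix(0, np, nc)
  Sm <- matrix(0, np, nc); Nm <- matrix(0, np, nc)
  for (k in seq_len(np)) {
    i1 <- codmat[pairs[1, k], codon_pos]
    i2 <- codmat[pairs[2, k], codon_pos]
    ok <- !is.na(i1) & !is.na(i2)
    flat <- (i2[ok] - 1L) * 64L + i1[ok]
    SD[k, ok] <- tabs$sd[flat]
    ND[k, ok] <- tabs$nd[flat]
    Sm[k, ok] <- (syn[i1[ok]] + syn[i2[ok]]) / 2
    Nm[k, ok] <- 3 - Sm[k, ok]
  }
  list(SD = SD, ND = ND, S = Sm, N = Nm)
}

.mean_dn_minus_ds <- function(mats, w) {
  sd_t <- mats$SD %*% w
  nd_t <- mats$ND %*% w
  S <- mats$S %*% w
  N <- mats$N %*% w
  ps <- sd_t / pmax(S, 1e-12)
  pn <- nd_t / pmax(N, 1e-12)
  ds <- .jc_codon(ps)
  dn <- .jc_codon(pn)
  list(
    diff = colMeans(dn - ds, na.rm = TRUE),
    mean_dn = colMeans(dn, na.rm = TRUE),
    mean_ds = colMeans(ds, na.rm = TRUE)
  )
}

#' Codon-based Z-test for positive selection
#'
#' Tests H1: mean pairwise dN > mean pairwise dS (modified Nei-Gojobori with
#' Jukes-Cantor correction, averaged over all sequence pairs). The standard
#' error of (dN - dS) comes from bootstrap resampling of codon columns.
#'
#' @param alignment Allele alignment.
#' @param partition `"full"`, `"pbr"` or `"non_pbr"`.
#' @param boot_reps Number of bootstrap replicates (>= 100).
#' @param R Transition/transversion ratio for site counting.
#' @param frame_offset Reading-frame offset.
#' @param pbr_mask Codon positions of the peptide-binding region; required
#'   for the `pbr`/`non_pbr` partitions.
#' @param seed Optional integer seed for the bootstrap.
#' @return One-row tibble with `partition`, `n_seq`, `n_codons`, `mean_dn`,
#'   `mean_ds`, `z`, `p_value` and `applicable` (`FALSE` for monomorphic
#'   alignments, where the test is undefined).
#' @export
codon_z_test <- function(alignment, partition = c("full", "pbr", "non_pbr"),
                         boot_reps = 500, R = 1, frame_offset = 0L,
                         pbr_mask = NULL, seed = NULL) {
  partition <- match.arg(partition)
  if (boot_reps < 100) abort("boot_reps must be >= 100", class = "mhctsp_error")
  alignment <- as_allele_alignment(alignment)
  if (!is.null(seed)) set.seed(seed)
  cods <- lapply(alignment$seq, codon_indices, frame_offset = frame_offset)
  codmat <- do.call(rbind, cods)
  if (any(codmat %in% STOP_IDX, na.rm = TRUE)) {
    abort("premature stop codon in alignment", class = "mhctsp_error")
  }
  n_codons_total <- ncol(codmat)
  codon_pos <- switch(partition,
    full = seq_len(n_codons_total),
    pbr = intersect(pbr_mask, seq_len(n_codons_total)),
    non_pbr = setdiff(seq_len(n_codons_total), pbr_mask)
  )
  if (length(codon_pos) == 0) {
    abort("empty codon partition", class = "mhctsp_error")
  }
  na_row <- function(applicable) tibble(
    partition = partition, n_seq = nrow(alignment),
    n_codons = length(codon_pos),
    mean_dn = NA_real_, mean_ds = NA_real_,
    z = NA_real_, p_value = NA_real_, applicable = applicable
  )
  if (nrow(alignment) < 2) return(na_row(FALSE))
  sub <- codmat[, codon_pos, drop = FALSE]
  mono <- all(apply(sub, 2, function(x) length(unique(x[!is.na(x)])) <= 1L))
  if (mono) return(na_row(FALSE))
  mats <- .ng_pair_matrices(codmat, codon_pos, R)
  nc <- length(codon_pos)
  obs <- .mean_dn_minus_ds(mats, matrix(1, nc, 1))
  W <- rmultinom(boot_reps, nc, rep(1 / nc, nc))
  boot <- .mean_dn_minus_ds(mats, W)
  se <- stats::sd(boot$diff, na.rm = TRUE)
  if (!is.finite(se) || se == 0) return(na_row(FALSE))
  z <- obs$diff / se
  tibble(
    partition = partition, n_seq = nrow(alignment), n_codons = nc,
    mean_dn = obs$mean_dn, mean_ds = obs$mean_ds,
    z = z, p_value = 1 - pnorm(z), applicable = TRUE
  )
}

#' Tajima's D
#'
#' Standard Tajima (1989) D from the number of segregating sites and the
#' mean pairwise difference count. Sites with ambiguous bases are ignored.
#'
#' @param alignment Allele alignment with at least 4 sequences.
#' @return Scalar D, or `NA` when there are no segregating sites.
#' @export
tajimas_d <- function(alignment) {
  alignment <- as_allele_alignment(alignment)
  n <- nrow(alignment)
  if (n < 4) abort("Tajima's D needs >= 4 sequences", class = "mhctsp_error")
  mat <- do.call(rbind, strsplit(alignment$seq, ""))
  usable <- apply(mat, 2, function(col) all(col %in% NUC))
  mat <- mat[, usable, drop = FALSE]
  S <- sum(apply(mat, 2, function(col) length(unique(col)) > 1L))
  if (S == 0L) return(NA_real_)
  k <- mean(combn(n, 2, function(ij) sum(mat[ij[1], ] != mat[ij[2], ])))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Entropy-based substitution-saturation test
#'
#' Computes an index of substitution saturation as the ratio of the mean
#' per-site Shannon entropy to the expected per-site entropy at full
#' saturation (estimated by Monte-Carlo on alignments of iid uniform
#' bases with the same dimensions), together with a critical value and a
#' one-sample t-test of the per-site index values against it.
#'
#' @param alignment Allele alignment with >= 4 sequences and >= 4 sites.
#' @param reps Monte-Carlo replicates for the saturation expectation.
#' @param seed Optional integer seed.
#' @return One-row tibble with `iss`, `iss_c`, `p_value`, `n_seq`, `n_sites`.
#' @export
saturation_test <- function(alignment, reps = 50, seed = NULL) {
  alignment <- as_allele_alignment(alignment)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(alignment)
  if (n < 4) abort("saturation test needs >= 4 sequences",
                   class = "mhctsp_error")
  L <- alignment_length(alignment)
  if (L < 4) abort("alignment shorter than 4 sites", class = "mhctsp_error")
  mat <- do.call(rbind, strsplit(alignment$seq, ""))
  site_entropy <- function(col) {
    col <- col[col %in% NUC]
    if (length(col) == 0) return(NA_real_)
    f <- table(factor(col, levels = NUC)) / length(col)
    f <- f[f > 0]
    -sum(f * log2(f))
  }
  h_obs <- apply(mat, 2, site_entropy)
  # expected per-site entropy at full saturation for n sequences
  sim_h <- replicate(reps, {
    simmat <- matrix(sample(NUC, n * L, replace = TRUE), n, L)
    apply(simmat, 2, site_entropy)
  })
  h_fss <- mean(sim_h)
  iss_site <- h_obs / h_fss
  iss <- mean(iss_site, na.rm = TRUE)
  # critical value: mean index of the fully saturated simulations
  iss_c <- mean(colMeans(sim_h) / h_fss)
  vals <- iss_site[!is.na(iss_site)]
  if (stats::sd(vals) == 0) {
    p <- if (iss < iss_c) 0 else 1
  } else {
    tt <- stats::t.test(vals, mu = iss_c, alternative = "less")
    p <- tt$p.value
  }
  tibble(iss = iss, iss_c = iss_c, p_value = p, n_seq = n, n_sites = L)
}
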
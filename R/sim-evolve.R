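# Sequence evolution along the simulated genealogy: HKY with 4-category
# discrete Gamma rate heterogeneity, with nonsynonymous changes at
# peptide-binding-region codons accepted at a multiplied rate (pbr_omega)
# and changes creating stop codons rejected. Implemented as an exact
# thinned event simulation, so codon context is always current.

# 4-category discrete Gamma rates, median method, normalised to mean 1
discrete_gamma_rates <- function(shape, k = 4L) {
  if (shape <= 0) return(rep(1, k))
  r <- qgamma((2 * seq_len(k) - 1) / (2 * k), shape = shape, rate = shape)
  r / mean(r)
}

.random_root_seq <- function(n_codons, remainder) {
  cods <- sample(SENSE_IDX, n_codons, replace = TRUE)
  nts <- unlist(strsplit(CODON_STR[cods], ""))
  c(match(nts, NUC), sample.int(4, remainder, replace = TRUE))
}

#' Evolve sequences along a simulated genealogy
#'
#' Evolves the amplicon fragment down the gene tree under HKY+Gamma(4)
#' at the configured neutral rate, multiplying the acceptance probability
#' of nonsynonymous changes at PBR codons by `pbr_omega` and rejecting
#' changes that would create a stop codon. The 3' remainder that does not
#' fill a codon evolves neutrally.
#'
#' @param truth A `sim_truth` from [simulate_gene_genealogy()].
#' @param cfg Configuration; defaults to the one stored in `truth`.
#' @return `truth` with `alignment` (allele alignment tibble) and
#'   `substitutions` (accepted synonymous / nonsynonymous / noncoding
#'   event counts) added.
#' @export
evolve_alignment <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(cfg$seed + 1L)
  tree <- truth$genealogy
  L <- cfg$fragment_length
  off <- cfg$frame_offset
  n_codons <- (L - off) %/% 3L
  remainder <- L - off - 3L * n_codons
  if (off > 0 || remainder > 0) {
    # evolve offset/remainder sites neutrally at the fragment ends
  }
  # per-site category rates and omega multipliers
  gam <- discrete_gamma_rates(cfg$gamma_shape)
  site_cat <- sample.int(4L, L, replace = TRUE)
  site_rate <- gam[site_cat]
  codon_of <- rep(NA_integer_, L)
  if (n_codons > 0) {
    codon_sites <- off + seq_len(3L * n_codons)
    codon_of[codon_sites] <- rep(seq_len(n_codons), each = 3L)
  }
  non_pbr <- if (is.null(cfg$non_pbr_omega)) 1 else cfg$non_pbr_omega
  omega <- ifelse(!is.na(codon_of) & codon_of %in% cfg$pbr_mask,
                  cfg$pbr_omega, non_pbr)
  omega[is.na(codon_of)] <- 1
  m_bound <- pmax(1, omega)
  w <- cfg$neutral_rate * site_rate * m_bound
  kappa <- cfg$hky_kappa
  ts_partner <- c(3L, 4L, 1L, 2L) # A<->G, C<->T
  counts <- c(syn = 0L, nonsyn = 0L, noncoding = 0L)
  evolve_branch <- function(seq_int, t_my) {
    n_ev <- rpois(1, sum(w) * t_my)
    if (n_ev == 0) return(seq_int)
    sites <- sample.int(L, n_ev, replace = TRUE, prob = w)
    for (s in sites) {
      a <- seq_int[s]
      others <- setdiff(1:4, a)
      pr <- ifelse(others == ts_partner[a], kappa, 1)
      b <- sample(others, 1, prob = pr)
      cod <- codon_of[s]
      if (is.na(cod)) {
        seq_int[s] <- b
        counts["noncoding"] <<- counts["noncoding"] + 1L
        next
      }
      cs <- off + (cod - 1L) * 3L + 1:3
      old_cod <- seq_int[cs]
      new_cod <- old_cod
      new_cod[s - cs[1] + 1L] <- b
      i_old <- 16L * (old_cod[1] - 1L) + 4L * (old_cod[2] - 1L) + old_cod[3]
      i_new <- 16L * (new_cod[1] - 1L) + 4L * (new_cod[2] - 1L) + new_cod[3]
      if (i_new %in% STOP_IDX) next
      syn <- GENETIC_CODE_VEC[i_new] == GENETIC_CODE_VEC[i_old]
      p_acc <- if (syn) 1 / m_bound[s] else omega[s] / m_bound[s]
      if (runif(1) <= p_acc) {
        seq_int[s] <- b
        counts[if (syn) "syn" else "nonsyn"] <<-
          counts[if (syn) "syn" else "nonsyn"] + 1L
      }
    }
    seq_int
  }
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- .random_root_seq(n_codons, L - 3L * n_codons)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chd <- ord$edge[k, 2]
    seqs[[chd]] <- evolve_branch(seqs[[par]], ord$edge.length[k])
  }
  tip_seqs <- vapply(seq_len(n_tip), function(i) {
    paste(NUC[seqs[[i]]], collapse = "")
  }, character(1))
  aln <- truth$membership |>
    mutate(seq = tip_seqs[match(.data$allele, tree$tip.label)]) |>
    as_allele_alignment()
  truth$alignment <- aln
  truth$root_seq <- paste(NUC[seqs[[root]]], collapse = "")
  truth$substitutions <- counts
  truth$site_categories <- site_cat
  truth
}

#' Apply gene-conversion events to a simulated alignment
#'
#' Each event copies a tract of `conversion_tract` nt from a donor allele
#' into an acceptor allele. The number of events is Poisson with mean
#' `conversion_rate` per lineage per My of lineage stem age, and donors
#' are drawn from a different lineage of the same species when one exists
#' (the homogenizing, concerted-evolution regime); events are logged in
#' the truth object. Explicit `events` (tibble with `donor`, `acceptor`,
#' `start`) override the random draw.
#'
#' @param truth A `sim_truth` with an `alignment` (see
#'   [evolve_alignment()]).
#' @param cfg Configuration; defaults to the one stored in `truth`.
#' @param events Optional forced events.
#' @return `truth` with alignment modified and `conversion_events` added.
#' @export
apply_gene_conversion <- function(truth, cfg = truth$config, events = NULL) {
  stopifnot(inherits(truth, "sim_truth"), !is.null(truth$alignment))
  if (cfg$conversion_tract > cfg$fragment_length) {
    abort("conversion tract longer than fragment", class = "mhctsp_error")
  }
  set.seed(cfg$seed + 2L)
  aln <- truth$alignment
  L <- alignment_length(aln)
  tract <- cfg$conversion_tract
  if (is.null(events)) {
    lam <- cfg$conversion_rate * sum(truth$lineage_ages$stem_age)
    n_ev <- rpois(1, lam)
    events <- NULL
    if (n_ev > 0) {
      acceptors <- sample(aln$allele, n_ev, replace = TRUE)
      events <- tibble(
        acceptor = acceptors,
        donor = vapply(acceptors, function(a) {
          sp <- aln$species[aln$allele == a]
          lin <- truth$membership$lineage[truth$membership$allele == a]
          pool <- truth$membership |>
            filter(.data$species == sp, .data$lineage != lin)
          if (nrow(pool) == 0) {
            pool <- truth$membership |> filter(.data$allele != a)
          }
          sample(pool$allele, 1)
        }, character(1)),
        start = sample.int(L - tract + 1L, n_ev, replace = TRUE)
      )
    } else {
      events <- tibble(acceptor = character(0), donor = character(0),
                       start = integer(0))
    }
  }
  events <- as_tibble(events)
  if (nrow(events) > 0) {
    events$end <- pmin(events$start + tract - 1L, L)
    for (k in seq_len(nrow(events))) {
      d <- aln$seq[aln$allele == events$donor[k]]
      a_i <- which(aln$allele == events$acceptor[k])
      s <- events$start[k]; e <- events$end[k]
      substr(aln$seq[a_i], s, e) <- substr(d, s, e)
    }
  } else {
    events$end <- integer(0)
  }
  truth$alignment <- aln
  truth$conversion_events <- events
  truth
}
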
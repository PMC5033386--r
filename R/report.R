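# Per-species diversity and selection report: the machinery behind a
# Table-1-style summary (individuals, variants, nucleotide diversity,
# synonymous/nonsynonymous diversity, dN/dS, Z-test p-values for the
# whole fragment and the PBR partition, Tajima's D).

#' Per-species diversity and selection report
#'
#' One row per species: number of individuals, total variants, the
#' per-individual variant range, nucleotide diversity (p-distance),
#' synonymous and nonsynonymous diversity (modified Nei-Gojobori), their
#' ratio (1 decimal, matching the usual reporting precision), one-tailed
#' codon Z-test p-values for positive selection on the whole fragment and
#' on the PBR partition, and Tajima's D.
#'
#' @param pool A `species_pool` (see [pool_species_variants()]), or an
#'   allele alignment tibble (then individual counts are omitted).
#' @param pbr_mask PBR codon positions.
#' @param R Transition/transversion ratio (`NULL`: per-species
#'   estimate).
#' @param frame_offset Reading-frame offset.
#' @param boot_reps Bootstrap replicates for the Z-test.
#' @param seed Optional seed for the Z-test bootstrap.
#' @return Tibble with one row per species.
#' @export
diversity_report <- function(pool, pbr_mask = default_pbr_mask(), R = NULL,
                             frame_offset = 0L, boot_reps = 500,
                             seed = NULL) {
  if (inherits(pool, "species_pool")) {
    alignment <- pool$alignment
    counts <- pool$summary
  } else {
    alignment <- as_allele_alignment(pool)
    counts <- alignment |>
      group_by(.data$species) |>
      summarise(n_individuals = NA_integer_,
                variants_total = dplyr::n(),
                variants_indiv_min = NA_integer_,
                variants_indiv_max = NA_integer_, .groups = "drop")
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(split(alignment, alignment$species), function(sp_aln) {
    n_var <- nrow(sp_aln)
    if (n_var < 2) {
      return(tibble(species = sp_aln$species[1], pi = NA_real_,
                    pi_ds = NA_real_, pi_dn = NA_real_,
                    dn_ds = NA_real_, p_z_full = NA_real_,
                    p_z_pbr = NA_real_, tajima_d = NA_real_))
    }
    Rsp <- if (is.null(R)) estimate_ts_tv_ratio(sp_aln) else R
    pi <- as.numeric(nucleotide_diversity(sp_aln, "overall"))
    pi_ds <- as.numeric(nucleotide_diversity(sp_aln, "dS", R = Rsp,
                                             frame_offset = frame_offset))
    pi_dn <- as.numeric(nucleotide_diversity(sp_aln, "dN", R = Rsp,
                                             frame_offset = frame_offset))
    z_full <- codon_z_test(sp_aln, "full", boot_reps = boot_reps, R = Rsp,
                           frame_offset = frame_offset)
    z_pbr <- codon_z_test(sp_aln, "pbr", boot_reps = boot_reps, R = Rsp,
                          frame_offset = frame_offset, pbr_mask = pbr_mask)
    td <- if (n_var >= 4) tajimas_d(sp_aln) else NA_real_
    tibble(
      species = sp_aln$species[1],
      pi = pi, pi_ds = pi_ds, pi_dn = pi_dn,
      dn_ds = round(pi_dn / pi_ds, 1),
      p_z_full = z_full$p_value, p_z_pbr = z_pbr$p_value,
      tajima_d = td
    )
  })
  counts |> left_join(bind_rows(rows), by = "species")
}
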
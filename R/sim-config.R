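# Simulation configuration: the assumed evolutionary and sequencing
# process. Defaults emulate a corvid-like study design: four deep
# MHC IIB lineage-founding duplications shared across a 7-species,
# 4-genus species set, a 248-nt exon-2 amplicon, and replicated
# pyrosequencing-style reads with point errors and PCR chimeras.

.default_species_tree <-
  "(((((Cobr:1,Coco:1):1,Coma:2):5,Cofr:7):8,Gagl:15):4,(Pipi:13,Cycy:13):6);"

.default_genus_map <- c(
  Cobr = "Corvus", Coco = "Corvus", Coma = "Corvus", Cofr = "Corvus",
  Gagl = "Garrulus", Pipi = "Pica", Cycy = "Cyanopica"
)

.default_individuals <- c(
  Cobr = 18, Coco = 18, Coma = 18, Cofr = 3, Gagl = 4, Pipi = 4, Cycy = 3
)

#' Simulation configuration
#'
#' Builds the configuration object consumed by the simulator operations.
#' Defaults describe the emulated study system: lineage-founding gene
#' duplications at 53, 53, 53 and 49.1 My (the two oldest sharing the root
#' event; `lineage_attach` places later lineages on the backbone, by
#' default L1 splitting from L3 at 49.1 My), a fixed 7-species/4-genus
#' species tree with crown age 19 My, a zebra-finch-like neutral rate of
#' 2.21e-3 substitutions/site/My, HKY+Gamma(4 categories) substitution
#' with an elevated nonsynonymous rate at peptide-binding-region codons,
#' optional short-tract gene conversion, and two replicate PCRs per
#' individual with Poisson read depth, per-base point errors and PCR
#' chimeras.
#'
#' @param duplication_times Stem (founding) ages in My of each allelic
#'   lineage; must all predate the oldest species split.
#' @param species_tree Newick string (ultrametric, branch lengths in My).
#' @param genus_map Named character vector species -> genus.
#' @param n_individuals Named integer vector of individuals per species.
#' @param n_alleles_per_species_per_lineage Alleles segregating per
#'   species within each lineage.
#' @param fragment_length Amplicon length in nt.
#' @param frame_offset Reading-frame offset of the fragment.
#' @param neutral_rate Neutral substitution rate, subs/site/My.
#' @param hky_kappa HKY transition/transversion rate ratio.
#' @param gamma_shape Shape of the 4-category discrete Gamma.
#' @param pbr_mask Codon positions under elevated nonsynonymous rate.
#' @param pbr_omega Nonsynonymous acceptance multiplier at PBR codons
#'   (balancing selection).
#' @param non_pbr_omega Nonsynonymous acceptance multiplier outside the
#'   PBR (purifying selection on framework residues).
#' @param coal_ne Coalescent timescale (My) of the allelic classes
#'   maintained within a lineage by balancing selection.
#' @param conversion_rate Gene-conversion events per lineage per My.
#' @param conversion_tract Conversion tract length, nt.
#' @param read_depth_mean Mean reads per allele copy per PCR replicate.
#' @param error_rate Per-base substitution error rate of reads.
#' @param chimera_fraction Proportion of reads that are PCR chimeras.
#' @param lineage_attach Named character vector: lineage -> backbone
#'   lineage it splits from (for lineages beyond the root pair).
#' @param seed Integer seed driving every stochastic stage.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(duplication_times = c(L1 = 49.1, L2 = 53, L3 = 53,
                                             L4 = 53),
                       species_tree = .default_species_tree,
                       genus_map = .default_genus_map,
                       n_individuals = .default_individuals,
                       n_alleles_per_species_per_lineage = 2,
                       fragment_length = 248,
                       frame_offset = 0L,
                       neutral_rate = 0.00221,
                       hky_kappa = 4,
                       gamma_shape = 2,
                       pbr_mask = default_pbr_mask(),
                       pbr_omega = 4,
                       non_pbr_omega = 0.2,
                       coal_ne = 1,
                       conversion_rate = 0,
                       conversion_tract = 30,
                       read_depth_mean = 30,
                       error_rate = 0.003,
                       chimera_fraction = 0.1,
                       lineage_attach = c(L1 = "L3", L4 = "L2"),
                       seed = 1L) {
  if (is.null(names(duplication_times))) {
    names(duplication_times) <- paste0("L", seq_along(duplication_times))
  }
  cfg <- structure(
    list(
      duplication_times = duplication_times,
      species_tree = species_tree,
      genus_map = genus_map,
      n_individuals = n_individuals,
      n_alleles_per_species_per_lineage = n_alleles_per_species_per_lineage,
      fragment_length = fragment_length,
      frame_offset = as.integer(frame_offset),
      neutral_rate = neutral_rate,
      hky_kappa = hky_kappa,
      gamma_shape = gamma_shape,
      pbr_mask = pbr_mask,
      pbr_omega = pbr_omega,
      non_pbr_omega = non_pbr_omega,
      coal_ne = coal_ne,
      conversion_rate = conversion_rate,
      conversion_tract = conversion_tract,
      read_depth_mean = read_depth_mean,
      error_rate = error_rate,
      chimera_fraction = chimera_fraction,
      lineage_attach = lineage_attach,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: positive times, duplications older
#' than the oldest species split, non-negative rates, chimera fraction in
#' [0, 1).
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly; errors otherwise.
#' @export
validate_sim_config <- function(cfg) {
  sp <- ape::read.tree(text = cfg$species_tree)
  ages <- .node_ages(sp)
  max_split <- max(ages)
  if (any(cfg$duplication_times <= 0)) {
    abort("duplication times must be > 0", class = "mhctsp_error")
  }
  if (any(cfg$duplication_times < max_split)) {
    abort(
      sprintf(
        "duplication time younger than the oldest species split (%.3g My): scenario unrealizable",
        max_split
      ),
      class = "mhctsp_error"
    )
  }
  rates <- c(cfg$neutral_rate, cfg$conversion_rate, cfg$error_rate,
             cfg$coal_ne, cfg$gamma_shape, cfg$hky_kappa)
  if (any(rates < 0)) abort("rates must be >= 0", class = "mhctsp_error")
  if (cfg$chimera_fraction < 0 || cfg$chimera_fraction >= 1) {
    abort("chimera_fraction must be in [0, 1)", class = "mhctsp_error")
  }
  if (cfg$conversion_tract > cfg$fragment_length) {
    abort("conversion tract longer than fragment", class = "mhctsp_error")
  }
  missing_sp <- setdiff(sp$tip.label, names(cfg$genus_map))
  if (length(missing_sp)) {
    abort(paste("species without genus:", paste(missing_sp, collapse = ", ")),
          class = "mhctsp_error")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", length(x$duplication_times), "lineages at",
      paste(x$duplication_times, collapse = "/"), "My;",
      length(x$genus_map), "species; seed", x$seed, "\n")
  invisible(x)
}

# ages of all nodes of an ultrametric phylo (tips = 0)
.node_ages <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  depth <- numeric(n_node)
  po <- ape::reorder.phylo(tree, "postorder")
  # compute distance from root first
  dist_root <- numeric(n_node)
  for (k in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[k, 1]; chd <- po$edge[k, 2]
    dist_root[chd] <- dist_root[par] + po$edge.length[k]
  }
  max(dist_root) - dist_root
}
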
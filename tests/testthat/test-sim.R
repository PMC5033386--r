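# The synthetic-data generator: configuration invariants, genealogy
# structure, sequence evolution, gene conversion and read generation.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(duplication_times = c(L1 = 10)),
               class = "mhctsp_error") # younger than oldest split (19)
  expect_error(sim_config(chimera_fraction = 1), class = "mhctsp_error")
  expect_error(sim_config(error_rate = -0.1), class = "mhctsp_error")
  expect_error(sim_config(conversion_tract = 1000), class = "mhctsp_error")
})

test_that("single lineage with one allele per species recovers the species tree", {
  cfg <- sim_config(duplication_times = c(L1 = 53),
                    n_alleles_per_species_per_lineage = 1,
                    lineage_attach = NULL, seed = 3)
  truth <- simulate_gene_genealogy(cfg)
  g <- truth$genealogy
  g$tip.label <- sub("_L1_a1", "", g$tip.label)
  sp <- ape::read.tree(text = cfg$species_tree)
  expect_equal(ape::dist.topo(ape::unroot(g), ape::unroot(sp)), 0,
               ignore_attr = TRUE)
})

test_that("default scenario gives 4 disjoint all-species lineages at the configured ages", {
  truth <- simulate_gene_genealogy(sim_config(seed = 11))
  memb <- truth$membership
  expect_equal(sort(unique(memb$lineage)), paste0("L", 1:4))
  by_lin <- split(memb$species, memb$lineage)
  for (b in by_lin) expect_equal(sort(unique(b)), sort(names(sim_config()$genus_map)))
  # dyad ages follow the configured history
  d <- truth$dyad_ages
  expect_equal(d$age[d$lineage_a == "L1" & d$lineage_b == "L3"], 49.1)
  expect_equal(d$age[d$lineage_a == "L2" & d$lineage_b == "L3"], 53)
  expect_equal(d$age[d$lineage_a == "L3" & d$lineage_b == "L4"], 53)
  # TMRCA below founding duplication, for every lineage
  expect_true(all(truth$lineage_ages$crown_age <=
                    truth$lineage_ages$stem_age))
})

test_that("genealogy and downstream stages are deterministic under a seed", {
  t1 <- simulate_tsp_dataset(tiny_sim_cfg(seed = 5))
  t2 <- simulate_tsp_dataset(tiny_sim_cfg(seed = 5))
  expect_equal(ape::write.tree(t1$genealogy), ape::write.tree(t2$genealogy))
  expect_equal(t1$alignment$seq, t2$alignment$seq)
  expect_equal(t1$reads$raw_seq, t2$reads$raw_seq)
  # byte-identical FASTA
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_sim_dataset(t1, d1); write_sim_dataset(t2, d2)
  expect_identical(readLines(file.path(d1, "reads.fasta")),
                   readLines(file.path(d2, "reads.fasta")))
})

test_that("zero branch lengths leave all sequences at the root state", {
  cfg <- shallow_neutral_cfg(seed = 8, n_classes = 3, neutral_rate = 0)
  truth <- simulate_gene_genealogy(cfg) |> evolve_alignment()
  expect_equal(unique(truth$alignment$seq), truth$root_seq)
})

test_that("neutral control run realizes dN/dS near 1 against NG site counts", {
  cfg <- sim_config(
    duplication_times = c(L1 = 30), species_tree = "(A:5,B:5);",
    genus_map = c(A = "GA", B = "GB"), n_individuals = c(A = 1, B = 1),
    n_alleles_per_species_per_lineage = 1, fragment_length = 9999,
    gamma_shape = 1e7, pbr_mask = integer(0), pbr_omega = 1,
    non_pbr_omega = 1, seed = 4
  )
  truth <- simulate_gene_genealogy(cfg) |> evolve_alignment()
  syn <- mhctsp:::ng_syn_sites(1.5)
  idx <- mhctsp:::codon_indices(truth$root_seq)
  S <- sum(syn[idx]); N <- 3 * length(idx) - S
  cnt <- truth$substitutions
  ratio <- (cnt[["nonsyn"]] / N) / (cnt[["syn"]] / S)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("PBR omega elevates the nonsynonymous rate where configured", {
  # partition-level NG estimates: PBR above non-PBR in nearly all runs
  hits <- 0; n <- 25
  for (sd in 1:n) {
    truth <- simulate_gene_genealogy(
      shallow_neutral_cfg(seed = sd, n_classes = 8, pbr_omega = 8,
                          non_pbr_omega = 0.2)
    ) |> evolve_alignment()
    zp <- codon_z_test(truth$alignment, "pbr", boot_reps = 100, R = 1.5,
                       pbr_mask = sim_config()$pbr_mask, seed = sd)
    zn <- codon_z_test(truth$alignment, "non_pbr", boot_reps = 100,
                       R = 1.5, pbr_mask = sim_config()$pbr_mask, seed = sd)
    dr <- function(z) z$mean_dn - z$mean_ds
    if (isTRUE(zp$applicable) && isTRUE(zn$applicable) &&
        dr(zp) > dr(zn)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n, 0.95)
})

test_that("configured whole-fragment selection regime sits in the observed band", {
  cfg <- sim_config()
  n_cod <- (cfg$fragment_length - cfg$frame_offset) %/% 3
  n_pbr <- length(intersect(cfg$pbr_mask, seq_len(n_cod)))
  mean_omega <- (cfg$pbr_omega * n_pbr +
                   cfg$non_pbr_omega * (n_cod - n_pbr)) / n_cod
  expect_gte(mean_omega, 1.3)
  expect_lte(mean_omega, 1.6)
})

test_that("gene conversion copies tracts and homogenizes species", {
  base <- simulate_gene_genealogy(tiny_sim_cfg(seed = 9)) |>
    evolve_alignment()
  # rate 0: unchanged
  un <- apply_gene_conversion(base)
  expect_equal(un$alignment$seq, base$alignment$seq)
  expect_equal(nrow(un$conversion_events), 0)

  # forced event: acceptor tract becomes identical to donor tract
  ev <- tibble::tibble(donor = base$alignment$allele[1],
                       acceptor = base$alignment$allele[30],
                       start = 11L)
  fc <- apply_gene_conversion(base, events = ev)
  tract <- function(s) substr(s, 11, 11 + base$config$conversion_tract - 1)
  expect_equal(tract(fc$alignment$seq[30]), tract(fc$alignment$seq[1]))

  # high conversion rate shrinks mean within-species distance
  mean_within <- function(truth) {
    aln <- truth$alignment
    mean(sapply(split(aln, aln$species), function(s) {
      m <- alignment_distances(s, "p")
      mean(m[upper.tri(m)])
    }))
  }
  lo <- mean(sapply(1:5, function(sd) {
    mean_within(simulate_gene_genealogy(tiny_sim_cfg(seed = sd)) |>
                  evolve_alignment() |> apply_gene_conversion())
  }))
  hi_cfgs <- lapply(1:5, function(sd) tiny_sim_cfg(seed = sd,
                                                   conversion_rate = 2))
  hi <- mean(sapply(hi_cfgs, function(cf) {
    mean_within(simulate_gene_genealogy(cf) |> evolve_alignment() |>
                  apply_gene_conversion())
  }))
  expect_lt(hi, lo)
})

test_that("read generation honours error, chimera and depth settings", {
  clean <- simulate_tsp_dataset(tiny_sim_cfg(seed = 10, error_rate = 0,
                                             chimera_fraction = 0))
  expect_true(all(clean$reads$fragment %in% clean$alignment$seq))
  expect_equal(sum(clean$reads$is_chimera), 0)

  expect_error(
    simulate_tsp_dataset(tiny_sim_cfg(seed = 1, read_depth_mean = 0.5)),
    class = "mhctsp_error"
  )

  # chimera count within binomial 99% bounds
  big <- simulate_tsp_dataset(tiny_sim_cfg(seed = 12))
  n <- nrow(big$reads)
  k <- sum(big$reads$is_chimera)
  bounds <- qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
  # chimeras carry recorded breakpoints
  expect_true(all(!is.na(big$reads$breakpoint[big$reads$is_chimera])))
})
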
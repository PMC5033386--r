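# Modified Nei-Gojobori machinery, distances and diversity statistics.

test_that("pairwise distances match the closed forms and flag saturation", {
  r <- pairwise_distance("AAAAAAAA", "GAGAAAAC")
  expect_equal(r$P, 0.25)
  expect_equal(r$Q, 0.125)
  expect_equal(r$d_k2, -0.5 * log(1 - 2 * 0.25 - 0.125) -
                 0.25 * log(1 - 2 * 0.125), tolerance = 1e-10)
  expect_equal(round(r$d_k2, 4), 0.5623)

  same <- pairwise_distance("ACGT", "ACGT")
  expect_equal(same$p, 0)
  expect_equal(same$d_jc, 0)
  expect_equal(same$d_k2, 0)

  # P = 0.5, Q = 0.25 makes 1 - 2P - Q negative
  s1 <- paste(rep("A", 8), collapse = "")
  s2 <- paste(c(rep("G", 4), rep("C", 2), rep("A", 2)), collapse = "")
  expect_error(pairwise_distance(s1, s2, "K2"),
               class = "mhctsp_saturation")
  ok <- pairwise_distance(s1, s2, "K2", allow_saturated = TRUE)
  expect_true(ok$saturated)
  expect_true(is.na(ok$d_k2))
})

test_that("K2/JC distances agree with ape::dist.dna", {
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  mutate_some <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- vapply(ch[pos],
                      function(a) sample(setdiff(c("A", "C", "G", "T"), a),
                                         1), "")
    paste(ch, collapse = "")
  }
  seqs <- c(base, vapply(c(0, 5, 10, 15, 20), function(k) {
    mutate_some(base, k)
  }, character(1)))
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(seqs, "")))
  ours_k2 <- alignment_distances(
    tibble::tibble(allele = paste0("s", 1:6), seq = seqs), "K2")
  ape_k2 <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(unname(ours_k2), unname(ape_k2), tolerance = 1e-10,
               ignore_attr = TRUE)
  ours_jc <- alignment_distances(
    tibble::tibble(allele = paste0("s", 1:6), seq = seqs), "JC")
  ape_jc <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  expect_equal(unname(ours_jc), unname(ape_jc), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("fast distance matrix equals the per-pair implementation", {
  set.seed(21)
  seqs <- replicate(8, paste(sample(c("A", "C", "G", "T"), 90,
                                    replace = TRUE), collapse = ""))
  codes <- mhctsp:::.encode_alignment(seqs)
  fast <- mhctsp:::.fast_dist(codes, paste0("s", 1:8), "K2")
  slow <- mhctsp:::distance_matrix(seqs, paste0("s", 1:8), "K2")
  expect_equal(unname(fast), unname(unclass(slow)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("dN/dS counts match the worked single-substitution example", {
  s1 <- paste0(strrep("GGG", 8), "TTT")
  s2 <- paste0(strrep("GGG", 8), "TTC")
  r <- pairwise_dn_ds(s1, s2, R = 1)
  expect_equal(r$sd, 1)
  expect_equal(r$nd, 0)
  expect_equal(r$s_sites, 25 / 3, tolerance = 1e-12)
  expect_equal(r$ds, -3 / 4 * log(1 - 4 * 0.12 / 3), tolerance = 1e-10)
  expect_equal(r$dn, 0)

  ident <- pairwise_dn_ds(s1, s1, R = 1)
  expect_equal(ident$nd + ident$sd, 0)
  expect_equal(ident$n_sites + ident$s_sites, 27)
})

test_that("pathway averaging matches brute-force ordering enumeration", {
  # codon pair differing at 2 positions (padded so nothing saturates)
  pad <- strrep("TTT", 10)
  r <- pairwise_dn_ds(paste0(pad, "AAA"), paste0(pad, "AGG"), R = 1)
  oc <- oracle_path_counts("AAA", "AGG")
  expect_equal(r$sd, unname(oc["sd"]))
  expect_equal(r$nd, unname(oc["nd"]))
  # spot-check a 3-difference pair (6 pathways)
  r3 <- pairwise_dn_ds(paste0(pad, "ATG"), paste0(pad, "CGT"), R = 1)
  oc3 <- oracle_path_counts("ATG", "CGT")
  expect_equal(r3$sd, unname(oc3["sd"]))
  expect_equal(r3$nd, unname(oc3["nd"]))
})

test_that("premature stops and saturated proportions raise errors", {
  expect_error(pairwise_dn_ds("TAAGGG", "TACGGG"), class = "mhctsp_error")
  # construct strongly diverged codon strings with ps >= 3/4
  s1 <- strrep("TTT", 30)
  s2 <- strrep("CTC", 30)
  expect_error(pairwise_dn_ds(s1, s2, R = 1), class = "mhctsp_saturation")
})

test_that("nucleotide diversity is the mean over pairs and matches the matrix", {
  aln <- tibble::tibble(
    allele = c("a", "b", "c"),
    seq = c("AAAAAAAAAA", "AAAAAAAAGG", "GGGAAAAAGG")
  )
  # pairwise p: ab = .2, ac = .5, bc = .3 -> mean 1/3
  expect_equal(as.numeric(nucleotide_diversity(aln)),
               mean(c(0.2, 0.5, 0.3)))
  m <- alignment_distances(aln, "p")
  expect_equal(as.numeric(nucleotide_diversity(aln)),
               mean(m[upper.tri(m)]))
  ident <- tibble::tibble(allele = c("a", "b"), seq = c("ACGT", "ACGT"))
  expect_equal(as.numeric(nucleotide_diversity(ident)), 0)
})

test_that("Tajima's D matches direct formula evaluation and handles S=0", {
  aln <- tibble::tibble(
    allele = letters[1:4],
    seq = c("AAAAAAAA", "AAAAAAAG", "AAAAAAGG", "AAAAAGGA")
  )
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  S <- sum(apply(mat, 2, function(x) length(unique(x)) > 1))
  k <- mean(combn(4, 2, function(ij) sum(mat[ij[1], ] != mat[ij[2], ])))
  n <- 4
  a1 <- sum(1 / 1:3); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(aln), expected, tolerance = 1e-12)

  mono <- tibble::tibble(allele = letters[1:4], seq = rep("ACGTACGT", 4))
  expect_true(is.na(tajimas_d(mono)))
})

test_that("Tajima's D is near zero on neutral coalescent alignments", {
  vals <- sapply(1:200, function(sd) {
    truth <- evolve_alignment(coalescent_truth(sd))
    tajimas_d(truth$alignment)
  })
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.3)
})

test_that("saturation index separates invariant, diverged and random data", {
  inv <- tibble::tibble(allele = letters[1:5], seq = rep(strrep("ACGT", 20), 5))
  r_inv <- saturation_test(inv, reps = 20, seed = 1)
  expect_equal(r_inv$iss, 0)
  expect_lt(r_inv$p_value, 0.05)

  set.seed(2)
  rnd <- tibble::tibble(
    allele = paste0("r", 1:8),
    seq = replicate(8, paste(sample(c("A", "C", "G", "T"), 200,
                                    replace = TRUE), collapse = ""))
  )
  r_rnd <- saturation_test(rnd, reps = 20, seed = 3)
  expect_gt(r_rnd$iss, 0.8)

  low <- simulate_gene_genealogy(tiny_sim_cfg(seed = 4)) |>
    evolve_alignment()
  r_low <- saturation_test(low$alignment, reps = 20, seed = 5)
  expect_lt(r_low$iss, r_low$iss_c)
  expect_lt(r_low$p_value, 0.05)
})

test_that("codon Z-test returns not-applicable on monomorphic alignments", {
  mono <- tibble::tibble(allele = letters[1:5],
                         seq = rep(strrep("ATG", 30), 5))
  z <- codon_z_test(mono, "full", boot_reps = 100, seed = 1)
  expect_false(z$applicable)
  expect_error(codon_z_test(mono, "full", boot_reps = 50),
               class = "mhctsp_error")
})

test_that("codon Z-test detects selection simulated at elevated omega", {
  # 30 alleles at study-like depth; this regime realizes a whole-fragment
  # dN/dS estimate around 1.5
  hits <- 0
  for (sd in 1:20) {
    cfg <- sim_config(
      duplication_times = c(L1 = 53), species_tree = "(A:19,B:19);",
      genus_map = c(A = "GA", B = "GB"), n_individuals = c(A = 1, B = 1),
      n_alleles_per_species_per_lineage = 15, coal_ne = 5,
      pbr_omega = 6, non_pbr_omega = 1, seed = sd
    )
    tr <- simulate_gene_genealogy(cfg) |> evolve_alignment()
    z <- codon_z_test(tr$alignment, "full", boot_reps = 100, R = 1.5,
                      seed = sd)
    if (isTRUE(z$applicable) && !is.na(z$p_value) && z$p_value < 0.05) {
      hits <- hits + 1
    }
  }
  expect_gt(hits, 10)
})

test_that("diversity report mirrors the per-species summary layout", {
  truth <- simulate_tsp_dataset(tiny_sim_cfg(seed = 6))
  pool <- run_genotyping(
    dplyr::select(truth$reads, "read_id", "raw_seq"), truth$mid_table)
  rep <- diversity_report(pool, boot_reps = 100, seed = 1)
  expect_true(all(c("species", "n_individuals", "variants_total",
                    "variants_indiv_min", "variants_indiv_max", "pi",
                    "pi_ds", "pi_dn", "dn_ds", "p_z_full", "p_z_pbr",
                    "tajima_d") %in% names(rep)))
  expect_equal(nrow(rep), 7)
  expect_true(all(rep$pi > 0 & rep$pi < 1, na.rm = TRUE))
  expect_true(all(rep$p_z_pbr >= 0 & rep$p_z_pbr <= 1, na.rm = TRUE))
})
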
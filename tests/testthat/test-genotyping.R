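# Replicate-validated genotyping: demultiplexing, filtering, validation,
# low-divergence collapse, species pooling, and the conservation /
# idempotence properties.

mk_reads <- function(seqs, mids = NULL) {
  tibble::tibble(read_id = paste0("r", seq_along(seqs)), raw_seq = seqs)
}

test_that("demultiplex assigns exact tag pairs and discards switched tags", {
  mid <- tibble::tibble(
    fwd_tag = c("AAAA", "CCCC"), rev_tag = c("TTTT", "GGGG"),
    individual = c("i1", "i2"), replicate = c("A", "A")
  )
  frag <- strrep("ACG", 10)
  reads <- mk_reads(c(
    paste0("AAAA", frag, "TTTT"),   # i1
    paste0("CCCC", frag, "GGGG"),   # i2
    paste0("AAAA", frag, "GGGG")    # switched: fwd of i1, rev of i2
  ))
  out <- demultiplex(reads, mid, fwd_primer = "", rev_primer = "")
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_discarded"), 1L)
  expect_equal(sort(out$individual), c("i1", "i2"))
  expect_equal(out$seq[1], frag)

  # conservation when all reads are tagged correctly
  ok <- demultiplex(mk_reads(rep(paste0("AAAA", frag, "TTTT"), 5)), mid,
                    fwd_primer = "", rev_primer = "")
  expect_equal(nrow(ok), 5)
  expect_equal(attr(ok, "n_discarded"), 0L)

  empty <- demultiplex(mk_reads(character(0)), mid)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_discarded"), 0L)

  dup <- dplyr::bind_rows(mid, mid[1, ])
  expect_error(demultiplex(reads, dup), class = "mhctsp_error")
})

test_that("filter_reads rejects short, indel, ambiguous and stop-codon reads", {
  good <- strrep("ATG", 10) # 30 nt, no stops
  reads <- tibble::tibble(
    read_id = c("ok", "short", "indel", "stopc", "ambig"),
    individual = "i1", replicate = "A",
    seq = c(good, good, substr(good, 1, 29), paste0("TAA", strrep("ATG", 9)),
            paste0("N", substr(good, 2, 30))),
    raw_length = c(50, 20, 50, 50, 50)
  )
  out <- filter_reads(reads, ref_length = 30, min_len = 40,
                      frame_offset = 0)
  rej <- attr(out, "rejections")
  expect_equal(out$read_id, "ok")
  expect_equal(rej$reason[rej$read_id == "short"], "short")
  expect_equal(rej$reason[rej$read_id == "indel"], "indel")
  expect_equal(rej$reason[rej$read_id == "stopc"], "stop_codon")
  expect_equal(rej$reason[rej$read_id == "ambig"], "ambiguous")
  # conservation: kept + rejected = input
  expect_equal(nrow(out) + nrow(rej), nrow(reads))
})

test_that("frame 'auto' picks the offset minimising internal stops", {
  # frame 0 reads TAA GAA ... (internal stop); frames 1-2 are clean
  s <- paste0("T", strrep("AAG", 12)) # 37 nt
  reads <- tibble::tibble(read_id = "r1", individual = "i", replicate = "A",
                          seq = s, raw_length = 300)
  out <- filter_reads(reads, ref_length = 37, min_len = 200,
                      frame_offset = "auto")
  expect_equal(attr(out, "frame_offset"), 1L)
})

test_that("validation requires the copy threshold in both replicates", {
  seqs <- c(a = strrep("ACT", 10), b = strrep("AGT", 10))
  mk <- function(rep_id, counts) {
    tibble::tibble(
      individual = "i1", replicate = rep_id,
      seq = unname(rep(seqs, counts))
    )
  }
  reads <- dplyr::bind_rows(mk("A", c(3, 5)), mk("B", c(3, 0)))
  out <- validate_variants(reads, min_copies = 3)
  expect_equal(out$seq, unname(seqs["a"])) # b fails in replicate B
  rej <- attr(out, "rejected")
  expect_equal(rej$reason, "insufficient_replication")

  # 2 + 7 also fails: the threshold is per replicate
  reads2 <- dplyr::bind_rows(mk("A", c(2, 3)), mk("B", c(7, 3)))
  out2 <- validate_variants(reads2, min_copies = 3)
  expect_false(unname(seqs["a"]) %in% out2$seq)
  expect_true(unname(seqs["b"]) %in% out2$seq)

  expect_error(validate_variants(mk("A", c(3, 3)), min_copies = 3),
               class = "mhctsp_error") # replicate B missing
})

test_that("low-divergence collapse keeps 3-nt neighbours, drops 2-nt ones", {
  base <- strrep("AAC", 10)
  two_off <- paste0("GGC", substr(base, 4, 30))
  three_off <- paste0("GGG", substr(base, 4, 30))
  cand <- tibble::tibble(
    individual = "i1",
    seq = c(base, two_off, three_off),
    count_A = c(10, 3, 3), count_B = c(10, 3, 3),
    total_reads = c(20, 6, 6)
  )
  out <- collapse_low_divergence(cand, min_nt_diff = 3)
  expect_true(base %in% out$seq)
  expect_false(two_off %in% out$seq)
  expect_true(three_off %in% out$seq)
  expect_equal(attr(out, "rejected")$reason, "low_divergence")

  single <- collapse_low_divergence(cand[1, ], min_nt_diff = 3)
  expect_equal(nrow(single), 1)
})

test_that("species pooling deduplicates alleles and reports ranges", {
  gt <- tibble::tibble(
    individual = c("s1_i1", "s1_i2", "s1_i2", "s2_i1"),
    seq = c("AAAA", "AAAA", "CCCC", "GGGG"),
    support_reads = c(10, 8, 6, 12)
  )
  sm <- tibble::tibble(individual = c("s1_i1", "s1_i2", "s2_i1"),
                       species = c("s1", "s1", "s2"))
  pool <- pool_species_variants(gt, sm)
  s1 <- pool$summary[pool$summary$species == "s1", ]
  expect_equal(s1$variants_total, 2) # shared allele counted once
  expect_equal(s1$variants_indiv_min, 1)
  expect_equal(s1$variants_indiv_max, 2)
  expect_equal(nrow(pool$alignment), 3)

  bad <- gt
  bad$seq[1] <- "AAAAA"
  expect_error(pool_species_variants(bad, sm), class = "mhctsp_error")
})

test_that("genotyping is idempotent on its own validated output", {
  truth <- simulate_tsp_dataset(tiny_sim_cfg(seed = 31))
  pool <- run_genotyping(
    dplyr::select(truth$reads, "read_id", "raw_seq"), truth$mid_table)
  gt <- attr(pool, "genotypes")
  # feed the validated alleles back: 3 identical copies in each replicate
  reread <- gt |>
    dplyr::select("individual", "seq") |>
    tidyr::crossing(replicate = c("A", "B"),
                    copy = 1:3) |>
    dplyr::mutate(read_id = paste0("x", dplyr::row_number()),
                  raw_length = 300)
  gt2 <- genotype_individuals(reread, min_copies = 3, min_nt_diff = 3)
  key <- function(g) paste(g$individual, g$seq)
  expect_setequal(key(gt2), key(gt))
})

test_that("pooled variants on clean reads equal the simulator truth", {
  cfg <- tiny_sim_cfg(seed = 32, error_rate = 0, chimera_fraction = 0)
  truth <- simulate_tsp_dataset(cfg)
  expect_true(all(truth$reads$fragment %in% truth$alignment$seq))
  pool <- run_genotyping(
    dplyr::select(truth$reads, "read_id", "raw_seq"), truth$mid_table)
  carried <- truth$genotypes |>
    dplyr::left_join(truth$alignment, by = "allele") |>
    dplyr::distinct(species, seq)
  expect_setequal(pool$alignment$seq, carried$seq)
})
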
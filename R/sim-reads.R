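# Replicated amplicon-read generation: diploid individuals drawn per
# lineage-locus, two independent PCR replicates, Poisson depth per allele
# copy, per-base point errors, and PCR chimeras formed from two parent
# reads of the same individual with a single uniform breakpoint. Reads
# carry MID tag pairs and primers, so the demultiplexer and length filter
# see realistic raw sequences.

FWD_PRIMER <- "TGTCACTTCACGAACGGCAC"
REV_PRIMER <- "GTAGTTGTGCCGGCAGTACG"

# deterministic pool of distinct 8-nt multiplex identifier tags
.make_mids <- function(n) {
  stopifnot(n <= 4^8)
  idx <- (seq_len(n) * 997L) %% (4L^8L) # 997 coprime to 4^8: distinct tags
  vapply(idx, function(i) {
    digits <- integer(8)
    for (k in 1:8) {
      digits[k] <- i %% 4L
      i <- i %/% 4L
    }
    paste(NUC[digits + 1L], collapse = "")
  }, character(1))
}

.mutate_reads <- function(seqs, error_rate) {
  L <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), L, error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(L, n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(a) sample(setdiff(NUC, a), 1), "")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Generate replicated amplicon reads from a simulated alignment
#'
#' Assigns each individual up to two allele copies per lineage (diploid
#' per lineage-locus, drawn with replacement from the species' alleles of
#' that lineage), then produces two PCR replicates per individual with
#' Poisson(`read_depth_mean`) reads per allele copy. A `chimera_fraction`
#' of reads are replaced by two-parent recombinants with a uniform
#' breakpoint; point errors are added to every fragment at `error_rate`
#' per base. Raw reads are MID-tagged and primer-flanked.
#'
#' @param truth A `sim_truth` with an alignment.
#' @param cfg Configuration; defaults to the one stored in `truth`.
#' @return `truth` with `reads` (tibble: read_id, individual, replicate,
#'   raw_seq, fragment, template, is_chimera, breakpoint), `genotypes`
#'   (individual-allele copy table), `mid_table` and `chimera_reads`
#'   added.
#' @export
generate_amplicon_reads <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "sim_truth"), !is.null(truth$alignment))
  if (cfg$read_depth_mean < 1) {
    abort("read_depth_mean must be >= 1", class = "mhctsp_error")
  }
  set.seed(cfg$seed + 3L)
  aln <- truth$alignment
  memb <- truth$membership
  L <- alignment_length(aln)
  # individuals and their diploid genotypes per lineage
  indivs <- purrr::imap_dfr(cfg$n_individuals, function(n, sp) {
    if (n < 1) return(tibble(individual = character(0), species = character(0)))
    tibble(individual = sprintf("%s_i%02d", sp, seq_len(n)), species = sp)
  })
  geno <- purrr::pmap_dfr(indivs, function(individual, species) {
    pools <- memb |> filter(.data$species == .env$species)
    purrr::map_dfr(split(pools, pools$lineage), function(p) {
      picked <- sample(p$allele, 2, replace = TRUE)
      tibble(individual = individual, lineage = p$lineage[1],
             allele = picked, copy = 1:2)
    })
  })
  seq_of <- setNames(aln$seq, aln$allele)
  # template reads: one row per read
  temp <- geno |>
    tidyr::crossing(replicate = c("A", "B")) |>
    mutate(depth = rpois(dplyr::n(), cfg$read_depth_mean)) |>
    tidyr::uncount(.data$depth) |>
    select("individual", "replicate", template = "allele")
  temp$fragment <- unname(seq_of[temp$template])
  # chimeras: replace a Bernoulli(chimera_fraction) subset, parents drawn
  # from the same individual x replicate pool of template reads
  temp$is_chimera <- as.logical(rbinom(nrow(temp), 1, cfg$chimera_fraction))
  temp$breakpoint <- NA_integer_
  grp <- paste(temp$individual, temp$replicate)
  orig_frag <- temp$fragment
  orig_templ <- temp$template
  for (g in unique(grp[temp$is_chimera])) {
    rows <- which(grp == g)
    chim <- rows[temp$is_chimera[rows]]
    if (length(rows) < 2) {
      temp$is_chimera[chim] <- FALSE
      next
    }
    for (r in chim) {
      par2 <- sample(rows, 2)
      bp <- sample.int(L - 1L, 1)
      temp$fragment[r] <- paste0(
        substr(orig_frag[par2[1]], 1, bp),
        substr(orig_frag[par2[2]], bp + 1L, L)
      )
      temp$template[r] <- paste0(orig_templ[par2[1]], "x",
                                 orig_templ[par2[2]])
      temp$breakpoint[r] <- bp
    }
  }
  temp$fragment <- .mutate_reads(temp$fragment, cfg$error_rate)
  # MID table: unique (fwd, rev) tag pair per individual x replicate
  pairs <- indivs |>
    tidyr::crossing(replicate = c("A", "B")) |>
    select("individual", "replicate")
  mids <- .make_mids(2L * nrow(pairs))
  mid_table <- pairs |>
    mutate(
      fwd_tag = mids[seq_len(nrow(pairs))],
      rev_tag = mids[nrow(pairs) + seq_len(nrow(pairs))]
    ) |>
    select("fwd_tag", "rev_tag", "individual", "replicate")
  temp <- temp |>
    left_join(mid_table, by = c("individual", "replicate")) |>
    group_by(.data$individual, .data$replicate) |>
    mutate(read_id = sprintf("%s|%s|read%d", .data$individual,
                             .data$replicate, row_number())) |>
    ungroup() |>
    mutate(raw_seq = paste0(.data$fwd_tag, FWD_PRIMER, .data$fragment,
                            REV_PRIMER, .data$rev_tag)) |>
    select("read_id", "individual", "replicate", "raw_seq", "fragment",
           "template", "is_chimera", "breakpoint")
  truth$reads <- temp
  truth$genotypes <- geno
  truth$mid_table <- mid_table
  truth$chimera_reads <- temp$read_id[temp$is_chimera]
  truth
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: genealogy, sequence evolution, optional gene
#' conversion, amplicon reads.
#'
#' @param cfg A [sim_config()].
#' @return A complete `sim_truth` bundle.
#' @export
simulate_tsp_dataset <- function(cfg = sim_config()) {
  simulate_gene_genealogy(cfg) |>
    evolve_alignment() |>
    apply_gene_conversion() |>
    generate_amplicon_reads()
}

#' Write a simulated dataset to files
#'
#' Writes reads as FASTA (headers `individual|replicate|readN`), the true
#' alignment as FASTA, the genealogy as Newick with node ages appended in
#' comment brackets, the MID table as TSV and the remaining ground truth
#' as a JSON sidecar.
#'
#' @param truth A complete `sim_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_tbl(
    truth$reads |> select(id = "read_id", seq = "raw_seq"),
    file.path(dir, "reads.fasta")
  )
  write_fasta_tbl(
    truth$alignment |> select(id = "allele", "seq"),
    file.path(dir, "alignment.fasta")
  )
  ages <- .node_ages(truth$genealogy)
  tr <- truth$genealogy
  n_tip <- length(tr$tip.label)
  tr$node.label <- sprintf("[&age=%.6g]", ages[(n_tip + 1):length(ages)])
  ape::write.tree(tr, file.path(dir, "genealogy.nwk"))
  utils::write.table(
    truth$mid_table, file.path(dir, "mids.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  sidecar <- list(
    membership = truth$membership,
    lineage_ages = truth$lineage_ages,
    dyad_ages = truth$dyad_ages,
    genotypes = truth$genotypes,
    chimera_reads = truth$chimera_reads,
    conversion_events = truth$conversion_events
  )
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
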
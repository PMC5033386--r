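# Replicate-validated amplicon genotyping: demultiplex by exact MID tag
# pairs, filter by length / indels / stop codons, validate variants that
# reach a copy-number threshold in both independent PCR replicates, and
# collapse candidates lying within a minimum nucleotide distance of a
# more common variant.

#' Demultiplex raw amplicon reads by MID tag pairs
#'
#' Assigns reads whose forward and reverse tags exactly match a row of
#' the MID table; reads whose tag pair is not in the table (tag switching)
#' are discarded and counted. Tags and primers are stripped from the
#' output fragment; the pre-trim length is retained for the length
#' filter.
#'
#' @param raw_reads Tibble with columns `read_id` and `raw_seq` (or a
#'   FASTA path readable by [read_fasta_tbl()], using `id` as read id).
#' @param mid_table Tibble with columns `fwd_tag`, `rev_tag`,
#'   `individual`, `replicate`; duplicate tag pairs are an error.
#' @param fwd_primer,rev_primer Primer sequences stripped after the tags.
#' @return Tibble with `individual`, `replicate`, `read_id`, `seq`
#'   (trimmed fragment) and `raw_length`; attribute `n_discarded` counts
#'   tag-mismatched reads.
#' @export
demultiplex <- function(raw_reads, mid_table,
                        fwd_primer = FWD_PRIMER, rev_primer = REV_PRIMER) {
  if (is.character(raw_reads) && length(raw_reads) == 1) {
    raw_reads <- read_fasta_tbl(raw_reads) |> rename(read_id = "id",
                                                     raw_seq = "seq")
  }
  raw_reads <- as_tibble(raw_reads)
  mid_table <- as_tibble(mid_table)
  if (anyDuplicated(mid_table[, c("fwd_tag", "rev_tag")])) {
    abort("duplicate (fwd_tag, rev_tag) pair in MID table",
          class = "mhctsp_error")
  }
  if (nrow(raw_reads) == 0) {
    out <- tibble(individual = character(0), replicate = character(0),
                  read_id = character(0), seq = character(0),
                  raw_length = integer(0))
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  tl <- nchar(mid_table$fwd_tag[1])
  tr <- nchar(mid_table$rev_tag[1])
  n <- nchar(raw_reads$raw_seq)
  fwd <- substr(raw_reads$raw_seq, 1, tl)
  rev <- substr(raw_reads$raw_seq, n - tr + 1L, n)
  key <- paste(fwd, rev)
  tab_key <- paste(mid_table$fwd_tag, mid_table$rev_tag)
  hit <- match(key, tab_key)
  discarded <- sum(is.na(hit))
  keep <- !is.na(hit)
  body <- substr(raw_reads$raw_seq[keep], tl + 1L, n[keep] - tr)
  # strip primers when present at the expected ends
  fp <- nchar(fwd_primer); rp <- nchar(rev_primer)
  has_fp <- substr(body, 1, fp) == fwd_primer
  has_rp <- substr(body, nchar(body) - rp + 1L, nchar(body)) == rev_primer
  frag <- body
  frag[has_fp] <- substr(frag[has_fp], fp + 1L, nchar(frag[has_fp]))
  frag[has_rp & has_fp] <- substr(frag[has_rp & has_fp], 1,
                                  nchar(frag[has_rp & has_fp]) - rp)
  frag[has_rp & !has_fp] <- substr(frag[has_rp & !has_fp], 1,
                                   nchar(frag[has_rp & !has_fp]) - rp)
  out <- tibble(
    individual = mid_table$individual[hit[keep]],
    replicate = mid_table$replicate[hit[keep]],
    read_id = raw_reads$read_id[keep],
    seq = frag,
    raw_length = n[keep]
  )
  attr(out, "n_discarded") <- discarded
  out
}

#' Filter demultiplexed reads by length, indels and stop codons
#'
#' Retains reads whose pre-trim length is at least `min_len`, whose
#' trimmed fragment exactly matches the reference length (a mismatch is
#' treated as an indel), that contain no ambiguous bases, and whose
#' translation has no internal stop codon.
#'
#' @param reads Demultiplexed read tibble (see [demultiplex()]).
#' @param ref_length Expected trimmed fragment length.
#' @param min_len Minimum pre-trim read length (default 270).
#' @param frame_offset Reading frame for the stop-codon check, or
#'   `"auto"` to choose the offset minimising internal stops across the
#'   read pool.
#' @return Filtered read tibble; attribute `rejections` is a tibble of
#'   (read_id, reason) with reasons `short`, `indel`, `ambiguous`,
#'   `stop_codon`; attribute `frame_offset` is the offset used.
#' @export
filter_reads <- function(reads, ref_length, min_len = 270,
                         frame_offset = 0L) {
  reads <- as_tibble(reads)
  if (!"raw_length" %in% names(reads)) reads$raw_length <- nchar(reads$seq)
  reason <- rep(NA_character_, nrow(reads))
  reason[is.na(reason) & reads$raw_length < min_len] <- "short"
  reason[is.na(reason) & nchar(reads$seq) != ref_length] <- "indel"
  reason[is.na(reason) & grepl("[^ACGT]", reads$seq)] <- "ambiguous"
  if (identical(frame_offset, "auto")) {
    pool <- reads$seq[is.na(reason)]
    stops <- vapply(0:2, function(off) {
      sum(vapply(pool, has_internal_stop, logical(1), frame_offset = off))
    }, numeric(1))
    frame_offset <- which.min(stops) - 1L
  }
  ok <- is.na(reason)
  stop_hit <- vapply(reads$seq[ok], has_internal_stop, logical(1),
                     frame_offset = frame_offset)
  reason[which(ok)[stop_hit]] <- "stop_codon"
  out <- reads[is.na(reason), , drop = FALSE]
  attr(out, "rejections") <- tibble(
    read_id = reads$read_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  attr(out, "frame_offset") <- as.integer(frame_offset)
  out
}

#' Validate variants by replication across independent PCRs
#'
#' A sequence is a candidate variant for an individual iff at least
#' `min_copies` identical reads support it in every PCR replicate of that
#' individual.
#'
#' @param reads Filtered read tibble for one individual (columns
#'   `individual`, `replicate`, `seq`), with exactly the configured
#'   replicates present.
#' @param min_copies Per-replicate identical-read threshold (default 3).
#' @param replicates Replicate labels that must all support a variant.
#' @return Tibble of candidates: `individual`, `seq`, per-replicate
#'   counts (`count_A`, `count_B`, ...), `total_reads`; attribute
#'   `rejected` lists sequences failing replication with reason
#'   `insufficient_replication`.
#' @export
validate_variants <- function(reads, min_copies = 3,
                              replicates = c("A", "B")) {
  reads <- as_tibble(reads)
  ind <- unique(reads$individual)
  if (length(ind) != 1) {
    abort("validate_variants expects reads of a single individual",
          class = "mhctsp_error")
  }
  missing_rep <- setdiff(replicates, unique(reads$replicate))
  if (length(missing_rep)) {
    abort(
      sprintf("replicate %s missing for %s: validation impossible",
              paste(missing_rep, collapse = ","), ind),
      class = "mhctsp_error"
    )
  }
  counts <- reads |>
    filter(.data$replicate %in% replicates) |>
    count(.data$seq, .data$replicate) |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "n",
                       names_prefix = "count_", values_fill = 0L)
  cnt_cols <- paste0("count_", replicates)
  for (cc in cnt_cols) if (!cc %in% names(counts)) counts[[cc]] <- 0L
  counts$total_reads <- rowSums(counts[, cnt_cols, drop = FALSE])
  ok <- apply(counts[, cnt_cols, drop = FALSE] >= min_copies, 1, all)
  out <- counts[ok, , drop = FALSE] |>
    mutate(individual = ind) |>
    dplyr::relocate("individual")
  attr(out, "rejected") <- counts[!ok, , drop = FALSE] |>
    mutate(individual = ind, reason = "insufficient_replication")
  out
}

#' Collapse candidates within a minimum distance of commoner variants
#'
#' Iterates candidates in decreasing total read support (ties broken
#' lexicographically by sequence) and keeps a candidate iff its Hamming
#' distance to every already-kept candidate is at least `min_nt_diff`.
#'
#' @param candidates Candidate tibble from [validate_variants()].
#' @param min_nt_diff Minimum nucleotide difference (default 3).
#' @return Validated genotype tibble (kept candidates, with
#'   `support_reads` = total reads); attribute `rejected` lists dropped
#'   candidates with reason `low_divergence`.
#' @export
collapse_low_divergence <- function(candidates, min_nt_diff = 3) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) {
    attr(candidates, "rejected") <- candidates
    return(candidates)
  }
  ord <- order(-candidates$total_reads, candidates$seq)
  cand <- candidates[ord, , drop = FALSE]
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  kept <- integer(0)
  dropped <- integer(0)
  for (i in seq_len(nrow(cand))) {
    d_ok <- all(vapply(kept, function(k) {
      hamming(cand$seq[i], cand$seq[k]) >= min_nt_diff
    }, logical(1)))
    if (d_ok) kept <- c(kept, i) else dropped <- c(dropped, i)
  }
  out <- cand[kept, , drop = FALSE] |>
    rename(support_reads = "total_reads")
  attr(out, "rejected") <- cand[dropped, , drop = FALSE] |>
    mutate(reason = "low_divergence")
  out
}

#' Genotype every individual in a filtered read set
#'
#' Runs [validate_variants()] and [collapse_low_divergence()] per
#' individual.
#'
#' @param reads Filtered read tibble (all individuals).
#' @param min_copies Per-replicate threshold.
#' @param min_nt_diff Minimum distance to a commoner variant.
#' @param replicates Replicate labels required per individual.
#' @return Tibble of validated alleles per individual with per-replicate
#'   counts and `support_reads`; attribute `rejected` collects all
#'   rejected candidates.
#' @export
genotype_individuals <- function(reads, min_copies = 3, min_nt_diff = 3,
                                 replicates = c("A", "B")) {
  parts <- split(as_tibble(reads), reads$individual)
  res <- lapply(parts, function(r) {
    collapse_low_divergence(
      validate_variants(r, min_copies, replicates),
      min_nt_diff
    )
  })
  rej <- purrr::map_dfr(res, function(x) {
    r <- attr(x, "rejected")
    if (is.null(r)) tibble() else r
  })
  out <- bind_rows(res)
  attr(out, "rejected") <- rej
  out
}

#' Pool validated variants per species
#'
#' Collapses validated per-individual alleles into unique per-species
#' variants, assigning stable allele ids, and reports the Table-1-style
#' per-species summary (individuals genotyped, total variants, min-max
#' variants per individual).
#'
#' @param genotypes Validated genotype tibble (see
#'   [genotype_individuals()]).
#' @param species_map Data frame `individual` -> `species` (and
#'   optionally `genus`), or named character vector.
#' @return List of class `species_pool`: `alignment` (allele alignment
#'   tibble with `support_reads` = summed reads), `occurrence`
#'   (individual x allele), `summary` (per-species table).
#' @export
pool_species_variants <- function(genotypes, species_map) {
  genotypes <- as_tibble(genotypes)
  if (!is.data.frame(species_map)) {
    species_map <- tibble(individual = names(species_map),
                          species = unname(species_map))
  }
  species_map <- as_tibble(species_map)
  if (!"genus" %in% names(species_map)) species_map$genus <- species_map$species
  g <- genotypes |>
    left_join(species_map, by = "individual")
  if (any(is.na(g$species))) {
    abort("individual missing from species map", class = "mhctsp_error")
  }
  if (length(unique(nchar(g$seq))) > 1) {
    abort("pooled alleles have unequal lengths", class = "mhctsp_error")
  }
  alleles <- g |>
    group_by(.data$species, .data$genus, .data$seq) |>
    summarise(support_reads = sum(.data$support_reads),
              n_individuals = dplyr::n_distinct(.data$individual),
              .groups = "drop") |>
    arrange(.data$species, desc(.data$support_reads), .data$seq) |>
    group_by(.data$species) |>
    mutate(allele = sprintf("%s_v%02d", .data$species, row_number())) |>
    ungroup()
  alignment <- alleles |>
    select("allele", "species", "genus", "seq", "support_reads") |>
    as_allele_alignment()
  occurrence <- g |>
    left_join(alleles |> select("seq", "species", "allele"),
              by = c("seq", "species")) |>
    select("individual", "species", "allele")
  summary <- g |>
    group_by(.data$species) |>
    summarise(
      n_individuals = dplyr::n_distinct(.data$individual),
      variants_total = dplyr::n_distinct(.data$seq),
      .groups = "drop"
    ) |>
    left_join(
      g |>
        count(.data$species, .data$individual) |>
        group_by(.data$species) |>
        summarise(variants_indiv_min = min(.data$n),
                  variants_indiv_max = max(.data$n), .groups = "drop"),
      by = "species"
    )
  structure(
    list(alignment = alignment, occurrence = occurrence, summary = summary),
    class = "species_pool"
  )
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Species pool:", nrow(x$alignment), "unique alleles across",
      nrow(x$summary), "species\n")
  print(x$summary)
  invisible(x)
}

#' Genotype a simulated or file-based read set end to end
#'
#' Demultiplex, filter, validate, collapse, pool: the full genotyping
#' stage with read-count conservation between stages.
#'
#' @param raw_reads Raw read tibble (`read_id`, `raw_seq`) or FASTA path.
#' @param mid_table MID table tibble or TSV path.
#' @param species_map `individual` -> species/genus map; if `NULL`,
#'   species is parsed from individual ids as the prefix before `_`.
#' @param ref_length Reference fragment length.
#' @param min_len Minimum pre-trim read length.
#' @param min_copies Per-replicate copy threshold.
#' @param min_nt_diff Minimum distance to commoner variants.
#' @param frame_offset Frame for stop-codon screening (or `"auto"`).
#' @return A `species_pool` with attribute `stages` recording read counts
#'   through the pipeline.
#' @export
run_genotyping <- function(raw_reads, mid_table, species_map = NULL,
                           ref_length = 248, min_len = 270, min_copies = 3,
                           min_nt_diff = 3, frame_offset = 0L) {
  if (is.character(mid_table) && length(mid_table) == 1) {
    mid_table <- as_tibble(utils::read.delim(mid_table,
                                             colClasses = "character"))
  }
  dm <- demultiplex(raw_reads, mid_table)
  fl <- filter_reads(dm, ref_length, min_len, frame_offset)
  gt <- genotype_individuals(fl, min_copies, min_nt_diff)
  if (is.null(species_map)) {
    ind <- unique(gt$individual)
    species_map <- tibble(individual = ind,
                          species = sub("_.*$", "", ind))
  }
  pool <- pool_species_variants(gt, species_map)
  attr(pool, "stages") <- tibble(
    stage = c("demultiplexed", "tag_discarded", "filtered", "filter_rejected",
              "validated_alleles"),
    n = c(nrow(dm), attr(dm, "n_discarded"), nrow(fl),
          nrow(attr(fl, "rejections")), nrow(gt))
  )
  attr(pool, "genotypes") <- gt
  pool
}
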
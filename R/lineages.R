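# Trans-species lineage detection: maximal clades of a supported tree that
# reach a bootstrap-support threshold and span a minimum number of genera,
# plus subsampling and amino-acid motif summaries of the detected lineages.

#' Detect trans-species allelic lineages
#'
#' Finds maximal clades of the (midpoint-rooted) tree whose bipartition
#' support is at least `support_min`, whose members span at least
#' `min_genera` genera, and that are cohesive clusters: every within-clade
#' pairwise distance is smaller than every clade-to-outside distance.
#' The cohesion condition distinguishes an allelic lineage from the
#' complement side of its own stem bipartition (which carries the same
#' bootstrap support and genus span but mixes deeply diverged lineages).
#' A reported lineage is never nested inside another reported lineage;
#' lineages are numbered L1, L2, ... in preorder traversal order. Clades
#' passing genus span and cohesion with support in [0.5, `support_min`)
#' are returned separately as non-significant candidate clusters.
#'
#' @param stree A `supported_tree` (see [bootstrap_support()]); rooted
#'   internally by midpoint if not already rooted.
#' @param genus_map Data frame with columns `allele` and `genus` covering
#'   every tip, or named character vector allele -> genus.
#' @param support_min Minimum bootstrap support (default 0.75).
#' @param min_genera Minimum number of genera spanned (default 4).
#' @param cohesion_slack Tolerance of the cluster condition: a clade is
#'   cohesive when max within-clade patristic distance is at most
#'   `(1 + cohesion_slack)` times the min clade-to-outside distance.
#' @return Tibble with one row per member allele: `lineage`, `allele`,
#'   `genus`, `support`, `n_genera`. Attributes: `lineages` (per-lineage
#'   summary tibble) and `candidates` (non-significant clusters).
#' @export
detect_lineages <- function(stree, genus_map, support_min = 0.75,
                            min_genera = 4, cohesion_slack = 0.2) {
  stopifnot(inherits(stree, "supported_tree"))
  if (is.data.frame(genus_map)) {
    genus_map <- setNames(genus_map$genus, genus_map$allele)
  }
  rooted <- if (ape::is.rooted(stree$tree)) stree$tree else
    midpoint_root(stree$tree)
  tips <- rooted$tip.label
  unmapped <- setdiff(tips, names(genus_map))
  if (length(unmapped)) {
    abort(paste("tips without genus mapping:",
                paste(unmapped, collapse = ", ")),
          class = "mhctsp_error")
  }
  n_tip <- length(tips)
  desc <- .node_descendants(rooted)
  root <- n_tip + 1L
  nodes <- setdiff(seq_len(max(rooted$edge)), seq_len(n_tip))
  # cohesion is judged on patristic (tree-path) distances: raw pairwise
  # distances at these depths are noisy enough to blur the margin. A true
  # lineage has max-within <= ~min-across; the complement of a lineage's
  # stem bipartition (same support, same genus span) mixes lineages and
  # sits at ratios >= ~1.5, so a 20% slack separates the two regimes.
  dm <- stats::cophenetic(stree$tree)
  cohesive <- function(members) {
    inside <- rownames(dm) %in% members
    if (sum(inside) < 2 || all(inside)) return(TRUE)
    max(dm[inside, inside]) <=
      (1 + cohesion_slack) * min(dm[inside, !inside, drop = FALSE])
  }
  info <- lapply(nodes, function(nd) {
    members <- tips[desc[[nd]]]
    genera <- unique(genus_map[members])
    sup <- .node_support(rooted, nd, stree$support)
    list(node = nd, members = members, n_genera = length(genera),
         support = sup, cohesive = cohesive(members))
  })
  qualifies <- function(x, thr) {
    !is.na(x$support) && x$support >= thr && x$n_genera >= min_genera &&
      x$cohesive
  }
  # preorder node sequence for deterministic numbering and maximality
  preorder <- integer(0)
  stack <- root
  kids <- split(rooted$edge[, 2], rooted$edge[, 1])
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    preorder <- c(preorder, nd)
    ch <- sort(kids[[as.character(nd)]])
    stack <- c(ch[ch > n_tip], stack)
  }
  by_node <- setNames(info, vapply(info, function(x) as.character(x$node),
                                   character(1)))
  taken <- character(0) # alleles already claimed by a reported lineage
  out <- list(); cand <- list()
  for (nd in preorder) {
    if (nd == root) next
    x <- by_node[[as.character(nd)]]
    if (any(x$members %in% taken)) next # nested inside a reported lineage
    if (qualifies(x, support_min)) {
      out[[length(out) + 1L]] <- x
      taken <- c(taken, x$members)
    } else if (qualifies(x, 0.5)) {
      cand[[length(cand) + 1L]] <- x
    }
  }
  lin_ids <- paste0("L", seq_along(out))
  member_tbl <- purrr::map2_dfr(out, lin_ids, function(x, id) {
    tibble(
      lineage = id, allele = x$members,
      genus = unname(genus_map[x$members]),
      support = x$support, n_genera = x$n_genera
    )
  })
  if (nrow(member_tbl) == 0) {
    member_tbl <- tibble(
      lineage = character(0), allele = character(0), genus = character(0),
      support = numeric(0), n_genera = integer(0)
    )
  }
  summ <- purrr::map2_dfr(out, lin_ids, function(x, id) {
    tibble(lineage = id, n_members = length(x$members),
           n_genera = x$n_genera, support = x$support)
  })
  cand_tbl <- purrr::map_dfr(cand, function(x) {
    tibble(
      members = paste(sort(x$members), collapse = "|"),
      n_members = length(x$members), n_genera = x$n_genera,
      support = x$support, significant = FALSE
    )
  })
  attr(member_tbl, "lineages") <- summ
  attr(member_tbl, "candidates") <- cand_tbl
  attr(member_tbl, "rooted_tree") <- rooted
  member_tbl
}

#' Subsample lineage members per species
#'
#' Within each detected lineage, keeps at most `max_per_species` alleles
#' per species, preferring higher read support (column `support_reads` if
#' present) then lexicographic allele id. Alleles outside the detected
#' lineages are untouched. Warns when the cap removes a lineage's last
#' representative of a species.
#'
#' @param alignment Allele alignment (rows for all alleles).
#' @param lineages Membership tibble from [detect_lineages()].
#' @param max_per_species Cap per species within each lineage.
#' @return Reduced alignment tibble.
#' @export
subsample_lineage_members <- function(alignment, lineages,
                                      max_per_species = 6) {
  alignment <- as_allele_alignment(alignment)
  memb <- lineages |>
    select("lineage", "allele") |>
    left_join(alignment |> select(-dplyr::any_of("lineage")),
              by = "allele")
  if (!"support_reads" %in% names(memb)) memb$support_reads <- 0
  kept <- memb |>
    group_by(.data$lineage, .data$species) |>
    arrange(desc(.data$support_reads), .data$allele, .by_group = TRUE) |>
    dplyr::slice_head(n = max_per_species) |>
    ungroup()
  lost <- memb |>
    distinct(.data$lineage, .data$species) |>
    dplyr::anti_join(kept |> distinct(.data$lineage, .data$species),
                     by = c("lineage", "species"))
  if (nrow(lost) > 0) {
    warn(paste0(
      "subsampling removed all alleles of some species from a lineage: ",
      paste(paste(lost$lineage, lost$species, sep = "/"), collapse = ", ")
    ))
  }
  drop_ids <- setdiff(memb$allele, kept$allele)
  alignment |> filter(!.data$allele %in% drop_ids)
}

#' Amino-acid motif summary of detected lineages
#'
#' Translates the member alleles of each lineage and summarises: the
#' majority-rule consensus peptide, per-column conservation, peptides
#' identical across two or more genera, and the diagnostic columns at
#' which lineage consensuses differ.
#'
#' @param alignment Allele alignment containing the lineage members.
#' @param lineages Membership tibble from [detect_lineages()].
#' @param frame_offset Reading-frame offset for translation.
#' @return List of class `motif_summary` with tibbles `consensus`,
#'   `conservation`, `shared_peptides`, `diagnostic_columns`.
#' @export
motif_summary <- function(alignment, lineages, frame_offset = 0L) {
  alignment <- as_allele_alignment(alignment)
  memb <- lineages |>
    select("lineage", "allele", "genus") |>
    left_join(alignment |> select("allele", "seq"), by = "allele")
  if (any(is.na(memb$seq))) {
    abort("lineage members missing from alignment", class = "mhctsp_error")
  }
  memb$peptide <- vapply(memb$seq, translate_seq, character(1),
                         frame_offset = frame_offset)
  bad <- grepl("*", memb$peptide, fixed = TRUE)
  if (any(bad)) {
    abort(paste("internal stop codon in allele(s):",
                paste(memb$allele[bad], collapse = ", ")),
          class = "mhctsp_error")
  }
  per_lineage <- split(memb, memb$lineage)
  cons_of <- function(peps) {
    m <- do.call(rbind, strsplit(peps, ""))
    apply(m, 2, function(col) {
      tb <- sort(table(col), decreasing = TRUE)
      top <- tb[tb == max(tb)]
      sort(names(top))[1]
    })
  }
  consensus <- purrr::imap_dfr(per_lineage, function(df, id) {
    tibble(lineage = id, consensus = paste(cons_of(df$peptide), collapse = ""))
  })
  conservation <- purrr::imap_dfr(per_lineage, function(df, id) {
    m <- do.call(rbind, strsplit(df$peptide, ""))
    tibble(
      lineage = id, column = seq_len(ncol(m)),
      conservation = apply(m, 2, function(col) max(table(col)) / length(col))
    )
  })
  shared <- memb |>
    distinct(.data$lineage, .data$genus, .data$peptide) |>
    group_by(.data$lineage, .data$peptide) |>
    summarise(n_genera = dplyr::n_distinct(.data$genus),
              genera = paste(sort(unique(.data$genus)), collapse = "|"),
              .groups = "drop") |>
    filter(.data$n_genera >= 2)
  cm <- do.call(rbind, strsplit(consensus$consensus, ""))
  diag_cols <- if (nrow(cm) >= 2) {
    which(apply(cm, 2, function(col) length(unique(col)) > 1L))
  } else {
    integer(0)
  }
  diagnostic <- if (length(diag_cols)) {
    purrr::map_dfr(diag_cols, function(cl) {
      tibble(column = cl, lineage = consensus$lineage, residue = cm[, cl])
    })
  } else {
    tibble(column = integer(0), lineage = character(0),
           residue = character(0))
  }
  structure(
    list(consensus = consensus, conservation = conservation,
         shared_peptides = shared, diagnostic_columns = diagnostic),
    class = "motif_summary"
  )
}

#' @export
print.motif_summary <- function(x, ...) {
  cat("Motif summary:", nrow(x$consensus), "lineages;",
      nrow(x$shared_peptides), "peptides shared across >=2 genera;",
      length(unique(x$diagnostic_columns$column)), "diagnostic columns\n")
  invisible(x)
}
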
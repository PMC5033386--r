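# Independent oracles used across the suite. They deliberately avoid the
# package's own codon tables: the genetic code comes from Biostrings and
# the pathway enumeration is a direct recursive implementation.

oracle_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc <- Biostrings::GENETIC_CODE
      code <<- setNames(unname(gc), names(gc))
    }
    code
  }
})

oracle_is_stop <- function(codon) oracle_code()[[codon]] == "*"

# brute-force pathway enumeration of synonymous / nonsynonymous
# differences between two codons: average over all orderings of the
# differing positions, excluding pathways through stop codons (all
# pathways if every one hits a stop)
oracle_path_counts <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  perms <- if (length(diffs) == 1) {
    list(diffs)
  } else if (length(diffs) == 2) {
    list(diffs, rev(diffs))
  } else {
    do.call(c, lapply(combinat_perms(diffs), list))
  }
  res <- lapply(perms, function(ord) {
    cur <- a
    sd <- 0; nd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      c_cur <- paste(cur, collapse = "")
      c_nxt <- paste(nxt, collapse = "")
      if (oracle_is_stop(c_nxt) && c_nxt != c2) ok <- FALSE
      if (oracle_code()[[c_cur]] == oracle_code()[[c_nxt]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd, ok = ok)
  })
  mat <- do.call(rbind, res)
  use <- mat[, "ok"] == 1
  if (!any(use)) use <- rep(TRUE, nrow(mat))
  c(sd = mean(mat[use, "sd"]), nd = mean(mat[use, "nd"]))
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# independent weighted synonymous-site count for one codon
oracle_syn_sites <- function(codon, R) {
  a <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    w_syn <- 0; w_all <- 0
    for (to in setdiff(c("A", "C", "G", "T"), a[pos])) {
      mut <- a; mut[pos] <- to
      ts <- paste0(sort(c(a[pos], to)), collapse = "") %in% c("AG", "CT")
      w <- if (ts) R else 1
      w_all <- w_all + w
      mutc <- paste(mut, collapse = "")
      if (!oracle_is_stop(mutc) &&
          oracle_code()[[mutc]] == oracle_code()[[codon]]) {
        w_syn <- w_syn + w
      }
    }
    total <- total + w_syn / w_all
  }
  total
}

# exhaustive-search parsimony score: minimum changes over all internal
# state assignments
oracle_parsimony <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  states <- sort(unique(unname(tip_states)))
  internal <- setdiff(seq_len(max(tree$edge)), seq_len(n_tip))
  assn <- as.matrix(expand.grid(rep(list(states), length(internal)),
                                stringsAsFactors = FALSE))
  best <- Inf
  node_state <- character(max(tree$edge))
  node_state[seq_len(n_tip)] <- tip_states[tree$tip.label]
  for (r in seq_len(nrow(assn))) {
    node_state[internal] <- assn[r, ]
    chg <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    best <- min(best, chg)
  }
  best
}

# small simulation configs shared by tests
tiny_sim_cfg <- function(seed = 1, ...) {
  sim_config(
    n_individuals = c(Cobr = 2, Coco = 2, Coma = 2, Cofr = 2,
                      Gagl = 2, Pipi = 2, Cycy = 2),
    seed = seed, ...
  )
}

shallow_neutral_cfg <- function(seed = 1, n_classes = 5, pbr_omega = 1,
                                non_pbr_omega = 1, ...) {
  sim_config(
    duplication_times = c(L1 = 8), species_tree = "(A:2,B:2);",
    genus_map = c(A = "GA", B = "GB"),
    n_individuals = c(A = 1, B = 1),
    n_alleles_per_species_per_lineage = n_classes, coal_ne = 2,
    pbr_omega = pbr_omega, non_pbr_omega = non_pbr_omega,
    seed = seed, ...
  )
}

# a plain Kingman coalescent genealogy wrapped as a sim_truth, for
# neutral-expectation checks that need an unstructured gene tree
coalescent_truth <- function(seed, n = 8, scale_my = 5) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * scale_my
  tr$tip.label <- paste0("t", seq_len(n))
  cfg <- shallow_neutral_cfg(seed = seed)
  structure(
    list(
      genealogy = tr,
      membership = tibble::tibble(
        allele = tr$tip.label, species = "sp", genus = "g", lineage = "L1"
      ),
      config = cfg
    ),
    class = "sim_truth"
  )
}

exact_lineage_recovery <- function(lin, membership) {
  got <- split(lin$allele, lin$lineage)
  want <- split(membership$allele, membership$lineage)
  length(got) == length(want) &&
    all(vapply(got, function(g) {
      any(vapply(want, function(w) setequal(g, w), logical(1)))
    }, logical(1)))
}
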
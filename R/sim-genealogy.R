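# Gene-genealogy simulation: each allelic lineage is founded by a gene
# duplication that predates the species radiation. Within a lineage,
# alleles belong to persistent allelic classes maintained by balancing
# selection: each class is trans-specific (one representative per species,
# tracking the species tree exactly), and the classes themselves coalesce
# above the species-tree root at timescale coal_ne, censored so that every
# lineage crown stays below its founding duplication. Lineage stems join
# on a backbone whose node ages are the configured duplication times.

# species-tree-shaped subtree for one allelic class; returns
# list(nwk, age = species root age)
.class_subtree <- function(lineage, class_i, sp_tree, sp_ages) {
  n_tip <- length(sp_tree$tip.label)
  kids <- split(sp_tree$edge[, 2], sp_tree$edge[, 1])
  build <- function(node, parent_age) {
    if (node <= n_tip) {
      sprintf("%s_%s_a%d:%.10g", sp_tree$tip.label[node], lineage,
              class_i, parent_age)
    } else {
      age <- sp_ages[node]
      parts <- vapply(sort(kids[[as.character(node)]]), build,
                      character(1), parent_age = age)
      sprintf("(%s):%.10g", paste(parts, collapse = ","), parent_age - age)
    }
  }
  root <- n_tip + 1L
  root_age <- sp_ages[root]
  parts <- vapply(sort(kids[[as.character(root)]]), build, character(1),
                  parent_age = root_age)
  list(nwk = sprintf("(%s)", paste(parts, collapse = ",")), age = root_age)
}

# crown of one lineage: its allelic-class subtrees coalesce between the
# species root age and `cap` (truncated-exponential waiting times, pair
# rate 1/coal_ne), so the lineage TMRCA never reaches its founding age
.lineage_crown <- function(lineage, sp_tree, sp_ages, cfg, cap) {
  m <- cfg$n_alleles_per_species_per_lineage
  nodes <- lapply(seq_len(m), .class_subtree, lineage = lineage,
                  sp_tree = sp_tree, sp_ages = sp_ages)
  t <- nodes[[1]]$age
  top <- cap - 0.05 * (cap - t) # keep a positive stem below the duplication
  while (length(nodes) > 1L) {
    j <- length(nodes)
    lambda <- choose(j, 2) / cfg$coal_ne
    u <- runif(1)
    gap <- -log(1 - u * (1 - exp(-lambda * (top - t)))) / lambda
    t <- t + gap
    pick <- sample.int(j, 2)
    a <- nodes[[pick[1]]]; b <- nodes[[pick[2]]]
    merged <- list(
      nwk = sprintf("(%s:%.10g,%s:%.10g)", a$nwk, t - a$age, b$nwk, t - b$age),
      age = t
    )
    nodes <- c(nodes[-pick], list(merged))
  }
  nodes[[1]]
}

#' Simulate the gene genealogy of duplicated allelic lineages
#'
#' Builds one gene tree per lineage embedded in the species tree and joins
#' the lineage stems at the configured duplication ages. Node times are in
#' My. The returned truth object records lineage membership and the
#' pairwise lineage divergence ages.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_truth` with elements `genealogy` (ultrametric
#'   `phylo`, branch lengths in My), `membership` (tibble: allele, species,
#'   genus, lineage), `lineage_ages` (tibble: lineage, stem_age,
#'   crown_age), `dyad_ages` (tibble: lineage pair, divergence age) and
#'   `config`.
#' @export
simulate_gene_genealogy <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  sp_tree <- ape::read.tree(text = cfg$species_tree)
  sp_ages <- .node_ages(sp_tree)
  dup <- cfg$duplication_times[order(-cfg$duplication_times,
                                     names(cfg$duplication_times))]
  lins <- names(dup)
  # backbone: two oldest lineages share the root; each later lineage
  # attaches to cfg$lineage_attach[lineage] (default: the first lineage)
  host_of <- function(l) {
    h <- cfg$lineage_attach[[l]]
    if (is.null(h) || is.na(h)) lins[1] else h
  }
  atts <- list() # host -> list of (age, lineage), added oldest-first
  caps <- dup
  if (length(lins) > 2) {
    for (l in lins[-(1:2)]) {
      h <- host_of(l)
      atts[[h]] <- c(atts[[h]], list(list(age = dup[[l]], lineage = l)))
      caps[[h]] <- min(caps[[h]], dup[[l]])
    }
  }
  crowns <- lapply(setNames(lins, lins), function(l) {
    .lineage_crown(l, sp_tree, sp_ages, cfg, caps[[l]])
  })
  subtree_below <- function(l, top_age) {
    ev <- atts[[l]]
    if (!is.null(ev)) {
      ages <- vapply(ev, `[[`, numeric(1), "age")
      ev <- ev[order(-ages)]
      ev <- Filter(function(e) e$age <= top_age + 1e-9, ev)
    }
    if (is.null(ev) || length(ev) == 0) {
      cr <- crowns[[l]]
      return(sprintf("%s:%.10g", cr$nwk, top_age - cr$age))
    }
    e1 <- ev[[1]]
    atts[[l]] <<- ev[-1]
    inner_host <- subtree_below(l, e1$age)
    inner_new <- subtree_below(e1$lineage, e1$age)
    sprintf("(%s,%s):%.10g", inner_host, inner_new, top_age - e1$age)
  }
  if (length(lins) == 1L) {
    txt <- sprintf("%s;", crowns[[lins[1]]]$nwk)
  } else {
    root_age <- dup[[1]]
    left <- subtree_below(lins[1], root_age)
    right <- subtree_below(lins[2], root_age)
    txt <- sprintf("(%s,%s);", left, right)
  }
  gtree <- ape::read.tree(text = txt)
  membership <- tibble(allele = gtree$tip.label) |>
    tidyr::separate_wider_delim("allele", "_",
                                names = c("species", "lineage", "copy"),
                                cols_remove = FALSE) |>
    mutate(genus = unname(cfg$genus_map[.data$species])) |>
    select("allele", "species", "genus", "lineage")
  # lineage crown/stem ages and pairwise divergence ages from the tree
  ages <- .node_ages(gtree)
  mrca_age <- function(tips) {
    if (length(tips) == 1) return(0)
    ages[ape::getMRCA(gtree, tips)]
  }
  lin_tbl <- membership |>
    group_by(.data$lineage) |>
    summarise(crown_age = mrca_age(.data$allele), .groups = "drop") |>
    mutate(stem_age = unname(dup[.data$lineage]))
  dyads <- if (length(lins) < 2) {
    tibble(lineage_a = character(0), lineage_b = character(0),
           age = numeric(0))
  } else {
    pr <- t(combn(sort(lins), 2))
    tibble(lineage_a = pr[, 1], lineage_b = pr[, 2]) |>
    mutate(age = purrr::map2_dbl(.data$lineage_a, .data$lineage_b,
      function(a, b) {
        mrca_age(membership$allele[membership$lineage %in% c(a, b)])
      }))
  }
  structure(
    list(
      genealogy = gtree,
      membership = membership,
      lineage_ages = lin_tbl,
      dyad_ages = dyads,
      config = cfg
    ),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated truth:", nrow(x$membership), "alleles,",
      length(unique(x$membership$lineage)), "lineages,",
      length(unique(x$membership$species)), "species\n")
  if (!is.null(x$alignment)) cat("  alignment:", nrow(x$alignment),
                                 "sequences x", alignment_length(x$alignment),
                                 "nt\n")
  if (!is.null(x$reads)) cat("  reads:", nrow(x$reads), "\n")
  invisible(x)
}
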
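# Bayesian divergence dating on a fixed topology: HKY+Gamma(4) likelihood
# (Felsenstein pruning, compiled), Yule tree prior, and strict /
# random-local / relaxed-exponential clock models. The clock rate is fixed
# externally -- in this pipeline from the functional-constraint-adjusted
# substitution rate -- and node ages are sampled in My.

#' Clock and chain configuration for divergence dating
#'
#' @param clock Clock model: `"strict"`, `"random_local"` or
#'   `"relaxed_exponential"`.
#' @param rate Clock rate in substitutions/site/My (typically from
#'   [adjusted_rate()]); fixed, not sampled.
#' @param generations Total MCMC generations.
#' @param burnin Discarded generations (default 10% of the chain).
#' @param thin Sampling interval.
#' @param sample_birth_rate Sample the Yule birth rate (otherwise fixed at
#'   `birth_rate_init`).
#' @param birth_rate_init Initial (or fixed) Yule birth rate, events/My.
#' @param birth_rate_prior_mean Mean of the exponential prior on the birth
#'   rate.
#' @param kappa_init,shape_init Initial HKY kappa and Gamma shape.
#' @param rlc_p Prior probability that a branch changes rate under the
#'   random local clock.
#' @param rlc_sdlog Log-scale SD of random-local rate multipliers.
#' @param seed Integer seed.
#' @return Object of class `clock_config`.
#' @export
clock_config <- function(clock = c("random_local", "strict",
                                   "relaxed_exponential"),
                         rate = 0.0016,
                         generations = 1e5, burnin = NULL, thin = 50,
                         sample_birth_rate = TRUE,
                         birth_rate_init = 0.05,
                         birth_rate_prior_mean = 0.1,
                         kappa_init = 4, shape_init = 1,
                         rlc_p = 0.1, rlc_sdlog = 0.5,
                         seed = 1L) {
  clock <- match.arg(clock)
  if (is.null(burnin)) burnin <- floor(generations * 0.1)
  if (generations <= burnin || burnin < 0) {
    abort("need generations > burnin >= 0", class = "mhctsp_error")
  }
  if (rate <= 0) abort("clock rate must be > 0", class = "mhctsp_error")
  structure(
    list(clock = clock, rate = rate, generations = generations,
         burnin = burnin, thin = thin,
         sample_birth_rate = sample_birth_rate,
         birth_rate_init = birth_rate_init,
         birth_rate_prior_mean = birth_rate_prior_mean,
         kappa_init = kappa_init, shape_init = shape_init,
         rlc_p = rlc_p, rlc_sdlog = rlc_sdlog, seed = as.integer(seed)),
    class = "clock_config"
  )
}

# convert a rooted binary phylo into the 0-based arrays the sampler wants
.tree_arrays <- function(tree) {
  if (!ape::is.rooted(tree)) abort("tree must be rooted",
                                   class = "mhctsp_error")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  n_tip <- length(tree$tip.label)
  n_node <- 2L * n_tip - 1L
  kid1 <- kid2 <- rep(-1L, n_node)
  parent <- rep(-1L, n_node)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1] - 1L
    c <- tree$edge[k, 2] - 1L
    parent[c + 1L] <- p
    if (kid1[p + 1L] < 0) kid1[p + 1L] <- c else kid2[p + 1L] <- c
  }
  po <- ape::reorder.phylo(tree, "postorder")
  post_int <- unique(po$edge[, 1]) - 1L
  list(tree = tree, n_tip = n_tip, n_node = n_node,
       kid1 = kid1, kid2 = kid2, parent = parent, postorder = post_int)
}

# pattern-compress an alignment for the pruning engine
.tip_patterns <- function(alignment, tip_labels) {
  seqs <- alignment$seq[match(tip_labels, alignment$allele)]
  if (any(is.na(seqs))) {
    abort("tree tips missing from alignment", class = "mhctsp_error")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  code <- matrix(match(mat, NUC) - 1L, nrow = nrow(mat))
  code[is.na(code)] <- -1L
  key <- apply(code, 2, paste, collapse = ",")
  idx <- match(key, unique(key))
  w <- as.numeric(table(idx))
  list(tipstate = code[, !duplicated(idx), drop = FALSE], patw = w)
}

# initial node ages from a phylogram: node height = longest path to a
# descendant tip, divided by the clock rate
.init_ages <- function(arr, rate) {
  tree <- arr$tree
  n_tip <- arr$n_tip
  h <- numeric(arr$n_node)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; c <- po$edge[k, 2]
    h[p] <- max(h[p], h[c] + po$edge.length[k])
  }
  ages <- h / rate
  ages[seq_len(n_tip)] <- 0
  pmax(ages, 1e-6 * max(ages))
  ages[-seq_len(n_tip)] <- pmax(ages[-seq_len(n_tip)], 1e-4)
  # enforce strict parent > child ordering
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; c <- po$edge[k, 2]
    if (c > n_tip && ages[p] <= ages[c]) ages[p] <- ages[c] * 1.001 + 1e-4
  }
  ages
}

#' Date clades by MCMC under a fixed topology
#'
#' Samples internal node ages (My), HKY kappa, Gamma shape, the Yule birth
#' rate and clock-model parameters by Metropolis-Hastings, with the
#' likelihood computed by Felsenstein pruning under HKY+Gamma(4) and the
#' clock rate fixed. Returns the thinned post-burnin trace with the ages
#' of the requested clades.
#'
#' @param alignment Allele alignment (gap-free).
#' @param start_tree Rooted `phylo` over the alignment's alleles (branch
#'   lengths in substitutions/site, e.g. a midpoint-rooted NJ tree), or a
#'   `supported_tree`.
#' @param cfg A [clock_config()].
#' @param clade_definitions Named list of tip-label vectors; each must be
#'   monophyletic in `start_tree`. Their TMRCAs are recorded as trace
#'   columns. The root age is always recorded as `root`.
#' @param mrca_definitions Named list of tip-label vectors whose MRCA age
#'   is recorded without requiring monophyly (used for lineage dyads).
#' @param likelihood_on Set `FALSE` to sample from the prior only.
#' @return A `posterior_trace` object: tibble `samples` (state, clade
#'   ages, kappa, shape, birth_rate, mean_rate, loglik), plus `summary`
#'   via [trace_summary()], `ess_ok` (all ESS >= 100) and metadata.
#' @export
mcmc_date <- function(alignment, start_tree, cfg = clock_config(),
                      clade_definitions = list(),
                      mrca_definitions = list(),
                      likelihood_on = TRUE) {
  alignment <- as_allele_alignment(alignment)
  if (inherits(start_tree, "supported_tree")) start_tree <- start_tree$tree
  if (!ape::is.rooted(start_tree)) start_tree <- midpoint_root(start_tree)
  arr <- .tree_arrays(start_tree)
  tree <- arr$tree
  pats <- .tip_patterns(alignment, tree$tip.label)
  freqs <- table(factor(strsplit(paste(alignment$seq, collapse = ""),
                                 "")[[1]], levels = NUC))
  pi <- as.numeric(freqs) / sum(freqs)
  ages0 <- .init_ages(arr, cfg$rate)
  # clade -> internal node (checked monophyletic)
  desc <- .node_descendants(tree)
  clade_nodes <- vapply(names(clade_definitions), function(nm) {
    tips <- clade_definitions[[nm]]
    if (length(tips) < 2) abort("clades need >= 2 tips",
                                class = "mhctsp_error")
    nd <- ape::getMRCA(tree, tips)
    got <- sort(tree$tip.label[desc[[nd]]])
    if (!identical(got, sort(tips))) {
      abort(sprintf("clade %s is not monophyletic in the start tree", nm),
            class = "mhctsp_error")
    }
    nd
  }, integer(1))
  mrca_nodes <- vapply(names(mrca_definitions), function(nm) {
    ape::getMRCA(tree, mrca_definitions[[nm]])
  }, integer(1))
  set.seed(cfg$seed)
  clock_code <- match(cfg$clock,
                      c("strict", "random_local", "relaxed_exponential")) - 1L
  res <- mcmc_chain_cpp(
    arr$kid1, arr$kid2, arr$parent, arr$postorder,
    pats$tipstate, pats$patw,
    ages0, cfg$rate, clock_code, pi,
    cfg$kappa_init, cfg$shape_init, cfg$birth_rate_init,
    cfg$sample_birth_rate, 1 / cfg$birth_rate_prior_mean,
    as.numeric(cfg$generations), as.numeric(cfg$burnin), as.integer(cfg$thin),
    likelihood_on,
    cfg$rlc_p, cfg$rlc_sdlog,
    rep(0, arr$n_node)
  )
  m <- res$samples[seq_len(res$n_samples), , drop = FALSE]
  n_tip <- arr$n_tip
  nint <- arr$n_node - n_tip
  root_node <- arr$postorder[length(arr$postorder)] + 1L
  samples <- tibble(state = res$state[seq_len(res$n_samples)])
  samples$root <- m[, root_node - n_tip]
  for (nm in names(clade_nodes)) {
    samples[[nm]] <- m[, clade_nodes[[nm]] - n_tip]
  }
  for (nm in names(mrca_nodes)) {
    samples[[nm]] <- m[, mrca_nodes[[nm]] - n_tip]
  }
  samples$kappa <- m[, nint + 1]
  samples$gamma_shape <- m[, nint + 2]
  samples$birth_rate <- m[, nint + 3]
  samples$mean_rate <- m[, nint + 4]
  samples$loglik <- m[, nint + 5]
  node_ages <- m[, seq_len(nint), drop = FALSE]
  colnames(node_ages) <- paste0("node", (n_tip + 1):arr$n_node)
  out <- structure(
    list(samples = samples, node_ages = node_ages, tree = tree,
         config = cfg, clades = clade_definitions,
         likelihood_on = likelihood_on),
    class = "posterior_trace"
  )
  drop_cols <- c("state", "loglik")
  summ <- trace_summary(out)
  out$summary <- summ
  ess_vals <- summ$ess[!summ$parameter %in% drop_cols]
  out$ess_ok <- all(ess_vals >= 100)
  out
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat("Posterior trace:", nrow(x$samples), "samples,",
      x$config$clock, "clock, rate", x$config$rate, "subs/site/My\n")
  if (!is.null(x$ess_ok) && !x$ess_ok) {
    cat("  WARNING: some parameters have ESS < 100; estimates unreliable\n")
  }
  print(x$summary)
  invisible(x)
}

#' @export
tidy.posterior_trace <- function(x, ...) x$summary

#' @export
glance.posterior_trace <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    clock = x$config$clock,
    rate = x$config$rate,
    ess_ok = x$ess_ok,
    min_ess = min(x$summary$ess[x$summary$parameter != "state"])
  )
}

#' Date every lineage pair and the all-lineage ancestor
#'
#' Runs [mcmc_date()] once on the alignment restricted to the detected
#' lineages, recording the TMRCA of each lineage, each unordered lineage
#' pair (the union clade) and all lineages together.
#'
#' @param alignment Allele alignment.
#' @param lineages Lineage membership tibble from [detect_lineages()].
#' @param avg_rate Clock rate shared by all lineages (typically the
#'   across-lineage average adjusted rate), subs/site/My.
#' @param start_tree Rooted tree spanning the lineage members.
#' @param cfg `clock_config`; its `rate` is overridden by `avg_rate`.
#' @return List with `trace` (the `posterior_trace`) and `dyads` (tibble:
#'   clade, mean, hpd_lower, hpd_upper, ess).
#' @export
lineage_divergence_times <- function(alignment, lineages, avg_rate,
                                     start_tree, cfg = clock_config()) {
  lin_ids <- sort(unique(lineages$lineage))
  if (length(lin_ids) < 2) {
    abort("need >= 2 lineages", class = "mhctsp_error")
  }
  cfg$rate <- avg_rate
  members <- split(lineages$allele, lineages$lineage)
  dyad_defs <- list()
  for (pr in combn(lin_ids, 2, simplify = FALSE)) {
    dyad_defs[[paste(pr, collapse = "-")]] <-
      c(members[[pr[1]]], members[[pr[2]]])
  }
  keep <- unname(unlist(members))
  aln <- alignment |> filter(.data$allele %in% keep)
  if (inherits(start_tree, "supported_tree")) start_tree <- start_tree$tree
  if (!ape::is.rooted(start_tree)) start_tree <- midpoint_root(start_tree)
  start_tree <- ape::keep.tip(start_tree, keep)
  tr <- mcmc_date(aln, start_tree, cfg, clade_definitions = members,
                  mrca_definitions = dyad_defs)
  dyads <- tr$summary |>
    filter(.data$parameter %in% c(names(members), names(dyad_defs),
                                  "root")) |>
    rename(clade = "parameter")
  list(trace = tr, dyads = dyads)
}
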
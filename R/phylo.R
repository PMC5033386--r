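# Distance-based tree building: neighbor joining on K2 distances with
# nonparametric bootstrap support and midpoint rooting. Tie-breaking is
# lexicographic in leaf labels throughout, so trees are bit-reproducible.

# canonical key for the bipartition separating `tips_in` from the rest:
# the side not containing the alphabetically first leaf, sorted, joined
split_key <- function(tips_in, all_tips) {
  ref <- min(all_tips)
  side <- if (ref %in% tips_in) setdiff(all_tips, tips_in) else tips_in
  paste(sort(side), collapse = "|")
}

# all nontrivial splits of a phylo, as canonical keys
tree_splits <- function(tree) {
  all_tips <- tree$tip.label
  n_tip <- length(all_tips)
  desc <- .node_descendants(tree)
  root <- n_tip + 1L
  internal <- setdiff(unique(tree$edge[, 1]), integer(0))
  keys <- character(0)
  for (nd in setdiff(seq_len(max(tree$edge)), seq_len(n_tip))) {
    if (nd == root) next
    tips_in <- all_tips[desc[[nd]]]
    if (length(tips_in) <= 1L || length(tips_in) >= n_tip - 1L) next
    keys <- c(keys, split_key(tips_in, all_tips))
  }
  unique(keys)
}

# list: node number -> integer vector of descendant tip indices
.node_descendants <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # postorder over edges
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; chd <- po$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[chd]])
  }
  desc
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q criterion.
#' Negative branch lengths are clamped to zero with the deficit shifted to
#' the sister branch, and ties in Q are broken lexicographically by the
#' smallest leaf label in each cluster, making the result invariant to
#' input row order.
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/col names;
#'   at least 3 taxa. `NA` entries (saturated pairs) are an error.
#' @return Unrooted `phylo` object.
#' @export
nj_tree <- function(d) {
  if (is.data.frame(d)) d <- as.matrix(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 3) abort("need >= 3 taxa", class = "mhctsp_error")
  if (any(is.na(d))) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    pr <- sort(c(labels[bad[1]], labels[bad[2]]))
    abort(
      sprintf("undefined (saturated) distance between %s and %s",
              pr[1], pr[2]),
      class = "mhctsp_saturation"
    )
  }
  # cluster state: newick fragment, smallest leaf label (for tie-breaks)
  nwk <- labels
  rep_lab <- labels
  D <- d
  active <- seq_len(n)
  join_len <- function(li) max(li, 0)
  while (length(active) > 3) {
    r <- length(active)
    Da <- D[active, active]
    Rsum <- rowSums(Da)
    Q <- (r - 2) * Da - outer(Rsum, Rsum, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(rep_lab[active[ij[1]]], rep_lab[active[ij[2]]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    dij <- D[i, j]
    li <- dij / 2 + (Rsum[pick[1]] - Rsum[pick[2]]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_nwk <- if (rep_lab[i] <= rep_lab[j]) {
      sprintf("(%s:%.10g,%s:%.10g)", nwk[i], li, nwk[j], lj)
    } else {
      sprintf("(%s:%.10g,%s:%.10g)", nwk[j], lj, nwk[i], li)
    }
    newd <- (D[i, active] + D[j, active] - dij) / 2
    # reuse slot i for the merged cluster
    D[i, active] <- newd
    D[active, i] <- newd
    D[i, i] <- 0
    nwk[i] <- new_nwk
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active <- setdiff(active, j)
  }
  a <- active[1]; b <- active[2]; c <- active[3]
  la <- (D[a, b] + D[a, c] - D[b, c]) / 2
  lb <- (D[a, b] + D[b, c] - D[a, c]) / 2
  lc <- (D[a, c] + D[b, c] - D[a, b]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  ord <- order(rep_lab[c(a, b, c)])
  parts <- c(
    sprintf("%s:%.10g", nwk[a], la),
    sprintf("%s:%.10g", nwk[b], lb),
    sprintf("%s:%.10g", nwk[c], lc)
  )[ord]
  txt <- sprintf("(%s);", paste(parts, collapse = ","))
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `reps` times, rebuilds the tree each time, and
#' reports for every internal bipartition of the original tree the
#' proportion of replicates containing it. Replicates with saturated
#' distances are dropped and counted; more than 10% dropped is an error.
#'
#' @param alignment Allele alignment.
#' @param reps Bootstrap replicates (>= 100).
#' @param model Distance model (default K2).
#' @param seed Optional integer seed.
#' @return A `supported_tree`: list with `tree` (unrooted `phylo`),
#'   `support` (tibble of split key / support), `reps`, `dropped`.
#' @export
bootstrap_support <- function(alignment, reps = 500, model = "K2",
                              seed = NULL) {
  if (reps < 100) abort("reps must be >= 100", class = "mhctsp_error")
  alignment <- as_allele_alignment(alignment)
  if (!is.null(seed)) set.seed(seed)
  codes <- .encode_alignment(alignment$seq)
  dm <- .fast_dist(codes, alignment$allele, model)
  if (any(is.na(dm))) {
    bad <- which(is.na(dm), arr.ind = TRUE)[1, ]
    abort(
      sprintf("saturated pair in full alignment: %s | %s",
              alignment$allele[bad[1]], alignment$allele[bad[2]]),
      class = "mhctsp_saturation"
    )
  }
  tree <- nj_tree(dm)
  keys <- tree_splits(tree)
  counts <- setNames(numeric(length(keys)), keys)
  L <- alignment_length(alignment)
  dropped <- 0L
  used <- 0L
  for (b in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    bd <- .fast_dist(codes[, cols, drop = FALSE], alignment$allele, model)
    if (any(is.na(bd))) {
      dropped <- dropped + 1L
      next
    }
    bt <- nj_tree(bd)
    bk <- tree_splits(bt)
    hit <- keys %in% bk
    counts[hit] <- counts[hit] + 1
    used <- used + 1L
  }
  if (dropped > 0.1 * reps) {
    abort(sprintf("%d of %d bootstrap replicates saturated", dropped, reps),
          class = "mhctsp_saturation")
  }
  structure(
    list(
      tree = tree,
      support = tibble(split = keys, support = unname(counts) / used),
      reps = reps, dropped = dropped, model = model,
      dist = dm,
      note = "NJ on K2 distances (distance-based engine)"
    ),
    class = "supported_tree"
  )
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("Supported tree:", length(x$tree$tip.label), "tips,",
      nrow(x$support), "internal bipartitions,",
      x$reps, "bootstrap replicates\n")
  invisible(x)
}

# adjacency list of an unrooted/rooted phylo: for each node, neighbours
# and edge lengths
.tree_adjacency <- function(tree) {
  n_node <- max(tree$edge)
  adj <- vector("list", n_node)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  adj
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.
#' Bipartition supports are unaffected: they attach to splits, not to the
#' rooting.
#'
#' @param x A `phylo` or `supported_tree`.
#' @return Rooted `phylo`, or the `supported_tree` with its tree rooted.
#' @export
midpoint_root <- function(x) {
  if (inherits(x, "supported_tree")) {
    x$tree <- midpoint_root(x$tree)
    return(x)
  }
  tree <- x
  n_tip <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  tipD <- D[seq_len(n_tip), seq_len(n_tip)]
  mx <- which(tipD == max(tipD), arr.ind = TRUE)[1, ]
  a <- mx[1]; b <- mx[2]
  path <- ape::nodepath(tree, a, b)
  half <- tipD[a, b] / 2
  acc <- 0
  adj <- .tree_adjacency(tree)
  for (k in seq_len(length(path) - 1)) {
    u <- path[k]; v <- path[k + 1]
    w <- adj[[u]][adj[[u]][, 1] == v, 2][1]
    if (acc + w >= half - 1e-12) {
      pos_u <- half - acc
      return(.root_on_edge(tree, adj, u, v, pos_u))
    }
    acc <- acc + w
  }
  tree # degenerate: already centered
}

# build a rooted phylo with the root placed on edge (u,v) at distance
# pos_u from u, via newick reconstruction from the new root
.root_on_edge <- function(tree, adj, u, v, pos_u) {
  labs <- tree$tip.label
  n_tip <- length(labs)
  sub_nwk <- function(node, parent) {
    nb <- adj[[node]]
    kids <- nb[nb[, 1] != parent, , drop = FALSE]
    if (nrow(kids) == 0) return(labs[node])
    parts <- vapply(seq_len(nrow(kids)), function(i) {
      sprintf("%s:%.10g", sub_nwk(kids[i, 1], node), max(kids[i, 2], 0))
    }, character(1))
    if (node <= n_tip) labs[node] else sprintf("(%s)", paste(parts, collapse = ","))
  }
  w <- adj[[u]][adj[[u]][, 1] == v, 2][1]
  left <- sprintf("%s:%.10g", sub_nwk(u, v), max(pos_u, 0))
  right <- sprintf("%s:%.10g", sub_nwk(v, u), max(w - pos_u, 0))
  txt <- sprintf("(%s,%s);", left, right)
  ape::collapse.singles(ape::read.tree(text = txt))
}

#' Bipartition supports as a tidy tibble
#'
#' @param x A `supported_tree`.
#' @return Tibble with `split` (canonical key) and `support`.
#' @export
tidy.supported_tree <- function(x, ...) x$support

#' @export
glance.supported_tree <- function(x, ...) {
  tibble(
    n_tips = length(x$tree$tip.label),
    n_splits = nrow(x$support),
    reps = x$reps,
    dropped = x$dropped,
    mean_support = mean(x$support$support)
  )
}

# support of the bipartition below `node` of a rooted tree, looked up in a
# supported_tree's table; NA when the split is trivial or absent
.node_support <- function(rooted, node, support_tbl) {
  n_tip <- length(rooted$tip.label)
  desc <- .node_descendants(rooted)
  tips_in <- rooted$tip.label[desc[[node]]]
  if (length(tips_in) <= 1L || length(tips_in) >= n_tip - 1L) return(NA_real_)
  key <- split_key(tips_in, rooted$tip.label)
  hit <- match(key, support_tbl$split)
  if (is.na(hit)) NA_real_ else support_tbl$support[hit]
}
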
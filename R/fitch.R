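# Fitch two-pass parsimony for ancestral-state reconstruction of lineage
# identities (or per-site sequence states) on a cladogram.

#' Fitch parsimony ancestral reconstruction
#'
#' Two-pass Fitch algorithm on a rooted cladogram. For categorical tip
#' states, returns per-node state sets and the minimal change count; for
#' sequences (equal-length character strings), runs per site and sums the
#' scores.
#'
#' @param cladogram Rooted `phylo` (multifurcations are resolved
#'   arbitrarily first).
#' @param tip_states Named character vector (tip label -> state), or
#'   named vector of equal-length sequences with `per_site = TRUE`.
#' @param per_site Treat states as sequences and sum per-site scores.
#' @return List of class `fitch_fit`: `score`, `node_states` (tibble
#'   `node`, `states` -- slash-separated first-pass set, tips included),
#'   and for `per_site` runs `site_scores`.
#' @export
fitch_ancestral <- function(cladogram, tip_states, per_site = FALSE) {
  tree <- cladogram
  if (!ape::is.rooted(tree)) abort("cladogram must be rooted",
                                   class = "mhctsp_error")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) {
    abort(paste("unlabeled tips:", paste(missing, collapse = ", ")),
          class = "mhctsp_error")
  }
  states <- tip_states[tree$tip.label]
  if (per_site) {
    L <- nchar(states[1])
    if (any(nchar(states) != L)) {
      abort("sequences must be equal length", class = "mhctsp_error")
    }
    mats <- do.call(rbind, strsplit(unname(states), ""))
    site_scores <- integer(L)
    for (s in seq_len(L)) {
      st <- setNames(mats[, s], tree$tip.label)
      site_scores[s] <- .fitch_one(tree, st)$score
    }
    return(structure(
      list(score = sum(site_scores), site_scores = site_scores,
           node_states = NULL),
      class = "fitch_fit"
    ))
  }
  structure(.fitch_one(tree, states), class = "fitch_fit")
}

.fitch_one <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- states[[tree$tip.label[i]]]
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  score <- 0L
  for (nd in unique(po$edge[, 1])) {
    ch <- kids[[as.character(nd)]]
    acc <- sets[[ch[1]]]
    for (c2 in ch[-1]) {
      inter <- intersect(acc, sets[[c2]])
      if (length(inter)) {
        acc <- inter
      } else {
        acc <- union(acc, sets[[c2]])
        score <- score + 1L
      }
    }
    sets[[nd]] <- acc
  }
  node_states <- tibble(
    node = seq_len(n_node),
    is_tip = seq_len(n_node) <= n_tip,
    label = c(tree$tip.label, rep(NA_character_, n_node - n_tip)),
    states = vapply(sets, function(s) paste(sort(s), collapse = "/"),
                    character(1))
  )
  list(score = score, node_states = node_states)
}

#' @export
print.fitch_fit <- function(x, ...) {
  cat("Fitch parsimony: score", x$score, "\n")
  invisible(x)
}
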
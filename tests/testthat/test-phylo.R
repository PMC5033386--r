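# Neighbor joining, bootstrap support and midpoint rooting.

random_additive_tree <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  tr
}

tree_splits_public <- function(tree) mhctsp:::tree_splits(tree)

test_that("NJ recovers the worked additive example exactly", {
  lab <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 3
  d["B", "C"] <- 6; d["B", "D"] <- 4; d["C", "D"] <- 4
  d <- d + t(d)
  tr <- nj_tree(d)
  expect_equal(unname(ape::cophenetic.phylo(tr)[lab, lab]), unname(d),
               tolerance = 1e-9)
  # topology AB | CD
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
})

test_that("three taxa use the three-point formulas", {
  lab <- c("a", "b", "c")
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  expect_equal(unname(ape::cophenetic.phylo(tr)[lab, lab]), unname(d),
               tolerance = 1e-9)
})

test_that("NJ agrees with ape::nj on random matrices", {
  set.seed(14)
  for (i in 1:5) {
    tr0 <- random_additive_tree(8)
    d <- ape::cophenetic.phylo(tr0)
    ours <- nj_tree(d)
    apes <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(apes)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ output is invariant under input row permutation", {
  lab <- c("a", "b", "c", "d", "e")
  d <- matrix(1, 5, 5, dimnames = list(lab, lab)) # equidistant: all ties
  diag(d) <- 0
  t1 <- ape::write.tree(nj_tree(d))
  perm <- c(4, 2, 5, 1, 3)
  t2 <- ape::write.tree(nj_tree(d[perm, perm]))
  expect_identical(t1, t2)
})

test_that("NJ errors on saturated entries naming the pair", {
  d <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_error(nj_tree(d), "x.*z", class = "mhctsp_saturation")
})

test_that("bootstrap gives unanimous support for clean clades and is deterministic", {
  set.seed(3)
  chA <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  chA[1:2] <- "A" # so the jittered variants really differ below
  cladeA <- paste(chA, collapse = "")
  chB <- chA
  pos <- sample(3:60, 18) # two clean clades ~30% apart, no saturation
  chB[pos] <- vapply(chB[pos],
                     function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1),
                     "")
  chB[1:2] <- "C"
  cladeB <- paste(chB, collapse = "")
  jitter <- function(s, k, alphabet) {
    ch <- strsplit(s, "")[[1]]
    ch[seq_len(k)] <- alphabet
    paste(ch, collapse = "")
  }
  aln <- tibble::tibble(
    allele = c("a1", "a2", "a3", "b1", "b2", "b3"),
    seq = c(cladeA, jitter(cladeA, 1, "T"), jitter(cladeA, 2, c("T", "G")),
            cladeB, jitter(cladeB, 1, "T"), jitter(cladeB, 2, c("T", "A")))
  )
  st <- bootstrap_support(aln, reps = 100, seed = 1)
  expect_true(all(st$support$support[
    st$support$split %in% c("b1|b2|b3", "a2|a3")] >= 0.9))
  key_ab <- mhctsp:::split_key(c("a1", "a2", "a3"), aln$allele)
  expect_equal(st$support$support[st$support$split == key_ab], 1)

  st2 <- bootstrap_support(aln, reps = 100, seed = 1)
  expect_identical(st$support, st2$support)
})

test_that("bootstrap support converges with replicate number", {
  truth <- simulate_gene_genealogy(
    tiny_sim_cfg(seed = 17, n_alleles_per_species_per_lineage = 1)
  ) |> evolve_alignment()
  sup_at <- function(reps) {
    st <- bootstrap_support(truth$alignment, reps = reps, seed = 5)
    l1 <- truth$membership$allele[truth$membership$lineage == "L1"]
    st$support$support[st$support$split ==
                         mhctsp:::split_key(l1, truth$alignment$allele)]
  }
  s100 <- sup_at(100); s500 <- sup_at(500)
  se100 <- sqrt(s100 * (1 - s100) / 100 + 1e-6)
  expect_lt(abs(s500 - s100), 5 * se100 + 0.05)
})

test_that("midpoint rooting matches the worked examples and keeps supports", {
  two <- ape::read.tree(text = "(A:2,B:2);")
  r2 <- midpoint_root(two)
  expect_equal(sort(r2$edge.length), c(2, 2))

  t3 <- ape::read.tree(text = "((A:1,B:1):0,C:4);")
  r3 <- midpoint_root(t3)
  # root must sit on C's branch, 2.5 from C
  depths <- ape::node.depth.edgelength(r3)
  expect_equal(max(depths[1:3]), 2.5, tolerance = 1e-9)
  expect_equal(unname(sort(ape::cophenetic.phylo(r3)[c("A", "C"), "B"])),
               c(2, 5), tolerance = 1e-9)

  # cross-check against phangorn's midpoint on a random tree
  set.seed(8)
  tr <- ape::unroot(random_additive_tree(7))
  ours <- midpoint_root(tr)
  ph <- phangorn::midpoint(tr)
  expect_equal(unname(ape::cophenetic.phylo(ours)),
               unname(ape::cophenetic.phylo(ph)[rownames(ape::cophenetic.phylo(ours)),
                                                colnames(ape::cophenetic.phylo(ours))]),
               tolerance = 1e-8)
  d_ours <- ape::node.depth.edgelength(ours)
  d_ph <- ape::node.depth.edgelength(ph)
  expect_equal(max(d_ours[seq_along(ours$tip.label)]),
               max(d_ph[seq_along(ph$tip.label)]), tolerance = 1e-8)

  # supports attach to bipartitions: rooting does not change them
  truth <- simulate_gene_genealogy(
    tiny_sim_cfg(seed = 18, n_alleles_per_species_per_lineage = 1)
  ) |> evolve_alignment()
  st <- bootstrap_support(truth$alignment, reps = 100, seed = 2)
  rooted <- midpoint_root(st)
  expect_identical(rooted$support, st$support)
  expect_setequal(tree_splits_public(rooted$tree),
                  tree_splits_public(st$tree))
})
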
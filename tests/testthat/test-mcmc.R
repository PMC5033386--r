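# The dating engine: HKY transition probabilities, pruning likelihood,
# Yule prior sampling, trace summaries and clock behaviour.

test_that("HKY transition probabilities equal the matrix exponential", {
  pi <- c(0.3, 0.2, 0.25, 0.25)
  for (kappa in c(1, 3, 8)) {
    for (d in c(0.01, 0.3, 1.5)) {
      P <- mhctsp:::hky_pmat_cpp(d, kappa, pi)
      Q <- matrix(0, 4, 4)
      for (i in 1:4) for (j in 1:4) if (i != j) {
        ts <- (i %in% c(1, 3) && j %in% c(1, 3)) ||
          (i %in% c(2, 4) && j %in% c(2, 4))
        Q[i, j] <- pi[j] * ifelse(ts, kappa, 1)
      }
      diag(Q) <- -rowSums(Q)
      Q <- Q / -sum(pi * diag(Q))
      Pe <- as.matrix(Matrix::expm(Q * d))
      expect_lt(max(abs(P - Pe)), 1e-12)
      expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
    }
  }
})

test_that("two-leaf pruning equals the closed-form HKY product", {
  aln <- tibble::tibble(allele = c("a", "b"),
                        seq = c("ACGTACGTACGTCCGG", "ACGTACGAACGTCCGA"))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  arr <- mhctsp:::.tree_arrays(tr)
  pats <- mhctsp:::.tip_patterns(as_allele_alignment(aln), tr$tip.label)
  pi4 <- rep(0.25, 4)
  ll <- mhctsp:::pruning_loglik_cpp(
    arr$kid1, arr$kid2, arr$parent, arr$postorder, pats$tipstate,
    pats$patw, c(0, 0, 0.1), rep(1, 3), 2, 1e9, pi4)
  P <- mhctsp:::hky_pmat_cpp(0.1, 2, pi4)
  s1 <- strsplit(aln$seq[1], "")[[1]]
  s2 <- strsplit(aln$seq[2], "")[[1]]
  m <- setNames(1:4, c("A", "C", "G", "T"))
  ll2 <- sum(log(vapply(seq_along(s1), function(k) {
    sum(pi4 * P[, m[s1[k]]] * P[, m[s2[k]]])
  }, numeric(1))))
  expect_lt(abs(ll - ll2), 1e-10)
})

test_that("prior-only sampling reproduces Yule node-age moments", {
  aln <- tibble::tibble(allele = c("a", "b", "c"), seq = rep("ACGT", 3))
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  lam <- 0.1
  cfg <- clock_config(clock = "strict", rate = 0.002, generations = 2e5,
                      burnin = 2e4, thin = 20, sample_birth_rate = FALSE,
                      birth_rate_init = lam, seed = 5)
  pt <- mcmc_date(aln, tr, cfg, clade_definitions = list(ab = c("a", "b")),
                  likelihood_on = FALSE)
  s <- pt$samples
  # gaps between node ages are Exp(k * lambda): E[x3] = 1/(3 lam),
  # E[root] = 1/(3 lam) + 1/(2 lam)
  expect_lt(abs(mean(s$ab) - 1 / (3 * lam)) / (1 / (3 * lam)), 0.1)
  expect_lt(abs(mean(s$root) - (1 / (3 * lam) + 1 / (2 * lam))) /
              (1 / (3 * lam) + 1 / (2 * lam)), 0.1)
})

test_that("identical sequences put the pair TMRCA near zero", {
  aln <- tibble::tibble(allele = c("a", "b"),
                        seq = rep(strrep("ACGT", 62), 2))
  tr <- ape::read.tree(text = "(a:0.001,b:0.001);")
  cfg <- clock_config(clock = "strict", rate = 2e-3, generations = 3e4,
                      burnin = 3e3, thin = 10, seed = 2)
  pt <- mcmc_date(aln, tr, cfg)
  sm <- pt$summary[pt$summary$parameter == "root", ]
  expect_lt(sm$mean, 3) # a 248-site pair with zero differences is young
})

test_that("non-monophyletic clade definitions are refused", {
  truth <- simulate_gene_genealogy(
    tiny_sim_cfg(seed = 20, n_alleles_per_species_per_lineage = 1)
  ) |> evolve_alignment()
  st <- bootstrap_support(truth$alignment, reps = 100, seed = 3)
  rooted <- midpoint_root(st)
  l1 <- truth$membership$allele[truth$membership$lineage == "L1"]
  l2 <- truth$membership$allele[truth$membership$lineage == "L2"]
  mixed <- c(l1[1:3], l2[1:3])
  cfg <- clock_config(generations = 2000, burnin = 100, thin = 10,
                      rate = 2e-3, seed = 1)
  expect_error(
    mcmc_date(truth$alignment, rooted, cfg,
              clade_definitions = list(bad = mixed)),
    class = "mhctsp_error"
  )
})

test_that("doubling the clock rate halves inferred ages", {
  set.seed(31)
  aln <- tibble::tibble(
    allele = c("a", "b"),
    seq = {
      P <- mhctsp:::hky_pmat_cpp(0.02, 4, rep(0.25, 4))
      root <- sample(1:4, 248, replace = TRUE)
      nuc <- c("A", "C", "G", "T")
      ev <- function(r) vapply(r, function(x) sample(1:4, 1, prob = P[x, ]), 1L)
      c(paste(nuc[ev(root)], collapse = ""),
        paste(nuc[ev(root)], collapse = ""))
    }
  )
  tr <- ape::read.tree(text = "(a:0.02,b:0.02);")
  run <- function(rate) {
    cfg <- clock_config(clock = "strict", rate = rate, generations = 5e4,
                        burnin = 5e3, thin = 20, seed = 7)
    pt <- mcmc_date(aln, tr, cfg)
    pt$summary$mean[pt$summary$parameter == "root"]
  }
  a1 <- run(2e-3); a2 <- run(4e-3)
  expect_lt(abs(a1 / a2 - 2), 0.4)
})

test_that("ESS matches iid and AR(1) expectations", {
  set.seed(10)
  x <- rnorm(10000)
  expect_gt(ess(x), 0.8 * length(x))
  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), 20000))
  expected <- length(ar) * (1 - rho) / (1 + rho)
  expect_lt(abs(ess(ar) - expected) / expected, 0.25)
})

test_that("HPD intervals are shortest and match normal quantiles", {
  set.seed(11)
  x <- rnorm(10000)
  h <- hpd_interval(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.12)
  expect_lt(abs(h[2] - 1.96), 0.12)
  const <- rep(3, 500)
  hc <- hpd_interval(const)
  expect_equal(hc[1], hc[2])
  s <- trace_summary(tibble::tibble(p = const))
  expect_equal(s$sd, 0)
  expect_equal(s$hpd_width, 0)
})

test_that("trace summary reports the S-table style columns", {
  set.seed(12)
  tt <- tibble::tibble(age = rnorm(500, 20, 2), kappa = rexp(500, 1))
  s <- trace_summary(tt)
  expect_setequal(s$parameter, c("age", "kappa"))
  expect_true(all(c("mean", "sd", "se", "ess", "hpd_lower", "hpd_upper",
                    "hpd_width") %in% names(s)))
  expect_equal(s$se, s$sd / sqrt(s$ess), tolerance = 1e-12)
  expect_error(trace_summary(tt[1:50, ]), class = "mhctsp_error")
})

test_that("lineage dyad dating recovers the simulated duplication ages", {
  # neutral generator: the realized substitution rate equals the
  # configured neutral rate, so dating under that rate must recover the
  # 53 / 49.1 My duplication history
  truth <- simulate_gene_genealogy(
    tiny_sim_cfg(seed = 23, n_alleles_per_species_per_lineage = 1,
                 pbr_omega = 1, non_pbr_omega = 1)
  ) |> evolve_alignment()
  st <- bootstrap_support(truth$alignment, reps = 100, seed = 4)
  lin <- detect_lineages(st, dplyr::select(truth$membership,
                                           "allele", "genus"))
  expect_true(exact_lineage_recovery(lin, truth$membership))
  cfg <- clock_config(clock = "strict", rate = 2.21e-3,
                      generations = 5e4, burnin = 5e3, thin = 20, seed = 9)
  out <- lineage_divergence_times(truth$alignment, lin, 2.21e-3,
                                  st, cfg)
  dyads <- out$dyads
  # dyad TMRCAs never exceed the all-lineage root in any summary
  root_mean <- dyads$mean[dyads$clade == "root"]
  expect_true(all(dyads$mean <= root_mean + 1e-9))
  # every lineage pair present
  expect_equal(sum(grepl("-", dyads$clade)), 6)
  # detected lineage labels are arbitrary; compare against truth via
  # membership: the oldest dyads sit near 53 My, and the youngest dyad
  # (the 49.1 My pair) stays below them
  pair_rows <- dyads[grepl("-", dyads$clade), ]
  expect_lt(abs(max(pair_rows$mean) - 53) / 53, 0.25)
  expect_lt(abs(min(pair_rows$mean) - 49.1) / 49.1, 0.25)
  # and the dyad means fall inside their own HPDs around the truth
  expect_true(any(pair_rows$hpd_lower <= 53 & pair_rows$hpd_upper >= 53))
})
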
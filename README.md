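# mhctsp

Detecting and dating trans-species allelic lineages in MHC class IIB
exon-2 amplicon data.

## The problem

MHC class II beta genes encode the peptide-binding region (PBR) that
presents pathogen peptides to T cells. Balancing selection keeps PBR
alleles polymorphic for so long that allelic lineages survive speciation:
on a gene tree, alleles cluster by lineage across species and genera
rather than by species. This *trans-species polymorphism* (TSP) is both a
signature of long-term balancing selection and a window onto ancient gene
duplications. `mhctsp` implements the full analysis for tagged amplicon
data typed in multiple related species (the motivating system is a
248-nt IIB exon-2 fragment in seven corvid species from four genera):

- **Genotyping**: reads are demultiplexed on exact MID tag pairs, length-
  and indel-filtered, screened for internal stop codons, validated only
  when ≥ 3 identical reads appear in *both* independent PCR replicates,
  and collapsed when closer than 3 nt to a commoner variant.
- **Selection statistics**: per-species nucleotide diversity π,
  synonymous/nonsynonymous diversity by the modified Nei–Gojobori method
  (transition/transversion-weighted site counts, pathway-averaged
  differences, Jukes–Cantor correction), the codon Z-test
  `Z = (d̄N − d̄S)/SE` with codon-bootstrap SE, Tajima's D, and an
  entropy-based substitution-saturation screen.
- **Phylogeny**: neighbor joining on Kimura 2-parameter distances,
  `d = −½ ln(1−2P−Q) − ¼ ln(1−2Q)`, with nonparametric bootstrap support
  and midpoint rooting; deterministic tie-breaking makes trees
  bit-reproducible.
- **Lineage detection**: maximal clades with bootstrap support ≥ 0.75
  spanning ≥ 4 genera that form cohesive clusters (max within-clade
  patristic distance ≤ 1.2 × min clade-to-outside distance), plus
  amino-acid motif summaries.
- **Adjusted substitution rate**: within each lineage, synonymous
  divergence is regressed through the origin on total divergence over all
  allele pairs; the slope (the functional-constraint estimate) multiplies
  a published neutral nuclear rate (zebra finch 2.21e-9 or chicken
  1.91e-9 subs/site/year) to give the lineage's clock rate.
- **Bayesian dating**: MCMC over node ages on a fixed topology under
  HKY+Γ(4) (compiled Felsenstein pruning), a Yule prior, and strict,
  random-local or relaxed-exponential clocks; traces are summarised by
  mean, SD, SE, ESS (Geyer) and 95% HPD, with an ESS ≥ 100 reliability
  gate.
- **Synthetic data**: a seeded generator producing gene genealogies with
  lineage-founding duplications (defaults 53, 53, 53, 49.1 My), HKY+Γ
  sequences with elevated PBR and purifying framework dN/dS, optional
  gene conversion, and replicated tagged reads with point errors and PCR
  chimeras — with full ground truth, so every stage is testable offline.

## A worked example

```r
library(mhctsp)

truth <- simulate_tsp_dataset(sim_config(seed = 1))
pool  <- run_genotyping(truth$reads[, c("read_id", "raw_seq")],
                        truth$mid_table)
pool$alignment$genus <- unname(sim_config()$genus_map[pool$alignment$species])

stree    <- bootstrap_support(pool$alignment, reps = 500, seed = 2)
lineages <- detect_lineages(stree, pool$alignment[, c("allele", "genus")])
attr(lineages, "lineages")
#> # A tibble: 4 × 4
#>   lineage n_members n_genera support
#>   <chr>       <int>    <int>   <dbl>
#> 1 L1             14        4   1
#> 2 L2             14        4   0.99
#> 3 L3             14        4   0.98
#> 4 L4             14        4   0.986

rates <- lineage_rates(pool$alignment, lineages)
rates[, c("lineage", "slope", "adjusted_rate_zebra_finch")]
#> # A tibble: 4 × 3
#>   lineage slope adjusted_rate_zebra_finch
#>   <chr>   <dbl>                     <dbl>
#> 1 L1      0.739                   0.00163
#> 2 L2      0.923                   0.00204
#> 3 L3      0.860                   0.00190
#> 4 L4      0.773                   0.00171
attr(rates, "avg_rates")
#> zebra_finch     chicken
#>     0.00182     0.00157
```

All four simulated duplication lineages come back with ≥ 98% bootstrap
support, each spanning all four genera; the constraint slopes fall below
1 (the fragment's synonymous change lags total change because
nonsynonymous substitutions at the PBR outpace it), and the adjusted
rates land near 1.6–2.0 × 10⁻³ subs/site/My. `lineage_divergence_times()`
then dates every lineage, every lineage pair and the all-lineage ancestor
from one MCMC run, and `run_pipeline()` chains all stages into a report
bundle with a manifest.

`vignettes/mhctsp-methods.Rmd` explains the models, the generator's
assumptions, every tunable threshold, and the known limitations
(including where pathway-counting dN/dS estimates and the adjusted-rate
assumption break down).

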
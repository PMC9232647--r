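# haplomt

Tools for discovering, dating and classifying deep mitochondrial DNA
(mtDNA) haplogroups — the workflow by which a "new" branch of the human
maternal tree is recognised: variant profiles are parsed from
PhyloTree-style nomenclature, classified against a haplogroup reference
tree under a strict definitive-placement rule, dated with a strict-clock
Bayesian sampler under a partitioned HKY+Γ model with a Bayesian-skyline
coalescent demography, and annotated by extracting the synapomorphies
(defining variants) of every surviving clade. The package is aimed at
population geneticists and phylogeneticists working with whole-mtDNA or
control-region data who need a reproducible, scriptable version of this
pipeline with a built-in simulator for validation.

## The models in brief

* **Nomenclature.** Variants in PhyloTree notation against a 16,569-position
  reference: `T3423C`, `A12021c` (transversion), `459.1C` (insertion),
  `8281-8289d` (deletion), `T146C!` (back mutation). Hotspot masking removes
  SNPs at 152, 195, 310, 16519 and indels at 309–315, 515–524, 3105–3107,
  16183–16184, 16193 by default.
* **Classification.** A sample descends into a child haplogroup only when
  100% of the callable branch variants are derived, with no such pattern in
  the sister branch; a placement is *definitive* only when the whole path
  was callable and derived and every child branch is positively excluded.
* **Dating.** Strict clock calibrated at μ = 2.285×10⁻⁸
  substitutions·site⁻¹·year⁻¹ (a lognormal prior moment-matched to an
  averaged rate survey), HKY+Γ likelihood over six partitions (codon
  positions 1–3, hypervariable segments, tRNAs, other non-coding) with
  relative rates constrained to site-weighted mean 1, a Bayesian-skyline
  coalescent tree prior, MCMC over node ages (optionally topology via NNI),
  and maximum-clade-credibility summarisation with 95% HPD intervals.
  N̂ₑ through time comes from the classic skyline, k(k−1)·w/2 per
  coalescent interval, pooled over grouped intervals and posterior trees.
* **Annotation.** Nodes under 0.5 posterior support are collapsed to
  polytomies; ancestral sequences are reconstructed by Fitch parsimony or
  marginal ML (single-rate reversible model, reference root prior), and
  per-branch mutation lists are emitted in PhyloTree tokens.
* **Population inference.** An equal-rates discrete Markov model fitted by
  ML gives marginal ancestral population probabilities; nodes are
  interpreted only above 0.9. Haplogroup frequencies aggregate per region
  with max-normalised heatmap tables.

See `vignettes/haplogroup-discovery.Rmd` for assumptions, parameter
defaults and numerical choices.

## Worked example

```r
library(haplomt)

ht  <- l5p7_haplotree()          # packaged clade system with defining variants
ref <- mt_reference()

# a sample carrying the cumulative genotype of clade L7
p <- expected_genotype(ht, "L7")
p
#> <mt_profile> L7: 5 variant(s), 0 uncertain site(s), covered 1-16569

classify(p, ht, ref)
#> <mt_classification> assigned L7 (definitive)

# clade report from the packaged printed ages: stem = parent age - clade age
tab <- build_clade_table(l5p7_clade_ages()[, c("clade", "parent", "mean_age",
                                               "hpd_upper", "hpd_lower",
                                               "posterior")])
tab[tab$clade %in% c("L7a", "L7a1", "L7b"), c("clade", "mean_age", "stem_length")]
#>   clade mean_age stem_length
#>     L7a    79365       12111
#>     L7b    54409       37067
#>    L7a1    16333       63032
```

The three stem lengths read: clade L7a split from its sister ~91.5 kya and
coalesced at 79,365 years BP (stem 12,111 years); the L7a1 stem of 63,032
years is the long "fuse" between the ~79 kya split and its recent
coalescence — the signature of a lineage that barely survived.

Dating a simulated dataset (12 contemporary mitogenomes, true root age
50,843 years in this replicate):

```r
cfg <- sim_config(seed = 101, n_tips = 12, ne = 2000, gen_time = 25)
tr  <- simulate_coalescent_tree(cfg)
sim <- simulate_sequences(tr, cfg)
run <- mcmc_sample(sim$alignment, tr, steps = 10000, seed = 201,
                   parts = cfg$parts, topology = "fixed")
mean(run$log$root_age[-(1:100)])
#> [1] 49865.14
```

The posterior mean root age lands within 2% of the simulated truth here;
across 20 replicates the mean absolute error is about 10% with 95% HPD
coverage of 90–100% (see the acceptance script below).

A command-line wrapper with `classify`, `date`, `skyline`, `simulate` and
`report` subcommands is installed under `inst/scripts/haplomt`.

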
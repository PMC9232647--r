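---
title: "Models and methods behind haplomt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplomt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

haplomt implements the inference workflow used to discover and date deep
mitochondrial DNA haplogroups: variant nomenclature handling, classification
against a haplogroup reference tree, strict-clock Bayesian divergence dating
under a partitioned HKY+Γ model with a Bayesian-skyline coalescent
demography, ancestral-state reconstruction with per-branch synapomorphy
extraction, and population-label reconstruction. This vignette explains the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## Variant nomenclature

Variants are written in PhyloTree notation relative to a 16,569-position
reference coordinate system: `T3423C` (transition), `A12021c`
(transversion, lowercase target), `459.1C` (first inserted base after
position 459), `8281-8289d` (span deletion), and a trailing `!` for back
mutations. Two conventions deserve comment.

* **Back mutations.** A `!`-flagged SNP applied at a site that currently
  carries its derived base reverts the site to its reference base; applied
  at a site still carrying the reference base, it acts as an ordinary
  forward change. The second case is what a clade-defining string such as
  `T146C!` needs when the first event at the site happened outside the
  clade under study: within the clade, the branch event is simply T→C, and
  the flag records that this is a reversion relative to deeper ancestry.

* **Unspecified-count insertions.** Tokens such as `(573.XC)` describe a
  variable-length homopolymer insertion. They are parsed and carried as
  annotation, but excluded from likelihoods, classification and
  synapomorphy counting, because their length (and hence identity) is not
  comparable across samples.

The default hotspot mask removes the four most recurrent SNP positions
(152, 195, 310, 16519) and ignores indels in the ranges 309–315, 515–524,
3105–3107, 16183–16184 and 16193; all are classical homoplasy or alignment
trouble spots of the control region and the 3107 reference spacer. The mask
is configurable. Position 195 is a borderline case: some deep clades carry
a reversion there, but because the site is hypervariable it stays excluded
by default and does not count toward classification confidence.

### The packaged reference

The true rCRS/RSRS sequence is not redistributed with the package. The
packaged reference (`mt_reference()`) is a deterministic synthetic stand-in
with human-mtDNA-like base composition in which every position named by the
packaged L5'7 clade system carries its published ancestral base, so all
printed mutation strings apply without conflict. The per-position
functional annotation (codon positions from the standard human mtDNA gene
map, tRNA genes, HVS-I 16024–16569, HVS-II 57–372, HVS-III 438–574, other
non-coding including the rRNAs) uses real gene coordinates. Analyses that
depend only on variant positions and tokens — which is everything the
package computes — are unaffected by the synthetic background sequence.

## Classification: the definitive-placement rule

A sample descends from the root of the haplogroup tree into a child clade
only when **all callable** variants on that branch are derived and at least
one is callable. "Callable" means: inside the sample's covered range, not
heteroplasmic (IUPAC-uncertain sites are evidence of nothing), not masked,
and not annotation-only; an indel counts only when its whole span is
covered. When both a branch and its sister qualify — homoplasy or
contamination — the walk stops at the parent and flags the conflict rather
than choosing arbitrarily.

A placement is **definitive** when (i) every variant on the accepted path
was callable and derived, (ii) no sister branch on the path qualified, and
(iii) every child branch of the assigned clade is positively excluded,
i.e. all of its variants were callable and found ancestral (vacuously true
for terminal clades). Consequently a control-region-only sample can never
be definitive for a coding-region-defined clade, and heteroplasmy at a
defining site demotes a call from definitive to compatible — it never
redirects it to a sister clade, because positive evidence is required for
descent.

## Dating model

The dating engine is a strict-clock Bayesian sampler over rooted
ultrametric trees:

* **Substitution model.** HKY with empirical base frequencies and
  discrete-Γ rate heterogeneity (4 equiprobable categories, the field
  convention). The likelihood uses Felsenstein pruning over compressed
  site patterns (C++ core), with IUPAC codes as partial observations.
  The rate matrix is normalised to one expected substitution per site per
  unit length, so branch lengths in years combine with a clock rate in
  substitutions/site/year.
* **Partitioning.** Six bins — codon positions 1–3, the combined
  hypervariable segments, tRNAs, and other non-coding sites — each with a
  relative rate estimated under the constraint that the site-weighted mean
  rate equals 1 (the overall clock is fixed to the mean rate; only the
  distribution across bins moves).
* **Clock prior.** The clock rate is calibrated at 2.285×10⁻⁸
  substitutions · site⁻¹ · year⁻¹, the average of published whole-mtDNA
  rates. `average_rate_prior()` forms the equal-weight mixture of a rate
  survey (mean and standard deviation per study) and fits a lognormal by
  moment matching, so the prior mean equals the survey average and the
  spread carries between-study disagreement. The packaged default survey
  is a synthetic three-component stand-in whose means average exactly
  2.285×10⁻⁸. Because published sources are ambiguous about whether the
  rate was then sampled or held fixed, both modes exist
  (`clock_mode = "sample"` is the default; `"fixed"` pins the rate to the
  prior mean).
* **Tree prior.** A piecewise-constant coalescent: the classic Bayesian
  skyline with coalescent events split into contiguous groups (default 5),
  each group's population size sampled under a broad log-uniform prior.
  A single-group skyline is the constant-size coalescent.
* **Kernels.** Multiplier (scale) moves on rates, κ, α and population
  sizes; uniform node-age slides within the (child, parent) bracket; a
  whole-tree scale move; a delta-exchange move on relative partition rates;
  and optional age-respecting NNI exchanges for topology search. Proposal
  scales were chosen once to land acceptance rates broadly in the 20–80%
  range on the package's test problems. Priors on the nuisance parameters
  follow common practice: lognormal(1, 1.25) for κ, Exp(1) for α.
* **Convergence.** Every run records its seed, settings and per-kernel
  acceptance rates. The default convergence gate is agreement between two
  independent chains (`chains_agree()`, z < 3 on
  autocorrelation-adjusted Monte-Carlo errors); `effective_sample_size()`
  implements the initial-positive-sequence truncated autocorrelation sum.

Posterior samples are summarised by the maximum clade credibility tree
(the sampled topology maximising the product of clade posterior
frequencies) with per-clade mean ages and empirical 95% HPD intervals
(shortest interval containing 95% of the draws). Nodes under 0.5 posterior
support are conventionally collapsed into polytomies before annotation;
the threshold is a parameter.

## Ancestral states and synapomorphies

Per-branch defining variants are obtained by reconstructing ancestral
sequences at the variable sites and reading off parent/child differences.
Two engines are provided and agree on homoplasy-free data:

* **Fitch parsimony**, with set-valued states resolved root-down
  (preferring the parent state, then the reference base, then alphabetical
  order) — also the package's minimum-change counter.
* **Marginal ML** under a single-rate reversible model with empirical base
  frequencies (an F81-type model; the branch-length scale is itself fitted
  by maximising the likelihood). Exact ties resolve toward the parent
  state, which avoids manufacturing spurious synapomorphies.

The **root prior matters**: under the stationary prior, a change shared by
the whole ingroup can be parked on a long outgroup branch (the root being
reconstructed as derived). Because mtDNA variant data are expressed
relative to a known ancestral reference — and the simulator roots its
genealogies at the reference — the default root prior is a point mass on
the reference base (`root_prior = "reference"`); the stationary prior
remains available. Indels are carried by presence/absence parsimony and
reported as annotation-level events; they never enter the nucleotide
likelihood. A branch token is flagged `!` when it restores the root state
at a site that changed earlier on the same root-ward path.

Clade report rows compute the stem length as parent mean age minus clade
mean age; a missing parent age leaves the stem empty rather than zero. The
packaged printed age table reproduces its printed stem lengths within ±1
year (printed-rounding tolerance; four rows are exact and are checked
exactly).

## Population-label reconstruction and frequency tables

`ancestral_populations()` fits an equal-rates k-state Markov model (the
minimal discrete model for seven population categories and small samples)
by maximum likelihood, and returns marginal per-node probability vectors;
unknown tips enter as uniform partial observations. Only nodes whose best
category exceeds 0.9 are flagged informative — below that, drift and
admixture make interpretation unsafe. The implementation agrees with an
independent engine (`ape::ace`, ER model) to numerical precision in rate,
likelihood (up to the root-prior constant log k) and node marginals, which
is one of the package's cross-checks rather than its implementation.

`aggregate_frequencies()` tallies per-region haplogroup counts into
within-region frequencies and normalises each haplogroup to its maximum
across regions, flagging the peak region; regions without data are absent,
not zero. The tables are plain data frames and CSV, consumable by any
mapping or charting layer (cartography is out of scope).

## The synthetic-data generator

`simulate_coalescent_tree()` draws standard haploid coalescent genealogies
with rate k(k−1)/(2·Nₑ(t)) per generation under a piecewise-constant Nₑ,
converted to years by a generation time (default 25 years).
`simulate_sequences()` evolves sites independently down the genealogy
under the partitioned HKY+Γ strict clock, each site with a fixed Γ
category, and returns both the alignment and the true per-branch mutation
lists. Defaults mirror the package's study conditions: μ = 2.285×10⁻⁸
site⁻¹ year⁻¹, the full 16,569-site coordinate system, κ = 22 and
Γ-shape 0.4 (typical whole-mtDNA values), Nₑ = 5,000, and relative bin
rates elevated in HVS and third codon positions and depressed in tRNAs and
second positions (rescaled to site-weighted mean 1). The generator also
produces the two degradation artifacts the pipeline must tolerate:
heteroplasmy (variants turned into IUPAC uncertain sites with a stated
probability) and control-region-only truncation.

What the generator does **not** emulate: recurrent-hotspot rate spikes
beyond the Γ tail, insertions/deletions arising de novo (indels appear
only via planted fixtures), sequencing error that is not heteroplasmy-like,
selection, and population structure in the genealogy. Passing tests
therefore demonstrate correctness of the inference machinery under the
stated model, not robustness to every artifact of real archives.

`plant_haplogroup_fixture()` turns any haplogroup tree into a complete
fixture: one tip per named clade carrying its cumulative genotype plus an
outgroup with the root genotype, with expected classifications. Note that
such ancestral-genotype tips violate the molecular clock (a tip identical
to a deep ancestor implies a zero-change path to the present), so the
fixture is dated with a **fixed topology** (`haplotree_as_phylo()` builds
the implied dated tree); free NNI search on fixture data will legitimately
cluster the near-reference genotypes instead. Clock-consistent data for
topology-search tests come from the sequence simulator.

## Problem sizes and numerical choices

The package's own verification suite uses desk-scale problem sizes chosen
to make the checks sharp but fast: exhaustive-enumeration likelihood
oracles on up to 5 taxa and 4 sites (relative agreement demanded at
10⁻¹⁰); strict-clock recovery on 20 replicate 12-taxon full-length
datasets at 10⁴ MCMC steps (posterior mean root age within 15% on average,
95% HPD coverage at least 80%). The recovery study dates under the
calibrated **fixed** clock: with a dozen contemporary sequences the clock
rate and the root age are strongly confounded, so sampling the rate under
its survey prior inflates the posterior-mean age error to 15–19% across
replicate sets without materially improving coverage, whereas the
fixed-clock mode — the mode in which such calibrated dating is normally
reported — recovers root ages to 7–10% with coverage at or above 90%.
Skyline recovery uses 20 constant-size
50-tip genealogies (mean Nₑ within a factor 1.5, trend interval covering
zero). Headline analyses in the literature run two chains of 5×10⁷ steps
over dozens of mitogenomes; nothing in the implementation caps chain
lengths — the sampler scales linearly in steps × patterns.

Other numerical choices: site patterns are compressed per partition;
pruning rescales partial likelihoods per node to avoid underflow; the HKY
transition probabilities come from the exact spectral decomposition of the
π-symmetrised rate matrix; discrete-Γ category rates are the analytic
means of equiprobable slices; the empirical base frequencies carry a +1
pseudocount so degenerate alignments stay proper; and zero-length
coalescent intervals contribute nothing to the skyline but are tolerated.

## Known limitations

Relaxed clocks, tip-date calibration of ancient genomes, per-partition
model selection and bootstrap ML search are deliberately out of scope. The
skyline is the classic per-interval closed form aggregated over sampled
trees (with grouped intervals), not the full joint smoothing prior, so its
credibility bands on real posteriors are approximate. Nₑ is reported in
branch-length units (years × generation time) unless a generation time is
supplied. Deletions are compared by exact span with no left-realignment;
inputs are assumed normalised to PhyloTree conventions.
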
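---
title: "Low-density panels, family-based imputation and genomic prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-density panels, family-based imputation and genomic prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aquaimpute)
```

aquaimpute evaluates a cost-reduction strategy for genomic selection in
aquaculture breeding programmes: genotype the parents at high density (HD),
genotype the offspring with a much cheaper low-density (LD) panel, impute the
offspring back to HD using the haplotypes they inherited from their parents,
and run genomic prediction on the result. The package provides every stage —
synthetic populations, quality control, panel design, imputation, imputation
accuracy metrics, and GBLUP cross-validation — so the whole strategy can be
stress-tested end to end without access to a commercial dataset.

This vignette documents the models and the numerical choices. It states no
empirical result; the numbers the package produces come from its tests and
from `scripts/acceptance.R`.

## The synthetic population

Aquaculture broodstock are typically a small set of parents (tens) producing
large full-sib families (tens of offspring each), two generations deep, with
strong relatedness and long shared haplotypes. The generator mirrors that
structure directly.

**Founders.** Founder haplotypes are mosaics of a small pool of
`n_ancestral` haplotypes: along each chromosome a founder haplotype copies
one ancestor and switches to a different one with probability
`1 - exp(-switch_rate * gap_bp)` between adjacent SNPs. This is not a
coalescent; it is the simplest mechanism with a single interpretable LD knob
(`switch_rate`, expected segment length `1/switch_rate` bp) that produces the
two properties the analysis depends on: tunable LD and long haplotypes shared
identically by related parents. Optionally the ancestors themselves are
mosaics of a yet smaller `n_proto` pool at a faster switch rate, which
produces two-scale LD (strong short-range, weak long-range) similar to
populations founded from a handful of wild source stocks.

**Marker map.** SNP positions are drawn uniformly per chromosome, or — with
`snp_clustering > 0` — from 2.5-Mb blocks whose density weights are gamma
distributed (shape `1/snp_clustering`). Real SNP-array and RAD-seq maps are
strongly clustered, and the clustering matters: a panel drawn uniformly *over
SNPs* concentrates where the map is dense, whereas a panel spaced evenly *in
bp* covers the genome. Allele frequencies come from `maf_law` (default
uniform on (0.1, 0.9)).

**Transmission.** `gene_drop()` transmits recombinant gametes down the
pedigree: crossover counts are Poisson with mean `genetic_length_cm/100` per
chromosome and positions are uniform on the genetic map (Haldane, no
interference; constant cM/bp within a chromosome). Genotype = hap1 + hap2 at
every site by construction, and Mendelian errors are structurally impossible
at genotyping-error rate 0. Sex-specific recombination is supported through
`sire_map_scale`/`dam_map_scale`; salmonids in particular show strong male
recombination suppression, and the salmon-like preset uses 0.1/1.3.

**Phenotypes.** `n_qtl` causal SNPs are drawn from the segregating markers —
uniformly over markers, or with `qtl_placement = "uniform_bp"` weighted by
the physical interval each marker represents, so causal positions stay
uniform along the genome even on a clustered map (causal variants have no
reason to follow array density). Effects are normal; the breeding value is
the weighted QTL dosage sum, rescaled so the realized additive variance is
exactly `h2_target` of the phenotypic variance (residuals N(0, 1 − h²)).
Binary traits threshold the realized liability at its `1 - prevalence`
quantile. Exact h² control at this scale makes parameter-recovery tests
meaningful with 20 replicates instead of hundreds.

All randomness flows from one root seed through named substreams
(founders, gametes, effects, fills, folds), so stages can be re-run in
isolation and whole experiments are bit-reproducible.

### The salmon-like preset

`sim_preset("salmon_like")` is the package's reference study condition:
60 parents, 100 factorial full-sib families, 1,000 offspring, 10,000 SNPs.
The genome and LD calibration follow Atlantic salmon: 29 chromosome pairs
(75 Mb, 75 cM sex-averaged each), male recombination suppression (0.1/1.3),
clustered marker positions (`snp_clustering = 3`), causal variants uniform
in bp, a founder pool of 10 ancestral haplotypes with slow mosaic decay
(`switch_rate = 3e-8`, expected shared segments tens of Mb — farmed salmon
have small effective population size and famously long-range LD), and a
trait of h² 0.2 (the salmon sea-lice trait's genomic heritability estimate
is 0.19). `sim_preset("oyster_like")` instead uses 10 chromosomes and a
fast-decaying, more diverse founder pool.

What the generator does *not* emulate: genotyping error beyond a symmetric
flip rate, assembly/map errors, null alleles, selection, multi-generation
pedigrees, sex chromosomes, or the segregation distortion reported for
bivalves. Tests passing on these populations show the pipeline's logic and
its qualitative behaviour, not performance guarantees for any real dataset.

## Quality control

`filter_individuals()` removes individuals above 20% missing genotypes and
offspring with exactly one genotyped parent (half-anchored individuals that
family-based imputation cannot treat symmetrically); parents are never
removed by the one-parent rule. `filter_snps()` removes SNPs with >10%
missingness, exact Hardy–Weinberg p below 1e-6, MAF below 0.05, or trio
Mendelian error rate above 10%. All thresholds are strict inequalities, so
boundary values are kept. Every criterion is computed on the input data;
the order (missingness → HWE → MAF → Mendelian) affects only which reason a
doubly-failing SNP is reported under, not the kept set. The HWE test is the
exact (Wigginton-style) two-sided test — well-defined at low counts where
the chi-square approximation is not — implemented by direct summation of
the exact sampling distribution over heterozygote counts, with monomorphic
sites returning p = 1 by convention. Mendelian conflicts are reported, never
zeroed: downstream imputation receives the original genotypes. After
imputation the MAF filter is applied once more (`post_imputation_maf_filter`),
because frequency-based filling can push rare SNPs below the usable range.

## Panel design

Three selection methods build an LD panel from the HD map.

* **Physical.** Panel slots are allocated to chromosomes proportionally to
  length (bp of the last mapped SNP — no external assembly resource needed)
  with largest-remainder rounding and a floor of two per chromosome, since
  the first and last SNP of every chromosome are always selected. The
  remaining slots become equally spaced target positions, each resolved to
  the nearest not-yet-selected SNP (equidistant ties to the higher bp). A
  chromosome with fewer SNPs than its allocation contributes all of them and
  the shortfall is not redistributed, so achieved density may be slightly
  below target.
* **Genetic (LD pruning).** Windowed greedy pruning of pairwise squared
  correlations: within each 50-SNP window (step 5, never spanning
  chromosomes), while any kept pair has r² above the threshold, the
  offending pair's lower-MAF member is removed (ties to the later map
  position — keeping the more informative marker is the package's choice;
  pruning tools leave this unspecified). The threshold is then bisected
  until the pruned set is as close as possible to the target, and the exact
  size is enforced by trimming at evenly spaced indices or topping up with
  the highest-MAF excluded SNPs; the adjustment is recorded in the panel's
  `details`. Zero-variance pairs define r² = 0 so invariant SNPs never
  trigger pruning.
* **Random.** Uniform sample without replacement, deterministic per seed.

`mask_to_panel()` sets off-panel genotypes of the target individuals
(offspring) to missing; reference parents keep their HD genotypes.

## Imputation

The imputer is a two-generation family imputer: parents are the reference,
each offspring is treated independently (results do not depend on the order
of individuals).

**Parent phasing.** `phase_parents()` works chromosome by chromosome in two
stages. (1) Within non-overlapping windows of `window_sites` SNPs (default
12), all consistent haplotype decompositions of every parent's genotype are
enumerated and an EM iteration estimates window-haplotype frequencies; each
parent gets its most probable pair. Enumeration is capped at 16 heterozygous
sites per window — beyond the cap the extra sites are phased arbitrarily,
which at the default window size is never reached in practice. (2) Windows
are chained left to right: each parent's two growing haplotypes are extended
by the window pair in the orientation best supported by *haplotype sharing*
— other parents whose left tails (last `tail_sites` SNPs, default 15) are
near-identical vote for the continuation they carry, with exp(−Hamming)
kernels so isolated window errors do not break the votes. The first pass is
online (only already-chained parents vote, so arbitrary initial orientations
never feed back); subsequent passes refine leave-one-out until stable.
A final polish re-phases every window over all its consistent
decompositions, scored by sharing with the other parents' current phase in
the window and both flanking contexts; this repairs both mis-oriented
windows and residual within-window EM errors (in the package's simulations
it roughly halves the switch-error count). The design exploits the long
shared haplotypes of closely related broodstock; its known failure mode is
a haplotype pair that occurs *only* as that pair in the sample, whose
chaining is genuinely unidentifiable from genotypes. An `"oracle"` mode
returns the simulated truth, used to isolate downstream error sources. A
naive "reassign each parent the most frequent consistent library pair"
sweep was rejected: each parent's current pair is itself in the library,
making the initial random phase a fixed point.

`refine_parent_phase()` adds the family's second source of phase evidence:
a switch error in a parent makes *every* offspring's gamete-origin path
change state at the same position, whereas real crossovers fall at
offspring-specific positions. Positions where at least half of the
path-informative offspring switch are called phase errors and the parent's
haplotypes are flipped from there on, to the resolution of the informative
markers. Errors shorter than the informative-marker spacing remain
invisible to this check by construction.

**Gamete-origin decoding.** At markers where the offspring genotype and the
other parent's genotype jointly determine the transmitted allele and the
focal parent is heterozygous, the transmitted allele identifies one parental
haplotype. `infer_gamete_origin()` finds the minimal-cost two-state path
over these informative markers (mismatch cost 1 per disagreement, switch
cost 3 by default — roughly ln of the expected number of informative markers
per crossover; both configurable) by dynamic programming with lexicographic
tie-breaking: fewer switches, then haplotype 1. The DP is validated against
exhaustive path enumeration in the tests.

**Allele copying and random fill.** `impute_offspring()` fills each masked
genotype gamete by gamete. Where the focal parent is homozygous the
transmitted allele is certain and always copied. At parent-heterozygous
sites the allele is copied from the haplotype assigned by the path between
the flanking informative markers. Markers inside a switch interval (flanks
decoded to different haplotypes) and chromosomes with no informative
markers fall back to sampling alleles independently from the
reference-population allele frequency — honest uncertainty, matching the
frequency-based random filling used by the pedigree imputation software the
strategy emulates, rather than guessing a breakpoint. Genotypes forced by
Mendelian rules (hom × hom parents) are filled first; observed genotypes
are never altered; every entry carries a provenance tag (`observed`,
`mendelian`, `haplotype-copy`, `random-fill`).

`external_imputer_adapter()` round-trips the same inputs through a
user-supplied command or function in a simple TSV dosage dialect and
validates shape, completeness and that observed genotypes were preserved —
so results from standalone imputation software can flow through the same
evaluation pipeline. No external software is bundled.

## Accuracy metrics

Per-individual imputation accuracy is the Pearson correlation between true
and imputed dosages over that individual's masked sites; the mean ± sd over
individuals is the headline statistic. Panel (observed) SNPs are excluded
by default — including them inflates the statistic with genotypes that were
never imputed; `include_observed = TRUE` gives the other convention, since
published analyses rarely state which they used. Zero-variance individuals
have an undefined correlation and are reported as missing and counted, not
silently dropped. Per-SNP concordance is the percentage of masked genotypes
exactly equal to the truth. MAF-binned accuracy groups per-SNP correlations
into the five bins (0,0.1], …, (0.4,0.5] (left-open, right-closed; MAF
exactly 0.1 falls in the first bin); monomorphic SNPs are excluded with a
warning.

## GBLUP

The GRM is the standardized form
`g_jk = (1/N) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2 p_i (1 − p_i))` with
allele frequencies estimated from the supplied genotypes — computed once per
dataset on parents plus offspring and reused across cross-validation folds,
matching a single-GRM-per-dataset workflow. Monomorphic SNPs are excluded;
residual missing genotypes are mean-imputed with a message.

`reml_fit()` fits `y = Xb + a + e`, `a ~ N(0, G σ²_a)` by REML: the GRM is
eigendecomposed once, the model is rotated so the covariance is diagonal in
the variance ratio, and the profiled REML log-likelihood is maximized over
h² ∈ [1e-6, 1 − 1e-6] by one-dimensional optimization — exact and fast at
these sizes, with no sparse solver. A GRM whose smallest eigenvalue is below
1e-8 gets 1e-6 added to the diagonal (semidefiniteness to round-off is
routine since the GRM rank is bounded by the SNP count; a materially
indefinite matrix triggers a message). `gblup_predict()` returns the BLUP
breeding values at the REML estimates via the conditional form
`a = σ²_a G V⁻¹(y − Xb)`; the tests verify it against direct inversion of
the mixed-model equations.

`cross_validate()` runs the replicated k-fold design (default 20 × 5-fold):
folds are drawn uniformly over phenotyped individuals — not
family-stratified, since the emulated workflow does not stratify — variance
components are re-estimated on each training set, and each fold's accuracy
is `cor(EBV, y)/sqrt(h2_full)` with the heritability denominator estimated
once on the full data (in a multi-panel study: once from the HD panel and
shared by all panels, so panels differ only in their numerator). Fold-level
accuracies are averaged; with singleton folds the predictions of a
replicate are pooled instead, as a per-fold correlation is then undefined.
Binary traits are analysed with the same linear model on 0/1 codes — a
logit GBLUP is out of scope, and on the liability-threshold traits the
generator produces, the linear analysis is the standard approximation.

## The experiment driver

`run_experiment()` wires the stages together for a panel × density grid and
emits a tidy report (`method`, `density`, `imputation`, `metric`, `mean`,
`sd`, `n`) with the three curves of interest: HD cross-validation accuracy,
LD-panel accuracy without imputation, and accuracy after imputation, plus
per-panel imputation accuracy. `cost_comparison()` implements the
genotyping-cost arithmetic (totals and percent reduction).

## Problem sizes

The test-suite defaults are chosen for a desk-scale run: the reference
pattern experiment uses the salmon-like preset at its full size (60 parents,
1,000 offspring, ~10,000 SNPs, 29 chromosomes) with densities
{300, 1,000, 3,000} and 10 replicates of 5-fold cross-validation (random
panels are evaluated as the mean over several independent draws, mirroring
the multiple random panels of the emulated design); parameter-recovery
suites use n = 1,000 offspring with 20 replicates per heritability; oracle
equivalence suites use instances small enough for exhaustive enumeration
(≤ 20 SNPs for pruning, ≤ 12 markers for path decoding, n ≤ 50 for the
mixed-model solver, totals ≤ 500 for the exact HWE test).

## Known limitations

* The ancestral-mosaic founder model has no mutation and a fixed pool size;
  its LD decay is geometric, not the composite curve of a real population.
* The phasing heuristic depends on haplotype sharing; in small parent sets
  where a haplotype pair is confounded (appears only as that pair), switch
  errors are unavoidable without offspring information.
* Random filling deliberately injects variance where the gamete origin is
  unresolved; the imputed matrix is a draw, not a posterior mean, so
  downstream GRMs carry that extra noise (dosage-expectation output is a
  possible extension).
* The cross-validation statistic divides by √h²; with a noisy h² estimate
  the accuracy scale inherits that noise, and values slightly above 1 can
  occur by chance.
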
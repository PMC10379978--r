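---
title: "Models and methods in haplodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in haplodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodyn)
```

`haplodyn` analyses haplotype-resolved RNA-seq time courses of plants under
salt (NaCl) and osmotic (PEG) stress. This vignette explains the statistical
models behind each stage, the parameters that matter, what the synthetic
generator does and does not emulate, and the design decisions that were
genuinely open.

## The experimental design the package assumes

One pooled library per condition: control at 0, 24, 48 and 72 h, NaCl and
PEG at 24, 48 and 72 h — ten libraries, no replicates. All stages treat the
column sums of assigned fragments as the library sizes; raw sequenced-read
totals are not available downstream of counting, and the difference is a
near-constant factor that cancels in every comparison the package makes.
Treated libraries are always compared to the control at the same time point,
which removes slow drift in the control series; the 0 h control is used only
as a fallback when no same-time control exists.

## Quantification

FPKM is `count * 1e9 / (length_bp * library_size)`. For allele-level
matrices, both alleles of a pair use the gene's transcript length, so the
allelic ratio is a pure count ratio — length and depth cancel. For GFF3
input the transcript length is the merged-exon length of the longest
transcript, falling back to the gene span; the format's 1-based inclusive
coordinates are respected. Expression classes use right-closed boundaries
at 5, 20 and 100 FPKM, and the low-expression filter removes genes below
5 FPKM in every library. Sample clustering uses Spearman correlation
(average ranks on ties) on genes above 1 FPKM in at least one sample —
"at least one" is the permissive reading of an underdetermined convention,
and a `filter_rule = "all"` switch exposes the strict one. The linkage is
average linkage on `1 - rho`, the common choice for sample dendrograms.

## The fixed-dispersion exact test

With one library per condition, a dispersion cannot be estimated, so it is
fixed: the biological coefficient of variation (BCV) is 0.1 and the
negative-binomial dispersion is its square, 0.01. The test:

1. rescales both counts to the geometric mean of the two library sizes
   (mean-preserving scaling, rounded to integers) — a deliberate
   simplification of the quantile-adjustment step some packages use; it is
   symmetric and enumeration-checkable;
2. conditions on the rescaled sum `s`; under the null the first count
   follows the two-group NB conditional distribution with equal size
   parameters `1/phi` (a beta-binomial form);
3. sums the probabilities of all outcomes no more likely than the observed
   one (two-sided), capping at 1.

Numerical details that are easy to get wrong: probabilities are compared on
the log scale with a `1e-9` tolerance so that exactly tied (mirror-image)
outcomes are always included, and a total within `1e-12` of 1 is snapped to
1 so that symmetric observations report exactly `p = 1`. The conditional
pmf is evaluated with `lchoose`, which remains stable for non-integer size
parameters and sums in the thousands.

Two properties of this design are worth stating plainly. First, a discrete
exact test is conservative wherever the conditional support is sparse: its
attained size approaches the nominal 0.05 only at high counts. The
type-I-error benchmark in the test suite therefore simulates deep libraries
(mean ~650 fragments per feature), where the nominal-size property can
actually hold; a separate guard asserts the test never becomes
anti-conservative at typical depths. Second, gene-level counts formed by
summing two allele-level NB draws have dispersion of roughly `phi/2`, not
`phi`, so gene-level testing at the fixed `phi` is mildly conservative —
an inherent property of analysing allele-summed counts with a fixed
dispersion, not a defect of the test.

Benjamini–Hochberg is implemented as the textbook step-up
(`q_(i) = min_{j>=i} (m/j) p_(j)`, capped at 1) and cross-checked against
the reference implementation in the tests. Fold changes use a prior count
of 0.5 per library so zeros stay finite.

## ASE calling and bias-trajectory classification

A pair is biased when one allele's FPKM is at least `fold` (default 2)
times the other's. The boundary is inclusive: "twofold changed" is read as
`>= 2`, and the comparison is the multiplicative `a >= fold * b`, which is
zero-safe without a pseudocount and honours the boundary exactly (a
pseudocount inside the comparison would misclassify the exact-boundary
case). A pseudocount of 0.001 is used only for the reported log2 allelic
ratio. Pairs whose higher allele is below 0.5 FPKM are `NOT_EXPRESSED`:
without a floor, a ratio of 0.002/0.001 would count as bias.

Per time point, the (control, NaCl, PEG) statuses collapse to biased/not
(direction-blind) and map to the seven observable categories; triplets with
no bias anywhere, or any `NOT_EXPRESSED` member, are excluded from the
universe. Responsiveness compares each treated status to control:
`conserved` (biased in all three), `salt_specific` (only NaCl differs),
`drought_specific` (only PEG differs), `both`. These definitions make the
accounting identities exact on any input: salt-responsive = both +
salt-specific, drought-responsive = both + drought-specific, responsive =
universe − conserved. Direction flips (A-biased in one condition, B-biased
in another) are collapsed into "biased" for category purposes — the
category table is direction-blind — but counted in a `direction_flip`
diagnostic so the information is preserved. Percentages are reported
half-up at two decimals, matching how such tables are printed.

Cross-time union sets of responsive genes are also reported. Published
per-time counts reconcile exactly with category tables, but cross-time
totals depend on an unstated union rule; the package reports per-time
counts (which are identity-exact) plus a documented union
(union of per-time responsive sets), and does not attempt to arbitrate
between differing printed totals.

## The co-expression core

The network is unsigned: adjacency `|cor|^beta` with Pearson correlation,
the cited framework's default. The soft threshold is the smallest power
whose scale-free fit (signed R² of the log-log regression of binned
connectivity frequency on mean connectivity, 10 bins) reaches 0.85, else
the power maximising the fit (6 on ties). The topological overlap is the
standard unsigned TOM; connectivities and shared-neighbour sums exclude
the diagonal.

Module detection is average-linkage clustering on `1 - TOM` with a static
branch cut at height 0.95. A static cut replaces the dynamic tree-cut
algorithm deliberately: dynamic cutting is a large procedure with many
unstated parameters, and planted-module recovery — not label-exact parity
with another implementation — is what this package tests; the height is
configurable. Clusters below `min_module_size = 80` become `grey`. Module
eigengenes are the first principal component of the standardized module
expression, sign-aligned to correlate positively with the module mean
profile (removing PC sign ambiguity so results are deterministic). Modules
whose eigengene dissimilarity `1 - cor` is below `merge_cut_height = 0.3`
merge iteratively, closest pair first, recomputing eigengenes after each
merge.

Module–trait correlation uses one-hot indicators per (treatment, time)
group — the only construction readable from a per-sample trait heatmap —
with two-sided p from the t distribution on `n - 2` degrees of freedom.
Hub screening keeps module members with `|GS| > 0.2` (gene significance:
correlation with any trait) and `|MM| > 0.8` (module membership:
correlation with the own-module eigengene), both strict inequalities,
ranked by the number of within-module edges at adjacency weight ≥ 0.3.

## Enrichment and intersections

Over-representation is one-sided hypergeometric (`P(X >= k)`), matching a
test for enrichment rather than depletion, with BH across all tested terms
and significance at q < 0.05. The default universe is the set of genes
passing the low-expression filter (the definition is configurable; whether
published analyses used annotated or expressed genes as the universe is
typically unstated). Term maps are consumed as flat term-to-gene tables;
no ontology-graph propagation is attempted. Upset-style reports give
exclusive-region cardinalities, which partition the union by construction.

## The synthetic generator

The generator emulates the pooled stress time course at the level the
analysis consumes: fragment counts.

* **Counts**: negative binomial per allele with dispersion `bcv^2`
  (default BCV 0.1). Gene counts are the sum of the two allele counts.
* **Baselines**: log-normal mean fragment counts, natural-log mean 5 and
  sd 1.2 by default (median ~150 fragments per gene) — a modest, realistic
  spread. Gene lengths are log-normal around 2 kb.
* **Library sizes**: log-normal size factors (sd 0.1). Expected per-library
  totals are rescaled to a constant before size factors are applied:
  sequencing depth is set by the instrument, so biology changes
  composition, not expected depth.
* **Allelic bias**: a biased pair splits the gene mean as
  `2^r / (1 + 2^r)` to allele A for allelic log2 ratio `r`, with `|r|`
  uniform on `log2_bias_range` (default 1.5–3.5, lower bound ≥ 1 so
  simulated bias is detectable at the twofold criterion).
* **Bias switching**: the general model draws the control state with
  probability `pi_bias` and flips it independently per treated condition
  (`switch_loss`/`switch_gain`). This two-flip model spans the seven
  observable categories but cannot reproduce an arbitrary category table:
  printed tables can violate its independence constraint (conserved×BNN =
  BBN×BNB), i.e. real treated states are dependent given control. The
  generator therefore also accepts a per-time category multinomial, and
  `table1_preset()` uses it with the published proportions, making
  expected category frequencies exact by construction.
* **Preset effect sizes and depth**: the preset uses
  `log2_bias_range = c(2, 4)` and mean fragment counts around 2,200 per
  gene, mirroring the published sequencing depth of roughly 80 million
  fragments per library. Both choices make category identity — not
  detection power at the twofold boundary or Poisson noise at the
  expression floor — the quantity a preset run measures.
* **Modules**: when module structure is on, every gene receives an
  independent log-scale biological noise layer of sd `module_sd`
  (default 0.5); members of a module share a latent factor so their
  pairwise latent correlation is `module_cor`. Background genes are, in
  effect, modules of size one. Without that layer, the only biological
  variation in the transcriptome is the modules themselves, and
  library-composition feedback makes all background genes mutually
  correlated — a spurious module.
* **DE effects**: per treatment, a fraction `pi_de` of genes get a log2
  fold change drawn from `log2_de_range`, constant across that
  treatment's time points.

What the generator does **not** emulate: read-level artefacts (mapping
bias, multi-mapping, SNP-level allele assignment), transcript-level
quantification ambiguity, batch effects, and biological time-trends in the
control series. Passing tests therefore demonstrate the correctness and
calibration of the statistics on data satisfying the model's assumptions,
not robustness to alignment-level artefacts of real haplotype-resolved
data.

## Benchmark problem sizes

The suite's stochastic benchmarks use sizes chosen to make their targets
estimable: category recovery runs the preset at 20,000 gene pairs
(multinomial sampling error well under the ±2-percentage-point check);
the type-I benchmark uses 5,000 null genes in the dense-support regime
described above; module recovery plants 3 modules of 100 genes among 600
with `module_cor = 0.8` and a **triplicated** design (30 libraries,
`n_reps = 3`) — pairwise correlation estimates from 10 samples have
standard error near 1/3, which drowns partition structure regardless of
the detector, and the replication hook exists precisely for such power
studies; the structureless-noise guard uses 500 independent genes.

## Known limitations

* The exact test deliberately omits quantile adjustment and TMM
  normalization; with pooled single libraries, column-sum scaling is the
  defensible default, and a hook records where a different normalization
  would plug in.
* Static branch cutting can split a sprawling module that dynamic cutting
  would keep whole; the merge step recovers most of these cases, but label
  parity with other implementations is out of scope.
* The twofold ASE criterion is a plain fold-change rule by design;
  no binomial/beta-binomial ASE test is performed, so shallow libraries
  near the expression floor will produce noisy calls (hence the floor).
* Cross-time union ASE totals depend on an unstated rule (see above) and
  should be read as the package's documented convention, not a reproduction
  of any particular printed total.
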
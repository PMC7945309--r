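---
title: "gbsfoil: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gbsfoil: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what `gbsfoil` computes and why it is built the way
it is: the generative model behind the synthetic data, the contracts of the
assembly and filtering stages, the DFOIL statistics and their
classification table, and the numerical and design choices made where the
underlying methods literature leaves the details open.

# The synthetic GBS model

`simulateGBS()` generates a complete GBS system from a `simConfig()`:

* **Tree and units.** A rooted ultrametric species tree (time units are
  arbitrary; the packaged `defaultSpeciesTree()` has root depth 1.0) whose
  tips are taxa. Each taxon holds `popsPerTaxon` populations diverging at
  `popSplitDepth` (default 0.02), each with `indsPerPop` diploid
  individuals (default 5, matching a typical design of five plants per
  sampled population).
* **Sequence evolution.** Each locus evolves independently by Jukes-Cantor
  substitution: along a branch of length $b$ every site substitutes with
  probability $1 - e^{-\mu b}$, the new base uniform over the other three.
  JC is the simplest testable choice; nothing downstream depends on the
  substitution model beyond site patterns existing. Within-population
  variation adds Poisson(`popTheta` $\times$ locus length) extra mutations
  to each of an individual's two alleles.
* **Introgression.** An `introgressionEvent(donor, recipient, gamma,
  tAdmix)` affects each locus independently with probability `gamma`; an
  affected locus is re-simulated on a genealogy in which the recipient
  lineage (a population, or a whole taxon clade) is detached and re-attached
  to the donor lineage at depth `tAdmix`. This locus-wise genealogy
  replacement is exactly the signal a locus-based D statistic responds to.
  An event whose `tAdmix` is older than the donor's divergence from its
  sister attaches the recipient to the ancestral branch, so
  "ancestor-of-(P1,P2)" scenarios need no special event type.
* **Artifacts.** Each (individual, locus) read stack is lost with
  probability `dropout`; a fraction `paralogRate` of loci is merged pairwise
  (reads relabeled to one id), creating the hypervariable composite loci
  that multi-copy genomic regions produce in real de novo assemblies.
  Reads are full-locus length (GBS fragments start and end at restriction
  sites, so there is no random shearing), Poisson(`coverage`) per allele,
  with per-base error `baseError` flipping to a uniform other base.

**Default calibration.** The defaults emulate the study design the package
is tested against: 13 taxa (one of them used later as outgroup) x 2
populations x 5 individuals, 500 loci of 30 bp, `dropout = 0.2` (realized
missingness ~20%, inside the 15-25% range typical of published GBS
datasets), and `mu = 0.02` per site per unit depth with
`popTheta = 0.002`, which yields roughly 2 variable sites per locus among
taxon-level units and ~5 among all individuals - the 1.5-5 SNPs/locus
regime of short-fragment GBS. These defaults are the study conditions of
the test suite and are not tuned per test.

**What the generator does not emulate:** incomplete lineage sorting (within-
species coalescence beyond the `popTheta` noise), indels, realistic
sequencing-error profiles, PCR duplicates, barcode/adapter artifacts, and
reference biases. Passing tests therefore demonstrate correctness of the
pipeline's logic under a clean, clock-like model - not robustness to every
property of real data. ILS in particular is absent by construction, so the
null calibration below measures the significance machinery, not the
biological false-positive rate under deep coalescent variance.

# Assembly contracts

The two-step assembly mirrors the common GBS practice of clustering a small
representative set and mapping everyone else against the result:

* `buildReferenceLoci()` single-linkage clusters the pooled unique reads of
  the representatives at identity >= `tauId` (default 0.90), discards
  clusters with summed depth < `minDepth` (default 3), and takes a
  depth-weighted per-column majority consensus (ties to the
  lexicographically smallest base, so consensus is deterministic).
* `assignToLoci()` assigns each unique read to the reference locus of
  maximal consensus identity, requiring identity >= `tauAssign` (0.90) and a
  margin >= `margin` (0.02) over the second-best hit - the margin is the
  defense against paralog cross-mapping. Within a locus, unique sequences of
  depth >= `minDepth` become allele candidates; shallower sequences are
  absorbed into the nearest candidate (error correction) or dropped; at most
  `aMax` (4) deepest alleles are kept, accommodating polyploid or
  paralog-contaminated genotypes.

Thresholds are deliberately conservative and exposed as arguments: the
upstream literature does not publish the clustering parameters of the
original pipelines, so exact locus counts from any particular study are not
reproducible by construction. The round-trip property (a clean simulation
reassembles to exactly the simulated loci with exactly the true alleles) is
tested at `tauId = 0.8`: with the default tree the deepest tip pairs
diverge ~4% in expectation, so 0.8 keeps every within-locus read pair above
the threshold with large margin while unrelated 30-bp loci sit near 25%
identity - the precondition "divergence below the threshold" then holds
with room to spare, which a 0.9 threshold does not guarantee for the
occasional deep outgroup allele.

Alignment is positional (gap-free): equal-length restriction-anchored
fragments are stacked, never gap-aligned. Reads of deviating length are the
caller's responsibility to trim first; mixed lengths are an error, not a
warning.

# Filtering and dataset construction

* **Variability** of a locus is the proportion of alignment columns with
  >= 2 distinct non-missing states. A proportion (not a raw SNP count)
  makes the rule invariant to locus length.
* **Hypervariability filter:** remove loci with
  $v > \bar v + k \cdot \mathrm{IQR}(v)$, default $k = 3$. The mean/IQR
  pairing is unusual but is applied literally as stated by the workflows
  this package follows; IQR uses R's default type-7 quantiles. Merged
  paralogs produce $v$ near 0.75 against a clean background an order of
  magnitude lower, so sensitivity is high (the acceptance checks require
  >= 90%).
* **Missingness filter:** one pass, individuals first (presence fraction
  < `thetaInd`, default 0.10, relative to the current loci), then loci
  (presence < `thetaLoc`, default 0.70, relative to the remaining
  individuals). Inequalities are strict - "fewer than 10%" keeps an
  individual at exactly 10%. There is no iteration to a fixed point; the
  locus rule is evaluated against post-step-1 individuals, which is what
  makes the dataset invariant (every retained locus present in >=
  `thetaLoc` of units) hold.
* **Levels.** `individual` keeps all individuals; `population` keeps the
  best individual per population; `taxon` builds one composite per taxon
  from its best individual, filling loci it lacks from members of the same
  population (fill-in donors ordered by their own locus counts, then id,
  so composites are deterministic). "Best" = most retained loci, ties
  broken by total reads, then lexicographically smallest id - the source
  workflows never define "best", so the package picks the measurable
  definition and documents it. After unit selection the locus-presence rule
  is re-applied to the selected units. Filters are likewise re-applied when
  a dataset is restricted to a taxon subset, matching the practice of
  building separate working alignments per subset rather than pruning a
  master alignment.
* **Representations.** `toSupermatrix()` picks one allele per unit per
  locus uniformly at random and fills missing loci with `N`;
  `toSNPMatrix()` keeps variable columns, reduces >2-state sites to two
  random states (others become missing), and codes 0/1 anchored to the
  first non-missing unit; `bootstrapLoci()` resamples loci, not sites.
  All three take a `seed` and are deterministic under it.

# The DFOIL statistics

`countSitePatterns()` processes each column of the five sequences (P1, P2,
P3, P4, outgroup): columns with any `N`/gap or more than two states are
skipped; the rest are polarized against the outgroup into one of 16
patterns. `dStat()` computes $D = (L-R)/(L+R)$ and
$\chi^2 = (L-R)^2/(L+R)$ with a 1-df upper-tail p-value; sign is 0 unless
$p \le \alpha$ (default 0.01) and $L + R = 0$ yields $D = 0$ by convention.
The left/right pattern subsets of DFO, DIL, DFI and DOL follow the
five-taxon D-statistic system of Pease & Hahn (2015); `dfoilPatterns()`
prints them. The subsets and the sign-to-category table were derived
analytically for this package from branch-length bookkeeping on a clock
tree under every donor/recipient scenario and verified by simulation before
being frozen into code and tests; they match the published definitions.

Applicability requires $t(P_1,P_2) \le t(P_3,P_4)$; `enumerateQuartets()`
enforces this, emitting every unordered pair of disjoint ingroup tip pairs
whose divergences are both strictly more recent (within tolerance
$10^{-6}$) than the divergence of the pairs from each other. Equal-depth
pair ties are kept with the lexicographically smaller pair as (P1, P2) by
default (`tiePolicy = "drop"` excludes them); published studies do not
state their convention, and published exhaustive-test totals likely depend
on it.

`mode = "dfoil_alt"` drops the four singleton-derived patterns from every
sum, for datasets whose terminal-branch signal is unreliable;
`mode = "auto"` chooses `dfoil_alt` when the smallest singleton-pattern
count falls below `primeMin` (default 10) - a transparent approximation of
the "find optimal parameters first" pre-run used by the exhaustive-test
wrappers, whose actual parameter choice is not documented.

Classification is an exact match of the four-sign vector against the table;
any unmatched vector is `ambiguous` rather than force-fitted. Terminal-pair
rows are polarized (donor -> recipient); ancestral rows are undirected - the
method cannot polarize events involving the (P1, P2) ancestor.

# The exhaustive scan and aggregation

`runScan()` runs one test per enumerated quintet against the supermatrix
(sequences are the concatenated random-allele haplotypes; columns with
missing data are skipped per test, so missingness costs sites, not tests).
`aggregateScan()` lifts unit-level calls to taxon pairs:

* A test's *callable* pairs are {P1,P3}, {P1,P4}, {P2,P3}, {P2,P4} plus the
  ancestral pseudo-pairs {anc(P1,P2), P3} and {anc(P1,P2), P4}; when P1 and
  P2 belong to the same taxon the "ancestor" is that taxon itself, which is
  how within-taxon pairs contribute cleanly to taxon-level totals. A pair's
  `nTests` counts tests where it was callable, making proportions
  comparable across pairs of unequal sampling.
* `nEvents` counts tests whose call involves the pair; `proportion =
  nEvents / nTests`; `directions` tallies polarized calls. Pairs are
  flagged at `pairReportProp` (default 0.05, the "introgression > 5%"
  reporting convention) and at `detailCount` (default 50 events, the
  "examined in detail" convention).

**Ranking by events, not proportion.** A real event between taxa A and B
also produces calls of the form anc(A, sister-of-A) x B: partially
polarized detections in tests where the statistic separating A from its
ancestor (the weakest of the four, with expectation proportional to
$t_{12} - \tau$) falls short of significance. These shadow pairs have small
callable-test denominators, so their *proportions* can exceed the true
pair's even though their *event counts* cannot, systematically. The
package therefore treats accumulated event counts as the primary ranking -
which is also the order of operations the reporting conventions above
describe (events first, detail threshold second) - and the acceptance
checks assert that the true pair is the argmax of pooled events and
exceeds the 5% proportion.

# Calibration checks and problem sizes

The test suite validates the pipeline at the emulated design scale: 13 taxa
x 2 populations x 5 individuals, 500 loci x 30 bp, population-level scans of
26 units (~4,700 tests per system). Two statistical choices deserve
explanation:

* **Null expectation.** Under the generator's clock-like null the
  expected counts of all non-singleton informative patterns vanish, so DFO
  and DIL collapse onto the same singleton contrast (P3- vs P4-derived
  singletons), as do DFI and DOL (P1 vs P2). A test therefore carries two
  effectively independent statistics, and the expected fraction of tests
  with at least one significant statistic is $1 - (1-\alpha)^2$.
* **Effective sample size.** Conditional on the 500 simulated loci the
  scan is deterministic, and tests share loci heavily; the independent
  replicates behind any scan-level fraction are the loci, not the ~4,700
  tests. The 3-standard-error band of the null-calibration check therefore
  uses $n =$ number of loci. Within-test pattern counts are also clumped
  (30 linked bp per locus), which makes the chi-square mildly
  anticonservative at small counts and inflates between-unit variance in
  per-unit false-positive proportions; the per-unit check is accordingly a
  qualitative bound (no unit dominated by false calls), not an equality.
* **Recovery pooling.** At `gamma = 0.3` the per-test chi-square sits near
  the $\alpha = 0.01$ cutoff by design of the scale, so single-system
  recovery metrics are noisy; the recovery check pools four replicate
  systems (same design, different sub-seeds) before asserting the flags,
  and measures strong-`gamma` donor polarity over all eight directed
  configurations with three replicates each.

# Degenerate inputs and numerical conventions

* Empty alignments, empty read sets, trees without branch lengths,
  non-ultrametric trees under `method = "require"`, unknown units in
  groupings, allele-length conflicts at a locus, and all-filtered matrices
  are errors with actionable messages, never silent results.
* `makeUltrametric(method = "equal_terminals")` preserves internal branch
  lengths and stretches each terminal so root-to-tip paths equalize
  (padding past the deepest internal node by the mean original terminal
  length); `method = "mean_path"` sets each node depth to its mean
  root-to-tip path and clips to monotonicity. Node depths must increase
  toward the root within a $10^{-6}$ tolerance.
* All stochastic steps consume R's RNG; orchestrators take explicit seeds
  (`simConfig(seed=)`, `toSupermatrix(seed=)`, ...) and are byte-reproducible
  under them, including FASTQ output.

# Known limitations

* No ILS in the generator: null-calibration results quantify the
  statistics' behavior under the package's model, not under deep
  coalescent discordance.
* Positional alignment only; indel-bearing loci must be handled upstream.
* The chi-square test is the cited software's convention, but with short
  linked loci it is overdispersed; block-resampling significance is out of
  scope.
* Exact locus counts of any particular published dataset are not
  reproducible because the original clustering/search parameters are
  unpublished; the package exposes its own parameters instead.
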
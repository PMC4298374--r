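---
title: "Multi-region biopsy heterogeneity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-region biopsy heterogeneity: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MultiRegionHet)
```

# The problem

Targeted sequencing of several spatially distinct core biopsies from the
same primary tumor reveals that somatic mutations in prognostic tumor
suppressor genes are often regionally restricted. Two questions follow.
First, what is the clonal structure of each tumor — which mutations are
truncal (present in every core, predating regional divergence) and which
arose on branches? Second, given the observed intratumor prevalence of each
gene's mutations, how many regions must be sampled so that a mutation, when
present, is detected with a chosen certainty? This vignette documents the
models behind each stage of the package, the parameters that matter, and
the choices made where the design was genuinely open.

# Variant filtering

Raw per-biopsy calls are filtered by four rules: consequence class
(missense, nonsense, and frameshift/inframe indels are kept; synonymous
and other classes excluded), minimum depth (default 10 reads), minimum
variant allele fraction (default 5%), and germline-SNP exclusion
(dbSNP-flagged calls are removed *only when they are single-base
substitutions* — an indel coinciding with a dbSNP record is kept, since
the germline-polymorphism argument applies to SNVs).

Numerical choices:

* Both thresholds are **inclusive**: "at least 5% of reads" retains a call
  at VAF exactly 0.05 (e.g. 1 alt read in 20), and depth exactly 10 is
  retained. VAF is computed per core; each core is an independent biopsy
  and observations of the same variant in different cores are filtered
  independently.
* Every excluded call is attributed to its **first failing rule** in the
  fixed order consequence → depth → VAF → dbSNP → (optional minimum
  alt-read count), so exclusion tallies are reproducible and
  `retained + sum(tally) = input`.
* The optional `minAltReads` knob (default 0 = off) exists because
  orthogonal validation in practice flags calls supported by very few
  reads; it is off by default because the core rules above define the
  analysis.

# Presence matrices and shared/nonshared classification

Mutation identity for cross-region collapsing is the exact variant key
(`chrom:pos:ref:alt`): identical keys in several cores collapse to one
row, while two distinct mutations of the same gene remain distinct rows —
a tumor can carry, e.g., two different *BAP1* mutations in different
cores, and these must not be merged. Gene-level positivity (any mutation
in the gene) is used for cohort frequencies, ubiquity and prevalence;
key-level identity is used for trees and mutations-per-tumor counts.

A *shared* mutation is present in every core of its tumor; *nonshared*
means absent from at least one. A single-core tumor makes every mutation
trivially shared — the definition quantifies over the sampled cores, not
the unobservable rest of the tumor. Declared regions with no surviving
calls are kept as all-zero columns: a wild-type biopsy is informative and
counts in every denominator. A gene's *ubiquity* among mutant tumors is
undefined (not zero) when no tumor carries it; the package signals an
explicit `undefinedEstimate` condition in that case so that "absent" and
"never shared" cannot be conflated.

# Clonal tree reconstruction

The model is a perfect phylogeny on binary characters: the ancestral state
is all-wild-type, each mutation is gained exactly once and never lost, and
each core is treated as a sample of a single clone. Under this model a
single rooted tree fitting all cores exists **iff** the region-sets of any
two mutations are nested or disjoint (a laminar family); the package tests
exactly this pairwise condition (`checkCompatibility`) and the test suite
cross-checks it against an exhaustive enumeration of parent assignments on
small inputs.

Construction orders region-sets by containment: all-region mutations form
the trunk, each maximal set under containment starts a branch, and every
region attaches as a leaf at the deepest node whose region-set contains it,
so the accumulated mutation set along the root-to-leaf path equals the
region's observed mutations (verified by `replayPresence` round-trips).

Deterministic tie-breaks, since the data cannot resolve them:

* Trunk (and any shared-edge) mutations are mutually unordered; they are
  carried as a set and printed in a canonical order — panel order *VHL*,
  *PBRM1*, *SETD2*, *BAP1*, *KDM5C*, then alphabetical — for reproducible
  output.
* Mutations with identical region-sets are indistinguishable by presence
  data and collapse onto one edge.
* Leaves and sibling subtrees are ordered by declared region order.

Incompatible matrices are refused with the full conflict list by default.
An opt-in `onConflict = "drop"` mode greedily removes the
fewest-regions-first conflicting mutation until laminar, reporting what it
dropped; it is opt-in because silent repair would invent a tree the data
contradict, and five-gene panel data in practice are tree-consistent.
Trees serialize to a Newick dialect whose edges carry `[&muts=...]`
comments; the writer/parser pair is part of the package because standard
Newick readers discard comments, which would break lossless round-trips.

# The binomial sampling-power model

For a gene with intratumor mutation prevalence $p$, modelling biopsies as
independent draws from a well-mixed tumor gives detection probability
$P(n) = 1 - (1-p)^n$ for $n$ biopsies, and the minimum $n$ reaching a
target certainty $t$ is $\lceil \log(1-t)/\log(1-p) \rceil$ (computed in
closed form, with a floating-point guard that steps the answer up or down
so it always agrees with a linear search; the comparison with the target
is inclusive — *reaching* 90% counts).

$p$ is estimated by pooling: the proportion of all cores with a mutation
in the gene across the patients who have at least one positive core. Two
assumptions are inherited from the sampling design: (1) biopsies are
independent and randomly placed within the tumor; (2) a patient with no
positive core does not carry the mutation, and is excluded from numerator
and denominator. A biopsy carrying two distinct mutations of the gene
counts once.

**A bias worth knowing about.** Assumption (2) makes the estimator
condition on detection: with $n$ cores per patient,
$E[\hat p] \approx p / (1 - (1-p)^n)$, which inflates $\hat p$ when
$(1-p)^n$ is non-negligible. With $n = 4$ cores the bias is ≈ 0.024 at
$p = 0.55$ and ≈ 0.019 at $p = 0.58$, but < 0.006 for $p \ge 0.70$. The
package therefore validates estimator recovery (to within 0.02) at
generating prevalences 0.95/0.75/0.70 on 2000-patient simulated cohorts,
where the conditioning bias is second-order; at lower prevalences with few
cores the estimator is *expected* to read high, which is a property of the
pooled conditional estimator itself, not of its implementation.

Percentages are reported by rounding half away from zero at the stated
precision; raw fractions are carried alongside. At $p = 0.41$,
$P(3) = 0.794621$, i.e. 80% at 5-point precision, and $t = 0.90$ requires
5 biopsies.

# The synthetic cohort generator

The generator emulates the study design the package targets: 14 tumors,
3–5 cores each (drawn uniformly), a five-gene panel, mean depth 950× with
Poisson-distributed per-site depth floored at one read.

* **Clone structure.** Each tumor draws a random hierarchical bipartition
  of its cores; subclonal mutations take their region-sets from its
  clusters, which guarantees laminarity by construction. Truncal mutations
  cover all cores. Default per-gene truncal/subclonal rates are the
  cohort-style per-patient mutation rates (64/36/21/21/29% for
  *VHL*/*PBRM1*/*SETD2*/*BAP1*/*KDM5C*) split by the observed ubiquity
  fractions (100/60/33/33/25%) — e.g. *PBRM1* truncal 0.6 × 5/14,
  subclonal 0.4 × 5/14. An optional double-mutation mode adds a second,
  distinct same-gene mutation in a disjoint cluster.
* **Read counts.** A core inside a mutation's region-set draws alt reads
  binomially with expected VAF $0.5 \times \mathrm{purity}$ — a
  heterozygous-diploid, single-clone-per-core model (clone fraction 1 for
  carried mutations). No copy-number model is applied; default purity is
  1, so the presence/absence abstraction is exact at high depth. Cores
  outside the set accrue alt reads only at the per-base error rate
  (default $10^{-3}$), and rows are emitted only when at least one alt
  read is observed, mimicking a caller's candidate list.
* **Decoys.** Germline dbSNP-flagged SNVs (VAF ≈ 0.5), synonymous calls,
  and sub-threshold artifacts (expected VAF 2%) are injected per biopsy at
  Poisson rates 0.5/0.3/0.3, each removable by exactly one filter rule, so
  filtering is exercised end to end and its exclusion tallies can be
  audited against the injected truth.

What the generator does **not** emulate — and hence what passing recovery
tests do and do not show: there is no spatial tumor-growth model, no
copy-number alteration or loss of mutations, no clone admixture within a
core (real cores are mixtures; here a core is a pure clone sample), no
depth covariates along the target regions, and decoy VAFs are stylized.
Perfect end-to-end recovery at zero noise demonstrates that the pipeline
introduces no distortion of its own; it does not certify performance on
real admixed, copy-number-altered tumors.

# Validation design and problem sizes

The test suite validates each stage against an independent route: the
filter against a hand-replayed rule table and a 12-row packaged boundary
fixture; compatibility against exhaustive parent-assignment enumeration
(≤ 4 mutations, ≤ 4 regions, 60 random cases); tree construction by exact
presence-matrix round-trips on 500 random laminar matrices (≤ 6 mutations,
≤ 5 regions) and refusal on 500 matrices with planted violations; the
closed-form detection probability against $10^5$-draw Monte-Carlo
simulation on a $p \times n$ grid (within three binomial standard errors
per point; the grid is kept to 20 points so that the familywise chance of
a > 3σ excursion under a correct implementation stays below ~5%); and the
prevalence estimator against its generating rates on 2000-patient
Bernoulli cohorts. A 14-tumor / 47-core cohort fixture is constructed in
test code to match the per-gene patient and core counts, ubiquity
fractions and topology-category counts of a real published cohort
sentence-for-sentence; the pooled prevalences printed for that cohort
(75/70/58/55%) are *not* simultaneously consistent with any integer core
counts (13/0.75 and 6/0.58 are non-integer), so power calculations take
printed prevalences directly as inputs rather than re-deriving them from
the fixture.

# Known limitations

* The perfect-phylogeny model cannot represent mutation loss (e.g. by
  copy-number deletion) or recurrent mutation; such data surface as
  compatibility conflicts rather than being forced into a tree.
* The binomial power model assumes spatially independent biopsies; real
  cores taken near one another are positively correlated, so the reported
  minimum biopsy numbers are optimistic lower bounds under clustering.
* The pooled prevalence estimator conditions on detection (see above) and
  pools across tumors, weighting patients by their core counts.
* Sub-core heterogeneity (different mutations of one gene within a single
  core) is handled by letting the user declare sub-regions as additional
  regions; the package does not deconvolve mixtures within a core.
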
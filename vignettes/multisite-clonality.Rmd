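---
title: "Multisite tumor clonality: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisite tumor clonality: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`clonemap` reconstructs the clonal architecture of a patient whose tumor has
been sequenced at several anatomical sites (multi-region biopsies or rapid
autopsy), and quantifies how badly a single biopsy misrepresents that
architecture. This vignette explains each model in the pipeline, the
parameters that matter, the numerical choices, and what the synthetic cohort
generator does and does not emulate.

## Cancer cell fractions

For a somatic variant observed with `alt` and `ref` tumor reads in a sample
of purity $P$, sitting on a segment of tumor total copy number $C$ with
germline copy number $n_C$ (2 on autosomes; sex chromosomes per sex), the
expected allele fraction if the mutation occupies $M$ of the $C$ copies is

$$E_f(M) = \frac{P\,M}{P\,C + (1-P)\,n_C}.$$

The multiplicity $\hat m$ is the $M \in \{1,\dots,C\}$ that maximizes a Beta
likelihood of the observed counts evaluated at $E_f(M)$, and the cancer cell
fraction is

$$\mathrm{CCF} = \frac{\mathrm{VAF}\,\big(n_C(1-P) + C\,P\big)}{\hat m\,P},$$

capped at 1. A mutation with CCF above the clonal threshold (default 0.87, a
mildly relaxed version of commonly used cutoffs that captures the left tail
of the CCF $\approx 1$ mode) is called clonal in that sample.

Numerical choices:

* the Beta density uses shapes `(alt + 1, ref + 1)` — the posterior under a
  uniform prior — so the density stays finite when either count is zero;
* $E_f$ is clamped to $[\epsilon, 1-\epsilon]$ with
  $\epsilon = 1/(\mathrm{depth}+2)$ before evaluation, so the candidate
  $E_f = 1$ (e.g. $M = C$ in a pure tumor) is not assigned zero density
  merely because a few reference reads exist;
* ties in the likelihood break toward the smaller multiplicity;
* variants not covered by any segment fall back to $C =$ rounded ploidy and
  are flagged; variants in homozygous deletions get no CCF.

Multiplicity is intrinsically ambiguous for subclonal mutations (a CCF-0.4
mutation on two copies has the same expected VAF as a CCF-0.8 mutation on
one); like all purity/ploidy-based CCF methods, the argmax resolves this in
favor of the nearest expected allele fraction.

A variant is *present* in a sample iff it has an observation with at least
2 alt reads; an absent record means absent. At the depths this package
targets (~600X) a 2-read floor guards against sequencing-error singletons.

## Copy-number metrics

The baseline copy number of a sample (or chromosome) is the length-weighted
median of segment total copy numbers, rounded half-up. Relative to it:
gains are segments above the genome baseline, deletions below,
amplifications require at least 7 copies and more than twice the chromosome
baseline (the two baselines are computed separately because the definitions
reference different scales), homozygous deletions are $C = 0$, and LOH
(minor-allele copy number 0 with $C \ge 1$) is tracked as an independent
flag since it co-occurs with any state. CIN summaries: wGII (unweighted mean
over chromosomes of the fraction of covered length off-baseline), %LOH
(fraction of covered genome in LOH), and LST (adjacent-segment transitions
with both flanks $\ge$ 10 Mb after discarding segments under 3 Mb — the
standard parameters from the LST literature). WGD is called when the genome
baseline reaches 3; this is a declared, configurable proxy for a dedicated
WGD caller. A copy-number event over a region is truncal for a patient when
every sample carries it, heterogeneous when only some do; samples without
coverage of the region count as no-event and are flagged.

Whether %LOH should count hemizygous losses on sex chromosomes is genuinely
open; `clonemap` counts every minor-allele-zero segment, which slightly
inflates %LOH in males.

## Clone clustering

Mutations are clustered across all of a patient's samples by their CCF
vectors, in the spirit of multi-sample Dirichlet-process tools
(PhylogicNDT, PyClone-VI) but deliberately simpler: a finite mixture of
per-sample binomial likelihoods, with the component location being the
clone's per-sample CCF vector, fitted by EM for $k = 1..k_\max$ and selected
by BIC. Read counts are represented on the CCF scale as
`round(ccf * depth)` successes out of `depth`; a mutation absent from a
sample contributes 0 successes out of the sample's median depth (absence is
evidence, weighted by how deeply the sample was sequenced). The fit is
deterministic given a seed and invariant to row order (mutations are sorted
by key internally). The rationale for the finite mixture: it is desk-scale
and deterministic, and the post-processing rules dominate the final
partition anyway.

Post-processing to a fixed point: clusters with fewer than 3 supporting
mutations are dissolved (members reassigned to the nearest surviving cluster
in Euclidean CCF space), and any two clusters whose mean CCFs differ by less
than 0.10 in *every* sample are merged, the merged mean recomputed from all
member mutations. When several pairs are eligible the closest pair merges
first, which makes the fixed point independent of processing order. Driver
variants that fall in clusters discarded later (during tree building) are
rescued into the cluster with the nearest mean CCF, ties to the lower
cluster id.

## Phylogeny, seeding, and migration

Trees are built over clone clusters under the pigeonhole principle (in every
sample, a parent's CCF must cover the sum of its children's CCFs) and the
infinite-sites assumption (each cluster has exactly one parent). The root is
the cluster clonal in every sample with the highest mean CCF; without one,
no tree is inferable (a typed error — this genuinely happens when sites
share no mutations). Remaining clusters attach, in decreasing mean-CCF
order, to the feasible parent minimizing the summed CCF gap; ties prefer the
deeper candidate, favoring chains (parsimonious mutation accrual). Clusters
with no feasible parent are removed and reported. Both constraints carry a
CCF tolerance (default 0.1) because cluster means are noisy; presence in a
site requires mean CCF at least 0.05.

Clone classes: trunk = the unbroken root path of clones clonal everywhere;
leaf = present in exactly one site; branch = the rest. For migrations, a
clone clonal (CCF above the clonal threshold — reused as the numeric
reading of "CCF approximately 1" at a destination, a declared choice) in one site but
subclonal in another must have seeded the former from the latter; the
source is the highest-CCF subclonal site, a single source per clone keeps
the migration count minimal, and a destination already explained by a
clonal descendant is skipped (the descendant carried this clone's mutations
with it). The per-site founder is the deepest clone clonal there and
present elsewhere; seeding patterns are monoclonal (one founder),
monophyletic polyclonal (founders on one ancestral chain), or polyphyletic
polyclonal (founders on parallel branches). A full migration ILP (as in
MACHINA) is out of scope; the CCF rules plus minimal-edge parsimony are
implemented.

## Heterogeneity statistics

* **Five-class taxonomy** over detected mutations of multi-sample patients:
  truncal; clonal-shared; subclonal-shared; clonal-private;
  subclonal-private — mutually exclusive and exhaustive.
* **Illusion of clonality**: for each mutation, the fraction of size-$k$
  sample subsets, among those containing the mutation, in which it is
  present and clonal in all $k$ members; computed in closed form as
  $\binom{n_C}{k} / [\binom{n}{k} - \binom{n-n_A}{k}]$ and averaged over
  mutations. Subsets from which the mutation is wholly absent are excluded
  from the denominator (an absent mutation cannot create an illusion); this
  matches the $k=1$ definition and is the declared reading for $k>1$.
* **Detection rates**: the chance a size-$k$ panel contains at least one
  carrier sample, $1 - \binom{n-a}{k}/\binom{n}{k}$.
* **Pairwise concordance**: shared over union of detected mutations.

Both subset statistics agree exactly with brute-force enumeration (the test
oracle) for any patient with up to 6 samples.

## Species-accumulation extrapolation

The expected number of distinct mutations found in $t \le n$ samples is the
exact subsampling mean $\sum_j f_j (1 - \binom{n-j}{t}/\binom{n}{t})$, where
$f_j$ counts mutations present in exactly $j$ samples. For $t > n$ two
extrapolators are available. The default is the Colwell–Mao incidence
estimator: the unseen count is the bias-corrected Chao2
$\hat f_0 = \frac{n-1}{n} f_1^2/(2 f_2)$ and discovery decays geometrically
at rate $f_1/(n\hat f_0 + f_1)$. The alternative (`method = "pade"`) is a
Good–Toulmin alternating series stabilized by a diagonal Padé approximant,
the classic abundance-data approach. The incidence estimator is the default
because multisite cohorts provide only 2–6 sampling units: the Good–Toulmin
series then has too few coefficients for a reliable rational approximation
— even with exact expected frequencies its feasible orders bracket the
truth by ±20% on a Bernoulli-presence test, whereas the incidence estimator
recovers the closed form exactly in expectation. The value at $t = 100$ is
reported as the asymptote, a lower bound on the patient's total mutation
burden; dividing the interpolated curve by it gives the fraction of the
burden detected with $k$ samples. One-step validation fits each 3-sample
subset of a patient's first four samples and compares the $t=4$ prediction
with the observed count.

## LOH overlap permutation test

Whether LOH hits the same genes in all of a patient's samples more often
than chance: per replicate and sample, LOH labels are shuffled uniformly
over segments after augmenting the label count by 20% (rounded up), and
replicates where any sample's realized LOH genome fraction drops below the
observed fraction are discarded — the augmented, filtered null is
deliberately an *upper bound* on random overlap, so significant results are
conservative. A gene is in LOH when at least 50% of its span is covered by
LOH segments (a declared threshold; gene counting alone does not define
one). The statistic is the count of genes in LOH in every sample, and the
p-value uses the add-one estimator $(1 + \#\{draws \ge obs\})/(1 + R)$, so
it is never exactly 0 (at $10^6$ replicates the smallest reportable value
is $10^{-6}$). Because the augmentation biases the null upward, p-values
under a true random-LOH model are conservative rather than uniform;
calibration of the core shuffle machinery is therefore checked with
augmentation off on equal-length segments, where the permutation null is
exact and the p-value distribution is uniform. Two pairwise overlap
readings are reported, since "fraction of LOH shared with other samples"
does not fix a denominator: base-pair (length of the query sample's LOH
inside the intersection of the others', over the query's LOH length) and
gene-level (fraction of the query's LOH genes in LOH in all others).

## The synthetic cohort generator

The generator emulates the statistical structure of a rapid-autopsy
multisite mCRPC cohort: a median of 3 sites per patient (max 6), ~590X
negative-binomial depth, purities uniform on 0.2–0.9 with lung/bone shifted
lower, 7–14 clones per patient, WGD in about half of patients (truncal in
about half of those), and LOH over a gene panel that includes recurrent
prostate-cancer drivers. Clone trees grow by random branching from a
truncal root. Sites are built sequentially: site 1 is the primary-like
lesion; each later site is founded by a seeding clone (chosen by the
configured seeding model and planted in an earlier site, which becomes the
ground-truth source). Within a site the founder and its ancestors are
clonal and descendants arise locally with Beta(1,2) stick-breaking of the
parent's residual CCF mass, so the pigeonhole constraint holds exactly by
construction. Expected allele fractions invert the CCF equation;
multiplicity 2 is drawn only for locally clonal mutations (multi-copy
mutations are early events duplicated by later gains). A record is emitted
only when the simulated alt depth reaches 2, the pipeline's own presence
rule.

Two deliberate idealizations, and what they imply for test conclusions:

* clone pairs whose CCF vectors differ by less than 0.15 in every sample
  are redrawn, because the pipeline's own 10% merge rule makes such clones
  unidentifiable in principle — recovery tests therefore measure the
  method's error on *resolvable* architectures, not the (irreducible)
  confounding of near-identical clones in real tumors;
* local subclones never sweep to fixation within a site, so clonal-private
  mutations are rarer than in real cohorts, where single-site clonal sweeps
  are common.

The generator also does not emulate mutational signatures, kataegis,
segment-level correlation between CNV and SNV placement, sample
cross-contamination, or purity-dependent calling sensitivity. Passing the
recovery tests therefore demonstrates correctness of the inference chain
under the generative assumptions, not robustness to every artifact of real
sequencing data.

## Problem sizes in the test suite

The suite favors exhaustive oracles at small sizes: brute-force multiplicity
checks on 10,000 random variants; subset statistics enumerated for patients
with up to 6 samples; tree choice enumerated over all labeled trees on 3
clusters; the permutation test enumerated on a 2-sample, 4-segment toy and
calibrated on 200 null datasets of 10^4 replicates; clustering/phylogeny
recovery on 20 simulated patients (3–5 sites, 5–12 clones, at least 10
mutations per clone, depth 600, purity at least 0.4). These sizes keep the
full suite under a few minutes while leaving every scientific claim backed
by an independent oracle.

## Known limitations

* Purity and ploidy are inputs; the package neither infers nor corrects
  them, and CCFs inherit their errors.
* Multiplicity ambiguity for subclonal variants (above) biases a minority
  of CCFs upward by integer factors.
* The clone tree is a point estimate; no topology uncertainty is reported.
* The WGD call is a baseline-ploidy proxy.
* The migration inference assumes the sampled sites include each seeding
  clone's source; unsampled intermediates appear as direct edges.
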
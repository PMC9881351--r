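---
title: "DEGnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DEGnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DEGnet)
```

DEGnet chains the stages of a small-cohort case–control biomarker screen —
differential expression, tissue-specificity filtering, interaction-network
module and hub analysis, enrichment, ceRNA assembly, diagnostic/prognostic
evaluation, and SNP association — and pairs every stage with a
planted-truth simulator. This vignette is the package's account of the
statistics it implements, the parameters that matter, and the choices made
where the design was genuinely open.

## Differential expression

The model is the standard two-group linear model per gene on log2-scale
values: `log2fc` is mean(case) − mean(control), tested with a pooled-variance
t. At 3–5 samples per group a per-gene variance estimate on 4–7 degrees of
freedom is unstable, so by default the variances are moderated
empirical-Bayes style: the pooled variances are modelled as draws from a
scaled inverse-χ² prior (d₀, s₀²), fitted by the method of moments on the
log variances (the excess spread beyond χ² sampling noise is inverted
through the trigamma function), and each gene's variance is shrunk to the
posterior mean with the t on d₀ + d df. When the observed spread is fully
explained by sampling noise the prior is degenerate: all genes share the
arithmetic mean variance and the total df is capped at the summed residual
df, so no gene can claim more information than the experiment holds. Exact
zeros are offset to 10⁻⁵ × the median variance before taking logs. The
plain pooled t (`varMethod = "none"`) and the 5th-percentile variance floor
(`"floor"`) remain selectable; the moderated default was chosen because the
plain t cannot reach the recovery rate the package's own acceptance suite
demands at the design sizes below, while moderation does — and the tests
verify the implementation against limma's empirical-Bayes fit to machine
precision.

The screen itself is `|log2fc| > 1.5` (strict — a gene at exactly 1.5 is
excluded) and `p_adj ≤ 0.05` (inclusive), with Benjamini–Hochberg
adjustment over all genes. The strict/inclusive split follows the usual
wording of such screens; the boundary tests freeze it. Duplicate gene IDs
(multi-probe genes) collapse to the probe with the highest mean before
testing. Matrices whose maximum exceeds 50 are assumed linear-scale and
log2(x+1)-transformed; anything else passes through, and the branch taken
is recorded.

## Tissue specificity

For each gene the atlas profile (linear scale) is summarized by its median
over tissues. A gene is specific when (1) the top tissue strictly exceeds
10 × that median, (2) the second-highest tissue is at most one third of the
top (inclusive at exactly one third), and (3) all tissues tied at the top
map to a single organ system. "Median" is the per-gene median across
tissues, matching how per-gene atlas profiles are read in practice. With a
zero median, rule 1 degenerates to max > 0; an all-zero profile is never
specific. Ties at the top spanning several systems are called not specific
and flagged `top_tie_across_systems`, since no single-system location
exists. The call is scale-invariant: multiplying a profile by any positive
constant changes nothing. The tissue → organ-system mapping is a
user-supplied file; a default covering nervous, haematologic/immune,
digestive, respiratory, circulatory, placenta, endocrine, genital and
others ships with the package.

## Interaction network

Edges are kept at combined score strictly above 0.4; scores above 1 are
taken to be on the 0–1000 integer dialect and divided by 1000; duplicate
edges keep the maximum score; self-loops are dropped.

Module detection follows the MCODE scheme: each vertex is weighted by the
density of the highest k-core of its closed neighbourhood times that core
number (vertices under the degree cutoff weigh 0); complexes grow outward
from the highest-weight unvisited seed, accepting neighbours whose weight
is at least seedweight × (1 − node-score-cutoff), to the depth limit;
complexes are disjoint. Defaults: node score cutoff 0.2, degree cutoff 2,
k-core 2, max depth 100, haircut on, fluff off, and modules are reported
only with ≥ 3 nodes and positive score. The module score is density × V
with the directed-style density E/(V(V−1)) — equivalently E/(V−1) — the
convention under which a 14-node/60-edge module scores 4.615, a
15-node/50-edge module 3.571 and a 9-node/28-edge module 3.5. The score of
every reported module is re-derivable from its induced subgraph and the
tests assert the identity to 1e−9.

The five hub centralities are implemented from their definitions: Degree;
local clustering coefficient (0 for degree < 2); MNC, the order of the
largest connected component of the open neighbourhood; DMNC, the edge
count of that component divided by its order to the power ε = 1.7 (the
published default of the method family — the value matters because it sets
how strongly DMNC discounts large sparse neighbourhoods); and MCC, the sum
of (|C|−1)! over maximal cliques through the node, falling back to plain
degree for nodes in no triangle (without the fallback all tree-like nodes
tie at their degree anyway via 2-cliques; the fallback makes that explicit
and matches common tooling). Maximal-clique enumeration refuses graphs
above 5000 nodes because the worst case is exponential. Rankings sort by
score descending with lexicographic tie-break; the top-k list is
tie-inclusive at rank k (default k = 14) so no tied gene is dropped by an
arbitrary ordering, and the hub consensus is the plain intersection of the
top-k sets, optionally intersected again with the tissue-specific set.

## Enrichment

Over-representation is the one-sided upper-tail hypergeometric test per
set, after intersecting each set with the analysis universe and applying
the size bounds (defaults 5–5000), with BH adjustment across tested sets.
Pre-ranked enrichment is the weighted Kolmogorov–Smirnov running sum: hits
step up by |score|^weight (normalized), misses step down by 1/(N−Nh); ES is
the most extreme deviation. The null permutes gene labels (hit positions),
matching pre-ranked practice where only the ranked list exists; NES divides
ES by the mean |null ES| of matching sign, and the permutation p uses
same-sign nulls with the +1-in-numerator-and-denominator correction, so a
single-set p can never be exactly zero. The significance gate combines
Q < 0.05 (BH over permutation p) with permutation FDR < 0.25. Degenerate
sets (empty intersection, or hitting the whole list — no misses to step
down) are refused rather than scored.

## ceRNA assembly

miRNA–gene pairs are kept when found in at least 4 of the (default 5)
prediction sources. Identifier matching is fully case-insensitive while
arm suffixes (-3p/-5p) stay significant; the first-seen spelling, with the
conventional "miR-" stem, is the canonical output form. ncRNA
interactions are filtered at CLIP support ≥ 5 (inclusive). Among circRNA
shear-site isoforms of one transcript, the winner maximizes sample count,
then score, then lexicographically smallest ID — a total order, so the
pick is deterministic. "Present in most selected predictions" is
implemented as a strict majority: an ncRNA attaches when it interacts with
more than half of some gene's consensus miRNAs; this is the one reading of
"most" that is reproducible, and it is configurable in spirit by filtering
the interaction table beforehand. The assembled network is tripartite by
construction (mRNA–miRNA and miRNA–ncRNA edges only) and the constraint is
asserted on every build.

## Biomarker evaluation

AUC is computed as the Mann–Whitney rank statistic — the probability a
random case outscores a random control, ties half-credited — and the ROC
staircase is built so its trapezoidal area equals that statistic exactly
(an identity the tests check, alongside all-pairs counting and pROC).
Higher expression is treated as case-like by default, with a per-gene
direction flag.

Prognostic evaluation splits samples at the marker median, with samples
exactly at the median assigned to the low group (a deterministic tie
rule; the conventional high/low reading of expression splits). The
Kaplan–Meier product-limit estimate is computed per group; the two-sample
log-rank statistic accumulates observed minus expected events over the
pooled distinct event times with the hypergeometric variance at each time
(ties across groups are handled by that form; no approximation toggle),
and the p-value is the χ²₁ upper tail. Degenerate splits (fewer than 2
samples on a side) are errors, not silent NA.

## SNP association

From a 2 × 3 genotype table (mm/Mm/MM per group), allele counts are
2·mm + Mm versus 2·MM + Mm, and frequencies are formatted as percentages
to one decimal, round-half-up (so 5/60 prints 8.3%). The headline ratio
statistic is the minor-allele frequency ratio cases/controls with the Katz
log-scale CI, exp(ln r ± z·√(1/a − 1/n₁ + 1/c − 1/n₂)); the complementary
major-allele line is reported the same way. This quantity is frequently
printed under the label "OR" although it is a ratio of proportions, not
the cross-product odds ratio — on the bundled reference counts the
cross-product gives 3.667 where the frequency ratio gives 3.000 — so the
package reports the frequency ratio as the headline *and* the classical
odds ratio with a Woolf CI alongside, clearly labelled. Zero minor alleles
in a group flag the result degenerate; no continuity correction is applied
silently. The allele-level test is the Pearson χ² on the 2 × 2 allele
table (closed form, df = 1). The dominant model compares carriers
(mm + Mm) against MM with a two-sided Fisher exact test as the headline,
and Pearson χ² with and without Yates correction reported alongside —
genotype-level p-values in the applied literature rarely state their test,
and on the reference counts the candidates genuinely disagree (Fisher
0.020, Yates 0.022, Pearson 0.010, 2 × 3 Pearson 0.034), so all are
surfaced rather than one forced. The minor allele defaults to the lower
pooled frequency and can be overridden per SNP.

## The synthetic-data generators

The generators define the study conditions the tests run under, and they
are deliberately simple:

- **Expression** is drawn directly on the log2 scale — gene baselines
  N(7, 1), i.i.d. Gaussian noise with SD 0.5, and the planted DEGs' case
  means shifted by 2.0 — with 5 cases vs 4 controls in the first cohort
  and 3 vs 3 in the second, the canonical tiny test-set design. 1000
  genes with 50 planted DEGs keep multiplicity realistic while the suite
  stays fast. Generating on log2 scale sidesteps any normalization
  question: only log2 values feed the downstream math.
- **Atlas** profiles are near-uniform (±20%) with planted genes given one
  dominant tissue at 100 × background, so planted genes pass both rules
  by construction and nothing else can.
- **Graphs** are Erdős–Rényi at p = 0.02 over 120 nodes with planted
  blocks (14 and 8 nodes) at within-block p = 0.9, scored so the 0.4
  filter keeps them.
- **Predictions** place each miRNA in exactly the configured number of
  sources; **survival** times are exponential with log-hazard 1.5 × the
  standardized expression of the indexed gene, and censoring is an
  independent exponential race calibrated so the expected censored
  fraction is exact; **genotypes** are Hardy–Weinberg draws per group at
  control MAF 1/12 and planted case/control frequency ratio 3 — the
  30 + 30 two-group design.

All randomness flows from one seed through fixed per-generator substreams,
so adding a generator never perturbs another's output, and identical
configurations are bit-identical. What the generators do **not** emulate:
probe-level artifacts, batch or platform effects, correlated genes,
heavy-tailed noise, linkage between SNPs, or informative censoring.
Passing recovery tests therefore demonstrates that the chain is correctly
wired and calibrated under its own assumptions — not that those rates
transfer to any particular real cohort.

## Test and simulation sizes

The suite sizes its simulations to be decisive yet quick: 20 seeds for DEG
sensitivity and null calibration (1000 genes each), 20 seeds for
dense-module recovery, 1000 genotype draws for CI coverage (the Katz
interval should cover the planted ratio 93–97% of the time; draws with
zero minor alleles are flagged degenerate and excluded since no interval
exists), 200 null rankings × 200 permutations for the enrichment type-I
check, 200 random graphs of ≤ 12 nodes for the MCC oracle identity, and
exhaustive enumeration oracles for Fisher (totals to 200), ORA (universes
to 15) and AUC (all pairs). The whole suite runs in well under a minute on
one core.

## Known limitations

- The MCODE-style growth is single-pass and disjoint-seeded; the original
  optional "fluff" post-processing is accepted as a flag but not applied.
- Pre-ranked FDR for a single set equals its permutation p; a pooled
  NES-based FDR across a large collection is not implemented beyond BH on
  the permutation p-values.
- The frequency-ratio CI relies on the log-scale normal approximation;
  at very low allele counts it is only as good as Katz's method.
- The pipeline's enrichment stage requires a user-supplied gene-set
  collection; no annotation content ships with the package.
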
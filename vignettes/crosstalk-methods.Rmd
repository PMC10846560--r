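---
title: "Methods: network propagation and disease-crosstalk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation and disease-crosstalk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cardiovascular disease (CVD) and cognitive disease (CD) co-occur far more
often than chance predicts, and oxidative stress (OS) is a common etiologic
factor linking the two — most visibly in vascular cognitive impairment.
`netcrosstalk` implements a network-medicine pipeline for finding the
proteins that mediate this crosstalk on a protein–protein interaction (PPI)
network: phenotype-specific guilt-by-association scoring, subnetwork
extraction, pairwise overlap ranking, a merged Global Network analysis with
a dual stress-included/excluded score, and pathway over-representation.
Because curated interactome snapshots are rarely redistributable, the
package also ships a synthetic-data generator with planted ground truth, so
every stage can be validated end-to-end without external downloads.

## Propagation model

All four scoring algorithms start from the seed indicator
$s_0(v) = 1$ if $v$ is a literature seed of the phenotype, else $0$, and end
with a min–max rescaling to $[0, 1]$ (a constant score vector maps to a
uniform 0.5, since ranks then carry no information).

**NetShort** shortens edges touching seeds: each edge gets weight
$w(u,v) = 1/(1 + s_0(u) + s_0(v))$, and
$\mathrm{raw}(v) = \sum_{t \in \text{seeds}, t \neq v} 1/d_w(v, t)$
with $d_w$ the weighted shortest-path distance (unreachable seeds contribute
0). Seeds are then assigned the maximum raw score so that a single-seed
phenotype does not rank its own seed last — seeds must stay top-ranked by
construction.

**NetZcore** runs $i$ synchronous rounds of neighbour averaging
$s_{k+1}(v) = \mathrm{mean}_{u \in N(v)}\, s_k(u)$ (isolated nodes keep
$s_0$) and standardizes the result against a null ensemble of $R$
degree-preserving rewired graphs scored identically:
$z(v) = (\mathrm{raw}(v) - \mu_{\text{null}}(v))/\sigma_{\text{null}}(v)$.
When $\sigma_{\text{null}} = 0$ (rigid graphs that admit no legal
double-edge swap), $z$ is set to 0 — a neutral value that avoids division
blow-ups.

**NetScore** is damped, degree-normalized message passing. Within each of
$r$ repetitions it iterates
$s_{k+1}(v) = (1-\lambda)\, s_{\text{base}}(v) + \lambda \sum_{u \in N(v)} s_k(u)/\deg(u)$
for $i$ steps; after each repetition the scores are rescaled to $[0,1]$ and
become the new baseline, letting the signal radiate one ring further per
repetition. $\lambda = 0$ reduces to the seed indicator, $\lambda = 1$ is
pure propagation.

**NetCombo**, the default prioritization, standardizes the three score
vectors to zero mean and unit variance (a zero-variance vector contributes
zeros), averages them elementwise, and rescales.

These update rules are explicit, test-friendly surrogates for the
GUILD-family algorithms of the same names: the published descriptions name
the algorithms and the seed/scaling conventions but not the exact update
equations, so this package fixes one concrete formula per algorithm and
validates each against independent oracles (exhaustive weighted
shortest-path enumeration for NetShort, hand-computed message-passing
rounds and exhaustive null ensembles for the others). They are a faithful
reimplementation of the approach, not a bit-for-bit port of the original
binaries.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `repetitions` (r) | 3 | NetScore re-basing rounds; each extends the reach of the signal |
| `iterations` (i) | 2 | message-passing steps per round (NetScore, NetZcore) |
| `damping` (lambda) | 0.5 | propagation weight versus baseline in NetScore, in [0,1] |
| `null_replicates` (R) | 100 | rewired graphs behind NetZcore's z-scores |
| `swaps_per_edge` | 10 | double-edge swaps per edge per rewiring |
| `rng_seed` | none | required; no silent default, every run is reproducible |

The propagation defaults are deliberately shallow (few iterations): PPI
modules are local structures and deeper propagation mostly diffuses signal
into hubs. `rng_seed` feeds every stochastic component through per-stage
derived seeds, so phenotype results do not depend on evaluation order.

## Subnetworks, overlap and the Global Network

A phenotype's subnetwork is its seeds, the top-scoring 2% of the network
(`fraction = 0.02`; the count is `ceiling(fraction * n)` over the full node
set, with cutoff ties broken by lexicographic protein id), and its
*linkers* — nodes outside the selection interacting with **at least two**
selected nodes. "Two" is read as $\ge 2$ rather than exactly 2, since
linkers are connectors and an exact-2 rule would arbitrarily drop
better-connected nodes. Seeds below the score cutoff are still included,
with role precedence seed > top > linker. The 2% pool counts all network
nodes (seeds are not excluded from the quota) and refers to the full node
set, not the largest component; both choices are configurable.

The overlap network of two phenotypes keeps the intersection of their node
sets; its edges default to the union of the parents' edges induced on the
intersection (so the overlap view stays connected whenever either parent
connects two shared nodes; intersection edges are available via
`edge_mode`). Each shared protein's **overlap score** is the mean of its
two parent scores, and candidate ranking excludes proteins that are seeds
in *either* parent — seeds are literature-curated, and the point of the
ranking is novelty.

The Global Network is the union of all phenotype subnetworks. Each node
carries its origin phenotypes and a category label (CVD, CD, OS and their
`&`-combinations in canonical order; multiplicity is ignored, so three CVD
parents and one CD parent still give `CVD&CD`). Centralities are normalized
degree ($\deg(v)/(n-1)$) and betweenness scaled by $2/((n-1)(n-2))$, so
values are comparable across network sizes. Central proteins are the top-5
per measure within each category group, the per-group **union** of the two
measures' lists (the two-column layout of the source analysis supports the
union reading).

The dual score takes, per protein, the maximum propagation score within
each disease category: the OS-excluded score is
$(\max_{\text{CVD}} + \max_{\text{CD}})/2$, the OS-included score averages
in the OS score, and their difference
$\delta = (\text{os} - \text{excluded})/3$ satisfies $|\delta| \le 1/3$
algebraically. Central proteins are refined to those with
$|\delta| \ge 0.1$; the comparison is **inclusive**, the weakest faithful
reading of "affected by 0.1", and the threshold is configurable. The delta
universe and the enrichment universe both default to the Global Network
node set (the analysis concerns proteins that made it into some phenotype
network); the full interactome can be supplied instead.

Interactors of the refined centrals are classified `cvd_only`, `cd_only`
or `both` by the categories in their origin; neighbours originating from
the OS network alone are reported as `os_only` rather than silently merged,
since the source analysis only tabulates CVD/CD/both.

## Enrichment

Over-representation uses the one-sided hypergeometric upper tail
$P(X \ge k)$ with Benjamini–Hochberg adjustment (via `stats::p.adjust`).
Proprietary multiple-testing schemes of web services are deliberately not
reimplemented: the scientific claim is *which* gene sets are enriched, and
BH is the transparent standard. Gene sets with fewer than 3 members in the
universe are skipped. The three enrichment settings are the refined
centrals plus their CVD-only, CD-only and shared interactors respectively,
each tested and adjusted independently.

## The synthetic study

`synthetic_crosstalk_study()` generates the validation conditions:

* a preferential-attachment interactome of **1000 proteins** (`attach_m = 2`,
  i.e. ~2000 edges) — scale-free and connected, emulating the hub structure
  of real PPI networks at a size where the full pipeline runs in seconds;
* **2 CVD + 1 CD + 1 OS modules of 40 members** each, densified by edge
  addition (never rewiring, so the scale-free backbone is preserved) to
  intra-module density 0.3 — dense enough for guilt-by-association to hold,
  sparse enough not to be a clique;
* **40% of members seeded** per phenotype — a realistic fraction of
  literature-known disease proteins within a disease module;
* module membership overlapping across categories by 10%
  (`inter_category_overlap = 0.1`), with the OS module drawing from CVD and
  CD modules alike, mirroring the empirical finding that stress-related
  proteins straddle both categories;
* **10 planted crosstalk bridges**: free proteins wired to two seeds of a
  CVD module and two seeds of a CD module, making each an eligible linker
  of both parents — the ground-truth positives for candidate recovery.

The 10% membership overlap and the seed-anchored bridge wiring were fixed
as design choices of the generator before any recovery measurement and are
not tuned.

What the generator does *not* emulate: the size of real interactomes
(~13k proteins), literature ascertainment bias in seed curation, false
positive/negative interactions, tissue specificity, and correlated module
overlap beyond the single overlap parameter. Passing the recovery tests
therefore shows the pipeline's machinery is correct and sensitive under
idealized module structure — not that any particular biological candidate
list is right.

### The recovery statistic

The headline check asks whether planted bridges surface near the top of
the candidate ranking. The literal top-candidate list of one overlap
subnetwork contains only a handful of proteins at this scale (the
intersection of two ~100-node subnetworks), so a within-list decile is not
meaningful. Instead `rank_planted_bridges()` ranks **every** non-seed
protein by the pair's overlap score (propagation scores every node, so the
mean extends to the full universe) and takes each bridge's best rank across
CVD-by-CD pairs. On the default study the bridges' median relative rank is
about 0.05 — comfortably inside the top decile of ~970 candidates — and
planted module members are enriched among each phenotype's top-2% at
$p < 10^{-30}$ (hypergeometric).

## Numerical and reproducibility choices

* All identifier orderings and tie-breaks use C-locale (`radix`)
  lexicographic sorting, so outputs are identical across locales.
* Min–max scaling of a constant vector yields 0.5 everywhere; NetZcore
  null sd of 0 yields z = 0; both degenerate cases are tested.
* Every stochastic stage derives its own 32-bit seed from the master
  `rng_seed` and a stage label, so stages can be re-run independently and
  two runs with the same configuration are byte-identical (checked down to
  file checksums in the manifest).
* TSV outputs are written with sorted rows and fixed numeric formatting
  (`%.12g`) for reproducible diffs.

## Problem sizes used in validation

The shipped test-and-validation suite runs the full pipeline on the
1000-node default study (twice, for byte-level determinism), sweeps the
NetShort oracle over all 142 connected graphs on 2–6 vertices (one per
isomorphism class, every 1- and 2-seed assignment), checks centralities and
linker detection against brute-force enumeration on hundreds of random
graphs of up to 12 nodes, and verifies hypergeometric p-values against
exhaustive draw enumeration for universes up to 25. These sizes were chosen
so each oracle is exact and the whole suite remains quick on a laptop.

## Known limitations

* The propagation update rules are standardized surrogates (see above);
  scores are comparable within this package, not with GUILD's binaries.
* Overlap candidate lists on small synthetic studies are short; the
  recovery statistic uses the full-universe ranking for that reason.
* The hypergeometric test assumes exchangeability of proteins within the
  universe; on a network-derived universe this ignores degree bias, which
  a practitioner may want to address with degree-matched nulls.
* One OS phenotype is assumed (the dual score needs exactly one
  oxidative-stress table); generalizing to several stress phenotypes would
  need a pooling rule.
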
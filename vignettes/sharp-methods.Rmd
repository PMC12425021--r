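---
title: "Network methods for hallmark-based aging drug repurposing"
author: "sharpr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network methods for hallmark-based aging drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharpr)
```

## The model

Aging is driven by a small set of interacting biological mechanisms — the
eleven hallmarks of aging (genomic instability, telomere attrition,
epigenetic alterations, loss of proteostasis, disabled macroautophagy,
deregulated nutrient sensing, mitochondrial dysfunction, cellular
senescence, stem-cell exhaustion, altered intercellular communication, and
extracellular-matrix changes). Genes annotated to a common mechanism tend
to occupy a common neighbourhood of the protein–protein interaction
network (the interactome), and the largest connected component (LCC) they
induce — the *hallmark module* — is the network representation of that
mechanism. This package asks two questions about any drug:

1. **Can it perturb a hallmark?** A drug whose protein targets sit close
   to a hallmark module, closer than degree-matched chance, is positioned
   to perturb that mechanism (*network proximity*).
2. **In which direction?** Comparing the drug's transcriptional
   perturbation signature with the aging expression signature over the
   module tells whether the drug pushes module genes *against* their
   age-associated drift (pro-longevity) or *with* it (age-accelerating).
   This is the *pAGE* statistic.

The two-step screen — proximity filter, then pAGE directionality — is what
`runSharp()` orchestrates.

## Statistics and conventions

### Module significance

For a gene set $A$, the observed LCC size is compared with the sizes
obtained for `nRandom` random gene sets of equal size and equal binned
degree distribution:

$$z = \frac{\mathrm{LCC}(A) - \mu_{\mathrm{null}}}{\sigma_{\mathrm{null}}}.$$

Degree matching uses log-spaced bins (powers of two over the degree range)
merged upward until every bin holds at least `minOccupancy = 100` nodes;
an undersized highest-degree tail merges into the bin below it, so the
occupancy floor always holds and the bins partition the node set. Samples
draw uniformly, without replacement within a sample, from each reference
gene's own bin. Reference genes stay eligible: the observed set must be a
possible draw from its own null, otherwise every $z$ acquires a bias that
grows with the reference's share of its bins (we measured a mean shift of
about $-0.17$ on a 600-node benchmark when reference genes were excluded).

A module is called significant at $z > 1.96$ and marginally significant at
$z > 1.645$. The empirical $p$-value uses $(r+1)/(n+1)$ smoothing so finite
replicate counts never report $p = 0$. When the null has zero spread
(e.g. the gene set is the whole network) $z$ is undefined and only the
empirical $p$ is reported.

### Separation

For gene sets $A$ and $B$,

$$s_{AB} = d_{AB} - \frac{d_{AA} + d_{BB}}{2},$$

with all three terms computed under the nearest-neighbour convention: each
node's distance to the closest *other* member of the relevant set. The
node itself never counts as its own nearest neighbour — in the cross term
too, so $s_{AA} = 0$ exactly and identical sets always separate by zero. A
singleton set has within-distance 0. Unreachable node–set pairs (real
interactomes carry small satellite components) are excluded from the means
and counted in the result, so runs remain auditable; when the two sets are
mutually unreachable the separation is reported as $+\infty$.

### Proximity

For a module $S$ and drug target set $T$,

$$P_{S,T} = \frac{1}{\lVert T\rVert} \sum_{t \in T} \min_{s \in S} d(s,t),$$

the mean, over targets, of the distance to the nearest module gene. Unlike
separation, a target inside the module contributes 0 — a drug that
directly hits module genes has proximity 0 by design. The measure is
deliberately asymmetric (averaged over targets, never symmetrised).
Targets absent from the network or unreachable from the module drop out of
the mean and are counted; a drug is screened only if at least one target
maps.

Significance compares $P_{S,T}$ with `nRandom` re-measurements in which
*both* $S$ and $T$ are replaced by degree-matched samples (the screening
default, `resample = "both"`). A single-sided null that keeps the module
fixed is available as `resample = "targets"`. The two answer different
questions. The double null asks "is this drug closer to the module than a
random drug is to a random gene set of the same degrees?" — for a real,
clustered module this is conservative, because scattered stand-ins for $S$
cover the network better than a localized module, shifting random drugs'
$z$ upward (about $+1.5$ on the benchmark graph). The single-sided null
asks "is this drug closer to *this* module than a random drug is?", and it
is the null under which a random drug is exactly a null draw; our
calibration experiments therefore use it (mean $z \approx 0.02$, sd
$\approx 1.02$, 2.5% tail $\approx 0.025$ over 400 simulations). Screening
keeps the double null as the default because that is the established
procedure for this class of screens.

Thresholds are fixed constants: $z < -1.96$ significant, $-1.96 \le z <
-1.645$ marginal. No multiple-testing correction is applied by default —
the thresholds are the screen's operating points, not inference claims —
but `fdrColumn = TRUE` adds a Benjamini–Hochberg column for users who want
one.

### Confidence stratification

Gene–hallmark annotations carry an evidence tier 1 (strongest) to 5
(weakest). The level-$L$ gene set of a hallmark is cumulative — all genes
with confidence $\le L$ — so the five sets are nested and level 1 is the
most stringent. Some hallmarks have no gene at the top tiers; their empty
level sets produce NA screen rows, and cross-level consistency rules
(`consistencyFilter()`) judge a drug on the levels that exist
(`"all-available"`) or on a minimum count (`"at-least-k"`). A drug
significant at every available level is the strongest evidence tier.

### pAGE

Over the module genes $G$ measured with nonzero value in both the aging
signature and the drug signature, each gene contributes
$-\operatorname{sign}(a_g)\,\operatorname{sign}(d_g)$: $+1$ when the drug
opposes the age-associated change, $-1$ when it reinforces it. pAGE is the
mean contribution, bounded in $[-1, 1]$; positive values mark beneficial
(pro-longevity) direction. The statistic reads only signs, so it is
invariant to positive rescaling of either signature; genes with value
exactly 0 carry no direction and are dropped from $G$ (a minimum-|value|
threshold is available for noisy signatures). A magnitude-weighted variant
(weights $|d_g|$, normalized to sum 1) is provided behind `weighted =
TRUE`; the unweighted form is the default because every qualitative
property required of the statistic — opposite signs increase it, same
signs decrease it, boundedness — is already delivered by the pure
sign-concordance mean, which is also the form whose sampling behaviour is
analytically transparent ($\mathbb{E}[\mathrm{pAGE}] = \rho$ under the
concordance model below).

pAGE significance permutes gene sets, not network structure: the null
draws `nRandom` uniform random gene sets of size $|G|$ from the
doubly-measured universe. Degree matching would be meaningless here —
degree is a network property, irrelevant to a transcriptome permutation.
When the module covers the whole measured universe the null degenerates
and $z$ stays NA.

Across confidence levels, a drug is classified pro-longevity only when
pAGE is positive at every level where it is defined, age-accelerating when
negative at every defined level, and inconsistent otherwise. Undefined
levels (no measured module gene) are skipped, not counted against the
drug.

When a drug has several perturbation instances (cell line, dose, exposure
time), `selectInstance()` keeps the one with the highest replicate
consistency (`distil_cc_q75`), breaking ties lexicographically on the
instance identifier for determinism.

## Numerical and degenerate-case choices

* **Distances** are unweighted BFS shortest paths (igraph); the full
  distance matrix is cached per interactome up to 4,000 nodes, beyond
  which queries fall back to per-call BFS.
* **Tie-breaks** are lexicographic everywhere a tie is possible (equal-size
  LCCs, equal `distil_cc_q75`), so all outputs are reproducible.
* **Seeds**: every stochastic routine takes a master seed that spawns one
  sub-seed per replicate, so any single replicate can be reproduced in
  isolation; RNG state is always restored on exit.
* **Empirical p**: $(r+1)/(n+1)$ smoothing throughout.
* **Degenerate nulls** (zero spread) never error mid-screen: they yield NA
  $z$ with a degeneracy flag and an `ns` classification.
* **Report rounding** in formatted outputs: proximity, pAGE and $z$ to 2
  decimals, percentages to 1 decimal. Tables on disk keep full precision.

## The synthetic benchmark and what it shows

`synthSpec()` defaults define the standing benchmark: a 2,000-node
background graph from a static power-law fitness model (exponent 2.5, mean
degree 8) — heavy-tailed like a real interactome, so the degree-binned
nulls are exercised meaningfully — with a 20-gene module wired at internal
density 0.6 (comfortably above the $2\ln(\mathrm{size})/\mathrm{size}$
connectivity threshold, so the module's own LCC covers essentially all of
it), drugs of 8 targets planted at hop distance 0/1/2 or placed uniformly
at random, and signature pairs whose drug signs oppose the aging signs on
module genes with probability $(1+\rho)/2$, making the expected pAGE
exactly $\rho$. A literal stub-matching configuration model is not
simple-graph-safe without rejection loops; the fitness model fixes the
edge count (hence the mean degree) and reproduces the heavy tail, which is
what the nulls care about. Degree-0 vertices are removed — an interactome
never carries isolated proteins, and an edge-list file could not represent
them anyway.

Under these conditions the test suite verifies: exact agreement of
proximity and separation with an exhaustive BFS oracle on 100 random
graphs; null calibration (mean $z$ within $\pm 0.15$, sd in $[0.8, 1.2]$,
2.5% tail within $[0.01, 0.04]$ over 400 simulations at 500 replicates);
planted-module detection in $\ge 95\%$ of 50 runs at 1,000 replicates;
hop-0 drug detection in $\ge 90\%$ of runs with $\le 5\%$ false alarms on
random drugs; pAGE recovery of $\rho \in \{-0.8, \ldots, 0.8\}$ within
$\pm 0.1$ over 200 replicates at $|G| = 50$; and byte-identical pipeline
outputs under a fixed seed. These sizes are the package's benchmark
choices; they are small enough to run routinely and large enough that the
binned nulls, the heavy tail and the planted structure all matter.

What the generator does *not* emulate: community structure beyond the
planted modules, correlated annotation errors, gene-symbol aliasing
(identifiers are case-sensitive exact strings; mapping is upstream work),
dosage or time-course structure in signatures, and tissue specificity.
Passing tests therefore demonstrate that the machinery is correct and
calibrated on networks with realistic degree structure — not that any
particular real-data screen is biologically right.

## Known limitations

* Proximity and separation treat the interactome as unweighted and
  undirected; evidence quality and interaction direction are ignored.
* The raw-$z$ thresholds are operating points without multiplicity
  control; at genome scale the marginal tier especially should be read as
  a screen, not a discovery claim.
* pAGE ignores magnitudes by default and cannot express dose dependence,
  non-linear response, or tissue-divergent effects.
* The analysis does not restrict to the interactome's largest connected
  component by default (`restrictLCC` exists for users who want it);
  unreachable distances are excluded-and-counted rather than imputed.
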
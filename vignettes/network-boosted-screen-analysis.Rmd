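---
title: "Network-boosted analysis of RNAi modifier screens: methods"
author: "polyqscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-boosted analysis of RNAi modifier screens: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqscreen)
```

## The problem

Expanded polyglutamine (polyQ) tracts in huntingtin impair the function of
neurons long before those neurons die. In *C. elegans*, disease-length
(128Q) huntingtin fragments expressed in touch receptor neurons nearly
abolish the animals' response to a light touch at the tail, giving a
behavioural readout of early neuronal dysfunction. Knocking down a gene by
RNAi and re-measuring touch response asks whether that gene modifies the
dysfunction: knockdowns that improve the response point at genes whose
activity contributes to pathogenesis (candidate inhibition targets), and
knockdowns that worsen it point at protective genes.

`polyqscreen` implements the full quantitative analysis of such a screen:
scoring, hit calling, gene-set enrichment, spectral smoothing of the score
signal over a functional gene network, module detection, and intersection
with dysregulation data from mouse models of Huntington's disease. Because
raw screens of this kind are rarely deposited, the package includes seeded
generators that emulate every input, so the whole chain is testable end to
end.

## Scoring and hit calling

Each animal receives `touches` (default 5) light touches; responding to 4
of 5 is 80% responsiveness. A clone's responsiveness is the mean over its
70–90 assayed animals, and its score for change in touch response is

$$ S = \frac{\text{percent response} - \text{mean baseline}}{\text{mean baseline}}, $$

where the baseline is the responsiveness of empty-vector control animals.
S is $-1$ at complete loss of touch response, $0$ at baseline, and positive
when knockdown improves the response ("suppressor" sense). With a 20.6%
baseline the upper bound of S is $(100 - 20.6)/20.6 \approx 3.85$. (Screen
write-ups sometimes quote a slightly different attainable maximum implying
a different baseline; the package always evaluates the formula as written
and never hard-codes the bound.)

Baselines are tracked per monthly batch, with a `"cumulated"` row as
fallback; the cumulated baseline in the emulated screen is stable at
20.6% ± 3%. A clone is called a hit only when the whole interval
$S \pm \mathrm{SD}(S)$ clears the baseline band $\pm 2.6$ baseline-SDs:

* suppressor: $S - \mathrm{SD} > 2.6\,\sigma_b$,
* enhancer: $S + \mathrm{SD} < -2.6\,\sigma_b$,
* anything else (including the exact band edge): no effect.

Two unit choices here were genuinely open and are documented as package
decisions. First, the baseline SD is converted to S units as
$\sigma_b = \text{sd percent}/\text{mean percent}$, so the band is applied
around 0 on the S scale. Second, $\mathrm{SD}(S)$ is the standard deviation
of per-animal S values; with 5 touches these are discrete (steps of 20% in
percent units) and no smoothing is applied. This interval reading is
deliberately conservative: the per-animal SD at these baselines is large
(≈ 0.9 S units), so only strong effects are called, and a null screen of
2000 clones produces essentially no false positives (the test suite checks
< 2%). Clones showing lethality, larval arrest, egg-laying defects,
developmental delay, or morphological/other abnormalities are excluded
before scoring and never re-enter the analysis; the first flag in that
canonical order is the recorded exclusion reason. Confirmation against a
secondary screen is same-sign agreement of hit calls (`confirm_hits()`),
the minimal rule consistent with a two-pass screen design.

## Gene-set enrichment

Enrichment of suppressor/enhancer lists (and of detected modules) is the
upper-tail hypergeometric test: with a universe of $N$ scored genes, a set
of $K$, a query of $n$ and overlap $k$, `hypergeom_upper_tail()` returns
$P[X \ge k]$. Raw p-values are reported by default — matching the
convention of screen pathway tables — with Benjamini–Hochberg q-values
behind `adjust = TRUE`. The default universe is every gene assayed and
scored (toxicity-excluded genes are out); genes with several clones count
once, and the minimum reported overlap defaults to 1 because single-gene
pathway hits are legitimate in small pathway collections. Gene Ontology
annotations can be closed under the true-path rule with
`propagate_ontology()` (memoised DFS over the `is_a` DAG, cycle detection),
and `category_counts()` reproduces the "most frequent categories covering
at least 18 genes" style of GO reporting.

## Spectral smoothing of the S signal

The S-scores of all scored genes are treated as a signal on a weighted
functional gene network (WormNet-style edge list). For each connected
component the graph Laplacian is diagonalised; eigenvectors play the role
of Fourier modes and eigenvalues of frequencies. The signal is projected
onto this basis (`graph_fourier()`), and `attenuation_series()` removes the
globally highest-frequency 2.5% of non-constant components per level, over
40 levels, reconstructing a progressively smoothed signal each time. The
rationale: densely interconnected genes in the same pathway should move
together, so high-frequency structure is mostly off-pathway noise.

Numerical conventions, each chosen once and flag-switchable:

* **Operator.** `spectral_basis()` defaults to the combinatorial Laplacian
  $L = D - W$, whose constant null vector makes filtering preserve
  per-component means and flatten each component to its mean at the final
  level. The *pipeline* (and `pipeline_config()`) defaults instead to the
  symmetric normalised Laplacian $D^{-1/2} L D^{-1/2}$. The reason is
  empirical and structural: with $L = D - W$, weakly weighted background
  edges produce small eigenvalues, so background noise is removed *last*
  and planted modules are engulfed by noise before they separate —
  planted-module recovery on the synthetic benchmark fails. Normalising by
  degree puts local disagreement at high frequency regardless of degree,
  and recovery then succeeds at every seed tried. Both operators are
  exposed; tests cover both.
* **Weights.** Edge confidences are scaled by the network-wide maximum
  (range (0, 1]) before building the operator. A min–max rescaling to
  [0, 1] is *not* used here because it maps the weakest edge to exactly 0,
  which can spectrally split a connected component; min–max normalisation
  is used where it belongs, in the confidence-graph export for display
  (`export_module_graph()`).
* **Ranking.** Frequencies are pooled across components and ranked by
  eigenvalue, ties broken by (component id, within-component index), so
  "2.5% per level" is a global fraction of the $m - c$ non-constant
  components and level $k$ removes $\lfloor k \cdot 0.025 \,(m-c)\rfloor$
  of them. Constant components are never removed.
* **Singletons.** Scored genes absent from the network are kept as
  singleton components: smoothing cannot change them and they can never
  seed a multi-gene module, but downstream gene lists stay complete.
* **Scale.** Components are diagonalised densely; this is intended for
  desk-scale networks (≤ a few thousand nodes per component; a warning is
  emitted beyond a configurable size).

The round-trip, Parseval, mean-preservation and Dirichlet-energy
(monotone non-increase of $x^\top L x$ in the matching operator) properties
are enforced by the test suite at tolerances of 1e-8/1e-9.

## Module detection

Given the attenuation series, candidate modules at a level are connected
subgraphs (size ≥ 2) of genes whose smoothed signal is strictly above
$\mu + \sigma$ (suppressor-like, "positive") or strictly below
$\mu - \sigma$ (enhancer-like, "negative"). $\mu$ and $\sigma$ are computed
once from the raw (level-0) signal and held fixed across levels — the
smoothed signal shrinks towards component means, so a fixed threshold makes
survival across levels informative; recomputing per level
(`threshold_per_level = TRUE`) keeps a constant fraction of genes above
threshold and weakens the filter. Modules must be born at level ≥ 4 and
keep at least 40% of their genes above threshold (inclusive: exactly 40%
passes) at each of ≥ 2 successive levels; "after the 4th attenuation" is
read as level ≥ 4. Redundant modules (Jaccard ≥ 0.8 by default) are
resolved in favour of the longer stability run, then earlier birth, then
larger size, then lexicographic order, making the output deterministic.
Surviving modules are annotated by hypergeometric enrichment against any
number of collections (pathways, druggable genes, htt partners, autophagy /
mitochondrial / synaptic gene lists, …) and exported as min–max-normalised
confidence graphs.

## Cross-species intersection

Worm modifier genes are mapped to mouse orthologs (many-to-many expansion;
counting at the mouse-gene level, since the overlap figures of interest
count mouse-side genes), then intersected with two striatal dysregulation
tables — emulating knock-in (CHL2-like) and transgenic (R6/2-like) HD mouse
models. The report classifies each conserved, dysregulated gene as
dysregulated in one model, both concordantly, or both oppositely, and
`prioritize()` implements the default target-selection rule: suppressor in
the worm *and* up-regulated in at least one mouse model, i.e. genes whose
inhibition is a candidate neuroprotective strategy. Direction is treated as
categorical (up/down); fold changes are out of scope.

## The synthetic generators

`synthetic_truth()` fixes the emulated study conditions:

| parameter | default | meaning |
|---|---|---|
| baseline | 20.6% ± 3% | empty-vector touch responsiveness |
| touches, animals | 5, 70–90 | per-animal assay geometry |
| n_genes | 500 | scored genes / network nodes |
| planted modules | 3 × 10 genes | alternating suppressor/enhancer sense |
| effect size | ±2σ | σ = baseline SD on the S scale (3/20.6) |
| p_in, p_out | 0.6, 0.01 | planted-partition edge probabilities |
| weights | U(0.5, 1] in-module, U(0, 0.5] background | confidence weights |

Background genes draw their true responsiveness from
Normal(20.6, 3) truncated to [1, 99], so the background S noise SD equals
σ and planted shifts are expressed in units of that noise. Per-animal
responses are Binomial(5, p) — beta-binomial overdispersion is available
for robustness testing — and control wells add well-to-well spread in true
responsiveness so the empirical baseline SD matches the configured 3% on
top of binomial error (~2% at 80 animals). Batch baselines exercise the
per-month baseline path. All generators are pure functions of
(parameters, seed).

What the generators deliberately do **not** emulate: the topology of a real
integrated gene network (hubs, degree heterogeneity, overlapping pathways),
off-target RNAi effects, batch drift in baselines, and mechanistic
toxicity (flags are assigned at random on request, not modelled). Passing
the planted-recovery benchmark therefore shows the chain is correct and
well-calibrated for clean planted structure, not that it would recover the
published module counts from the real network and screen — those depend on
undeposited raw data.

## Problem sizes used in the tests

The shipped tests run the screen model on up to 2000 simulated clones
(null false-positive rate), spectral properties on 100 random graphs of up
to 200 nodes, and the end-to-end recovery benchmark on the default
500-gene / 3-module conditions, recovering ≥ 2 of 3 planted modules at
Jaccard ≥ 0.5 against truth. These sizes were chosen as representative
desk-scale problems; all fixtures are generated in code at run time.

## Known limitations

* Dense eigendecomposition limits networks to a few thousand nodes per
  component; no Chebyshev/approximate filtering is provided.
* The hit-calling rule is conservative by construction; subtle modifiers
  are expected to surface through the network-smoothed modules rather than
  the per-clone hit list.
* Enrichment uses the classical term-independent hypergeometric test; no
  parent–child or topology-weighted GO algorithms.
* Orthology confidence and expression fold-changes are not modelled in the
  cross-species stage.
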
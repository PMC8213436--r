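---
title: "Methods: integrative network-pharmacology screening with herbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative network-pharmacology screening with herbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## Overview

herbnet implements the analysis backbone of integrative pharmacology for
multi-herb preparations: it connects what is *in* a preparation (annotated
mass-spectrometry features), what the preparation *does* transcriptionally
(differential expression and treatment-reversal of a disease signature),
and *through which proteins* it may act (topological screening of a
compound–target–disease network), ending in key-constituent selection and
pathway over-representation. Every stage is a plain function over tibbles,
every screening threshold lives in one configuration object, and seeded
generators plant ground truth for each stage so the whole chain is testable
offline.

This vignette explains each model and the choices behind it. It states no
empirical result that the package's tests do not themselves compute.

## Compound annotation by exact mass

A molecular formula is parsed into element counts and summed over
monoisotopic (most-abundant-isotope) atomic masses; the bundled mass table
(`element_masses()`) covers C, H, N, O, P, S, Na, K and Cl. Observed ions
are explained by electrospray adduct rules of the form

$$ m/z = k\,M + \delta, $$

with multiplicity $k \in \{1, 2\}$ and $\delta$ assembled from proton, atom
and electron masses: `[M+H]+`, `[M+K]+`, `[M+Na]+`, `[2M+H]+` and `[M-e]+`
in positive mode; `[M+COOH]-`, `[M-H]-` and `[2M-H]-` in negative mode.
Two conventions needed a decision, because the rule names alone do not fix
them: `[M-e]+` is implemented literally as loss of one electron
(0.000549 Da), and `[M+COOH]-` as addition of the formate anion CHO$_2^-$
(44.998203 Da), the standard formate-adduct convention in negative ESI.
All ions are treated as singly charged; isotope patterns and multiple
charging are out of scope.

A feature matches a library compound when the absolute mass error is
within **5 mDa or 10 ppm** — a *disjunction*, inclusive at both bounds,
which is the permissive reading of the combined tolerance used by vendor
annotation software: the mDa bound governs light ions (where 5 mDa is many
ppm) and the ppm bound heavy ones. All candidate matches are retained and
sorted by absolute error with the compound name as a deterministic
tie-break; the package never auto-picks a winner, because formula-level
matching cannot distinguish isomers. Retention time is carried through but
never used for matching.

Fragment ions are explained by neutral-loss arithmetic: the search
enumerates multisets of losses (by default at most 4 losses in total, each
used at most 3 times — enough for the di- and tri-glycosides this tooling
targets while keeping the search exact and fast) and keeps the multiset
whose summed mass best explains the precursor-minus-fragment difference
within the same tolerance. The bundled loss table holds the rhamnose
residue (C$_6$H$_{10}$O$_4$, 146.0579 Da), the glucose residue
(C$_6$H$_{10}$O$_5$, 162.0528 Da), H$_2$O, CO$_2$, C$_4$H$_7$,
C$_4$H$_8$O$_4$ and C$_3$H$_6$O$_3$. Two literature anchor compounds are
wired into every generated library and the test suite: the flavonoid
glycoside C$_{39}$H$_{50}$O$_{19}$, whose protonated ion (823.3019
computed) and −rha / −2rha fragments reproduce reported values within
0.5 mDa, and the saponin C$_{47}$H$_{76}$O$_{18}$, whose deprotonated ion
and −2Glc fragment behave likewise.

## Differential expression and counter-regulation

Counts are normalized to counts-per-million and log2-transformed
(`log2(CPM + 1)`). For a contrast, the per-gene log2 fold change is the
difference of group means on that scale, and the p-value comes from a
two-sided Welch t-test per gene. A gene is *flagged* when
$|\log_2 \mathrm{FC}| \ge 1$ (fold change of at least 2, inclusive) and
$p < 0.05$, with no multiple-testing correction — this mirrors the
screening convention of the transcriptome analyses this package emulates,
where the DEG call is a pre-filter for network construction rather than an
inferential endpoint; `bh_adjust()` is exported for users who want FDR
control. The test is deliberately minimal and pluggable (the `test`
argument of `call_degs()` accepts any row-wise p-value function):
dedicated count-model engines estimate dispersion by shrinkage and would
be preferred for real inference, but a location test on log-CPM is
transparent, dependency-light, and demonstrably well calibrated on the
generator's negative-binomial nulls (its type-I error at $p<0.05$ sits
within 2 binomial SE of 0.05 in the test suite). Note one consequence of
the conjunctive flag: under the null at moderate dispersion, significant
genes rarely also clear the fold-change bar, so the *flagged* null
fraction is below the nominal 0.05 — the calibration property belongs to
the p-value, not the flag.

A gene is **counter-regulated** when it is flagged in both contrasts with
opposite directions — induced by the disease stimulus (TNF vs control) and
reversed by treatment (TNF+treatment vs TNF), or vice versa. This
treatment-reverses-disease signature is the gene set carried into the
network stage.

## Network construction and two-stage hub extraction

The interaction network's nodes are the union of three gene collections —
the anti-inflammatory (counter-regulated) genes, the predicted constituent
targets, and the disease genes — with possibly overlapping role tags; its
edges are the supplied PPI edges restricted to that union, after dropping
self-loops and duplicates. Compound nodes are *not* part of this gene
network by default (the screened object is a protein–protein network;
constituent–gene links live in the selection stage's bipartite table), but
`include_constituent_edges = TRUE` admits them for exploratory use.

Centralities are exact: degree; raw (unnormalized) betweenness by
all-pairs shortest-path counting; closeness as $(n_c - 1) / \sum d$
restricted to each node's component of size $n_c$, with isolated nodes at
0. The hub screen keeps nodes with

* degree $\ge 2 \times$ median degree, and
* betweenness $\ge$ median betweenness, and
* closeness $\ge$ median closeness,

all medians over the current network, all comparisons inclusive (the
"two-fold or more" reading; strictness is not dictated by the rule's usual
phrasing, and the inclusive form keeps boundary nodes). Because the rule
only compares ranks against medians, any positive rescaling of
betweenness or closeness — i.e. any normalization convention — leaves the
selection unchanged; the tests assert this. Extraction is two-stage:
stage 1 screens the full network into a *core* set; stage 2 rebuilds the
PPI network induced on the core, recomputes centralities and medians on
that smaller network only, and screens again into the *hub* set. Densities
use the ordered-pair convention $E / (N(N-1))$ — the convention is
verified in tests against the two reported reference densities (2,251
nodes / 53,254 edges → 0.011; 566 / 23,558 → 0.074), which are consistent
with it and inconsistent with the unordered form. Screening should
concentrate the network, so stage-2 density is checked against stage-1
and a warning (not an error) is raised if it does not increase; a core of
fewer than 2 nodes skips stage 2 with an empty hub set.

## Constituent filtering and dual-median selection

Constituent–target predictions arrive with a structural-similarity score
and a QED drug-likeness score, both in [0, 1]; rows are kept when
similarity $\ge 0.80$ and QED $\ge 0.49$ (inclusive — predictions strictly
below 0.49 are what gets discarded). Whether the similarity cut should
apply per prediction row or per constituent aggregate is unstated in the
screening convention this mirrors; it is applied per row, the stricter and
simpler reading. Each constituent's **hub-target frequency** is the number
of *distinct* hub genes among its filtered targets, with zero-frequency
constituents retained so that medians are taken over the full panel.
**Content** is operationalized as the compound's MS response from the
annotated feature table — the only abundance proxy available without
authentic standards — and the column is configurable. A constituent is a
*key constituent* when frequency and content both **strictly** exceed the
respective medians ("higher than" is read strictly; the all-identical
panel therefore selects nothing, and at most $\lceil n/2 \rceil$
constituents can ever be selected). The rule is rank-based, hence
invariant under any increasing transform of content. The report includes
a per-herb roll-up of the selected constituents.

## Enrichment

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ for overlap $k$ between the query and a set of size $K$ in a
universe of $N$, with Benjamini–Hochberg control across the tested sets
and a top-30 export by default. This is a deliberate substitution for
web-service enrichment tools: their EASE-style score adjustments and
curated backgrounds are not replicated; the universe defaults to the union
of collection genes unless declared. Gene sets are read and written in
GMT. Functional-module groupings of pathways, where needed, are a static
label map applied after enrichment, never computed.

## The synthetic-data generators

The generators emit every pipeline input with planted ground truth, and
their defaults *are* the study conditions the package emulates: three
biological replicates per group over three groups (control, stimulus,
stimulus+treatment); negative-binomial counts with dispersion 0.05 and
log-normal baseline means (meanlog $\log 200$, sdlog 1, floored at 5);
planted effects of $|\log_2\mathrm{FC}| = 2$ (the screening threshold's
boundary times two); 1 mDa Gaussian m/z noise on features. Sizes default
to one fifth of the emulated study's bookkeeping (59 compounds, 75/43
disease-contrast DEGs with a 9-gene counter-regulated subset, a 27-node
hub tier, 10 key constituents) so the default suite runs in seconds, and
`full_scale = TRUE` restores the full printed sizes (293 compounds,
376/217 DEGs with a 45-gene counter-regulated subset, a 135-node hub tier,
48 key constituents). Each generator draws from its own RNG stream derived
from the master seed, so generators can be added or re-run without
perturbing one another, and all outputs are pure functions of the config.

Planted structure is deterministic in *position* and random in *value*:

* **Features** are true adduct m/z plus Gaussian noise; formulas come from
  a CHO grammar with an identifiability guard (no accepted mass within
  20 mDa of another accepted mass or of its double/half), so the noiseless
  limit re-annotates every feature uniquely.
* **Counts** place the counter-regulated genes on network periphery ids so
  the transcriptome and network stages share a namespace, emulating that
  disease-relevant transcripts appear in the interaction network; disease
  effects persist under treatment except for the counter-regulated subset,
  which reverts to baseline.
* **The network** has two planted tiers above a sparse Erdős–Rényi
  periphery (mean degree 1): a hub-tier clique wired to every node, and a
  middle tier wired to all hubs plus enough random periphery nodes to pass
  the stage-1 screen but fail stage 2 (the wiring count is derived
  self-consistently from the tier sizes, accounting for the back-degree
  those links add to the periphery). This makes two-stage extraction
  recover exactly the hub tier, and makes stage-2 density exceed stage-1
  by construction.
* **The target map** gives every background constituent exactly one
  hub-gene link at filter-passing scores (plus non-hub links at mixed
  scores, so the similarity/QED filter has work to do without touching
  frequencies), while key constituents bind 80% of the hub tier; key
  contents are drawn from a range strictly above the capped background
  response, so the dual-median rule recovers exactly the planted block.
* **Gene sets** are uniform draws plus one set containing most of the hub
  tier.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: mass spectra have no isotope patterns, co-elution,
in-source fragmentation or intensity-dependent mass error; counts have no
outlier samples, batch effects or gene–gene correlation; the PPI topology
is far cleaner than curated interactomes, whose hubs are degree-skewed but
not planted; and similarity/QED scores are independent draws rather than
products of real structure. Recovery rates on this synthetic family are
upper bounds on real-data behavior, not estimates of it.

## Numerical choices and degenerate inputs

* Mass constants: IUPAC monoisotopic masses, proton 1.007276466621 Da,
  electron 0.000548579909 Da, kept in a single audited table.
* Tolerance bounds are inclusive; fragment search caps (4 losses, 3 per
  loss) are configurable and logged in results.
* Welch t on a gene with zero variance in both groups returns p = 1
  (untestable, never flagged).
* Ties at a median: inclusive for the hub screen (a node exactly at
  2× median degree is kept), strict for key-constituent selection
  (a constituent exactly at a median is dropped) — each follows the
  wording of its rule.
* Empty or degenerate cases return empty results with warnings, not
  errors, wherever the pipeline can meaningfully continue (empty library,
  edgeless network, core < 2 nodes); schema violations and impossible
  configurations fail fast with named locations.
* Problem sizes in the shipped tests: the default 1/5-scale configs
  throughout; the full-scale generator only where the 48-constituent
  selection is asserted; the centrality oracle on 200 random graphs of at
  most 12 nodes, where exhaustive enumeration is exact and cheap.

## Limitations

The DEG engine is a screening tool, not a shrinkage-based count model;
identifications are formula-level only; the hub rule is a heuristic screen
whose output depends on the supplied PPI's completeness; enrichment
results inherit the arbitrariness of the chosen universe; and none of the
printed dataset-dependent totals of the emulated study (e.g. numbers of
identified compounds or DEGs from proprietary libraries and databases) are
reproduced here — only the rules that produced them are.
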
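---
title: "Fragment-count QSPR models of sensor sensitivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-count QSPR models of sensor sensitivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfpls)
```

## The model

`smfpls` relates the structure of an ionophore to the potentiometric
sensitivity (mV per decade of activity) of the membrane sensor built from
it. The model is deliberately plain: a linear regression of sensitivity on
counts of structural fragments,

$$y_i = b_0 + \sum_f b_f \, x_{if} + \varepsilon_i,$$

where $x_{if}$ counts how often fragment $f$ occurs in molecule $i$. The
chemistry enters entirely through the descriptor definition, and the
statistics entirely through how $b$ is estimated from a small, wide matrix.

### Fragments

A molecule is a hydrogen-suppressed labelled graph: atoms carry an element
symbol and formal charge, bonds an order 1–3. Aromatic input is kekulized
once at parse time (via OpenBabel), so fragments are always written over
localized single/double bonds — fragment strings like `C=C-C=C-C=N` denote
Kekulé alternation, and the same SMILES always produces the same
kekulization. A fragment is the atom/bond sequence along a *shortest* path
between two atoms, between 2 and 9 atoms long; every distinct shortest path
between every unordered atom pair contributes one count. Counting all tied
shortest paths (benzene's three antipodal pairs each have two) keeps the
counts invariant under atom relabelling — a property the test suite checks
against a brute-force path enumerator. Strings are canonicalized to the
byte-wise smaller of the two reading directions, so each path is one
vocabulary entry regardless of orientation. Hydrogens are never path atoms,
and charges, while retained on the graph, are not printed in fragment
symbols; both conventions match how such fragments are usually reported.
Bond symbols can be dropped (`bonds_in_string = FALSE`) for an atom-sequence
variant, off by default.

Distances and shortest-path enumeration are delegated to igraph; the
enumeration layer on top (windowing by path length, bond-symbol
interleaving, canonicalization, counting) is the package's own.

### Regression

The descriptor matrix is far wider than it is tall (hundreds to a thousand
fragments for tens of molecules), so coefficients are estimated by PLS1
(NIPALS). Design choices that matter:

* **Autoscaling.** Descriptor columns are centred and scaled to unit
  variance; the response is centred. The pruning threshold below is defined
  on these *weighted* coefficients, which makes one threshold meaningful
  across fragments of very different prevalence. Columns constant across the
  training set are dropped before scaling.
* **Latent-variable count.** Chosen by leave-one-out cross-validation —
  appropriate for corpora of a few dozen samples — minimising RMSECV with
  ties resolved to the smaller count. Centring, scaling and constant-column
  dropping are recomputed inside every fold; nothing from the held-out row
  touches the fold model. `max_lv` defaults to 10; for larger synthetic
  corpora (100 samples) the studies below raise it to 15 so the CV optimum
  is interior.
* **Numerics.** The LOO loop runs NIPALS against the full matrix with
  zero-padded residual vectors instead of rebuilding each fold's matrix;
  this is algebraically identical (scores and residuals are fold-centred, so
  all centring terms cancel) and is verified in the tests against an
  explicit per-fold refit to 1e-8. Rank exhaustion inside a fold truncates
  the component path; in a direct fit it is an error. At full rank PLS1
  reproduces ordinary least squares, which the tests use as an oracle, with
  mixOmics as an independent cross-implementation check.
* **Metrics.** RMSE is `sqrt(mean((y - ŷ)²))`; $R^2$ is the squared Pearson
  correlation between measured and predicted (the `r2_ss`
  $1 - SS_{res}/SS_{tot}$ variant is also stored); the slope is from the
  least-squares line of predicted on measured, the convention of
  measured-vs-predicted calibration plots. Constant responses make $R^2$
  and slope undefined and raise an error.

### Descriptor pruning and importance

After the first fit, descriptors with weighted coefficients inside ±0.05 are
removed in a single pass and the model is refit on the reduced vocabulary,
with the latent-variable count re-selected by LOO (an iterative mode exists
behind `iterate = TRUE`, off by default, since a single elimination is the
canonical procedure). The threshold default of 0.05 is the conventional
cut on weighted-coefficient plots. Re-selecting the LV count after pruning
is a choice — the alternative (keeping the pre-prune count) is not exposed
because the reduced matrix usually supports a different optimum.

The importance report ranks surviving fragments by |weighted coefficient|,
keeps those present in at least `min_support = 5` training molecules (rarer
fragments correlate by accident), and tags the sign of the contribution.
With `collapse_nested = TRUE`, a fragment that extends a reported fragment
only by terminal carbon atoms is suppressed when the two coefficients agree
within a relative tolerance (`nested_tol = 0.2`, a judgement call: "similar
contribution" has no standard definition); this declutters reports where a
hydrocarbon-elongated variant merely echoes its core fragment.

### Prediction and applicability

New molecules are described against the pruned vocabulary only: unknown
fragments are ignored, missing ones count zero. Each prediction carries a
coverage figure — the fraction of the molecule's distinct fragments found in
the vocabulary. Coverage below 0.5 triggers a warning but never alters the
prediction; it is a cheap applicability-domain heuristic, not part of the
model. A molecule sharing nothing with the vocabulary predicts at the
intercept.

Models serialize to JSON with 17 significant digits, which round-trips
doubles exactly: two identical training runs yield byte-identical files, and
a restored model predicts identically to the original. The file carries the
vocabulary, scaling vectors, both coefficient forms, metrics, the importance
table, the configuration and an MD5 digest of the training input.

## The synthetic corpus

Real training corpora for this problem are transcribed from heterogeneous
literature and are not redistributable, so the package carries a generator
that emulates the *structure* of the problem — a fragment-additive linear
law over small organic molecules — without mimicking any particular
chemistry.

Molecules grow as random trees over a C/N/O/P/S alphabet
(probabilities 0.75/0.10/0.10/0.03/0.02), atom by atom onto free valence
(C 4, N 3, O 2, P 5, S 2, counting bond orders), with branching probability
0.25, double-bond probability 0.10 and at most one ring closure
(probability 0.3, ring sizes 3–7). Default size is 3–7 heavy atoms, which
across 100 molecules yields a vocabulary of roughly 150–250 fragments. That
scale is a deliberate design point: the planted law is *sparse* (five active
fragments), and a sparse signal among thousands of autoscaled nuisance
columns is statistically unrecoverable from 100 samples by any regression —
early drafts with 8–30-atom molecules (vocabulary ≈ 4000–5000) failed
exactly that way, with cross-validated error plateauing far above the noise
floor while the in-sample fit stayed excellent. Real corpora behave better
than that regime suggests because their signal is diffuse across many
correlated fragments; the generator instead keeps the vocabulary small so
that a sparse, *identifiable* truth is both realistic to recover and
meaningful to test against.

The planted law is
$y_i = 20 + \sum_f w_f x_{if} + \varepsilon_i$, $\varepsilon \sim N(0, 1)$
mV/dec by default, with five active fragments drawn from those present in at
least 10% of the molecules, weights of 1–4 mV/dec per count with random
signs, and — for identifiability — pairwise count correlation among actives
capped at 0.5 (relaxed stepwise to 0.8 only if the pool is too entangled;
with collinear actives the weight attribution is arbitrary and "recovery"
would be ill-posed no matter the model). `plant_property` returns the ground
truth; `planted_response` applies an existing truth to held-out molecules
with fresh noise, which is how the recovery studies label their test sets.
All randomness flows from the single spec seed.

What the generator does *not* emulate: real ionophore chemistry (sizes,
functional-group grammar, ring systems), heterogeneous measurement protocols
across literature sources, and diffuse many-fragment signals. Passing the
recovery tests therefore demonstrates that the pipeline's machinery —
enumeration, PLS, CV, pruning, importance — is sound under its own model
assumptions; it does not certify predictive accuracy on any real corpus.

## Study sizes and numerical conventions

The shipped studies use: recovery — 20 seeds, 100 training and 30 held-out
molecules each, thresholds "held-out RMSE ≤ 2 noise sd" and "≥ 4 of 5
actives in the top-10 importance" in ≥ 90% of seeds; null — 20 seeds of
weight-free corpora with LOO $R^2 \le 0.3$; the fragment enumerator — 200
random graphs of ≤ 8 atoms against a brute-force oracle. The acceptance
script repeats a 10-replicate version. These sizes keep a full run in the
low minutes on one core while leaving the pass criteria statistically
stable.

Tolerances: NIPALS stops on residual covariance below 1e-12 (rank
exhaustion); constant columns are those with sd ≤ 1e-12; the
latent/coefficient prediction routes agree to 1e-8 and are tested so.
Degenerate inputs fail loudly: single-atom molecules yield empty fragment
maps, empty vocabularies refuse to fit, fewer than five records with a
measured sensitivity refuse to train, and an all-identical response is
rejected.

## Known limitations

* Fragments are linear paths only — no branched or cyclic subgraph
  descriptors, no atom typing beyond the element symbol, no stereochemistry.
* The published corpus this pipeline is designed to reproduce exists only as
  drawn structures; until a SMILES transcription is supplied
  (`inst/extdata/appendix_a1.csv`), the corpus-reproduction test reports
  failure and the reproduction cannot be verified here.
* One candidate ionophore (substance 2 of `table1_ionophores()`) has an
  ambiguous published name — identical to substance 1 despite a discussed
  linker-length series — so its shipped SMILES is a reconstruction with a
  pentane-1,5-diyl linker, flagged by the `reconstructed` column and
  adjustable via `substance2_linker`.
* Leave-one-out is the only cross-validation scheme; for corpora much larger
  than ~50 samples a k-fold scheme would be cheaper and less variable, but
  such corpora do not currently exist for this property.
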
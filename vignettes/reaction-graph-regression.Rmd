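---
title: "Graph-based reaction outcome regression: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based reaction outcome regression: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxngraph)
```

## The problem

High-throughput experimentation (HTE) campaigns for reactions such as the
palladium-catalysed Buchwald–Hartwig C–N coupling produce tables of the form
*substrates → outcome*: one row per reaction, a SMILES string per component
(amine, aryl bromide, product), and a numeric outcome (isolated yield, a
selectivity, or a UV-response ratio acting as a yield proxy). `rxngraph`
learns a regression from the 2D structures of the components to the outcome
without hand-crafted descriptors: each component is embedded by a
message-passing neural network over its molecular graph, the component
embeddings are fused into a single reaction vector, and a small dense head
predicts the outcome.

## The encoder

A molecule is a directed graph: atoms are nodes, and every bond contributes
two opposed directed edges so that information can flow along each direction
separately. Atom features are one-hot blocks for element, degree, formal
charge, chirality tag, attached-hydrogen count and hybridization, an
aromaticity flag and a scaled atomic mass; bond features are a bond-type
one-hot (single/double/triple/aromatic) plus conjugation, ring and
stereo-annotation flags. Hydrogens are implicit. With hidden width $d$ and
input projections $W_{i}^{(n)}, W_{i}^{(e)}$, the initial states are

$$h^0(v) = \mathrm{ReLU}\!\big(x(v)\,W_i^{(n)}\big), \qquad
  h^0(e_{v,w}) = \mathrm{ReLU}\!\big([\,x(v),\,x(e_{v,w})\,]\,W_i^{(e)}\big),$$

and each of the $K$ communicative rounds updates

$$m^k(v) = \sum_{e_{u,v}} h^{k-1}(e_{u,v}), \qquad
  h^k(v) = \mathrm{ReLU}\!\big([\,h^{k-1}(v),\,m^k(v)\,]\,W_c\big),$$
$$m^k(e_{v,w}) = h^k(v) - h^{k-1}(e_{w,v}), \qquad
  h^k(e_{v,w}) = \mathrm{ReLU}\!\big(h^0(e_{v,w}) + m^k(e_{v,w})\,W\big).$$

After $K$ rounds a final communicative layer fuses the aggregated edge
states, the node state and the raw atom features into per-node embeddings,
and a gated recurrent unit (GRU) consumed over the nodes in canonical order
returns its terminal hidden state as the molecule vector.

Reaction vectors are either the elementwise **sum** of the component
vectors (length $d$, order-invariant) or their ordered **concatenation**
(length $d \times n$, order-sensitive, amine–bromide–product by default).
Components with no meaningful graph (catalysts, inorganic bases) are
appended as one-hot blocks after the graph aggregation in both modes —
summing an indicator into a learned embedding space would be ill-typed.
A one-hidden-layer dense head (width $d$, ReLU, linear output) regresses
the z-scored outcome.

## Design choices where the architecture was genuinely open

Several details are not forced by the architecture family and were fixed
once, as package defaults, with a configuration switch where reasonable:

* **Edge-message subtraction.** The update for edge $e_{v,w}$ subtracts the
  previous state of the *reverse* edge $h^{k-1}(e_{w,v})$, preventing a
  message from echoing straight back to its source; this is the established
  behaviour of communicative message-passing encoders. A literal reading of
  the update could subtract the edge's own state instead; both are
  implemented (`edge_message = "reverse"` or `"self"`), reverse is the
  default, and the choice is recorded in the model's config.
* **Communicative function.** A single learned linear transform of the
  concatenated inputs followed by ReLU — the simplest form consistent with
  the role; widths are $2d \to d$ inside the loop and $2d + F_a \to d$ at
  the final layer.
* **Node-message aggregation.** Summation by default (`sum`), with `mean`
  and `max` available; sum is the lineage default for this encoder family.
* **Depth.** $K = 3$ by default; the information horizon of three bonds
  covers the substituent-to-reactive-site distances of typical coupling
  substrates.
* **Readout order and pooling.** The GRU is order-sensitive, so nodes are
  presented in the canonical atom order of the canonicalized SMILES (making
  the embedding independent of how the input SMILES was written), and the
  terminal hidden state — not a pooled average of per-step outputs — is the
  molecule vector.
* **R-squared convention.** "R²" is reported as the squared Pearson
  correlation between predictions and observations, the convention of the
  yield-prediction literature; the coefficient of determination is logged
  alongside (`r2_cod`), and the two agree for calibrated predictions.
* **Scaler.** Z-scoring uses the population standard deviation
  (`c(0, 10)` → $\mu = 5$, $\sigma = 5$) fitted on the gradient-update
  training rows only — never validation or test rows; a leakage test
  recomputes it from the stored indices.

The whole model — encoder, GRU and head — is trained end-to-end by
backpropagation written out analytically in R (matrix form, with molecules
of a minibatch fused into one disjoint-union graph). A finite-difference
test validates every parameter block's gradient to better than $10^{-4}$
relative error, and the vectorized forward pass is checked elementwise
against an independent loop-and-edge-list reference implementation.

## Training protocol

Outcomes are z-scored; the loss is mean squared error on the normalized
scale. Optimization uses Adam (learning rate $10^{-3}$, batches of 32, at
most 100 epochs by default). A validation split — 20% of the training
portion — is evaluated every epoch; when it stops improving for `patience`
consecutive epochs (default 10) training stops and the parameters of the
best-validation epoch are restored. Cross-validation partitions the data
into $k$ disjoint test folds (at $k=5$ the overall train:test geometry is
80:20), reports per-fold R²/MAE/RMSE in original units, and summarises them
as mean ± standard deviation across folds. All randomness — initialization,
splits, shuffling — fans out from one master seed, so identical configs
reproduce identical results bit for bit.

## HTE data reduction

For plate data quantified by UPLC, the outcome is the UV response ratio

$$\mathrm{ratio}_{UV} = \frac{A_{product} \times c}{A_{IS}} \times 100\%,$$

with $A_{product}$ and $A_{IS}$ the 254 nm response areas of the product
and the internal standard and $c = 0.0625$ the IS/product mole ratio at
100% theoretical yield; internally ratios are kept as fractions in $[0,1]$
and values above 1 are retained with a warning rather than clipped, since
the upstream spectra needed to adjudicate them are not available to the
package. Reactions are grouped into four quadrants by the aromatic class of
the ring directly bearing the reactive group — G1 (benzenoid amine ×
benzenoid bromide), G2 (benzenoid × pyridyl), G3 (pyridyl × benzenoid), G4
(pyridyl × pyridyl) — decided by substructure match on that ring only, so
fused systems classify by the attached ring. Group summaries report counts
and the fraction of reactions at or above a conversion threshold (default
0.5).

## What the synthetic generator emulates — and what it does not

`generate_reactions()` builds datasets with known ground truth from a
vocabulary of 12 amines and 12 bromides: benzene and pyridine cores with
H/Me/OMe/F/CF₃/CN substituents at ortho/meta/para positions, i.e. both
electron-donating and electron-withdrawing groups around the two core
classes, with the coupling product composed by joining the two aryl
fragments at a secondary nitrogen. The latent outcome is

$$\mathrm{truth} = \mathrm{logistic}(\beta_0 + a_i + b_j + w_{ij})^{s},$$

with per-substrate effects $a_i, b_j \sim N(0, 1)$, a pairwise interaction
$w_{ij} \sim N(0, 0.3)$ and $\beta_0 = 0.3$; observed outcomes add Gaussian
noise (SD 0.05 by default) and are clipped to $[0,1]$. The skew power
$s = 3$ makes roughly half of all outcomes fall below 0.2 — the strongly
left-skewed conversion profile typical of broad coupling campaigns — and
the median decreases monotonically in $s$.

The generator emulates the *structure* of HTE data (multi-component
reactions over a finite substrate vocabulary, smooth substituent-driven
effects, skewed bounded outcomes), not its chemistry: there are no
mechanism, solvent or catalyst effects, no heteroscedastic noise, no
systematically missing wells, and the substrate list is far smaller than a
real campaign's. Passing the recovery benchmarks therefore demonstrates
that the pipeline can learn a smooth structure–outcome map end-to-end and
generalize across held-out reactions of known substrates; it does not
certify accuracy on out-of-vocabulary substrates or real assay noise.

## Numerical notes and benchmark sizes

* ReLU masks in backpropagation use the post-activation sign; the measure-
  zero tie at exactly 0 is resolved as "inactive", matching the subgradient
  convention of standard frameworks.
* Parameters are initialized Xavier-uniform from the seeded generator;
  biases start at zero; the GRU state starts at zero.
* Molecules with a single atom have an empty edge set; all stages handle
  the $0 \times d$ case explicitly, and the single-node readout reduces to
  one GRU step.
* Multi-fragment SMILES (salts) keep the largest fragment with a warning;
  unparseable SMILES fail loudly with the offending string.
* The packaged benchmarks use sizes chosen to exercise every code path at
  desk scale: memorization on 20 noiseless reactions (hidden width 32),
  and 5-fold cross-validated recovery on 500 reactions with noise SD 0.05
  (hidden width 64, depth 2, ≤40 epochs), where mean test R² lands around
  0.9. The production default width of 300 is asserted on the dimension
  law and single-molecule encodings; recovery of the synthetic benchmark
  does not require it.

## Known limitations

* Atom chirality and bond stereo flags are carried from the MDL fields of
  the OpenBabel-generated structure block; for stereo-unassigned 2D input
  these are typically zero, so stereochemistry contributes little signal.
* Hybridization is derived from kekulized bond orders rather than a full
  perception model.
* The `max` node-message aggregator is available for encoding but not for
  training (no analytic gradient implemented); `sum` and `mean` train.
* The discard policy that produced curated public plate datasets (spectra-
  level quality filtering) is not reproducible from reduced tables; the
  loader accepts already-filtered tables as-is.
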
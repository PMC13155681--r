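---
title: "Methods: hybrid global-local dose-response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid global-local dose-response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairdose)
```

## The prediction problem

A combination screen measures, for a pair of drugs in a cell line, the
response over a grid of dose combinations. Each record is a tuple
$(d_1, d_2, r_1, r_2, c) \mapsto s$: drug identities, their doses, the cell
line, and the measured response $s$ (the package is agnostic to the
response scale — growth fractions, percent growth or a synergy score — and
uses the values as-is). Prediction tasks differ in what is missing: single
cells of an otherwise measured dose-response matrix, whole matrices of an
unscreened pair, or pairs involving an unseen drug or cell line.

`pairdose` combines two sources of information with very different
characters:

* **global structure** — how responses relate to chemistry, dose and
  expression across the whole screen — captured by one neural network
  trained on all samples;
* **local structure** — the shape of the one dose-response surface the
  query belongs to — captured per query from retrieved measurements of the
  same drug pair and cell line.

A learnable aggregator fuses the two, and degenerates exactly to the
global model when nothing local exists. This mirrors how a pharmacologist
would reason: trust the measured neighborhood of a surface where it exists,
fall back on screen-wide regularities where it does not.

## The global model

The network is $N_s(E_d(d_1), E_d(d_2), E_r(r_1), E_r(r_2), E_c(c))$, a
dense head over the concatenation of five embeddings, trained end-to-end by
mean squared error with Adam.

**Drug encoder $E_d$** (shared by both drugs): the SMILES string is
tokenized per character against a vocabulary built from the training
library (PAD and UNK reserved), embedded into learned vectors (the PAD
embedding is pinned at zero, which makes the encoder invariant to trailing
padding), passed through stacked valid-mode 1D convolutions with ReLU,
global max-pooled over positions, and projected linearly. Defaults: two
conv layers (32 then 64 filters, kernel width 5), embedding width 16,
output 64, `max_length` 128. Character-level convolutions see local
substructure tokens (rings, branches, heteroatoms) without any
hand-crafted fingerprint.

**Dose embedder $E_r$** (shared by both doses, fixed, not learned):
$E_r(d) = [\sin(2\pi f_1 d), \cos(2\pi f_1 d), \ldots,
\sin(2\pi f_c d), \cos(2\pi f_c d)]$ with $c$ frequencies log-spaced on
$[f_{\min}, f_{\max}]$. Assay doses span orders of magnitude, so the raw
concentration is first mapped by
$d' = (\log r - \log r_{\min}) / (\log r_{\max} - \log r_{\min})$ using the
training dose range; without this, micromolar values would alias every
frequency above $\sim 1/r_{\max}$. Defaults $c = 16$, $f_{\min} = 0.1$,
$f_{\max} = 50$: the slowest wave spans the normalized $[0,1]$ range once,
the fastest resolves roughly 1% dose differences. Per frequency,
$\sin^2 + \cos^2 = 1$, so the embedding has constant norm $\sqrt{c}$ —
dose information is carried purely in phase. Setting `sinusoidal = FALSE`
in [dose_embedder_config()] emits $d'$ itself (the raw-dose ablation).

**Cell encoder $E_c$**: exactly three fully connected ReLU layers over the
expression profile (the layer count is a fixed architectural commitment of
the model; widths default to 128 → 64 → 32). The profile length is
data-driven; screening panels commonly reduce expression to the
top-variance genes, e.g. 78 of them.

**Training.** A 10% validation slice is held out for early stopping
(patience 20); the same slice later provides out-of-fold pairs for the
aggregator. Because synergy is physically symmetric in the two
(drug, dose) slots, every training row is by default also presented
swapped (`pair_augment`), which empirically shrinks the prediction
asymmetry $|f(A,B,r_A,r_B,c) - f(B,A,r_B,r_A,c)|$ on held-out samples.
The learning rate must lie in $[10^{-5}, 10^{-1}]$ (default $10^{-3}$),
batch size 256, at most 300 epochs.

Two numerical choices matter and are easy to miss. First, the head's
output bias starts at the mean training response: Adam's per-step movement
is bounded by the learning rate, so a distant output scale (percent-growth
data, say) would otherwise consume the entire epoch budget just reaching
the right offset. Second, the PAD embedding row receives no gradient, so
padding stays exactly neutral throughout training.

## The local model

For a query, [retrieve_matching_samples()] returns every training sample
with the same *unordered* drug pair and cell line at a different dose
combination — matching is via a canonical pair key, and samples stored in
the swapped orientation are flipped so their doses align with the query's
slots. The $k$ retrieved samples plus the query become a graph: node
features are the frozen global encoders' joint embeddings (freezing keeps
per-query training cheap and deterministic), and each node connects to its
4 nearest neighbors by Euclidean distance in $(\log r_1, \log r_2)$ —
log-dose because screening grids are log-spaced; ties broken by node
index; the directed selection is symmetrized by union and the diagonal set
to one. A semi-supervised GCN with propagation
$H^{(l+1)} = \mathrm{ReLU}(\hat A H^{(l)} W^{(l)})$,
$\hat A = D^{-1/2} A D^{-1/2}$, and a linear scalar output layer is
trained per query by MSE on the labeled nodes; the output at the single
unlabeled node is the local prediction.

Per-query (rather than amortized) training is deliberate: each query's
graph is different, graphs are tiny (tens of nodes), and the cost is a few
hundred full-batch steps on matrices with ~20 rows.

**Numerical choices.**

* *Label standardization.* The labeled responses are centered and scaled
  before training and the transform undone on output. Without it, the
  epoch budget bounds how far the output can travel (same Adam argument as
  above), making the local model silently scale-dependent.
* *Depth 3, hidden width 16, learning rate $10^{-2}$, 300 epochs.* On a
  5-point log grid, two propagation layers confine the query's receptive
  field to its 4 nearest dose neighbors, and the predictor degenerates to
  neighbor averaging — measurably no better than an explicit
  neighbor-average baseline on held-out grid centers. A third layer lets
  label information from the whole matrix reach the query; this improved
  interpolation on every synthetic dataset we generated, not just one.
  The learning rate sits at the top of the model's admissible local range
  $[10^{-6}, 10^{-2}]$.
* *Normalization degeneracies.* The unit diagonal guarantees no zero
  degree, so $\hat A$ is always defined; $\hat A$ is non-expansive
  (spectral radius $\le 1$), though its *row sums* can exceed 1 on
  irregular graphs — a property worth stating because it is often
  misremembered the other way.

**Availability and fallbacks.** The graph path requires
$k \ge k_{\min} = 2$: with a single retrieved sample a one-neighbor graph
gives the GCN nothing to regularize, so $k = 1$ is resolved to the
fallback path. When no same-pair measurements exist but both monotherapy
curves do, the Bliss-independence product $g_1(r_1)\,g_2(r_2)$ of the two
curves — responses as growth fractions in $[0,1]$; percent-growth inputs
are divided by 100 and clipped with a warning — provides a pseudo-labeled
surface on the outer product of the dose grids, and those pseudo-samples
enter the graph as labeled nodes (a config switch could restrict them to
guiding retrieval only; labeling them was chosen because the null surface
is itself an informative prior for the true surface). With no monotherapy
data either, the $K = 20$ training samples nearest in cosine similarity of
joint features are retrieved ($K$ commonly 20, 50 or 100). A query for
which every path fails is a typed "unavailable" outcome, not an error.

## Aggregation

The learned aggregator is a small MLP over
$[\hat s_{\mathrm{global}}, \hat s_{\mathrm{local}},
\mathbb 1_{\mathrm{avail}}, \log(1+k)]$ — the availability flag and
neighborhood size let one network modulate how much to trust the local
estimate — parameterized as a *residual on the global prediction* with a
zero-initialized last layer, so the untrained aggregator is exactly the
global model. Queries without a local prediction bypass the network
entirely and return the global value bit-for-bit, in every mode. Training
pairs come from the global model's validation slice (out-of-fold with
respect to its gradient training): in-fold pairs would reward memorized
global predictions and teach the aggregator to ignore the local model.
A modest L2 penalty (default $10^{-3}$) keeps the residual near zero when
the local signal is uninformative; empirically, pure-noise local inputs
then cost at most a few percent held-out MSE. `fixed-average` and
`global-only` modes support the ablations.

## The synthetic screen generator

[generate_dataset()] emulates the joint structure of a combination screen:

* **Monotherapy**: Hill curves $g(r) = 1/(1 + (r/\mathrm{EC50})^h)$, with
  per-drug baseline $\log_{10}\mathrm{EC50} \sim U(-1.5, 1.5)$ and slope
  $h \sim U(0.8, 2.5)$.
* **Combination surfaces**: the Bliss null $g_1(r_1) g_2(r_2)$ plus a
  localized Gaussian deviation in log-dose space (amplitude
  $U(-0.3, 0.3)$ — negative = antagonism; width $U(0.5, 1.5)$ natural-log
  units; center uniform over the grid range), plus
  $\mathcal N(0, \sigma^2)$ noise, $\sigma = 0.05$ by default.
* **Expression**: each cell line draws a latent factor vector $z$;
  expression is $z$ times a loading matrix plus noise (78 genes, 4 factors
  by default), and the *same* $z$ shifts each drug's log EC50 through a
  drug-specific coefficient vector — so expression genuinely carries
  sensitivity information, which the generator self-checks by regression.
* **Doses**: 5 log-spaced doses from 0.01 to 100 (assay units), a wide
  one-size-fits-all grid since all drugs share it while EC50s span three
  decades.
* **SMILES**: drawn from an embedded list of valid small-molecule strings,
  extended by simple chain growth when more drugs are requested.

What the generator does *not* emulate — and hence what passing tests do
not establish about real screens: realistic gene-expression covariance,
drug-specific dose ranges, plate and batch effects, heteroscedastic
measurement error, Loewe-type interaction nulls, and any real
chemistry-activity relationship (the SMILES are decorative chemistry; the
signal flows through drug identity). Benchmarks here measure whether the
*machinery* — retrieval, graph propagation, aggregation, splits — behaves
as designed, not whether the model would reach any particular accuracy on
NCI-ALMANAC-like data.

A note on difficulty: with 10-fold dose steps and Hill slopes up to 2.5,
a surface's transition region can fall entirely between grid points, and
some surfaces are nearly flat so relative errors are dominated by noise in
a small range. Interpolating a held-out grid center is therefore
boundary-hard by construction — explicit interpolation baselines sit near
10% of the response range on typical draws — which is precisely what makes
it a discriminating test of the local path.

## Scenario splits and evaluation

[make_scenario_split()] realizes six regimes: S1 holds out random cells of
every matrix (the five folds partition each matrix, 20% per fold, and
monotherapy data stay available); S2 holds out whole pair matrices across
all cell lines (monotherapy kept — the Bliss fallback's natural habitat);
S3 is S2 with monotherapy removed (feature-similarity fallback);
`new-combo`, `new-drug` and `new-cell` hold out (pair, cell) matrices,
whole drugs, and whole cell lines respectively. In every scenario the
fold test sets partition the unit population and train/test never overlap;
for `new-drug`, a sample is tested in the fold of its lowest-fold drug and
trains only where both drugs are unseen. Monotherapy rows feed only the
Bliss fallback (the prediction model itself takes strictly the five
inputs).

[run_experiment()] wires the pipeline per fold — global training, local
predictions with scenario-appropriate fallback, out-of-fold aggregator
training, Pearson correlation on the test split — and evaluates the
ablation variants on identical predictions where possible. The local-only
variant needs a value for queries without local information; it falls back
to the training-mean response, the weakest defensible constant. All
randomness fans out from a single master seed into named sub-seeds (data,
split, per-fold init, per-query init), recorded in the report; a rerun
with the same master seed reproduces the report exactly.

Problem sizes: unit tests use screens of 4–7 drugs × 2 cell lines; the
built-in end-to-end benchmark uses 12 drugs × 6 cell lines × 5 × 5 grids
(9900 combination rows), S1 splits, a reduced global architecture
(drug/cell/dose embeddings of 32/16/16) and 60-epoch budgets, averaged
over 5 master seeds — sizes chosen so the full ablation comparison runs
comfortably on a laptop core while leaving the qualitative ordering
(full ≥ global-only ≫ local-only on S1) clearly resolved.

## Known limitations

* The per-query GCN retrains from scratch for every prediction; thousands
  of queries cost minutes. Caching per-matrix models or amortizing across
  queries would help and is deliberately out of scope.
* Self-pairs (the same drug twice) are accepted and keyed consistently,
  but no claims are made about their scientific interpretation.
* The feature-similarity fallback retrieves samples of *other* pairs;
  their responses live on other surfaces, and its accuracy degrades
  accordingly (visible as the local-only collapse under S3-style splits).
* Responses are never rescaled internally; mixing scales across rows of
  one table is the caller's responsibility.
* The drug encoder sees characters, not molecular graphs; two SMILES of
  the same molecule encode differently.
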
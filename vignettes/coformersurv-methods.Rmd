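---
title: "Collaborative transformer survival models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative transformer survival models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the model implemented by **coformersurv**, the
assumptions behind it, and the design choices made where the architecture
left genuine freedom. It is the companion to the reference documentation:
the function pages say *what* each piece computes, this document says *why*
it is computed that way.

## The model

The data are $v$ omics layers $X^{(1)}, \dots, X^{(v)}$ measured on the
same $n$ samples (e.g. gene expression and microRNA expression), and a
right-censored outcome per sample: an observed time $O_i$ and an event
indicator $\Delta_i \in \{0, 1\}$ ($\Delta_i = 1$ when death was observed
at $O_i$, $0$ when follow-up ended first). The model produces a risk score
$s_i = \beta^\top z^h_i$ from a learned embedding $z^h_i$ and is trained by
the Cox partial likelihood, so the hazard of sample $i$ is
$\lambda_0(t)\exp(s_i)$ with an unrestricted baseline $\lambda_0$.

The embedding is built by two attention mechanisms applied in sequence:

1. **Per-omics feature extraction.** Each preprocessed layer is mapped by
   one affine layer plus activation to a latent matrix
   $Z^{(l)} = f(X^{(l)} W^{(l)}_{\mathrm{emb}} + b^{(l)})$ of width
   `d_latent`.

2. **Inter-omics attention** (within each sample, across layers). Queries
   double as keys through a single shared projection $W_Q^c$, and values
   use $W_V^c$; for sample $i$ the attention from layer $u_1$ to layer
   $u_2$ is
   $\hat\alpha_i^{u_1,u_2} = \mathrm{softmax}_{u_2}\!\big(\langle q_i^{(u_1)},
   q_i^{(u_2)}\rangle / d_c\big)$, and the contextualized feature is
   $z_i^{(u_1,c)} = \sum_{u_2} \hat\alpha_i^{u_1,u_2} v_i^{(u_2)}$.
   Several heads run independently; each head's stacked output is
   compressed by one shared matrix $W_1^c$ and the heads are concatenated
   into $Z^c$. Note the score divisor is $d_c$ itself, not
   $\sqrt{d_c}$ — this is deliberate and kept as the model defines it,
   with `attention_scale = "sqrt_dim"` available as a config switch for
   the conventional scaling.

3. **Inter-sample graph transformer** (across samples). A KNN graph per
   omics is built with the exponential kernel
   $w(i,j) = \exp(-\rho^2(x_i, x_j) / (\mu\,\delta^2))$, $\delta^2$ the
   median squared pairwise distance; the per-omics graphs are fused by
   edge-union averaging and spectrally normalized into
   $\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$. Attention over
   samples is then *biased* by the graph: the exponential kernel is
   multiplied entrywise by $\hat A$ and restricted to fused-graph
   neighbourhoods $N_i$ (plus self), so each sample aggregates value
   vectors only from structurally similar samples, with weights that
   still adapt to the learned queries. A final projection gives $Z^h$.

4. **Cox head.** $s = Z^h \beta$, trained jointly with everything else by
   minimizing $-\sum_{i:\Delta_i=1}\big[s_i - \log\sum_{j: O_j \ge O_i}
   e^{s_j}\big]$. After training, the Breslow estimator turns the scores
   into a baseline cumulative hazard and hence survival curves
   $S_i(t) = \exp(-\Lambda_0(t) e^{s_i})$.

### Ablation variants

Six wirings are available through `build_model()`, matching the
architecture's natural ablations: `sgt` (one omics layer with its own
graph), `mgt` (concatenated embeddings, no inter-omics attention),
`crosst` (inter-omics features straight to the Cox head, no inter-sample
block), `crosst_segcn` (fixed-weight spectral GCN aggregation instead of
attention), `crosst_sa` (plain self-attention without the graph bias),
and the full `coformersurv`.

## Numerical and statistical decisions

**Risk sets.** The partial-likelihood definition with a *strict* risk set
$\{j: O_j > O_i\}$ leaves the latest event with an empty denominator, so
the default is the standard inclusive risk set $\{j: O_j \ge O_i\}$ with
Breslow handling of ties; `risk_set = "strict"` reproduces the strict
form, skipping events with empty risk sets. The log-sum-exp in the loss
and the Breslow denominators are computed with max-subtraction over a
single time-sorted pass.

**Attention stability.** All softmaxes subtract the row maximum before
exponentiating. In the graph-biased kernel the convolution entries act as
a multiplicative bias; they are constant in the scores, so the softmax
backward rule is unchanged. Scores that still reach `NaN` (diverged
training) abort with an error rather than propagating.

**Symmetrization.** KNN graphs are directed; the undirected adjacency
uses the elementwise maximum of $W$ and $W^\top$, which realizes the
union of directed edges while preserving the kernel values (the kernel is
symmetric). Averaging instead would down-weight one-sided edges twice —
once at symmetrization, once at fusion.

**Held-out samples and the graph.** Training is transductive over the
training cohort. Held-out samples are attached inductively: KNN edges to
training samples only, using the training $\delta^2$ and $\mu$, no
test–test edges, and the convolution matrix recomputed on the combined
graph. Held-out outcomes never enter preprocessing statistics, graph
construction or the loss; the test suite asserts this by permuting
held-out outcomes and checking that trained parameters are bit-identical.

**Preprocessing order.** Missing-value filter (10% threshold), median
imputation, `log2(x + 1)` only for non-negative matrices (skipped with a
warning for signed data such as methylation M-values; the base and
pseudocount are a convention, not prescribed by the architecture),
variance top-$k$ selection with ties broken by column order, then
standardization. In the evaluation harness all of these statistics are
fitted on the training split and applied unchanged to the test split —
the leak-free order. (`preprocess_omics()` on the full cohort before
splitting reproduces the simpler pre-split behaviour where wanted.)

**Defaults.** `d_latent = 64`, `d_c = 32`, two heads, combined width 64,
`d_h = 32`, rectified-linear activations, scaled uniform fan-in
initialization under a recorded seed, Adam at the fixed learning rate
`2e-4`, 300 full-batch epochs, no early stopping. Full-batch training is
the natural choice because the partial likelihood couples all samples
through risk sets and the graph couples them through neighbourhoods.
Dimensions and activations are conventions chosen once; the learning
rate is the one the method prescribes. Longer training continues to
reduce the training loss but mostly overfits at desk scale, and extreme
overtraining (thousands of epochs) can diverge to score overflow, so the
moderate fixed epoch count doubles as regularization. The graph
neighbourhood size $K$ is the one hyperparameter the method tunes by
cross-validation (`select_K()`); $K$ near 10–15 behaves well on cohorts
of a few hundred samples with clusters of ~100.

**Inter-sample attention is single-head and one layer deep,** and the
inter-sample block reuses one $W_Q$/$W_V$ pair for both the plain and the
graph-biased kernel; the architecture defines no deeper stack, so none is
configurable. Dense masking implements the neighbourhood restriction,
which is the right trade-off for cohorts up to a few thousand samples.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure this architecture
assumes, so every stage is exercisable without external data:

* **latent clusters** shared across omics layers (cluster centroids per
  layer, `cluster_sep` controlling separation) plus two shared latent
  factors — this is what makes per-omics KNN graphs agree with each other
  and recover the clusters (the test suite checks adjusted Rand > 0.9 by
  spectral clustering of the fused convolution matrix under a
  cluster-dominant configuration);
* **a linear hazard component** (sparse weights over `n_signal` features
  per layer), **a cross-omics interaction component** (products over a
  fixed recorded set of feature pairs — the signal that inter-omics
  attention can capture but purely additive models cannot), and **a
  per-cluster hazard offset**; each component is standardized before
  scaling so effect sizes are comparable;
* **Weibull event times** with hazard proportional to $e^{\eta_i}$
  (inverse-transform sampling) and **independent exponential censoring**
  whose rate is calibrated by bisection so the expected censoring
  fraction matches `censor_rate_target`.

The default effect sizes (3.0 linear, 1.4 interaction, 2.0 cluster)
define a strong-signal regime: the true log-hazard has standard deviation
near 3.9, which under proportional hazards puts the oracle concordance of
$\eta$ itself — the ceiling no fitted model should beat — around
0.88–0.91. This was chosen once, as the regime in which signal-recovery
behaviour is meaningful to test; weaker regimes are a config away.

What the generator does **not** emulate: count-valued RNA-seq marginals,
heavy-tailed library-size effects, batch structure, or informative
censoring. Passing tests on this generator therefore demonstrate that the
machinery recovers the kinds of structure it models — not that any
particular clinical performance level would be reached on real cohorts.

## Evaluation protocol

`repeated_holdout()` draws independent 80/20 splits (50 by default, fewer
in the examples here), refits the entire pipeline on each training part
(preprocessing statistics, graph, model), attaches the test part
inductively and reports the concordance index and the pooled
time-dependent AUC as mean ± sd across repeats. The concordance index
excludes pairs whose shorter time is censored or where both are censored;
score ties count 0.5 (ties are measure-zero for continuous scores). The
pooled AUC enumerates, at every distinct event time $t$, all pairs with
$O_i < t$ against $O_j > t$; the earlier index is unrestricted by default
(with `cases = "events_only"` for the conventional cumulative/dynamic
reading, since censored samples in the earlier set are arguably
ambiguous). Kaplan–Meier stratification splits at the median score
(strictly-greater goes to the high-risk group) and tests the two groups
with the standard two-sample log-rank statistic.

Desk-scale problem sizes are used throughout the tests and the
acceptance script — cohorts of 400–2000 samples with tens of features
per layer and 10 evaluation seeds — chosen so the full suite exercises
every code path at statistically meaningful sizes while remaining quick
to run end to end.

## Known limitations

* The proportional-hazards assumption is inherited from the Cox head;
  the model cannot express crossing hazards.
* One collaborative layer; no residual connections, layer norm or
  dropout — the architecture defines none, so regularization comes only
  from the epoch budget and the graph smoothing.
* Graph smoothing is a bias–variance trade: on cohorts where the
  per-sample features are already clean and low-dimensional (as in parts
  of the synthetic regime), the inter-sample aggregation can cost a
  little accuracy relative to the graph-free `crosst` wiring; its
  benefit is expected in the noisy, very high-dimensional regimes the
  architecture targets.
* Transductive training means the training graph must be rebuilt to add
  training samples; only scoring is inductive.
* The pooled AUC is not IPCW-adjusted; under heavy censoring it inherits
  the usual censoring bias of unweighted estimates.
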
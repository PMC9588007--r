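---
title: "Disentangling couplings from phylogeny: models, samplers and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling couplings from phylogeny: models, samplers and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopotts)
```

# The problem

Homologous protein sequences in an MSA are correlated for two distinct
reasons.  Residues in physical contact coevolve, which couples the
corresponding alignment columns; and all sequences descend from common
ancestors, which correlates whole rows.  Coevolution methods — Potts models
/ direct coupling analysis (DCA) — read column–column correlations as
evidence for contacts, so row-level phylogenetic correlation is a direct
confounder.  In natural alignments the two signals are inseparable; this
package builds the controlled synthetic setting in which they can be turned
on and off independently, and provides the statistics used to quantify the
damage phylogeny does to contact inference.  A second, complementary theme
is that the *column attentions* of MSA language models carry pairwise
sequence-distance information; the package implements the regression that
quantifies this and synthetic attention tensors with a planted, known
distance signal.

# Models and procedures

## Potts models

A sequence `x` of length $L$ over $q$ states ($q = 21$: twenty amino acids
plus the gap, an ordinary state) has energy
$$H(x) = -\sum_i h_i(x_i) - \sum_{i<j} e_{ij}(x_i, x_j),$$
and probability $P(x) = e^{-H(x)}/Z$.  On enumerable instances
(`exact_distribution`, up to $10^6$ states) $Z$ is computed exactly; this
is the oracle for every sampler and gauge test.  The parameterization is
redundant; `zero_sum_gauge` fixes it so every coupling block has zero row
and column means (and fields zero mean per site), shifting the removed
means into the fields so probabilities are untouched.  Contact scores are
the Frobenius norms of the gauge-fixed blocks over all $q$ states, followed
by the average product correction (APC), which removes multiplicative
per-site background before ranking.

Two APC conventions exist.  The scoring pipeline uses means over
*off-diagonal* entries (the diagonal of a coupling-score matrix is not a
score); with that convention APC kills constant backgrounds exactly but a
zero-diagonal product background only approximately.  With means over full
rows (`diag = "include"`), a genuinely rank-one matrix $u u^\top$ is
annihilated exactly — that cleaner algebraic property is exposed and tested
separately, while `"exclude"` remains the default used on coupling scores.

## Sampling, with and without phylogeny

`sample_equilibrium` runs $M$ independent Metropolis–Hastings chains from
uniform random starts: a proposal picks a site uniformly and a replacement
state uniformly among the other $q-1$ (the proposal excludes the current
state — "another state" read literally; the stationary law is unaffected,
only mixing speed), and is accepted with $\min(1, e^{-\Delta H})$, with
$\Delta H$ computed incrementally and verified against full recomputation in
the tests.  The default budget of $50\,L\,q$ proposals per chain is a
generous equilibration allowance for the desk-scale models the package
targets (independent-site and planted models mix in far fewer steps); it is
a plain argument (`n_steps`) for models that need more.

`sample_along_tree` places an equilibrium draw at the root, duplicates the
current sequence at each branching, and on a branch of length $b$ (expected
substitutions per site) keeps proposing until exactly
$\mathrm{round}(bL)$ proposals have been *accepted* (half-up rounding;
exact .5 rounds up, declared for determinism).  Because the root is an
equilibrium sample and the chain satisfies detailed balance, every node
sequence is an equilibrium sequence and the ensemble law of the leaves does
not depend on where the tree is rooted — asserted as a property over 200
seeded replicates.  A safety cap (1000 proposals per accepted-mutation unit
per site) converts pathological non-acceptance (e.g. deep single-well
models) into an error naming the branch rather than a hang.

## Pseudo-likelihood inference

`fit_plm` maximizes the weighted, $\ell_2$-penalized sum over sites of
conditional multinomial-logistic log-likelihoods — the pseudo-likelihood
approximation standard for contact inference.  Sequences are reweighted by
the reciprocal neighbour count at Hamming threshold $\delta = 0.2$ (the
automatic threshold estimation some implementations perform is replaced by
this fixed, overridable default), the log-likelihood is normalized by the
effective depth $M_\mathrm{eff}$ so that duplicating every sequence leaves
the fit invariant, and the penalties ($\lambda = 10^{-2}$ each for fields
and couplings by default) act on the asymmetric per-site parameters before
the two estimates of each $e_{ij}$ are averaged.  The objective is smooth
and convex; all sites are fitted jointly by L-BFGS (tolerance $10^{-5}$ on
the projected gradient, zero initialization), so each evaluation is two
dense matrix products and restarting cannot change the optimum.  No
pseudocounts are used — pseudo-likelihood does not need them.  A tiny
instance ($L = 3$, $q = 3$, $M = 50$) is checked against a generic BFGS
optimizer applied to a naive loop-written copy of the same objective.

## Contact-recovery evaluation

`roc_auc` is the midrank rank-sum statistic: the probability that a random
truth pair outscores a random non-truth pair, ties counting one half
(cross-checked against an independent ROC implementation).  Both the truth
set — the generator's own top APC coupling pairs, the "proxy contacts" of
the synthetic setting — and the candidate set exclude pairs with
$|i-j| \le 4$.  The phylogeny impact is
$\Delta = (A_\mathrm{eq} - A_\mathrm{tree})/A_\mathrm{eq}$.
`subsample_average_scores` reproduces the subsample-and-average protocol
(10 draws of 500 rows by default, reduced to $0.8M$ for shallow MSAs)
used when a scorer cannot ingest a full alignment.

## Attention–distance regression

Raw column attentions form a `(layer, head, column, M, M)` tensor of
row-stochastic matrices, with column index 0 the prepended
beginning-of-sequence (BOS) token.  Aggregation averages the symmetrized
maps over *all* columns, BOS included:
$A^{(l,h)} = \tfrac{1}{2(L+1)}\sum_{j=0}^{L}(A_j + A_j^\top)$.  For a
sequence pair $(i, i')$ the feature vector is the $(i, i')$ entry of every
$A^{(l,h)}$, in layer-major order.  The normalized Hamming distance
$y \in [0,1]$ is modelled as
$\mathbb{E}[y\,|\,a] = \sigma(\beta_0 + a\beta^\top)$ and fitted by
maximizing the Bernoulli quasi-log-likelihood
$y\log G + (1-y)\log(1-G)$ — in R, a quasi-binomial GLM with logit link,
whose IRLS solution is the unique optimum of this concave objective.
Responses equal to 0 (duplicate sequences) are legal and included.  There
is no regularization in the fit; perfectly collinear features are an error
rather than silently dropped.

Splits are over *rows*: 70% of sequences train, and only within-group
unordered pairs are used on either side, so no sequence appears in both a
training and a test pair.  Cross-MSA fits pool within-MSA pairs from
several alignments into one model.  Diagnostics are $R^2$, Pearson
correlation, and the OLS slope of truth on prediction (a calibration check:
slopes above 1 flag predictions compressed toward the mean).  Per-column
prediction feeds the model the symmetrized attentions of one column —
symmetrized, consistent with the aggregate construction, and without the
$1/(2(L+1))$ factor, whose absence is absorbed into nothing (coefficients
are only comparable within a convention) — and the spread of
per-column errors is summarized by the standard deviation of
(prediction − truth), stratified by column entropy.

# Synthetic generators: what they emulate, and what they do not

`planted_potts` stands in for generative models fitted to natural families:
a chosen number of site pairs (separation $\ge 5$) receive random coupling
blocks projected to the zero-sum gauge and scaled to a fixed Frobenius
norm; everything else is zero.  The planted pairs are then *exactly* the
generator's top coupling scores, making truth sets unambiguous.
`random_tree` provides Yule (pure-birth) and balanced topologies, rescaled
to a target mean root-to-leaf height in substitutions per site.

`surrogate_attentions` emulates the structure through which a trained
MSA language model could encode distances: at column $j$, head $(l,h)$
receives pre-softmax logits $\gamma_{lh}\,\mathrm{match}_j(i,i') +
\varepsilon$, where $\mathrm{match}_j$ indicates equal residues and
$\varepsilon$ is centered Gaussian noise.  Averaged over columns the match
indicator equals $1 - d_H$, so the planted link is linear on the logit
scale and recovery tests are sharp.  Heads with negative $\gamma$ (attending
to *similar* sequences) are planted by default, mirroring the mixed signs
observed in trained models.  The BOS column carries pure noise.

These generators are deliberately idealized.  They do not emulate:
amino-acid substitution preferences or rate heterogeneity; indels (the gap
is sampled like any state, not placed by an alignment process); the
imperfections of couplings *inferred* from finite natural alignments; or
real attention statistics, which are neither independent across heads nor
Gaussian on the logit scale.  Passing the regression benchmarks therefore
shows that the estimator recovers a monotone attention–distance link under
realistic noise — not that any particular trained network encodes one.
Likewise the disentangling benchmark establishes the *direction* of the
phylogeny effect on pseudo-likelihood inference; the published per-family
magnitudes depend on generative models fitted to deep natural alignments,
inferred trees, and a pretrained language model, none of which are (or can
be) reproduced at desk scale here.

# Study conditions and numerical choices

The package's own benchmarks, run by the test suite and
`scripts/acceptance.R`, use these sizes, chosen once as realistic
desk-scale analogues:

* **Sampler law check**: $L = 3$, $q = 3$ (27 states), $10^4$ chains of
  $10^5$ proposals; the total-variation distance to the exact law is
  required below 0.02.  With $10^4$ draws over 27 states the sampling-noise
  floor of the TV statistic is itself close to 0.02, so this bound is tight
  evidence of correctness for a moderately concentrated model.
* **Disentangling benchmark**: planted model with $L = 30$, $q = 8$, 10
  contacts of Frobenius norm 4 over fields of scale 0.3 ("strong"
  couplings: equilibrium recovery should saturate); MSAs of depth 2000;
  Yule trees of height 0.75, giving mean pairwise leaf distances ≈ 0.65
  versus ≈ 0.87 at equilibrium — relatedness comparable to a natural
  protein family.  Ten tree/sampler replicates; the claim is directional
  ($\Delta > 0$ in at least 9 of 10).
* **Regression benchmark**: 6 × 6 heads ($K = 36$ features), $M = 120$
  sequences, $L = 24$, logit noise 0.25, 70/30 split.  The depth is set by
  the noise-floor requirement: the held-out $R^2$ of an unregularized
  quasi-MLE on pure-noise features is biased by roughly $-K/n_\mathrm{train}$,
  and $M = 120$ (3486 training pairs) puts that bias near $-0.01$, an order
  of magnitude inside the $\pm 0.05$ band the noise-floor check uses.  Three
  exactly conserved columns are planted for the entropy stratification,
  which requires genuinely zero-entropy sites to be meaningful.
* **Root invariance**: $L = 8$, $q = 3$ planted model, a fixed 12-leaf
  topology rooted at two different nodes, 200 seeded samples per rooting,
  agreement within 3 standard errors of the mean pairwise leaf distance.

Other numerical choices: alphabet order fixed as `ACDEFGHIKLMNPQRSTVWY-`
(gap last) so encodings are stable across files; non-standard residues
(B, Z, X, U, O, `.`) map to the gap with a warning; gap–gap positions count
as matches in $d_H$ (the gap is the 21st state, consistently with $q = 21$
in the Hamiltonian); `top_pairs` breaks score ties lexicographically on
$(i, j)$ so cutoff lists are reproducible; $G$ is clipped inside logs at
$10^{-12}$; every stochastic function takes an explicit seed and touches no
global RNG state beyond a restored-on-exit stream.

# Limitations

Pseudo-likelihood fitting here is desk-scale: dense linear algebra over
$(Lq)^2$ coupling parameters is comfortable to $L \approx 50$, $q = 21$,
$M \approx 10^4$, but it is not a replacement for optimized DCA packages on
full-length proteins.  The fractional logit inherits the known depth bias
of pooled fits — pair counts grow quadratically with MSA depth, so pooled
models underweight shallow alignments, which the slope diagnostic is there
to expose.  Exact Boltzmann enumeration is limited to $q^L \le 10^6$.
Attention tensors are held densely in memory
($n_l\, n_h (L+1) M^2$ doubles), which bounds $M$ at a few hundred for
12 × 12 heads.
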
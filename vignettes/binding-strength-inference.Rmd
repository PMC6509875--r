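---
title: "Inferring transcription factor activity from promoter motif frequencies"
author: "baseTFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcription factor activity from promoter motif frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baseTFA)
```

## The model

baseTFA addresses a reverse-inference question: a two-condition expression
experiment shows thousands of genes moving up or down; which trans-acting
factors are responsible?  The method couples two ingredients.

**A condition-free binding strength.**  Suppose a motif scanner finds
$\tau$ candidate binding sites for a factor $T$ in the promoter of a gene
(a fixed window around the TSS, default $-1000$ bp to $+200$ bp).  If each
site is an independent Bernoulli binding trial with per-site probability
$p_0$, the probability that $T$ binds the promoter at least once is

$$ b = 1 - (1 - p_0)^{\tau} \approx \tau\, p_0 \quad (p_0 \text{ small}), $$

with signed approximation error $\tau p_0 - \left(1-(1-p_0)^\tau\right)$
that is non-negative (the union bound) and at most
$\tau(\tau-1)p_0^2/2$.  Because the statistic below is scale-free in $b$,
the common factor $p_0$ cancels and **raw motif counts can stand in for
binding strengths** — no ChIP experiment and no estimate of $p_0$ is
needed.  `countsToBinding()` exposes the exact formula too, for
sensitivity analysis at large $p_0$ where proportionality visibly breaks.

**A sorted-enrichment statistic.**  Per-gene differentiation is the
natural-log fold change $d_i = \ln(e_{i1}/e_{i0})$, split into
$d^+_i = \max(d_i, 0)$ and $d^-_i = \max(-d_i, 0)$ so activation and
repression are inferred separately.  For one direction, sort $d^+$
descending (permutation $\pi$, stable under ties) and form

$$ f_0(i) = \frac{\sum_{j\le i} d^+_{\pi(j)}}{\sum_{j} d^+_{\pi(j)}},
   \qquad
   f_1(i) = \frac{\sum_{j\le i} d^+_{\pi(j)} b_{\pi(j)}}
                 {\sum_{j} d^+_{\pi(j)} b_{\pi(j)}}. $$

The BASE score is the maximum gap $\delta = \max_i [f_1(i) - f_0(i)]$.  If
the factor's binding weight is concentrated on the most differentiated
genes, $f_1$ runs ahead of $f_0$ and $\delta$ is large; if $b$ is constant
the weights cancel and $\delta = 0$ identically.  Significance comes from
a permutation null: draw $K$ uniform re-pairings $\lambda$ of $b$ to
genes, recompute $\delta^*$, and report
$p = \#\{\delta^* > \delta\}/K$ (strict inequality).  For $N \le 8$ an
exact mode enumerates all $N!$ pairings.  Across motifs, q-values
(Benjamini–Hochberg by default, Storey's $\hat\pi_0(\lambda=0.5)$
estimator as an option) control the FDR within each direction.

### Assumptions worth stating

* Binding sites act as independent, identically distributed Bernoulli
  trials; cooperative or competitive binding is not modelled.
* Regulation is promoter-proximal: the fixed TSS window ignores distal
  enhancers.
* The null is gene-exchangeability of the binding vector; correlated
  promoter content across genes (e.g. CpG-island co-occurrence of many
  motifs) is not part of the null and can make motifs non-independent
  *between* tests (the q-values address ranking, not joint inference).

## One design question the formulas leave open

The printed recursion uses $d^+$ in the sorting step and in $f_1$, but the
reference curve $f_0$ can be read either with the *directional* component
$d^+$ or with the raw signed $d$.  We use $d^+$ in **both** curves: with
signed $d$, $f_0$ is non-monotone over the genes differentiated in the
other direction, the two directions are treated asymmetrically, and the
identity "constant $b \Rightarrow \delta = 0$" fails.  The literal signed
reading remains available as `runBase(..., literalF0 = TRUE)` for
comparison.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `upstream`, `downstream` | 1000, 200 bp | Promoter window around the TSS; proximal regulation focus. |
| `threshold` | 0.85 | Matrix similarity cutoff of the scanner (dimensionless, in [0, 1]). Proprietary per-motif cutoff profiles are not reproducible; `calibrateThreshold()` picks a cutoff achieving a target per-window false-positive rate on random background instead. |
| pseudocount | 0.5 per cell | Count-matrix regularization before row normalization; prevents zero frequencies from degenerating the log information weights. |
| `K` | 10 000 | Permutations per motif-direction test; resolution of the p-value is $1/K$. |
| `fdrMethod` | `"bh"` | Assumption-light step-up FDR; `"storey"` is less conservative when many motifs are truly null-free. |
| `rankBased` | `FALSE` | Replace $d^+$ and $b$ by their average ranks (zeros share the average of their positions) before scoring; trades power for robustness and makes results invariant under strictly increasing transforms of $d$. |
| `addOne` | `FALSE` | $p = (1+\#)/(1+K)$ estimator for users who need $p > 0$ guarantees. |

## Numerical and degenerate-case choices

* **Ties in the sort** are resolved stably by original index.  With tied
  $d^+$ values carrying unequal weights, the observed $\delta$ genuinely
  depends on which tied gene is cumulated first — this is a property of
  the statistic, not of the implementation.  The permutation null is
  unaffected (tied positions are exchangeable, so the null score multiset
  is order-invariant), and the p-value remains exact conditional on the
  tie resolution; a property test pins both facts down.
* **Degenerate inputs are flagged, never dropped**, so the motif ranking
  stays total: a direction with $\sum d^\pm = 0$ (`no_differentiation`)
  and a motif with $\sum d^\pm b = 0$ (`zero_weight`) report
  $\delta = 0$, $p = 1$; a constant binding vector (`constant_b`) gives
  $\delta = \delta^* = 0$ and hence $p = 0$ under strict inequality.
  A fully uniform PWM (no informative position) scores 0 everywhere with
  a warning rather than matching everything.
* **Windows containing N never match**; ambiguity codes become N at
  promoter extraction.
* **Both strands are always scanned** and palindromic double-hits kept:
  $\tau$ is a count of candidate Bernoulli trials, not of unique genomic
  sites.
* **Seeding**: each motif-direction test derives its own RNG seed
  deterministically from the master seed, the motif column index and the
  direction, so results are reproducible and independent of which other
  motifs are in the matrix.  The permutation kernel runs in C++ on R's
  own RNG stream.
* The binding-model error $\tau p_0 + \mathrm{expm1}(\tau\,
  \mathrm{log1p}(-p_0))$ is computed with `expm1`/`log1p` for accuracy and
  clamped at 0, since the mathematical quantity is non-negative and only
  sub-epsilon negative floating-point residue can occur.
* **One promoter per gene** at the 5'-most TSS (minimum start on `+`,
  maximum end on `-`), deterministic under record reordering; aggregating
  alternative promoters would change the meaning of $\tau$.  Window
  overlap with neighbouring genes is ignored.
* Genes present in the expression profile but absent from the count
  matrix are dropped (inner join, logged); zero-filling would manufacture
  enrichment signal.

## The Wilcoxon enrichment companion

To corroborate a TF call biologically, gene sets (GMT) are tested by the
two-sample Wilcoxon rank-sum test on the ranks of the signed $d$: "up"
asks whether in-set genes sit higher than exchangeability predicts, and
"down" lower, as two separate one-sided tests — no differential-expression
cutoff is involved.  Small sets (under 10 members) use the exact null
distribution (closed form when the ranks are tie-free; full enumeration of
membership assignments under ties when tractable), larger ones the normal
approximation with tie and continuity correction.  The threshold-based
Fisher-exact recipe is included (`fisherEnrichment()`) only as a
comparison foil; its outcome depends on an arbitrary cutoff.

## What the simulators emulate — and what they do not

`simulateNull()` realizes exactly the exchangeability null of the
permutation test: $d \sim \mathcal N(0, \sigma^2)$ i.i.d. and counts
$\tau \sim \text{Poisson}(\mu)$ independent of $d$.  Poisson is the
simplest integer-count null consistent with motif frequencies; a
negative-binomial option (`dispersion`) reflects that real promoter counts
are overdispersed.  `simulateAlternative()` couples one motif's counts to
$d^+$ through
$\tau_i \sim \text{Poisson}\!\big(\mu\,(1 + \beta\, d^+_i / \max d^+)\big)$
— through $d^+$, not signed $d$, so the planted signal is specifically
directional.  Note a structural consequence: across *all* genes the
planted counts are slightly anticorrelated with $d^-$ (down-genes keep
baseline counts while up-genes are elevated); directional specificity is
therefore assessed within the down-regulated subset and at the p-value
level.  `makeToyGenome()` builds a synthetic chromosome with gene models
on both strands, i.i.d. uniform background and exact consensus copies
planted at known promoter offsets, so extraction and counting can be
verified against ground truth, including boundary-clipped windows.

Real data differ in ways these generators deliberately omit: promoter
base composition is not i.i.d. (CpG islands, repeats), motif occurrences
co-occur across factors, expression noise is heteroskedastic, and counts
correlate with promoter length and GC content.  Passing the simulation
suite therefore demonstrates the *statistical machinery* — calibration,
power, directionality, scale-freeness, exactness of the permutation and
enrichment computations — not biological validity on any particular
organism.

## Problem sizes used by the test suite

Calibration and power checks run at 500 genes: 2000 null motif-tests at
$K = 500$ for the type-I error (empirical rate at $\alpha = 0.05$ expected
in $[0.03, 0.07]$), and 100 planted-regulator replicates at $K = 1000$
with 49 null motifs for recovery.  The power study draws
$d \sim |\mathcal N(0,1)|$ (`dDistribution = "half-normal"`), an all-up
profile in which every gene carries directional signal; with the signed
default roughly half the genes are uninformative for the up direction, and
recovery at the same effect size is correspondingly lower (about 70–75%
top-rank rate in our measurements) — a useful reminder that BASE power
depends on how much of the profile actually differentiates in the tested
direction.  Exactness checks (enumeration oracles) run at $N \le 7$ for
the permutation engine and $N \le 10$ for the rank-sum test, where full
enumeration is feasible in seconds.

## Known limitations

* Two profiles only; replicated designs must be summarized into one
  fold-change vector upstream.
* One motif at a time: cooperative multi-factor models are out of scope.
* Motif count is a proxy: identical counts with different site affinities
  are indistinguishable; users with condition-specific binding data can
  pass a real-valued gene-by-motif matrix directly to `runBase()`.
* The strict-inequality p-value can be exactly 0; use `addOne = TRUE`
  where downstream tools require positive p-values.
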
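---
title: "Censored mixture segmentation of saturated microarray spots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored mixture segmentation of saturated microarray spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censpot)
```

## The model

A 16-bit scanner records pixel intensities only up to the saturation
threshold $S = 65535$; pixels whose true signal exceeds $S$ are written as
exactly $S$. `censpot` treats those pixels as *right-censored
observations* rather than as true values, and does so inside the
segmentation model itself, so that a pixel's cluster membership — not
just a post-hoc intensity summary — can change when saturation is taken
into account.

The pixels $y_1,\dots,y_n$ of one target mask (the hexagonal or
rectangular cell around one spot center) are modeled as i.i.d. draws from
a $K$-component Gaussian mixture, $K \le 3$, whose last component is
right-censored at $S$:

$$ f(y;\theta) \;=\; \sum_{k<K}\pi_k\,\varphi(y;\mu_k,\sigma_k)
   \;+\; \pi_K\,\varphi_S(y;\mu_K,\sigma_K), $$

with $\varphi_S(y) = \varphi(y;\mu_K,\sigma_K)$ for $y<S$ and
$\varphi_S(S) = 1-\Phi\{(S-\mu_K)/\sigma_K\}$, a point mass. Means are
ordered $\mu_1<\dots<\mu_K$ for identifiability. The interpretation is by
position: component 1 is the local background, component $K$ the
foreground, and the middle component of a three-component fit collects
intermediate pixels (fuzzy edges of bright spots, donut holes). $K=1$
means the mask holds a blank or weak spot. We cap $K$ at three because
brighter structure than BG + intermediate + FG is not observed in
practice and additional components mostly chase noise.

Estimation is by EM on the complete-data likelihood, which separates into
a multinomial part for the labels, weighted normal likelihoods for the
regular components, and a weighted right-censored normal likelihood for
the last component. The E-step is the usual responsibility update
$z_{ik} \propto \pi_k f_k(y_i)$ (computed in log space); the M-step has
closed forms for all regular components, while the censored component's
$(\mu_K,\sigma_K)$ has no closed form and is maximized by Newton–Raphson.
Spot summaries are the model means: background $\hat\mu_1$, foreground
$\hat\mu_K$, and background-corrected intensity $\hat\mu_K-\hat\mu_1$.
Because $\hat\mu_K$ is a model parameter, not an average of observed
pixels, it can — and under heavy saturation should — exceed $S$.

## The censored-normal kernel

The weighted censored-normal MLE is solved in $(\mu, \log\sigma)$ so
Newton steps are unconstrained while $\sigma>0$ is automatic. Gradient
and Hessian are analytic; only four sufficient statistics of the data
enter them, so each Newton iteration is $O(1)$ after one pass over the
pixels. Steps are backtracked until they increase the objective, and a
Nelder–Mead safeguard takes over in the rare case a Newton step is
unusable. Convergence is declared when the log-likelihood gain falls
below $10^{-8}$, within 100 iterations. The fit matches
`survival::survreg` (an independent implementation of the same model) to
at least five significant digits in the test suite.

Degenerate situations are defined away explicitly:

* censoring is detected by exact equality $y = S$ — scanner saturation is
  an exact ceiling, not an approximate one;
* if all weighted mass sits on censored pixels the likelihood increases
  without bound in $\mu$; such fits raise a *non-identifiability* error
  (standalone use) or set the foreground to $S$ with a `degenerate_fg`
  flag (inside EM, where the spot is still reported);
* scales are floored at $10^{-6}S$ so a component cannot collapse to an
  exact point mass; fits that touch the floor are flagged.

## EM details and numerical choices

**Initialization** is deterministic: pixel values are sorted and split
into $K$ contiguous blocks whose sizes follow the starting weights —
$(0.8, 0.2)$ for $K=2$ and $(0.7, 0.1, 0.2)$ for $K=3$, reflecting
typical background/intermediate/spot area fractions of a target mask.
Block means and SDs seed $\mu,\sigma$. Deterministic initialization makes
every fit exactly reproducible without seeds.

**Label ordering.** Components are re-sorted by mean after every M-step,
so the identification constraint holds continuously instead of only at
convergence.

**Termination.** EM stops when the relative log-likelihood gain drops
below $10^{-6}$ or after 500 iterations (flagged `not_converged`). Two
further stopping rules keep the recorded likelihood trace monotone, which
the test suite asserts on a thousand randomized fits. First, in a
censored fit the censored label is attached to the *last* (largest-mean)
component, so when a regular component crosses the censored one near $S$
the relabeling can lower the observed likelihood; when that happens the
algorithm keeps the best iterate and stops (`em_stalled`). Second, when
the censored component's mass lands entirely on saturated pixels, the
foreground location is no longer identifiable and iteration stops at the
last proper iterate with `degenerate_fg` set. Both situations are
boundary pathologies of stress inputs; on realistic masks neither occurs.

**Model selection.** AIC/BIC use $-2\ell + \text{penalty}$ with $3K-1$
free parameters. The selection rule is made precise as: *the smallest $K$
whose criterion lies within `relThreshold` (default 0.001, i.e. 0.1%) of
the minimum*. This prefers parsimony when a more complex model wins by a
sliver, and is the rule used throughout the simulation study.

## Target masks and image I/O

Masks are built by nearest-center assignment: every pixel joins the
closest spot center, pixels farther than one pitch from all centers stay
unassigned, and edge cells are clipped at the borders and flagged. On an
orange-crate (hexagonally packed) lattice this produces hexagonal cells
without any explicit polygon rasterization, and it degrades gracefully
when the printed lattice is imperfect; on a rectangular lattice it
produces rectangles. Coordinates are 0-based $(row, col)$; centers are
supplied as $(x, y) = (col, row)$ to match scanner conventions. GenePix
result tables carry centers in micrometres; the micron-to-pixel factor is
a required argument rather than auto-detected, because the files do not
reliably carry the scanner resolution.

Images must be single-channel 16-bit grayscale TIFF. Extracted pixel
values are clamped to $[0, S]$, so passing an $S$ below 65535 applies an
artificial saturation threshold — the mechanism used to generate
controlled censoring experiments from uncensored images
(`applyCensoring()` does the same to masks in memory).

## What the simulation emulates

`makeScenario()` reproduces the study design used to validate the method:
masks of 500 exchangeable pixels drawn from a two- or three-component
mixture mimicking immunosignaturing arrays, with the foreground placed so
that 10%, 40% or 70% of its draws saturate. Fixed parameters: $K=2$ —
$\pi=(0.8,0.2)$, background $N(8000,2000^2)$; $K=3$ —
$\pi=(0.7,0.1,0.2)$, background $N(2000,1000^2)$, intermediate
$N(15000,6000^2)$. The foreground scale is fixed at $\sigma_K = 6000$
(the intermediate-component scale) and its location solved from the
saturation quantile, $\mu_K = S - \sigma_K\Phi^{-1}(1-p_{sat})$, so the
target saturation fraction holds exactly in expectation. Values are
continuous (the model is continuous and scanners' integer rounding is
immaterial at these scales) and are not truncated at zero — the
$N(2000,1000^2)$ background has ~2% of its mass below zero, and clamping
would bias the background mean upward by ~8 ADU. Three analysis arms see
identical data per trial: GMM0 (regular mixture, uncensored data), CGMM
(censored mixture, censored data), GMM1 (regular mixture, censored
data). Per-trial seeds derive from one master seed, so summaries are
byte-identical across reruns.

What the simulation does *not* emulate: spatial structure (pixels are
exchangeable within a mask — no donut/peak geometry, no spatial
correlation), gridding error, optical flare around bright spots, or
integer quantization. Passing the simulation therefore validates the
estimator and the selection rule under the stated mixture conditions, not
the full image-processing pipeline on real arrays; the grid/extraction
code is validated separately against brute-force geometric oracles and
synthetic images.

Problem sizes used by the checks: the acceptance script and the
acceptance tests run the full design — 1000 trials of 500-pixel masks per
design point (roughly 10 s per design point and arm); unit tests use
smaller masks and trial counts.

## Known limitations and observed discrepancies

* The censored component must retain weighted mass on at least one
  uncensored pixel; a spot whose foreground is entirely saturated is
  reported at $S$ with a `degenerate_fg` flag rather than extrapolated.
* Only right censoring at a known threshold is supported (no left or
  interval censoring, no robust/non-Gaussian components).
* The foreground truth of the validation study is under-determined: with
  $\sigma_K$ fixed at 6000, the regular-mixture arm (GMM1) fitted to
  heavily censored three-component data recovers the intermediate
  component cleanly and selects $K=3$ essentially always, rather than
  losing $K$ in a third of trials as reported for the original study;
  its foreground bias is negative and grows with the saturation rate, as
  expected, but its magnitude depends strongly on that unknown scale.
  The censored arm (CGMM) is insensitive to this choice — its biases stay
  below 0.03 in absolute value at every design point.
* Background-parameter biases of order $10^{-3}$ are at the resolution
  limit of what the published study pins down: they depend on
  generator details (e.g. truncation at zero) that are not stated, and on
  Monte-Carlo noise of the same order. The package reports its own
  Monte-Carlo standard errors (`relativeBiasSE()`) alongside the biases.
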
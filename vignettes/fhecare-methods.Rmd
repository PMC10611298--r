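---
title: "Methods: torus FHE, quantized encrypted inference and the federated simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: torus FHE, quantized encrypted inference and the federated simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fhecare` simulates, at desk scale, a remote-healthcare network in which
hospitals evaluate classifiers on patients' cardiac records without ever
seeing the records in the clear. This vignette is the package's account of
the mathematics it implements, the parameters that matter, and the design
choices that were genuinely open.

## The torus FHE core

### Discretized torus

The plaintext and ciphertext domain is the real torus $\mathbb{T} =
\mathbb{R}/\mathbb{Z}$, discretized as integers modulo $2^{32}$: the
integer $v$ stands for $v/2^{32} \in [0, 1)$. All torus arithmetic is
exact modular integer arithmetic carried in doubles (every intermediate
stays far below $2^{53}$), so there is no floating-point drift anywhere in
the core; noise enters only where the scheme says it does, as a rounded
Gaussian of configurable standard deviation. Ties in every rounding step
resolve half-up — base R's round-half-even would make decomposition ties
platform lore rather than a documented convention.

### Ciphertexts

An **LWE sample** is $(\mathbf{a}, b)$ with uniform mask $\mathbf{a} \in
\mathbb{T}^n$ and body $b = \mathbf{a}\cdot\mathbf{s} + \mu + e$ under a
binary key $\mathbf{s}$. The *phase* $b - \mathbf{a}\cdot\mathbf{s}$
recovers the message plus noise; decryption rounds the phase onto a small
equispaced message set. A **TLWE sample** is the same construction over
negacyclic polynomials $\mathbb{T}_N[X] = \mathbb{T}[X]/(X^N+1)$ with a
binary polynomial key, and a **TGSW sample** stacks $(k+1)\ell$ TLWE
encryptions of zero shifted by $m \cdot h$, where $h$ is the gadget matrix
with entries $1/B_g^p$. Each ciphertext carries a tracked worst-case noise
variance as test instrumentation; it composes additively under the linear
operations and is asserted against in the property suite.

### Gadget decomposition

Every coefficient is approximated by its nearest multiple of
$1/B_g^\ell$ and expanded in signed base-$B_g$ digits in
$(-B_g/2,\, B_g/2]$ (the tie $+B_g/2$ is kept; larger residues carry
upward). The reconstruction error is at most $\varepsilon =
1/(2B_g^\ell)$, which the tests verify with zero violations over
thousands of random draws. The external product contracts the digit
matrix against the TGSW rows — the inner multiply-accumulate, exact mod
$2^{32}$ in `uint64`, is the one compiled kernel in the package
(`src/negacyclic.cpp`).

### Key switching

To re-express a ciphertext under another key, each mask coefficient is
rounded to the nearest multiple of $2^{-t}$ (so the rounding error per
coefficient is below $2^{-(t+1)}$), expanded in binary digits, and
contracted against precomputed encryptions of $s'_i \cdot 2^{-j}$:
$(\mathbf{0}, b) - \sum_{i,j} a_{i,j}\,\mathrm{KS}_{i,j}$. With $t = 8$
and a 64-dimensional extracted key the rounding term dominates the whole
pipeline's output noise (standard deviation about $9\times10^{-3}$ on the
torus), which is why message points are kept at least $1/8$ apart.

### Bootstrapping

Bootstrapping maps an arbitrary-noise input onto one of two fixed
messages with output noise *independent of input noise*. Conventions, all
of them tested:

* Two-point encoding $(\mu_0, \mu_1)$ with derived constants
  $\bar\mu = (\mu_0+\mu_1)/2$ and $\bar\mu' = \mu_0 - \bar\mu$, exact on
  the discretized torus. The defaults $(0, 1/8)$ are configuration, not a
  scheme constant.
* The test vector is the staircase $\bar\mu'(1 + X + \cdots + X^{N-1})$;
  multiplying a staircase by $X^N$ is exactly negation (negacyclic wrap),
  and that offset is applied inside `bootstrap()` so that phases in the
  *upper half-torus* $[0, 1/2)$ select $\mu_1$ and phases in $[1/2, 1)$
  select $\mu_0$. A phase of exactly zero therefore resolves to $\mu_1$.
* The accumulator loop uses the CMUX form
  $\mathrm{ACC} \leftarrow \mathrm{ACC} + \mathrm{BK}_i \boxdot
  (X^{\bar a_i}\mathrm{ACC} - \mathrm{ACC})$, the exact-identity
  realization of multiplying by $h + (X^{\bar a_i}-1)\mathrm{BK}_i$.
* Sample extraction converts the accumulator's constant coefficient into
  an LWE sample under the flattened ("extracted") TLWE key; the final key
  switch back to the original key is optional. Terminal results that the
  key owner will decrypt directly skip it, avoiding the dominant noise
  term at the cost of a larger ciphertext.

### Grid-aligned fresh encryptions

Blind rotation rescales phases to $2N$ slots, rounding each mask
coefficient independently; over $n$ coefficients the rounding drift has a
standard deviation near one slot, which would be fatal for messages that
sit one slot apart. Fresh record encryptions and the key-switching key
therefore draw their masks from the $2N$-slot sub-grid, making the
rescaling exact: an integer score of $+1$ versus $-1$ is then classified
deterministically. This costs mask entropy and is one of several reasons
the parameter sets claim **no** cryptographic security.

### Parameter presets

| preset | $n$ | $N$ | $k$ | $B_g$ | $\ell$ | $t$ | fresh-LWE sd | TLWE sd | KSK sd |
|--------|----|-----|----|------|-------|----|--------------|---------|--------|
| TOY    | 16 | 64  | 1  | 64   | 3     | 8  | $2^{-20}$    | $2^{-25}$ | $2^{-24}$ |
| DEMO   | 64 | 256 | 1  | 64   | 3     | 10 | $2^{-22}$    | $2^{-27}$ | $2^{-26}$ |

TOY keeps a bootstrap near 15 ms in pure-R-plus-one-kernel form, so the
full property suite (1000 round trips, 1000 gadget draws, 500 key
switches, 600 bootstraps) runs in well under a minute; DEMO doubles the
phase resolution for the simulator. The noise levels are chosen so the
gate margins sit at 5–9 standard deviations of the composed noise —
comfortable for exactness, meaningless for security.

## Quantized encrypted inference

Features are quantized per-feature affinely to 3-bit levels calibrated on
training data (`round((x - min)/scale)`, clamped outside the calibrated
range). Levels ride on the $2N$-slot phase grid ($q \mapsto q/2N$), so
integer-affine homomorphic arithmetic keeps scores on the grid and the
**headroom** bound $|score| \le N - 1$ (63 at TOY) guarantees the sign of
a score is readable from its half-torus. Model quantization scales float
weights jointly by the largest $\lambda$ whose rounded integer weights
respect the headroom for *every representable input* — checked
exhaustively in tests.

* **Linear models**: one homomorphic dot product plus bias, one
  bootstrap extracting the sign as the label.
* **Trees** (depth ≤ 3): each comparison $x_j \le \theta$ is a
  bootstrapped sign of $\theta - x_j$ (exact on the grid); path
  indicators are one-hot products of comparison bits via bootstrapped AND
  gates over the $\{0, 1/4\}$ bit encoding (threshold $3/8$, margin
  $1/8$); the label is the sum of label-1 leaf indicators. Deeper trees
  are rejected toward the plaintext-quantized path.
* **Stump ensembles**: each comparison bootstrap lands directly on the
  stump's integer leaf increment, so the decrypted integer score equals
  the plaintext ensemble score exactly.

The agreement contract is strict equality between decrypted encrypted
predictions and the *plaintext quantized* model — not the float model;
quantization loss is a separate, visible step.

## The plaintext clinical stack

The pipeline follows the standard tabular recipe: median/mode imputation
(row-dropping available), presence/absence binarization of the 5-level
disease label, a default 10-feature input set (age, sex, cp, trestbps,
chol, fbs, restecg, thalach, exang, oldpeak — the commonly used subset;
configurable), one-hot encoding with learned level sets, a seeded
stratified 80:20 split, min–max normalization by *train* statistics only
(test values may leave $[0,1]$; never clipped), and balanced class
weights $w_c = n/(2\,\mathrm{count}_c)$, whose defining identity
$\sum_c w_c\,\mathrm{count}_c = n$ holds exactly.

The four classifiers ride on the standard engines — `glm` (weighted
logistic; the "linear regression" name is accepted as an alias since that
model is evaluated as a thresholded classifier), `e1071::svm` (libsvm,
linear kernel, $C = 1$), `rpart` (weighted Gini, `maxdepth` 10,
`minbucket` 10, `minsplit` 100) and `xgboost` (10 rounds, learning rate
0.1, depth 3) — behind one `fit_classifier()` surface with the
hyperparameter snapshot stored on the fit. AUROC is computed by the
package's own midrank statistic and cross-checked in tests against an
$O(n^2)$ concordant-pair oracle.

## The federated protocol

Severity drives scheduling: from a patient's recent stream the maximum
heart rate is compared against age-adjusted thresholds (severe when
$\mathrm{HR} \ge 0.9\,(220-\mathrm{age})$ or $\ge 150$; moderate at the
0.75/110 cutoffs; ties take the more severe mode — the thresholds are
configuration, chosen to echo standard exercise-physiology rules of
thumb). Mode 1 fans out to every prime server in one tick; Mode 2 relays
through the roster in order; Mode 3 buffers batches of at most 10
patients flushed at a configurable 1–5-minute interval (default 60 s).
The cloud holds one bounded queue per authorized server (default
capacity 10) plus a FIFO wait queue; job conservation
(accepted + waiting + completed = submitted) is a tested invariant.
Aggregation follows the exclude-origin rule: a prime-origin job collects
the other $N-1$ results through the cloud and appends its own locally.
Missing prime results flag the result set incomplete (the retry policy —
three attempts, then the flag — is a package choice; the protocol leaves
it open).

Patient–examiner messaging uses an abstract sealed-box envelope: the
simulator enforces the access-control semantics (only the named recipient
can unseal) without implementing real public-key cryptography, keeping
the two key systems — FHE evaluation keys, which are modeled as public
material, and identity envelopes — explicitly separate. The examiner
averages the per-prime scores (majority vote available as a config
alternative).

The privacy audit is a taint check, not a formality: every message a
hospital, the cloud or a prime server ever receives is serialized and
scanned for each patient's raw feature signature, quantized signature and
decrypted label sequence. Sealed envelopes serialize as digests, exactly
as a server would see them.

## The synthetic generator

`generate_heart_data()` emulates the 14-attribute UCI heart-disease
schema: marginal feature distributions loosely shaped on published
Cleveland summary statistics, a logistic label model over standardized
features with a root-found intercept hitting the configured prevalence
(default 0.46), severity expansion of positive labels into levels 1–4,
and injectable missingness that never touches the target column. It makes
**no claim of distributional fidelity**: features are drawn independently
(no real-world correlation structure, no site effects, no measurement
drift), so a pipeline that passes every test here is validated for its
*mechanics* — exactness, invariants, protocol semantics — not for
clinical performance on real cohorts. Published benchmark metrics on the
real UCI tables are out of reach of this generator by design, and the
package does not attempt to reproduce them.

`make_separable_fixture()` provides the training-sanity oracle: a known
unit weight vector, a margin band cleared around the boundary, optional
label-independent noise; classifiers must reach 95% accuracy on it and
logistic fits must recover the weight direction (cosine ≥ 0.9 at
$n = 2000$).

## Numerical and degenerate-input choices

* round-half-up everywhere a tie can occur (quantizer, decomposition,
  rescaling, decryption).
* constant training columns normalize to zeros with a warning; an
  entirely missing column is an error.
* single-class training labels and single-class AUROC are errors/`NA`
  with a warning, never silent.
* all randomized operations take an explicit seed and restore the
  caller's RNG state; generators are pure functions of (config, seed).

## Problem sizes

The test suite and the acceptance script run everything at TOY
parameters: 1000-trial round trips, 1000 gadget draws, 500 key switches,
600 refresh bootstraps, 100-record encrypted/plaintext agreement for the
linear and depth-3 tree models, a 5-patient full-network simulation, and
$n = 2000$ parameter recovery. These sizes were chosen so the entire
suite completes in a few minutes on one CPU while every statistical
assertion retains a comfortable margin.

## Known limitations

* The cryptographic parameters are educational; no security level is
  claimed or estimated, masks are deliberately grid-restricted, and no
  FFT/NTT acceleration is implemented.
* Encrypted evaluation covers linear models, depth-≤3 trees and small
  stump ensembles; full-size boosted forests run plaintext-quantized.
* The discrete-event clock is logical, not wall-clock; timing claims are
  out of scope.
* The sealed-envelope layer is an access-control simulation only.
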
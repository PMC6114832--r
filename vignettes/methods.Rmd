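---
title: "Position-propensity models for pseudouridine site prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-propensity models for pseudouridine site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoU)
```

# The problem

Pseudouridine (Ψ) is the most abundant post-transcriptional RNA
modification: an isomer of uridine installed by pseudouridine synthases in
tRNA, rRNA, snRNA and mRNA. Experimental mapping (CMC-based primer
extension, Ψ-seq and relatives) is laborious, so sequence-based classifiers
are used to prioritize candidate sites. The unit of prediction is a short
segment of length $2\xi + 1$ centered on a uridine,

$$R_\xi(U) = N_{-\xi} \cdots N_{-1}\, U\, N_{+1} \cdots N_{+\xi},$$

labeled positive when the central U is an experimentally validated Ψ site
and negative when it is not. Curated benchmark collections of this form use
$\xi = 10$ (21-nt segments, human and mouse) and $\xi = 15$ (31-nt,
yeast), balanced between classes. This package implements the full
modeling stack for such data: five feature encodings, a leakage-safe
leave-one-out protocol, SVM hyperparameter search, greedy forward feature
selection, and a sliding-window scanner for query sequences.

# Feature encodings

Five encodings turn a segment into a numeric vector. Two are plain k-mer
compositions:

* **NC** — the 4 nucleotide frequencies;
* **DC** — the 16 overlapping-dinucleotide frequencies (denominator
  $L - 1$).

**pseDNC** augments DC with $\lambda$ *tier correlation factors* computed
from physicochemical properties of dinucleotides (free energy,
hydrophilicity, stacking energy; shipped as a CSV resource). Each property
is z-scored across the 16 dinucleotides before use — the raw scales differ
by two orders of magnitude, and without standardization the stacking
energy column would dominate the correlation term. With $f_u$ the
dinucleotide frequencies and

$$\theta_j = \frac{1}{L-1-j} \sum_{i=1}^{L-1-j} \Theta(D_i, D_{i+j}),
\qquad
\Theta(D, D') = \frac{1}{n_p}\sum_k \left(P_k(D) - P_k(D')\right)^2,$$

the encoded vector is $d_u = f_u / (1 + w\sum_j \theta_j)$ for
$u \le 16$ and $d_{16+j} = w\,\theta_j / (1 + w\sum_j \theta_j)$. The
defaults $\lambda = 2$, $w = 0.5$, all three properties, are deliberately
modest: $\lambda$ must not exceed $L - 2$, and both parameters are
exposed in `psednc_config()` because published work using this encoding
rarely reports them — any reproduction of a pseDNC-bearing result should
treat them as a small sweep, not as known constants.

**PSNP / PSDP** are the position-specific propensity encodings, the part
of the stack that actually carries most of the signal. From a *training*
set, per-position occurrence frequencies are computed separately for the
positive and negative class, giving column-stochastic matrices $Z^+$ and
$Z^-$ ($4 \times (2\xi+1)$ over nucleotides, or $16 \times 2\xi$ over
overlapping dinucleotides), and the propensity matrix is their difference

$$Z = Z^+ - Z^-.$$

A segment is encoded by looking up its own nucleotide (dinucleotide) at
each position: component $j$ is $Z[N_j, j]$. Entries lie in $[-1, 1]$,
columns of $Z$ sum to zero, and the PSNP center column is identically
zero because both classes carry U there; the constant-zero center
component is kept so the vector length stays $2\xi + 1$ (a constant
feature is harmless to an SVM). Frequencies are maximum-likelihood counts
without pseudocounts — smoothing would silently change every downstream
number.

# Leakage-safe jackknife

The propensity matrices are fitted *from data*, so cross-validation must
refit them inside every fold: encoding a held-out sample with matrices
that were computed using that sample leaks its own class frequencies into
its features, and with per-position frequency differences this bias is
substantial at benchmark sizes. The jackknife here is therefore:

1. remove sample $k$;
2. fit $Z_{PSNP}$/$Z_{PSDP}$ on the remaining $n - 1$ samples;
3. encode both the training samples and sample $k$ with those matrices;
4. train the SVM on the $n - 1$ samples, score sample $k$;
5. aggregate the $n$ verdicts into confusion counts and metrics.

Internally step 2 is a count *downdate* (subtracting the held-out
sample's one-hot counts and renormalizing), which is algebraically
identical to refitting and keeps the protocol at one SVM fit per fold;
the test suite verifies downdate ≡ refit and that every fold's matrix
differs from the full-data matrix. Segment-local features (NC, DC,
pseDNC) are encoded once and cached — for recipes without propensity
features the per-fold encodings equal the global ones.

Leave-one-out was chosen over K-fold deliberately: it has no partition
randomness, so every number the package reports is unique and exactly
reproducible. Independent-test evaluation (`evaluate_independent()`) fits
matrices and SVM once on the full training set.

# Classifier and hyperparameters

The classifier is a C-classification SVM with RBF kernel, parameterized
by box constraint $c$ and *kernel scale* $s$ with
$K(x, y) = \exp(-\lVert x - y\rVert^2 / s^2)$. This is the MATLAB-style
convention; libsvm-based libraries (e1071 here) use
$\gamma = 1/s^2$, and the conversion is applied internally — getting it
wrong silently misplaces every published hyperparameter by a power of
two. Features are *not* standardized before the SVM: the encoders emit
bounded values, and rescaling would detach results from reported
$(c, s)$ optima. The solver tolerance is $10^{-3}$; across SVM
implementations accuracies can shift by roughly a point absolute, which
is the dominant reproduction variable for this class of model.

`grid_search()` runs the full jackknife at every $(c, s)$ cell; defaults
span $s \in \{2^{-3}, \dots, 2^{10}\}$ and
$c \in \{2^{-5}, \dots, 2^{10}\}$, and the whole per-cell table is
returned for audit. Ties are broken by higher accuracy, then smaller $c$
(flatter models), then larger $s$ (smoother kernels).

# Metrics

Evaluation uses the class-total formulation of the four standard
quantities, with $N^+$, $N^-$ the class sizes and $N^+_-$, $N^-_+$ the
false negatives and false positives:

$$\mathrm{Sen} = 1 - \frac{N^+_-}{N^+}, \quad
\mathrm{Spe} = 1 - \frac{N^-_+}{N^-}, \quad
\mathrm{Acc} = 1 - \frac{N^+_- + N^-_+}{N^+ + N^-},$$

$$\mathrm{MCC} = \frac{1 - \left(\frac{N^+_-}{N^+} + \frac{N^-_+}{N^-}\right)}
{\sqrt{\left(1 + \frac{N^-_+ - N^+_-}{N^+}\right)
       \left(1 + \frac{N^+_- - N^-_+}{N^-}\right)}}.$$

This is algebraically the Matthews correlation coefficient (the suite
checks the identity on $10^4$ random confusion tables). When the
denominator is zero — the classifier predicts one class for everything —
MCC is reported as 0 and flagged. AUC uses midranks, so it equals the
normalized Mann–Whitney statistic and the trapezoidal area under the
empirical ROC; ROC scores are the raw SVM decision values (threshold 0),
not calibrated posteriors — deterministic, and no extra fitting. Metrics
are kept at full precision internally; reports render percentages to two
decimals.

# Feature selection

`sfs()` is a greedy forward wrapper: round 1 grid-searches and
jackknife-scores each candidate feature type alone; each later round
scores every one-feature extension of the incumbent; the search stops
when no extension *strictly* improves the criterion (equality stops —
"convergence" needs a hard definition to be reproducible). The criterion
defaults to MCC with accuracy as tie-breaker. Hyperparameters are
re-optimized for every candidate recipe in every round, matching how
per-subset optima are reported in the field; whether published selections
re-ran their grids per round is usually unstated, so this is flagged as a
reproduction variable. The trace records every candidate table, and the
number of jackknife runs is logged and tested against
$\sum_r (|C| - r + 1)\,|grid|$.

# Scanning query sequences

`scan_sequence()` reproduces the deployment behavior: every uridine in
the query gets a $2\xi + 1$ window; windows overhanging a terminus are
completed by *mirror-image padding* — the sequence is reflected about its
terminal nucleotide, the terminus itself excluded from the reflection,
ping-ponging if the deficit exceeds the sequence length. Excluding the
terminus avoids duplicating the boundary base and leaves the operation
defined for any deficit. Queries must be at least $2\xi + 1$ nucleotides
(21 for the human/mouse presets, 31 for yeast). DNA-style input is
accepted (T → U silently); any other symbol, including ambiguity codes,
is a loud error rather than a skipped site. All reported coordinates are
1-based positions of the central U. `species_preset()` ships the three
deployable configurations (human: PSNP + DC, $s = 2$, $c = 8$; yeast:
DC + PSNP + pseDNC, $s = 0.25$, $c = 2$; mouse: PSNP + DC, $s = 1$,
$c = 2$).

# The synthetic benchmark generator

Real Ψ benchmarks cannot be redistributed with the package, so the test
and acceptance machinery runs on synthetic datasets that emulate their
*structure*: balanced classes of fixed odd-length segments over
{A, C, G, U} with an invariant central U, where positives carry a
class-conditional position-specific skew. At each biased position the
positive class draws a planted nucleotide with probability
$b + (1 - b)/4$ (bias strength $b \in [0, 1]$); negatives and all other
positions are uniform. Defaults — $\xi = 10$, 100 segments per class,
$b = 0.6$, four biased positions at offsets $-2, -1, +1, +2$ from the
center — were fixed once as a realistic motif-like flank signal at
benchmark-like scale. $b = 0$ is an exchangeable null; $b = 1$ makes the
planted positions constant in positives, hence separable. Generation is
bit-reproducible for a fixed seed, and a fixed planted motif can be
supplied to draw train and test sets from the same distribution.

What the generator does *not* emulate: dinucleotide and compositional
structure of real transcriptomes, sequence-identity redundancy between
segments, class imbalance, and any biological coupling between positions.
Passing tests on synthetic data therefore demonstrate correctness of the
machinery (encoders, leakage control, selection logic, metrics), not
predictive performance on real Ψ data.

# Numerical and degenerate-case choices

* Property z-scores use the sample standard deviation over the 16
  dinucleotides; the normalization check tolerance is $10^{-9}$.
* Propensity fitting requires at least one segment per class; the
  jackknife requires at least two per class so every fold's training set
  contains both.
* A **balanced leave-one-out caveat**: on data whose features carry no
  signal, an over-smooth kernel (kernel scale far above the feature
  magnitudes) collapses the SVM to a training-majority vote, and in
  balanced leave-one-out the held-out sample's class is always the
  training minority — accuracy then lands far *below* chance. This is a
  known pathology of the protocol, not of the implementation. The null
  checks therefore select hyperparameters by the same grid-search
  procedure used for signal-bearing data, under which null accuracy sits
  in the binomial chance band.
* libsvm solutions depend slightly (≈ $10^{-4}$ in decision values) on
  training-row order; aggregated jackknife verdicts are order-invariant
  and the suite asserts exact verdict equality under permutation.
* Decision threshold for calling a site is 0; the deployment threshold of
  the original web service is not published, and 0 is the natural choice
  for an uncalibrated margin.

# Problem sizes used in checks

The shipped tests and the acceptance script run jackknives at 100–200
segments, grids of 4–6 cells and forward selection over all five feature
types at $n = 200$ — sizes at which the full stack (≈ $10^3$–$10^4$ SVM
fits end to end) completes in a few minutes while every statistical
property being asserted (planted-signal recovery above 0.75 accuracy at
$b = 0.6$, null behavior at chance, separability at $b = 1$) is
well-resolved. Benchmark-scale runs ($n = 990$, $\xi = 10$) take a few
minutes per jackknife on one CPU.

# Known limitations

* Only $K = 2$ pseudo-composition (pseDNC) is implemented, with the three
  shipped properties; there is no general PseKNC.
* No backward/floating selection; no per-dimension filtering inside a
  feature type.
* No probability calibration and no classifiers beyond the RBF-SVM.
* K-fold CV and bootstrap are intentionally absent; leave-one-out plus
  independent tests cover model assessment here.
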
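---
title: "Estimating dynamic coupling by rank correspondence of state-space reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dynamic coupling by rank correspondence of state-space reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Given two simultaneously observed time series $x_t$ and $y_t$, we want to
know whether the system generating $x$ dynamically drives the system
generating $y$, in which direction, and how strongly — without assuming a
parametric model of either system. State-space-reconstruction (SSR) methods
approach this through Takens' theorem: the delay-coordinate map
$x_t \mapsto (x_t, x_{t+\tau}, \dots, x_{t+(D-1)\tau})$ embeds the
attractor of the full dynamical system into $\mathbb{R}^D$, up to a smooth
invertible distortion. If $x$ drives $y$, the driven variable $y$ carries
information about its driver, so the reconstruction $M_Y$ built from $y$
alone can be smoothly mapped onto the reconstruction $M_X$; the converse
fails when the coupling is one-way. Convergent cross mapping (CCM) tests
this by cross-predicting one variable from nearest neighbors in the other's
reconstruction. The method at the core of this package, convergent cross
sorting (CCS), replaces the local neighborhoods with a global comparison of
*distance ranks*, which behaves much better on short, noisy, or oscillatory
records.

# The CCS statistic

For each variable the package z-scores the series (toggleable via
`normalize`), builds the delay embedding, and computes Euclidean distances
between all admissible pairs of time points — pairs closer in time than a
Theiler-style exclusion window (default $D\tau$ samples) are discarded so
that trivially adjacent points do not dominate the low ranks. Distances in
each manifold are converted to ascending ranks $R_X$, $R_Y$ with ties
averaged. The per-pair rank error is $ERR = R_X - R_Y$.

Direction enters only through the ordering of these errors. For
score$(x \to y)$ the errors are ordered by the rank in the manifold of the
*driven* variable, $R_Y$: if $x$ truly drives $y$, small distances in $M_Y$
must correspond to small distances in $M_X$, so $|ERR|$ conditioned on low
$R_Y$ should be small. Squared errors are normalized against the
expectation under uncorrelated rankings,

$$NERR^2 = \frac{null - ERR^2}{null},$$

so that 1 means perfect rank correspondence and 0 chance level, and the
cumulative mean of $NERR^2$ over the $k$ lowest conditioning ranks is
formed as a function of the normalized rank $k/n$. The curve is thresholded
at a maximum rank fraction (default 0.25) and fit by least squares to
$a e^{-b r} + c$ with $b \ge 0$; the score is the intercept $f(0) = a + c$,
clipped to $[-1, 1]$. Extrapolating from the fitted curve estimates the
limiting low-rank correspondence while borrowing strength from larger
scales, where the cumulative average is far less variable than the raw
low-rank errors.

## The null expectation is rank-dependent

The package supports two normalizers. For two independent uniform rankings
of $n$ pairs, $E[(R_X - R_Y)^2] = (n^2-1)/6$ marginally. But conditioned on
one rank being $r$,

$$E[(R_X - r)^2] = \frac{n^2-1}{12} + \Big(\frac{n+1}{2} - r\Big)^2,$$

which is roughly *twice* the marginal value at the extreme ranks. Since the
score extrapolates the curve at low conditioning ranks, normalizing there
against the flat marginal value would push genuinely uncorrelated series
toward a score of $-1$ rather than $0$. The conditional (rank-dependent)
null is therefore the default (`nullMode = "conditional"`); it calibrates
independent series to scores averaging 0 (verified by simulation in the
test suite), while identical series score 1 under either normalizer. The
marginal form remains available for comparison.

## Numerical choices

- **Ties** get average ranks; stable under the duplicate distances common
  in coarsely quantized data.
- **Exponential fit**: `minpack.lm::nlsLM` with starting values taken from
  the curve ends and a box constraint $b \ge 0$; three parameters are the
  minimal family with a free asymptote and intercept. If the fit does not
  converge (for instance on an exactly constant curve), the intercept of a
  linear fit on the lowest decile of the thresholded curve is used and the
  score is flagged `fitOk = FALSE`.
- **Pair budget**: beyond `maxPairs` (default $2 \times 10^6$) pairs are
  uniformly subsampled with a seeded RNG — an explicit approximation for
  long records.
- **Degenerate inputs** (constant channels, all-zero distances) are
  errors, not silent zeros.

# The CCM baseline

CCM is implemented exactly as the comparison method: the $D+1$ nearest
neighbors of each point in the driven variable's reconstruction, weighted
by $w_i = e^{-d_i/d_1}$ (collapsing onto exact matches when $d_1 = 0$),
cross-map an estimate of the driver; the score is the Pearson correlation
between estimates and truth. Two conventions are pinned once and used
everywhere. First, direction: estimating $y$ from $M_X$ yields
CCM$(y \to x)$ — a manifold can only reconstruct a variable that drives
it. Second, alignment: each delay vector estimates the driver's value at
its *most recent* coordinate time, the standard backward-lag
shadow-manifold convention, so estimates use only the driven variable's
present and past. Both methods share the same exclusion window and
normalization defaults, so comparisons differ only in the correspondence
statistic.

# Simulated study systems

Three standard system classes cover the main signal regimes:

- **Coupled logistic maps** (deterministic, discrete, chaotic):
  $x_i(t+1) = x_i(t)\,[r_i - r_i x_i(t) - \sum_j K_{j\to i} x_j(t)]$, the
  standard benchmark form in the cross-mapping literature. Growth rates
  default to draws from $U(3.6, 4.0)$. States pushed out of $(0,1)$ by
  strong coupling or dynamical noise are clipped into the margin;
  non-finite trajectories are resampled with fresh initial conditions.
- **Coupled Van der Pol oscillators** (deterministic, continuous,
  approximately periodic): $\ddot{x}_i = \mu_i(1 - x_i^2)\dot{x}_i - x_i +
  \sum_j K_{j \to i}(x_j - x_i)$, diffusive coupling by default (direct
  forcing behind a switch), integrated by fixed-step RK4 (`dtInt = 0.05`,
  downsampled by 4). Dynamical noise is injected into the velocity each
  step scaled by $\sqrt{dt}$, so its intensity is step-size independent.
  Stiffness defaults to $U(0.5, 2.5)$; 50 nominal periods of burn-in.
- **Coupled AR models** (linear, stochastic): innovations are the
  dynamical noise (scale 1 by default — an AR model without innovations
  decays to a constant); the joint companion matrix must have spectral
  radius below 1.

Measurement noise is Gaussian, added to the finished series at a given SNR
in dB, with signal magnitude taken as the RMS of the mean-removed channel
(0 dB means noise RMS equals signal RMS). Dynamical and measurement noise
are orthogonal controls: with both off, trials are bit-reproducible from
their seeds.

## Detection experiments

Detection trials use three-variable networks free of transitive causal
paths — an indirect influence without a direct edge would make the
pairwise ground truth ambiguous — cycling a common driver, a common sink,
and a bidirectional pair with a bystander. Both edges of a trial share one
coupling strength drawn per trial from `defaultKRange` (logistic maps:
$U(0.02, 0.3)$, spanning barely detectable to strong); intrinsic
parameters are redrawn per variable and trial. All six directed pairs are
scored with a shared embedding (logistic maps: $D = 2$, $\tau = 1$) so
scores are commensurable, pooled across 200 trials, and summarized by the
Mann–Whitney ROC AUC with a stratified percentile bootstrap (1000
resamples) for the confidence interval. Pooling directed scores (rather
than averaging per-trial AUCs) matches the one-ROC-per-condition design of
the detection analysis.

The exact generating parameters behind the published detection figures are
not part of the public record, so these ranges are the package's declared
study conditions: they were fixed once, at values that put short-series
detection in the partial-accuracy regime the published operating points
describe (CCS AUC near .78 and CCM near .64 at $L = 50$ noise-free;
CCS near .75 at the top of the dynamical-noise sweep,
$\epsilon \in \{0, 0.005, 0.01, 0.02, 0.04\}$ for the maps), and the
acceptance suite re-verifies those operating points from scratch at 200
trials. The sweep top is where per-step state perturbations reach roughly
16% of the signal's standard deviation.

## What the generator does and does not emulate

The synthetic systems exercise chaotic, periodic/synchronous, and
stochastic regimes, third-party confounds (common driver), and both noise
types — the failure modes that matter for cross-mapping methods. They do
not emulate nonstationary spectra, 1/f backgrounds, volume conduction, or
shared reference artifacts of real electrophysiology; passing tests on
these systems demonstrates correctness of the machinery and qualitative
robustness, not field performance on any particular recording system.

# Windowed network states

For multichannel recordings, `windowedCCS` slides a window across
contiguous epochs (defaults mirror an LFP-style setup: 1 s epochs, 400 ms
windows, three windows tiling each epoch) and computes all $n(n-1)$
directed scores per window — a 6-dimensional state vector for three
channels. `clusterStates` standardizes and whitens these vectors, runs
seeded k-means (default $k = 5$, 25 restarts) in the full whitened space
(the two-component PCA projection is for display only), and back-transforms
centroids to raw score units; the back-transformed centroids equal the
cluster means exactly, which the tests check. Sequences of state labels
within an epoch are compared up to cyclic rotation — epochs cut from
longer events carry no meaningful phase — via the lexicographically
smallest rotation. Pattern extremeness is reported as
$-\log_{10}$ of a binomial tail probability under a
uniform-over-canonical-classes null (the number of classes follows from
Burnside's lemma); this null is a deliberate, simple choice — a rank-aware
Monte Carlo alternative (`null = "simulation"`) asks instead how often the
$n$-th most frequent pattern under uniformity beats the observed count.
Centroid edges with negative values are conventionally omitted from network
diagrams but always retained in the data.

A scripted generator (`syntheticWindowedScores`) produces windowed score
vectors from known regime centroids plus isotropic noise for validating the
clustering pipeline end to end (Hungarian-matched centroid RMSE below the
injected noise scale), and `regimeSwitchTriad` integrates three Van der Pol
oscillators through scripted coupling switches — with state carried
continuously across switches — as a synthetic stand-in for a multichannel
neural recording. No claim is made of reproducing any real recording's
numbers.

# Significance

`ccsSignificance` uses circular-shift surrogates: the second series is
rotated by a random offset larger than the exclusion window, preserving
each series' dynamics while destroying their alignment, and the one-sided
p-value uses the plus-one estimator $(1 + \#\{s \ge s_{obs}\})/(1 + N)$,
never exactly zero.

# Problem sizes and determinism

The test suite runs its statistical checks at the sizes the analyses
prescribe where that is cheap (200 trials for the detection operating
points and direction recovery) and at reduced replicate counts for
auxiliary trend checks; each test states its size. Every stochastic
function takes an explicit seed, derives child seeds for nested draws, and
restores the caller's RNG state, so all experiments are exactly
reproducible.

# Known limitations

- Scores of strongly synchronized oscillators saturate near 1 in both
  directions; direction is then genuinely unidentifiable from ranks alone.
  Small dynamical noise breaks the saturation.
- The rank-correspondence null assumes unstructured rankings; two
  *independent periodic* signals have highly structured distance ranks, so
  individual CCS scores for such pairs are high-variance (symmetric under
  label exchange, but not tightly centered at 0). Surrogate testing, not
  the raw score, is the reliable significance tool there.
- Automatic embedding-parameter selection is unreliable below roughly 100
  samples; the harnesses therefore use fixed per-system defaults, and every
  analysis accepts explicit `dim`/`lag` overrides.
- CCS scores are bounded and saturate under strong coupling, compressing
  resolution among strongly coupled pairs (small noise alleviates this).

```{r}
library(crosssort)
tr <- makeFixture("lm-unidirectional", seed = 1)
scoreAllPairs(trialSeries(tr), method = "CCS",
              params = EmbeddingParams(2, 1))
```
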
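---
title: "Models and methods: synaptic depression vs persistent activity in change detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: synaptic depression vs persistent activity in change detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(changenet)
```

## The scientific question

In a go/no-go visual change-detection task, a subject watches one image
flashed repeatedly (250 ms on, 500 ms gray) and must report the rare moments
when the image identity changes. Solving the task requires a short-term
memory of the previous image across the gray gap. Two circuit mechanisms can
carry that memory:

* **persistent recurrent activity** — the hidden population keeps firing
  through the gap, as in classical working-memory models; or
* **short-term synaptic depression** — recently driven input synapses are
  weakened, so a *repeat* arrives through depressed synapses (weak response)
  while a *novel* image arrives through recovered ones (strong response).
  The memory lives in the synaptic state, not in ongoing spiking.

`changenet` implements both mechanisms as small trainable networks in an
identical task environment, plus the analysis battery whose signatures
discriminate them: the symmetry of the 8×8 transition response-probability
matrix, the change modulation index of input units, linear population
decoding, the collapse of population PCA distance with stimulus repetition,
and the response pattern around omitted stimuli.

## Task model

Sessions are generated by `generate_session()`. Time is discretized at
`dt = 0.25` s, one frame per stimulus presentation; each presentation is one
image frame followed by two gray frames. The number of presentations between
scheduled events is drawn from a truncated geometric law on [4, 11] — the
discrete analogue of the truncated exponential used experimentally. The
hazard (0.3 per presentation beyond the fourth, forced at the eleventh) is
not reported by the experiments; this value reproduces a right-skewed repeat
distribution across the full [4, 11] range. At each scheduled event the
image either changes to one of the other seven images (uniformly; a *go*
trial) or repeats (a *catch*/sham-change trial). We schedule go and catch
trials with equal probability (`p_go = 0.5`) so that all 64 transition
cells, including the diagonal, accumulate trials at comparable rates.

Five percent of eligible presentations are replaced by gray (*omissions*),
with two structural constraints taken from the task: an omission never
immediately precedes a change or sham-change presentation, and the event
presentations themselves are never omitted. The 5% hazard applies to the
eligible presentations. Omissions appear only in evaluation sessions, never
during training — they are a probe the models have not seen.

`repeat_index` counts presentations since the last scheduled event, starting
at 1 on the event itself. After a catch trial the physical run of identical
images continues, but the scheduler restarts its count; the [4, 11] bound
applies to the scheduler's count.

## Input model

The models see each image as a sparse non-negative 64-dimensional embedding,
standing in for the output of a fixed pretrained visual encoder.
`generate_embeddings()` draws, for each input unit, a tuning breadth of 1–4
images (probabilities 0.4/0.3/0.2/0.1), graded amplitudes across its tuned
images, and a lognormal per-image *saliency* factor (`sdlog = 0.3`) that
makes some images drive the population more strongly than others — the raw
material of asymmetric detectability. Per-image total drive is normalized
before the saliency factor is applied, so `saliency_spread = 0` yields
exactly balanced images.

The amplitude scale is set so a typical active unit receives drive ≈ 2
(`amp_scale = 2`). Under the synapse defaults this is the
depression-dominated regime — sustained drive of 2 depresses a synapse to a
steady-state resource fraction of 0.4 — so repeated images produce
substantial repetition suppression, as the encoder's active units do.
Gray frames and omitted frames deliver exactly zero input: the encoder
response to the mean-luminance screen is defined as 0. This convention has a
visible consequence discussed under *Limitations*.

## Synaptic depression

Depression follows the Tsodyks–Markram resource model in rate form. Each
input unit carries a resource fraction $x \in (0, 1]$:

$$\frac{dx}{dt} = \frac{1 - x}{\tau_x} - U\,x\,r(t)$$

with release fraction $U = 0.5$ and recovery constant $\tau_x = 1.5$ s.
The postsynaptic drive is $W (x \odot r)$: all synapses from one presynaptic
unit share its resource state. Because the ODE is linear in $x$, the
implicit backward-Euler step at $\Delta t = 0.25$ s has a closed form,

$$x' = \frac{x + \Delta t/\tau_x}{1 + \Delta t/\tau_x + U\,\Delta t\,r},$$

solved in one division rather than iteratively. The discrete fixed point
coincides exactly with the continuous steady state
$x^* = (1/\tau_x) / (1/\tau_x + U r)$, the update maps $(0,1]$ into $(0,1]$
for any non-negative drive, and it is monotone decreasing in $r$. At strong
drive the 250-ms implicit step lags the fast transient of the continuous
trajectory (about 3.5% on the first step at $r = 2$) while agreeing with a
1-ms explicit integration to within 2% everywhere at moderate drive
($r \le 1$) and sharing its fixed point at all drives; the tests pin both
regimes.

## Network architectures

All models are 64 input units → 16 rectified hidden units → 1 sigmoid
output (the decision variable), differing only in which pathways exist:

* **STPNet** — feedforward, with depression on the input synapses:
  $h_t = \mathrm{relu}(W_{ad}(x_t \odot \tilde r_t) + b_h)$.
* **RNN** — no depression, recurrent hidden layer:
  $h_t = \mathrm{relu}(W_{pl}\tilde r_t + W_{rec}\tilde h_{t-1} + b_h)$.
* **STPRNN** — both: adapting and non-adapting input blocks plus recurrence.
  Zeroing the adapting block recovers the RNN exactly; zeroing the
  non-adapting and recurrent blocks recovers STPNet (a tested identity).

$\tilde r_t$ is the input after multiplicative noise,
$\mathrm{relu}(r(1+\varepsilon))$ with $\varepsilon \sim N(0, 0.5^2)$
i.i.d.; the same noise form is applied to hidden activities. Multiplicative
noise preserves zeros (silent units stay silent) and non-negativity, and its
rectification bias is below half a percent at sd 0.5. Noise is applied to
the input before depression gating: it models encoder variability, which
drives release. The hidden bias $b_h$ is constrained non-positive — it is a
rectification threshold, $h = \mathrm{relu}(Wu - \theta)$ with
$\theta \ge 0$, enforced by projection after each optimizer step. Per-unit
thresholds are what allow the network to convert the graded
repeat-vs-change difference in drive into a decision under noise, and a
non-positive bias guarantees that zero input produces exactly zero
feedforward activity, matching the observed silence of depression-based
responses during gray screens and omissions. A free (sign-unconstrained)
bias breaks that silence: trained networks acquire positive biases and
tonically active hidden units.

Weights use He-uniform initialization; the recurrent block uses the uniform
$[-1/\sqrt{n_h}, 1/\sqrt{n_h}]$ convention. Depression state starts at rest
($x = 1$) and hidden state at zero at session start, with no resets between
trials — the task is continuous.

## Training

Training treats the task as per-presentation binary classification (change
vs repeat), with the loss masked to image-presentation steps. The loss is a
weighted binary cross-entropy (weight 5 on change presentations, mean over
masked-in steps) plus an L2 penalty (weight 0.001) on the mean squared
hidden activity, encouraging low firing rates. Optimization is ADAM
(learning rate 0.001, betas 0.9/0.999) with exact
backpropagation-through-time over one whole session per epoch (100 trials;
the epoch size is this package's choice). Behavioral responses are sampled
from a Bernoulli distribution on the output sigmoid; epoch d-prime is
computed from hit and false-alarm rates with rates clipped to
$[1/2n, 1 - 1/2n]$ of the relevant trial count, and training stops once
d-prime has been at or above 1.5 for 5 consecutive epochs (patience), or at
5000 epochs. Ten networks per architecture are trained from different
seeds; every reported result is an ensemble average. A training run is
fully deterministic given its seed: the master seed expands into sub-seeds
for embeddings, initialization and the noise stream.

## Analyses

**Response-probability matrix and Q.** Bernoulli-sampled responses at the
event presentations fill the 8×8 matrix of response probability per image
transition (catch trials on the diagonal). For the symmetry metric the
off-diagonal entries are centered on their mean, the diagonal is excluded
from the centering, from both matrix parts and from both norms, and
$Q = (\|M_{sym}\| - \|M_{anti}\|) / (\|M_{sym}\| + \|M_{anti}\|)$ with
Frobenius norms over off-diagonal entries. $Q$ is invariant under image
relabeling, so display ordering is cosmetic. Empty cells are reported as
missing, never as zero; $Q$ requires all off-diagonal cells populated, and
evaluation sessions are sized accordingly (2000 trials per model, ~18
trials per go cell) to keep the per-cell sampling noise from inflating the
anti-symmetric part.

**Change modulation index.** Per unit,
$(\bar r_{change} - \bar r_{pre}) / (\bar r_{change} + \bar r_{pre})$,
where the means run over change presentations and over the presentations
immediately before a change. Units with a negative mean on either class are
excluded (their index would leave [−1, 1]); so are zero denominators. The
alternative go-vs-catch contrast is available via `mode = "go-catch"`.
Input-unit responses are read *post-depression* ($x \odot \tilde r$) for
the adapting architectures and as the noised embedding for the RNN — the
quantity a downstream neuron sees.

**Decoding.** Linear SVMs (cost 1, no internal rescaling) with stratified
3-fold cross-validation decode image identity (8-way, chance 1/8) from all
non-omitted presentations, or change vs pre-change (binary, chance 1/2;
this pairing keeps classes balanced). Change-decoder weights come from a
fit on all included presentations, oriented so change scores positive, and
are correlated with the change modulation index per unit. Decoder
predictions on go and catch trials are compared with sampled behavior by
the Jaccard score against a 1000-shuffle null.

**Population geometry.** Presentation vectors are centered on the mean
across all image presentations (that mean defines the origin), a PCA is fit
per dataset, and mean distance from the origin is traced against repeat
index (1 = the event presentation) for the full Euclidean distance and the
absolute first-component projection. Components are retained to 95%
cumulative variance; rank-deficient data retain all available components.
Distances pool all images at a given repeat index. Adapting populations
collapse toward the origin over repeats; persistent-activity populations
stay flat.

**Omission analysis.** Response probabilities are tabulated for go trials,
catch trials, all non-omitted presentations, omitted presentations, and
post-omitted presentations, with the task's conditioning rule: a response
during the omission forces that trial's post-omitted contribution to zero
(the experimental trial logic aborts such trials). Consecutive double
omissions are excluded from both omission categories. The model's 750-ms
response window collapses to the single decision step at the scheduled
presentation time.

## The synthetic adapting population

`generate_synthetic_population()` provides ground truth for validating the
metrics: single-image-tuned neurons whose presentation responses are
`tuning × x(t) × (1 + noise)`, with `x` run through the same depression
dynamics. Ground-truth indices are computed by applying the estimator to
the noise-free traces, so recovery error isolates trial noise; at
`noise_sd = 0.2` and 200 neurons the estimator's mean absolute error is
under 0.05. With `U = 0` the population does not adapt: change decoding
collapses to chance and the repeat-distance curve flattens (the negative
controls).

## What the generator does and does not emulate

The synthetic module reproduces the task statistics (timing, truncated
repeat law, omission constraints), the sparsity and heterogeneity of
encoder embeddings, and depression-consistent adaptation with known ground
truth. It does **not** reproduce: natural-image feature correlations
between embeddings (each unit's tuned image set is independent), calcium
indicator dynamics or negative dF/F baselines (the exclusion rule is
exercised by noise, not by indicator artifacts), reward and timeout
economics, or a nonzero encoder response to the gray screen. Passing tests
therefore validate the machinery and its discriminating signatures, not a
quantitative fit to any particular recorded dataset.

## Limitations and known deviations

* With gray input defined as exactly zero, a trained STPNet's response
  probability *during* omissions settles near its zero-input operating
  point (≈ 0.1 in ensemble runs) — clearly below the RNN's (≈ 0.65–0.7),
  the diagnostic ordering. An encoder with a nonzero gray-screen response
  would raise it toward the false-alarm baseline, and would likewise raise
  the post-omission rebound; with the zero convention the dissociation is,
  if anything, sharpened.
* The implicit 250-ms depression step underestimates how fast strong drive
  depletes resources within the first presentation (see above); at the
  drives the embeddings produce this is a transient effect with no impact
  on steady-state adaptation depth.
* Facilitation, per-synapse (rather than per-presynaptic-unit) resources,
  spiking, and explicit inhibition are out of scope; so are LDA/isomap
  variants of the geometry analysis, though `repeat_distance()` computes
  from the raw response table and a different reducer can be applied to the
  same presentation vectors.
* Evaluation problem sizes (10 seeds per architecture, 2000-trial
  evaluation sessions, 100-trial training epochs) are the package
  defaults; they were chosen to keep per-cell trial counts and ensemble
  confidence intervals informative.
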
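---
title: "Adversarial ECG synthesis: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial ECG synthesis: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecggan)
```

## The problem

Labeled clinical ECG data are scarce, privacy-encumbered, and expensive to
annotate, which limits supervised training of diagnostic models.  One remedy
is a generative model that learns the distribution of real single-lead ECG
waveforms and synthesizes new, de-identified traces with the same
morphology.  `ecggan` implements such a model — a generative adversarial
network whose generator is a two-layer bidirectional LSTM and whose
discriminator is a one-dimensional CNN — together with the recurrent
autoencoder baselines it is usually compared against and the distortion
metrics used to score generated signals.

Everything here runs on plain R: the forward and backward passes of every
network (LSTM, GRU, vanilla RNN, 1-D convolution, max pooling, dense
layers), dropout and Adam are implemented in the package and verified
against central finite differences in the test suite.  This keeps the whole
pipeline inspectable and dependency-light; the price is speed, which is why
the defaults for *experiments* mirror the full protocol while the tests use
reduced geometries (see "Problem sizes" below).

## The adversarial model

The generator consumes, per sequence, a `T x d` matrix of Gaussian noise —
one `d`-dimensional noise vector per time step (`d = 5` at generation
time).  Two BiLSTM layers process the sequence: each layer runs an LSTM
forwards and an independent LSTM backwards (initial hidden and cell states
zero), and combines the two directional hidden states per step through
`tanh(h_fwd W_f + h_bwd W_b + b)`.  "100 cells" is read as 100 hidden units
*per direction* per layer (the standard BiLSTM convention); the layer
output width equals the hidden width.  A dropout layer (p = 0.5) precedes a
time-distributed affine head shared across time steps that emits two values
per step: a time-step element and a lead element.  Only the lead channel is
a waveform; the discriminator consumes it alone, and the time channel is
retained in outputs for serialization.  Because all recurrent weights are
shared across time, one set of weights generates sequences of any length —
training uses 3120-sample windows, generation commonly 400 or 250 samples.

The noise input deserves a note: the source text calls each noise point a
"d-dimensional one-hot vector" while also saying the noise is Gaussian.
A one-hot reading is incompatible with Gaussian sampling and with the
`T x d` input size, so each time step is sampled as a `d`-dimensional
standard-Gaussian vector and the one-hot phrasing is treated as a misnomer.

The CNN discriminator follows the published geometry exactly for a
1 x 3120 x 1 input:

| layer | feature maps | filter/window | stride | output length |
|-------|-------------:|--------------:|-------:|--------------:|
| C1    | 10           | 120           | 5      | 601           |
| P1    | 10           | 46            | 3      | 186           |
| C2    | 5            | 36            | 3      | 51            |
| P2    | 5            | 24            | 3      | 10            |

then a fully connected layer of 25 units and a 2-class softmax whose first
component is the probability-of-real.  The published parameter table lists
its softmax row as 25 -> 25 and a final output 25 -> 1; a literal 25-unit
softmax cannot produce the stated two-class one-hot decision, so the head
is implemented as a 25 -> 2 affine map followed by the 2-class softmax, and
the scalar output is the "real" component.  Layer shapes follow
`conv_output_length()` (`floor((W - F + 2P)/S) + 1`) and
`pool_output_length()` (`floor((W - F)/S) + 1`), which the tests check
against explicit sliding-window enumeration over a grid of geometries.
The convolution nonlinearity is unnamed in the source; leaky ReLU
(slope 0.2) is used, configurable via `activation_slope`.

MLP, LSTM and GRU discriminator variants are provided for the architecture
comparison.  Their internals are unspecified in the source, so minimal
faithful stand-ins are used: MLP = two hidden layers (default 64, 16) with
leaky ReLU; LSTM/GRU = one recurrent layer (default width 32) whose last
hidden state feeds the 2-class softmax head.

Training alternates, per mini-batch, one discriminator update (binary
cross-entropy on real-vs-generated labels — the negation of the empirical
minimax objective) and one generator update through the frozen
discriminator.  The generator's default loss is the saturating form
(minimize `log(1 - D(G(z)))`, the published scheme); the non-saturating
`-log D(G(z))` is available via `g_loss_mode`.  Probabilities are clamped
at 1e-7 before logs.  The optimizer is Adam (moments 0.9/0.999); the source
names only the learning rate, and Adam is the de-facto default for GAN
training.  Default protocol: 500 epochs, mini-batch 100, learning rate
1e-5, sequence length 3120.  Per-epoch logged losses are means over
mini-batches (the source does not say; a per-epoch mean is the stablest
summary).  Every source of randomness — initialisation, batch order, noise,
dropout — is derived from the single training seed, so runs are bitwise
reproducible.

## Baselines

The recurrent autoencoder encodes a window with an RNN or LSTM and maps the
final hidden state to a latent code `d`; the decoder receives `d` at every
step together with the previous output (teacher-forced during training,
free-running for generation) and a shared dense head emits one sample per
step.  The reconstruction log-likelihood is realized as a unit-variance
Gaussian, i.e. the reported loss is the mean squared error — maximizing the
average per-point log-likelihood is the same optimization.  The variational
variant replaces the code with posterior mean and standard-deviation
vectors, draws the latent through the reparameterization trick
`d = mu + sigma * eps`, and minimizes the negative ELBO: reconstruction MSE
plus the closed-form Gaussian KL `0.5 * sum(mu^2 + sigma^2 - 1 - 2 log
sigma)` to the standard-normal prior.  The source's typeset ELBO places the
KL term ambiguously; the standard sign convention is implemented.

## Data handling

MIT-BIH-style WFDB records are read from the `.hea`/`.dat`/`.atr` triplet
(signal formats 212 and 16; the MIT annotation format including SKIP/AUX
records).  Records carry two leads; only one is used (`lead_index = 0` by
default, the first signal).  Lead values are raw ADC samples divided by a
constant 200 — the nominal ADC gain of those records; whether the published
protocol means the gain or an arbitrary constant is unstated, so the
divisor is a `scale` argument defaulting to 200.  Annotations are parsed
and kept for provenance but play no role in training.  Sequences are cut
into fixed-length windows starting at offsets 0, hop, 2·hop (0-based,
half-open); the published experiments imply non-overlapping 3120-sample
windows (208 per ~650,000-sample record), which is the default, and the hop
is configurable.

Min-max normalization as typeset, `(x - max)/(max - min)`, maps the maximum
to 0 and the minimum to −1 — almost certainly a typo for unit scaling.  The
default mode maps to [0, 1]; mode `"as-printed"` reproduces the typeset
formula for fidelity.  Constant sequences are a degenerate-input error.

## Metrics

PRD, RMSE and the discrete Fréchet distance score (reference, generated)
pairs.  PRD's published formula prints the factor 100 inside the radical;
the default follows the standard definition (`100 * sqrt(.)`), with an
`"as-printed"` mode.  The Fréchet distance is computed on 2-D points
`(index/(N-1), value)` so the ordering of points along the curve matters as
intended for time series; a value-only 1-D mode exists.  The dynamic
programme is checked exactly against a brute-force enumeration of all
monotone couplings (`discrete_frechet_brute()`) for short curves.

Generated sequences arise from noise and are unpaired, and the published
evaluation never states how they are matched to real windows — the largest
under-specification in the protocol.  `evaluate_generated()` defaults to
best-match pairing (each generated sequence scored against the real window
minimizing RMSE), which measures morphology rather than accidental index
alignment; fixed-index pairing is available for reproducible tests.  Both
sides are min-max normalized per sequence before scoring by default.
Because the pairing protocol behind the published metric tables is unknown
(the same model is reported with PRD 66.408 in one table and 51.799 in
another with no stated difference), those table values are not
reproduction targets; the package's tests verify the metric *formulas*
exactly and the training dynamics at desk scale instead.

## The synthetic fixture generator

`generate_ecg()` emulates a single-lead ECG as five Gaussian bumps (P, Q,
R, S, T) on the cardiac cycle phase plus seeded white Gaussian noise and an
optional 0.33 Hz baseline-wander sinusoid.  This is a deliberate
simplification of dynamical ODE-based simulators: the fixture's job is to
provide deterministic, parameterized signals with PQRST morphology so the
pipeline is testable without downloading MIT-BIH.  Default conditions:
60 bpm, 360 Hz (the MIT-BIH rate), amplitudes (0.15, −0.10, 1.00, −0.25,
0.35) lead units, widths (0.25, 0.10, 0.10, 0.10, 0.40) rad, positions
(−1.30, −0.30, 0.00, 0.30, 1.40) rad, noise sd 0.02 — a visually ECG-like
cycle with R amplitude ~1 (roughly 1 mV) and mild sensor noise.  What it
does *not* model: RR-interval variability, arrhythmic beats, multi-lead
projection, realistic noise spectra.  Tests passing on this fixture show
the machinery learns and scores simple quasi-periodic morphology; they do
not certify clinical realism on real recordings.

## Problem sizes and numerical choices

The full published protocol (48 records, 31.2 million points, 500 epochs at
sequence length 3120) is far beyond a test suite; the package keeps the
full geometry for shape-level checks and scales the *training* exercises
down.  The desk-scale configuration used by the training acceptance test:
50 synthetic windows of 312 samples (one tenth of 3120), generator hidden
width 16, `scaled_cnn_spec(312)` (filter/pooling windows shrunk
proportionally with small floors), 20 epochs, mini-batch 2, Adam 1e-3,
saturating generator loss, seed 1.  Mini-batch 2 is deliberate: with 50
windows it yields 500 adversarial updates in 20 epochs, which this
configuration needs to move the generator measurably; at mini-batch 5-10
(100-200 updates) the improvement direction was seed-dependent.  With 500
updates the trained generator beat the untrained one on best-match RMSE for
every seed tried (6/6; deltas −0.006 to −0.065).  The discriminator loss in
such short runs is not monotone — it hovers in a band around the
equilibrium value `2 log 2 ≈ 1.386` as the two players trade progress — so
the stability assertion is finiteness plus a bounded band, and generator
progress is asserted via the RMSE comparison.

Other numerical choices: Glorot-uniform initialisation, seeded; inverted
dropout; log-argument clamping at 1e-7; gradient correctness verified by
finite differences at tolerance 1e-6 in the tests; `set.seed`-derived RNG
only (no external RNG state leaks — seeded helpers save and restore the
caller's RNG stream).

## Known limitations

- Pure-R training is slow: the full 500-epoch, 3120-sample protocol is out
  of reach on one CPU; the package is faithful at full scale in
  architecture and exercised at reduced scale in training.
- The WFDB reader covers the MIT-BIH dialect (one `.dat` per record,
  formats 212/16), not the whole format family.
- Best-match pairing makes the reported metrics optimistic relative to any
  fixed pairing; this is disclosed in every report (`pairing` column).
- The desk-scale improvement check certifies learning signal, not sample
  quality; generated morphology after 500 tiny updates is still crude.

## Worked example

```{r example, eval = FALSE}
library(ecggan)

wins <- generate_dataset(synth_config(duration = 45, seed = 1),
                         n_records = 4, window_length = 312)

gan <- train_gan(
  wins,
  generator_config(noise_dim = 5, seq_len = 312, hidden_units = 16),
  scaled_cnn_spec(312),
  gan_train_config(epochs = 20, batch_size = 2, learning_rate = 1e-3,
                   seq_len = 312, seed = 1)
)

glance(gan)
autoplot(gan)

fake <- generate_ecgs(gan, n = 20, length = 312, seed = 99)
evaluate_generated(wins, fake)
```
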
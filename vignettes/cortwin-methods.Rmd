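---
title: "Modeling cortical signals with a hierarchical variational RNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cortical signals with a hierarchical variational RNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`cortwin` implements a digital-twin simulator for multichannel cortical
signals (ECoG-like recordings) built around a variational Bayesian
recurrent neural network with a spatial and temporal hierarchy:

* **Local region level.** One module per cortical region, each with a
  small bank of leaky deterministic units `d1` (time constant `tau1 = 2`,
  fast dynamics) and one stochastic latent unit `z1` per region. Each
  module emits that region's output channels through a `tanh` readout.
* **Functional network level.** A single module of deterministic units
  `d2` (`tau2 = 4`, slower dynamics) and latents `z2` that drives all
  region modules top-down.
* **Global state level.** A latent-only vector `z3` that is held constant
  across all time steps of a sequence, so it can only represent
  sequence-level structure — the brain-state analog (awake versus
  anesthetized) and individual identity.

Each latent carries a Gaussian prior parameterized top-down by the
previous deterministic state of its module (`mu` through `tanh`, `sigma`
through `exp`), and a Gaussian posterior parameterized by adaptive
internal states `a_mu`, `a_sigma` that are free optimization variables
per time step and sequence. At the first time step of every sequence the
prior is N(0, 1). Latents are sampled by the reparameterization
`z = mu + sigma * eps` with standard-normal `eps`. Deterministic units
follow the leaky update

    h_t = (1/tau) (W_d d_{t-1} + W_z z_t + W_td topdown_t + b)
          + (1 - 1/tau) h_{t-1},     d_t = tanh(h_t)

where the network level receives its own recurrence plus the current
`z2` and `z3` samples, and each region module receives its own
recurrence, its region's `z1`, and the current `d2`. The global level
has no deterministic units: `z3` enters the network-level sum directly,
so the level is implemented latent-only — nothing in the generative
dynamics would produce or consume a global deterministic state.

## The loss

Training and assimilation both minimize the variational free energy
(negative evidence lower bound), per step

    F_t = 1/2 * sum((x_t - xhat_t)^2)
          + sum_l W^(l) * KL[q(z_t^(l)) || p(z_t^(l))]

with the diagonal-Gaussian KL in closed form. The meta-prior `W^(l)`
balances reconstruction against prior adherence per level; because the
sequence-constant `z3` pays its KL only once per sequence (against the
N(0, 1) initial prior) while `z1`/`z2` pay at every step, information
that is constant across a sequence is cheapest stored in `z3` — this is
the mechanism behind the self-organization of brain-state clusters.

Gradients with respect to both the connection weights and the adaptive
states are computed by backpropagation through time, implemented in the
compiled core and validated against central finite differences (relative
tolerance 1e-4) in the test suite. Optimization uses Rectified Adam
(`alpha = 0.001`, `beta1 = 0.9`, `beta2 = 0.999`), with plain Adam
behind the `rectify = FALSE` switch. Training draws one `eps` per unit
per step per update (single-sample reparameterized ELBO); evaluation and
plotting use posterior means.

## Sliding-window data assimilation

After training, the weights are frozen and only the posterior adaptive
states are updated from incoming observations, inside a window of `H`
steps that advances one step at a time:

1. the posterior of the incoming step is initialized so that it equals
   the prior computed from the previous step's deterministic state (the
   clamped pre-activations are stored directly as adaptive states);
2. K times per step, the window is predicted top-down with fresh latent
   noise and the adaptive states of all windowed steps (plus the shared
   `z3`) receive one Rectified-Adam update on the summed window free
   energy;
3. the final mean-field pass of each step freezes the deterministic
   states, which seed later windows once the step has scrolled out.

At the start of a stream the window grows from 1 to `H` instead of
waiting for `H` observations, so output exists from the first step. A
step that traverses a full window therefore accumulates exactly `H * K`
update iterations (50,000 at the reference setting `H = 500`,
`K = 100`). Multi-step-ahead prediction (`predict_ahead`) rolls the
generative model forward from the current assimilation state using
priors only. Fixed-window posterior estimation
(`estimate_condition_latents`) is the same machinery with the window
pinned to the whole sequence, which keeps `z3` representative of the
entire sequence; it produces the repertoire used for interventions.

## Virtual interventions

An intervention clamps chosen latent units to a stored posterior — the
constant `z3` (global, drug-like), single `z2` units
(functional-network-targeted), or the `z1` of single regions
(region-targeted) — while all unclamped units generate from their
top-down priors with fresh noise. Clamps replay posterior means by
default; `sample_clamped = TRUE` replays draws from the stored posterior
distributions instead (the replay-versus-mean choice is not dictated by
the procedure itself, so both are exposed). Each repertoire entry is
kept per-sequence rather than averaged across sequences, and experiments
loop over entries.

## Analysis stack

* **Transfer entropy** from each `z2` unit's posterior-mean series to
  each region's mean `d1` series quantifies directed network control.
  The estimator discretizes both series into `Q = 4` quantile bins and
  computes the plug-in conditional mutual information with history 1,
  minus a permutation-null mean (100 surrogates) for bias. This
  estimator was chosen because it admits an exact brute-force oracle on
  discrete chains, which the tests exercise; the embedding and bin
  count are parameters. Rows (unit x fold fingerprints) are grouped by
  average-linkage hierarchical clustering on globally z-scored values
  into functional networks.
* **Silhouette widths** are computed from their defining averages under
  Euclidean distance in the `z3`-mean space; a point in a singleton
  cluster gets width 0. `assign_by_silhouette` classifies a point into
  the candidate cluster yielding the larger width; exact ties go to the
  first label in canonical sorted order.
* **k-NN assignment** uses a deterministic majority vote (canonical-order
  tie-break) with `k` chosen by leave-one-out cross-validation over odd
  candidates on the reference set.
* **Discriminator.** Sequences are segmented (2000 ms at the reference
  geometry), each segment converted to a multitaper spectrogram (100 ms
  Slepian-tapered windows, 10 ms step, `NW = 4`, 7 tapers, 0-200 Hz) and
  classified by a small 3-D convolutional network: one block of kernels
  sliding over channel x frequency x time, ReLU, global average pooling
  and a softmax head, trained 100 steps with Adam at learning rate
  5e-4 on cross-entropy. Power is log-transformed and globally
  standardized before the network. The exact layer configuration of the
  reference discriminator is not fixed by the procedure; the
  architecture here is deliberately minimal and configurable
  (`n_filters`, `kernel`).

## Synthetic data

`generate_sequence` emulates the structure that matters to the pipeline
without any real recordings: per-region band-limited oscillations
(randomized phases, slow amplitude modulation) plus AR(1) noise, in
microvolt-equivalent units. Channels of the same region share the
oscillatory component (same-region electrode pairs are strongly
correlated, which is also the premise of the model's region modules),
with small per-channel phase offsets, individual gains and independent
background noise. The regimes differ in spectral shape, the signature
of dissociative anesthesia: awake signals have a weak slow band and
strong mid/fast desynchronized activity; under "anesthesia" the
non-visual regions gain dominant slow waves (25x power in the lowest
band), mildly raised mid-band and attenuated fast-band power, roughly
doubling total power, while visual regions barely change — mirroring
the observation that broad-band power rises under anesthesia except in
visual cortex. Individuals differ by log-normal channel gains (SD 0.08)
and a small spectral tilt, kept smaller than the regime difference as
in the recordings. What the generator does **not** emulate: 1/f
spectral background, cross-regional phase coupling, non-stationary
artifacts; passing tests on it therefore demonstrate the mechanics of
the method, not performance on real cortical data.

## Desk-scale study configuration

The packaged tests and the acceptance script run a reduced geometry so
the whole pipeline executes in minutes on one CPU:

* 2 regions x 2 channels, with the second region "visual"
  (regime-invariant); 250 Hz sampling;
* regimes that differ in spectral shape: awake has weak slow-band and
  strong mid/fast activity, anesthesia (non-visual regions) has
  dominant 4 Hz slow waves, mildly raised 20 Hz and attenuated 45 Hz
  power, roughly doubling total power — a shape change forces a
  different dynamical regime of the generative network, which is what a
  sequence-constant latent selects; a pure broadband gain, by contrast,
  is absorbed by the per-step latents and leaves `z3` uninformative;
* a single training individual (4 sequences of 500 steps per condition)
  with the transition stream crossfaded from unseen sequences of the
  same individual. The study is deliberately single-individual: with
  several individuals, `z3` preferentially encodes per-channel gain
  patterns (individuality), because those cannot be expressed by shared
  weights or per-step latents at all — reproducing, at desk scale, the
  individuality clustering seen on real recordings — and regime
  clustering then needs far longer training than the desk budget;
* the meta-prior stays at the reference value 0.001 at all levels
  (raising it at this scale suppressed reconstruction before it helped
  the latent organization);
* training updates, assimilation settings (`H = 100`, `K = 20`) and
  discriminator settings (500 ms segments, 0-100 Hz band, four
  (2, 7, 11) kernels, 300 Adam steps — the reference recipe's 100 steps
  underfit this contrast) are bundled with the preset (`desk_study()`).

## Numerical choices and degenerate inputs

* Posterior-mean pre-activations are clamped to [-10, 10] (means stay
  strictly inside (-1, 1)); all log-sigma pre-activations -- prior and
  posterior, every level -- are clamped to [-3, 3], so sigma lives in
  [0.05, 20]. The sigma floor matters: if a prior sigma collapses, the
  KL curvature (which scales as 1/sigma^2) explodes and a single
  ill-conditioned unit can destroy the fit. Gradients are masked
  outside the clamps.
* Newly allocated posterior adaptive states start at sigma = 0.1
  (`init_sigma`), i.e. near-deterministic. Starting at sigma = 1 injects
  latent noise an order of magnitude above the normalized signal scale,
  and at short training budgets the optimizer then disconnects the
  latents (shrinking their input weights) instead of contracting sigma.
* Deterministic states start at zero, making the N(0, 1) initial prior
  exact under zero-weight prior networks.
* Weight initialization is scaled-uniform (Glorot-style) from a recorded
  seed; biases start at zero.
* Windows reaching before the stream start truncate to the available
  steps; `K = 0` assimilation degenerates to a pure prior rollout.
* All stochastic paths (latent draws, dataset sampling, holdout splits)
  run off explicit integer seeds; reruns are bit-identical.

## Known limitations

* The assimilation loop is sequential by construction (each window
  depends on the last); wall-clock scales with `T * K * H`.
* Steps that have left the window are frozen, so late information cannot
  revise old states — faithful to the advancing-window design but a
  limitation for offline smoothing uses.
* The model is not identifiable: different latent configurations can
  generate identical signals, so recovered latents are meaningful up to
  the cluster level, not unit-by-unit. A practical consequence at desk
  scale is training-seed sensitivity of cluster localization: an
  assimilation run can align its global-latent trajectory with a
  mirrored copy of the training cluster geometry, in which case k-NN
  localization drops below chance even though the clusters themselves,
  the discriminator and the interventions remain sound. Longer training
  and more data shrink this failure mode.
* The YAML model archive is plain text and adequate for desk-scale
  weights; a binary array format would be preferable for the full
  reference geometry.
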
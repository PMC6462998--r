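---
title: "A spiking model of dorsal-stream motion processing and heading decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking model of dorsal-stream motion processing and heading decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`spikeflow` simulates the dorsal visual pathway as a hierarchy of spiking
layers driven by synthetic luminance movies:

```
frames -> RGC filter (ON/OFF) -> LGN relay (+ IN/TRN feedback) -> V1 -> MT
       -> MST (expansion/contraction templates) -> LIP (left vs right)
```

Every retinotopic layer is a 20 x 20 grid of 400 neurons; V1 and MT
additionally carry 100 inhibitory neurons each on a dispersed 10 x 10
lattice; LIP consists of two mutually inhibiting neurons whose firing rates
express the perceptual decision that the focus of an expanding optic-flow
field lies left or right of the screen center.

## Retina

The retinal ganglion cell stage is a linear spatiotemporal filter. Its
spatial kernel is a difference of Gaussians with variance-normalized lobes,

$$w(r) = a_c\,\frac{e^{-r^2/\sigma_c^2}}{\sigma_c^2}
       - a_s\,\frac{e^{-r^2/\sigma_s^2}}{\sigma_s^2},$$

and its temporal kernel the biphasic difference of two Gamma densities
(shapes 2/2, scales 16/32 ms, weights 1/0.7, 200 ms support). The OFF
channel is the sign-inverted spatial kernel; filter outputs are signed
currents injected one-to-one into the LGN relay and interneuron layers.

Two defaults deserve comment:

* **Balanced kernel, small center** (`a_c = a_s = 1`,
  `sigma_c = 0.3` grid units, `sigma_s = 2.4`). A balanced kernel responds
  only to contrast: uniform fields, including the dark background, produce
  exactly zero drive. An unbalanced surround would let the OFF channel fire
  tonically over the background, which swamps the orientation signal in V1.
  The center width matches the 8 px dots of the flow stimulus so single
  dots are resolved by single lattice cells.
* **Adaptation and saturation at injection.** The filter itself is strictly
  linear (its unit tests assert homogeneity). At the injection stage the
  currents are divided by $1 + k\,\bar L$ with $\bar L$ the mean stimulus
  luminance (`adaptK = 50`) and clipped at $\pm 900$ pA. This Weber-like
  light adaptation equalizes sparse stimuli (50 dots, $\bar L \approx
  0.007$) and dense ones (bar fields, $\bar L \approx 0.18$), which
  otherwise differ by a factor of about six in drive; the clip models relay
  saturation and keeps extended bright regions from driving unphysiological
  currents.

## Neuron models

LGN relay cells use a conductance-based leaky integrate-and-fire model
whose spike triggers an after-hyperpolarizing conductance instead of a hard
reset (`g_ahp = 60` nS per spike, `tau_ahp = 10` ms, `g_L = 20` nS). The
AHP increment is deliberately large enough that a spike always pulls the
equilibrium potential back below threshold at the maximal (clipped)
injection; with a weaker AHP the no-reset model enters depolarization
block, emitting a single spike and then sitting silently above threshold.

All other layers use a current-based LIF with exponential postsynaptic
currents (`tau_m = 10` ms, 15 mV from rest to threshold, 2 ms refractory
period, 2 ms synaptic time constants). Both models are advanced with the
exact exponential update at `dt = 0.1` ms, with inputs held constant over a
step and spikes registered at step boundaries; membrane potentials are
floored at -120 mV, and |V| > 200 mV aborts the run as a numerical error.

## Maps and receptive fields

V1 orientation (period $\pi$) and MT direction (period $2\pi$) preferences
come from pinwheel maps built by superposing 30 random plane waves of
wavelength 10 grid units; the receptive-field phase map is an independent
realization. Both maps are constructed **mirror-symmetrically** about the
vertical midline (the right half is the reflected left half, with angles
reflected and phases negated). This guarantees that the circuitry feeding
the left and right decision channels is statistically identical; with
unconstrained maps the decision inherited a sizable left/right bias from
map-sampling luck.

V1 cells own elongated Gabor receptive fields (envelope 3 x 2 grid units,
carrier 0.25 cycles per grid unit). Feedforward LGN afferents attach where
the Gabor exceeds a cutoff of 0.08 in magnitude: ON cells on positive
lobes, OFF cells on negative lobes, all excitatory, with each cell's
afferent weights normalized to a fixed total so that responsiveness does
not vary with how many lattice sites a field happens to cover. Lateral
excitation follows positive Gabor correlation; lateral inhibition is
push-pull — strongest between cells of similar orientation whose phases
differ by about 180 degrees (von Mises weighting around $\pi$ times an
orientation-similarity factor), with a Gaussian spatial falloff.

## Feedforward motion pathway

MT inherits V1's structure; its feedforward weights follow

$$w_{ij} = k_c\, w_{cs}(\Delta x, \Delta y)\cos\varphi_{ij}
  \quad (0 \le \varphi_{ij} \le \pi/2,\ \text{else } 0),$$

where $w_{cs}$ is a difference-of-Gaussians in the cells' offset and
$\varphi_{ij}$ is the unsigned angle between the MT direction preference
and the V1 orientation preference treated as a vector angle in $[0, \pi)$,
folded to $[0, \pi]$. The full-circle difference is what makes the gate
meaningful for a direction map: cells preferring $\theta$ and $\theta +
\pi$ receive different input.

Each MST cell carries an expansion or contraction template with one of
three focal points at $x \in \{-5, 0, +5\}$ grid units ($y = 0$), assigned
to the focal point nearest the cell's own horizontal position (ties going
to the outer focal point, which keeps the left/right groups exactly
mirror-symmetric: 160/80/160 cells). An MT cell at distance $r$ from the
focal point is eligible when its direction preference lies within $\pi/8$
of the radial direction away from (expansion) or toward (contraction) the
focal point, and contributes
$e^{-d r^2}\, e^{-\rho^2/2\sigma_I^2}/(2\pi\sigma_I^2)$ with $\rho$ the
MT-MST offset. As for V1, each MST cell's afferents are normalized to a
fixed total.

The template concentration `d = 0.15` (a fairly tight template,
$\sigma \approx 1.8$ grid units) matters. Because the motion signal
reaching MT is axial — a streak oriented along $\theta$ looks the same as
one along $\theta + \pi$ — the broad horizontal-flow field between a focal
point and a displaced expansion center can masquerade as evidence **for
the opposite side** when templates integrate far from their focal point.
With broad templates ($d \le 0.05$) this systematically inverted decisions
at large displacements; tight templates confine the evidence to the
near-focal region where the radial structure is discriminative.

MST layers carry intra-layer lateral weights
$\pm e^{-\Delta^2/2\sigma_{ts}^2}$ (positive between cells sharing a focal
point, negative otherwise) and all-inhibitory inter-layer weights further
scaled by the focal-similarity Gaussian.

## Readout

The left LIP neuron receives excitation from expansion cells with the left
focal point and inhibition from every other MST cell; symmetrically for
the right neuron; the two inhibit each other. Decisions are read from
sliding-window rates: the winner is the side with the higher rate in the
final window, and the latency is the earliest time after which the
winner's rate never falls below the loser's. The display default for LIP
rate traces is a 50 ms window stepped by 10 ms; the **decision** windows
used by `runExperiment()` are 200 ms stepped by 20 ms, because with only
two readout neurons a 50 ms count (at most a few spikes) makes the prevail
criterion flip on single spikes.

Population decoding uses the spike-count-weighted vector average
$\hat\theta = \operatorname{atan2}\!\big(\sum_i n_i\sin\theta_i',
\sum_i n_i\cos\theta_i'\big)$ with angle doubling for orientation data
($\theta' = 2\theta$, result halved): a plain arctangent of the sine/cosine
ratio is ill-posed on the half-circle, and doubling is the standard
circular-statistics treatment of axial data. Zero or exactly cancelling
counts yield an explicitly undefined decode rather than a number.

# The synthetic stimuli

The flow stimulus is a random-dot kinematogram: 50 bright anti-aliased
dots (radius 4 px) on a dark 600 x 600 px screen, 36 moving radially away
from the expansion center and 14 in fixed random directions, all at 100
px/s. Dots live for 100 ms and are then re-positioned uniformly at random,
random-class dots keeping their direction verbatim and radial dots having
it recomputed from the center so the expansion subfield stays consistent.
Ages start uniformly staggered, so at the default frame interval of one
third of the lifetime (100/3 ms) one third of the dots renews per frame in
expectation. The expansion center sits 20-140 px (0.67-4.67 degrees at
29.85 px/degree) left or right of the screen center; seven magnitudes, two
sides. Trial duration is 600 ms.

The orientation/direction test stimulus is a two-region field of drifting
bar segments: a near-horizontal band (orientation 172 degrees, bottom
third) and an oblique band (64 degrees, top two thirds), each drifting
parallel to its bar orientation at 100 px/s. The exact bar geometry of the
original figure is not published; these two orientations and the 2:1 area
ratio were chosen analytically so that the area-weighted circular mean
orientation is ~50.9 degrees and the mean direction-vector angle ~93.4
degrees, the regime the published decodes describe. Bars are segmented
(90 px dashes, 30 px gaps) so that motion along the bar axis is visible at
all.

What the generator does *not* emulate: luminance noise, occlusion, speed
gradients of real optic flow (all dots share one speed), eye movements,
and anything chromatic. Passing tests therefore show that the circuit
performs the intended computation on idealized inputs, not that it matches
biological response statistics.

# Numerical choices

* `dt = 0.1` ms; retinal currents are computed at 1 ms resolution on a
  raster of 6 cells per grid unit and held piecewise constant.
* Synaptic delays are globally 1 ms.
* Background Poisson noise keeps the cortical layers responsive
  (V1 1500 Hz, MT 300 Hz, MST 500 Hz, LIP 4500 Hz of 40 pA events): V1
  needs a noise floor to respond to sparse dot input at all, while MT/MST
  noise is kept low because template normalization amplifies lone
  noise-hot cells into spurious group evidence.
* Projection gains were calibrated jointly so that bars drive LGN in a
  mostly graded regime, V1 sits at 10-25 Hz under bar stimulation, and LIP
  rates stay in the tens of Hz; weights with magnitude below 1e-3 of their
  projection maximum are pruned.
* Degenerate cases: an MT cell exactly at a focal point has undefined
  radial direction and template weight 0; exact rate ties at the end of a
  trial are reported as `undecided`; decodes of empty spike sets are
  flagged undefined.

# Known limitations

The motion representation entering MT is axial (orientation-like), because
feedforward V1 -> MT weighting cannot distinguish motion at $\theta$ from
$\theta + \pi$; true direction selectivity would need spatiotemporally
offset receptive fields, which this architecture does not contain. As a
consequence single-trial heading evidence is weak: with 50 short-lived
dots, per-trial dot-placement luck can activate the wrong template group,
and the left/right decision is reliable only in aggregate. In the
packaged displacement sweep (7 magnitudes x 2 sides x 3 trials, 600 ms)
the decision latency decreases with displacement magnitude and
intermediate leftward conditions prevail within 400 ms, but not every
(displacement, side) condition reaches a majority of correct trials. The
original report of asymmetric left/right decision times is consistent
with this picture.

# Reproducing the numbers

```{r}
library(spikeflow)

net <- assembleNetwork()
networkCensus(net)$layers

# orientation/direction decoding of the two-region bar stimulus
st <- makeBarStimulus(defaultBarStimulusSpec())
res <- runNetwork(net, st, noiseSeed = 1)
populationDecode(layerSpikes(res, "V1"), net@maps$v1)
populationDecode(layerSpikes(res, "MT"), net@maps$mt)

# heading-decision sweep
exp <- runExperiment(net, nTrials = 3, baseSeed = 1)
summarizeExperiment(exp)
```

The same computation, reduced to the two decoded angles, is scripted in
`scripts/acceptance.R`.
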
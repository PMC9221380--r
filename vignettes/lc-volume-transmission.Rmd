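---
title: "Modelling norepinephrine volume transmission in the locus coeruleus core"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling norepinephrine volume transmission in the locus coeruleus core}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsim)
```

## The scientific question

Somata of noradrenergic neurons in the locus coeruleus (LC) sit unusually
close to one another: in cleared-tissue reconstructions roughly a quarter
of the cells have their nearest neighbour within 25 um. Norepinephrine
(NE) released from somatic and dendritic sites therefore does not need a
synapse to reach a neighbouring cell — a quantal release can diffuse
through the extracellular space and activate the neighbour's
high-affinity alpha2-adrenergic receptors (K_D ~ 1 nM), opening GIRK
potassium channels and slowing its pacemaker. `lcsim` implements a
spiking-neuron model of this circuit at three levels:

1. a two-compartment conductance-based LC neuron with calcium-gated
   after-hyperpolarisation (the pacemaker);
2. calcium-dependent quantal NE release coupled to alpha2/GIRK
   conductance kernels (synaptic, autoreceptor and volume modes);
3. extracellular point-source diffusion of NE with reuptake and
   receptor-binding kinetics, from which an *effective* slow, attenuated
   GIRK kernel for neighbour ("bystander") inhibition is derived;

plus a synthetic 3-D geometry generator and nearest-neighbour (NN)
statistics that justify the 25 um interaction radius.

## The neuron model

Each neuron has a somatic and a passive dendritic compartment. The
somatic voltage obeys a current balance

$$ c_m \frac{dV_S}{dt} = I_{elec} - I_{Na} - I_K - I_P - I_{AHP} - I_{Ca}
   - I_{GIRK} - I_{dend} - I_L + \eta(t), $$

with transient sodium (instantaneous activation, inactivating),
delayed-rectifier potassium, persistent sodium, the calcium-gated AHP
current $I_{AHP} = g_{AHP}\, r\, (V - V_K)$ with
$r = [Ca]/([Ca] + 1\,\mu M)$, leak, the soma-dendrite coupling current
and the GIRK current. The dendrite carries leak, the coupling current
and optional gap junctions to other dendrites:
$c_m\, dV_D/dt = -I_{soma} - I_{GJ} - I_{LD}$.

Cytosolic calcium relaxes toward a voltage-dependent steady state

$$ [Ca]_\infty(V) = \frac{M_{Ca}}{132.6\,mV}\,
   \frac{V_{Ca} - V}{1 + e^{-(V + 25)/2.5}},\qquad
   [Ca]_{i+1} = [Ca]_\infty + ([Ca]_i - [Ca]_\infty)\,e^{-dt/\tau_{Ca}}, $$

with $f_{Ca} = 0.002\ \mu M/(mV\,ms)$, $k_{Ca} = 2$,
$\tau_{Ca} = 80\ ms$ and $V_{Ca} = 120\ mV$. The voltage factor peaks at
132.6 mV, which makes the ceiling
$M_{Ca} = f_{Ca} k_{Ca} \tau_{Ca} \cdot 132.6\,mV = 42.4\ \mu M$; the
constructor enforces this identity to 0.1% so the two forms of the
steady state can never drift apart. The exponential update is the exact
solution of the relaxation ODE at frozen voltage, so composing two half
steps equals one full step to machine precision — a property the test
suite asserts.

### Gating kinetics and how the defaults were chosen

The spike-current rate functions (Boltzmann activations with
sigmoidal voltage-dependent time constants) are of the standard
cortical type; their constants are exposed in
`lc_neuron_params()` rather than hard-coded. Because the LC literature
specifies the calcium subsystem and the validation surface but not a
complete set of maximal conductances, the defaults were selected — once,
before the test suite was frozen — so that the model reproduces the
experimentally anchored behaviour of adult mouse LC neurons:

* intrinsic pacemaking at 4.3 Hz (slice recordings: 4.2 +- 1.8 Hz),
  with wide spikes (half-width ~1.5 ms) and a prominent slow AHP;
* an approximately linear frequency-current relation with higher
  instantaneous rates for the first spikes of a step, increasingly so
  at higher amplitudes;
* a cytosolic calcium plateau of 1.3 uM when driven at 20 Hz — the
  quantity that anchors the release model, since the release weight is
  defined as $R_{rel}(ca) = 2\,ca/(1.3 + ca)$ (saturating at 2; the
  factor 2 is part of the model definition and deliberately not
  renormalised);
* GIRK-dominated subthreshold behaviour: the reported rectification
  scale (0.2 uS/mm^2, i.e. 0.02 mS/cm^2) must be able to silence a
  resting neighbour, which requires the high input resistance typical
  of LC cells. This constraint fixed the small leak (0.04 mS/cm^2)
  and moved the pacemaker drive onto the persistent sodium current.

The electrode current works in densities (uA/cm^2); `current_nA_to_density()`
maps nA-scale protocol amplitudes through the nominal somatic area
(0.027 cm^2), under which a 270 nA step corresponds to the ~10 uA/cm^2
that drives the default cell at 20 Hz. Because that mapping depends on
an area convention, every scenario preset instead calibrates the step
amplitude by bisection to hit 20 +- 1 Hz (`calibrate_step_current()`).

### Noise

$\eta(t)$ is zero-mean white current noise, amplitude 0.25 uA/cm^2
(scaled by $1/\sqrt{dt}$ so its strength is step-size invariant),
seeded through R's RNG. The amplitude was chosen so that spike timing
jitters by a few milliseconds while the 60-s spontaneous-rate estimate
varies by well under 0.1 Hz across seeds, matching the very low
run-to-run variability of the deterministic pacemaker.

## Release, GIRK kernels and the three interaction modes

Every presynaptic spike emits a release event weighted by
$R_{rel}$ at the spike-time calcium — graded release with no hard
threshold (at tonic calcium the weight is small but not zero). For a
synaptically wired pair the conductance contributed by each event is the
peak-normalised double exponential

$$ P_{open}(t) = B\,[e^{-t/\tau_{slow}} - e^{-t/\tau_{fast}}],\qquad
   \tau_{fast} = 300\ ms,\ \tau_{slow} = 350\ ms, $$

summed linearly over events, scaled by the synaptic strength $S_{ij}$
(1 for wired pairs) and rectified by
$G_{rect}(V) = 0.2/(1 + e^{0.05 (V - V_{GIRK})})$ uS/mm^2. $V_{GIRK}$
defaults to the potassium reversal (-90 mV) because GIRK is a potassium
conductance. The network integrator keeps two exponentially decaying
accumulators per edge, so the cost per time step is independent of the
event count while remaining exactly equal to the explicit event sum
(tested against the R reference implementation).

The three wiring modes of `network_config()` differ only in which kernel
carries the events: `dendro_somatic` and `autoinhibition` use the
300/350 ms synaptic kernel (the latter with diagonal wiring), `volume`
uses the effective diffusion kernel described below, evaluated at the
pair's distance.

### Measuring the conductance decay

After a release train ends, the summed kernel decays with limiting time
constant $\tau_{slow}$, but close to its peak the near-degenerate double
exponential still carries its fast component: a log-linear fit started
shortly after the peak over-estimates the constant by 10-30% (a fit of
the pure kernel over a window beginning 0.5 s after the peak yields
~395 ms). `girk_decay_fit()` therefore samples the tail (2-5 s after
the last event's kernel peak), where the envelope is single-exponential,
and first divides out the voltage-dependent rectification using the
recorded somatic voltage. Because a driven neuron resumes tonic firing
(and hence release) after a step, the decay probe uses the
`hold = TRUE` variant of the dendro-somatic preset, which silences the
source with a small hyperpolarising hold current to obtain a
release-free window.

## Extracellular diffusion and the effective kernel

A quantal release is modelled as an instantaneous point source in an
infinite medium with first-order reuptake:

$$ C(r, t) = \frac{\alpha}{(4 \pi D t)^{3/2}}
   \exp\!\left(-\frac{r^2}{4 D t} - k_{up} t\right), $$

with $D = 3.4\times10^{-6}\ cm^2/s$ and $k_{up} = 20\ s^{-1}$. Receptor
occupancy integrates $\tau\,dx/dt = -x + x_\infty(C)$ with
$x_\infty = C k_{on}/(C k_{on} + k_{off})$, $k_{on} = 1\ nM^{-1}s^{-1}$,
$k_{off} = 1.25\ s^{-1}$ ($K_D = 1.25$ nM), concentration frozen per
1-ms step (exact exponential update). The occupancy trace is then
convolved with a unit-gain alpha function ($\tau = 50$ ms) standing in
for transmitter binding/unbinding and the G-protein cascade.

### Calibrating the source amplitude

$\alpha$ is a released amount (concentration x volume) and no value
follows from the equation itself. The shipped calibration is the
quantal content of a large dense-core vesicle,
$N_q = 2.4\times10^{6}$ molecules
($\alpha = N_q/N_A \approx 4.0\times10^{6}$ nM um^3), the scale measured
amperometrically for somatodendritic catecholamine quanta; under it the
concentration transient passes through the ~200 nM amperometric range
about 9 um from the source. This choice reproduces the two quantities
that define the biology of the 25-um radius: a peak occupancy of ~26%
at 20 um (the ">15% of receptors can bind NE within the radius" claim)
and an effective-kernel attenuation of ~0.05-0.07 at 25 um. An
alternative calibration sometimes used for attenuation maps — pinning
the concentration at a small reference shell to 200 nM — yields
occupancies of ~0.03% at 20 um and would make the volume mode inert; it
is available by passing `alpha` explicitly but is not the default.

### What reuptake does to the numbers

Two consequences of $k_{up} = 20\ s^{-1}$ deserve emphasis, because they
set honest limits on what the volume mode can produce:

* the ratio $C(22.5\,\mu m, 500\,ms)/C_0$ is bounded above by
  $e^{-k_{up} t} = 4.5\times10^{-5}$ for *any* source calibration whose
  reference concentration is at least the local value, so attenuation
  maps at the $10^{-3}$ level over 200-800 ms are only consistent with
  negligible reuptake; with the shipped parameters the package computes
  ~$4\times10^{-6}$ at that point;
* the diffusion-driven GIRK drive at 25 um rises and falls within
  roughly a second (concentration transient ~0.2 s, binding memory
  $1/k_{off} = 0.8$ s, filter 50 ms), so the fitted effective kernel is
  a near-degenerate double exponential with time constants of ~0.5 s.
  Kernels on the 1.4-s scale — and with them conductance onsets delayed
  by over a second — emerge only when reuptake is effectively absent
  (`diffusion_params(k_up_ms = 0)` pushes the fitted constants into the
  multi-second range).

`fit_effective_kernel()` fits $A\,B'[e^{-t/\tau_s} - e^{-t/\tau_f}]$
with $B'$ normalising the shape to unit peak, so $A$ is directly the
attenuation relative to the unit-peak synaptic kernel. The volume mode
of the network uses this fitted kernel per source-target distance
(cached per distance; `kernel = "shipped"` substitutes the stored
constants instead of refitting). One modelling simplification is
deliberate: events superpose linearly in the effective-kernel
representation, which ignores receptor saturation across near-coincident
quanta; at the ~0.07 per-event amplitude relevant at 25 um the error is
second-order.

A note on onset metrics: an onset defined as the first crossing of 10%
of the eventual conductance peak is scale-invariant and, for kernels of
this family (which rise linearly from zero), is crossed within a few
hundred milliseconds regardless of how slow the kernel is — even a
1400/1450 ms kernel crosses 10% of its peak at ~55 ms. The perceptually
"delayed" rise of a slow kernel is captured by its time-to-peak, not by
a low onset threshold; `girk_onset_time()` implements the threshold
definition and the distinction is worth keeping in mind when comparing
onsets across kernels.

## Synthetic LC geometry

`generate_lc_cloud()` emulates the pooled soma-position statistics of
cleared-brain-stem reconstructions: ~289 cells per nucleus in a
rostrocaudally elongated ellipsoid (default semi-axes 200 x 170 x
1050 um), with 9% of cells placed as close satellites of another cell
(isotropic Gaussian displacement, scale 9 um). The satellite
sub-population is what distinguishes the LC clouds from a homogeneous
Poisson process: a uniform process matching the observed median NN
distance (41.3 um) would put only ~14% of cells within 25 um of a
neighbour, against the ~25% observed. The defaults were calibrated once
against the three pooled targets (median ~41.3 um, ~25% of cells with
NN < 25 um, n ~289 per nucleus) and then frozen; across 20 seeds the
generator yields a pooled median of ~41.9 um and a fraction of ~26%.

What the generator does *not* emulate: anisotropic light-sheet sampling
in z, curvature of the nucleus, the dorsoventral density gradient, and
segmentation artefacts. Passing tests on synthetic clouds therefore
show that the NN pipeline and its calibration are correct, not that
real LC tissue is a two-population ellipsoid.

Nearest-neighbour distances are computed per nucleus (pooling never
crosses nucleus boundaries), exactly — the implementation is checked
against an exhaustive $O(n^2)$ oracle. `fit_nn_distribution()` fits the
double-exponential family
$f(d) \propto [e^{-d/\lambda_{long}} - e^{-d/\lambda_{short}}]^{\gamma}$
by maximum likelihood. Near the degenerate limit
$\lambda_{long} \to \lambda_{short}$ (handled in closed form, no
division blow-up) the two scales trade off along a likelihood ridge, so
single fits scatter widely while the median across replicates is
unbiased; the fitter runs a small moment-based multi-start and
recovery checks use the median across replicates. On the shipped
synthetic clouds the fitted scales land near 30 um — the family adapts
to the generator's mixture shape, and reproducing any particular
published triple of constants is a property of the data it was fitted
to, not of the family.

## Numerical choices

* Fixed-step integration, default $dt = 0.025$ ms: exponential-Euler
  updates for gating and calcium (exact at frozen voltage), explicit
  Euler for the voltages; trajectories converge at first order under
  $dt$ halving and the pure-R reference stepper reproduces the compiled
  core bit-for-bit.
* Spike detection: upward crossing of 0 mV with a 2-ms lockout, both in
  the integrator (for release events) and in `detect_spikes()` (for
  traces sampled at >= 5 kHz).
* AP features: threshold by the dV/dt > 20 mV/ms criterion at the start
  of the contiguous depolarisation run ending at the peak; half-width
  between threshold and peak levels; AHP minimum within 100 ms.
* Traces are stored at 1 kHz by default (`record_dt = 1`),
  independently of the integration step.
* Release-event bookkeeping is O(edges) per step via paired
  exponential accumulators; kernels require
  $\tau_{slow} > \tau_{fast}$, and fitted volume kernels are widened by
  1 ms when a fit returns effectively equal constants.
* Degenerate inputs fail loudly: non-finite states name the neuron and
  time stamp, unsorted event tables and non-uniform time bases are
  errors, duplicate cell coordinates warn and are excluded from fits.

## Problem sizes used by the shipped checks

The package's own verification uses 60-s single-neuron runs across 5
seeds for the spontaneous rate, 10 seeds for the autoinhibition latency,
two-neuron scenarios of 6-15 s for the interaction experiments, 20
seeds of 4 x 289-cell nuclei for the geometry statistics, and
1200-sample replicates for the NN-family recovery study. These sizes
give sub-0.1-Hz rate precision and sub-micrometre geometry precision
while keeping the full suite in the half-minute range on one core.

## Known limitations

* No vesicle-pool depletion or presynaptic plasticity; release weight
  depends only on spike-time calcium.
* Reuptake is linear (no transporter saturation), the medium is
  isotropic and unbounded, and no tortuosity or extracellular volume
  fraction corrections are applied.
* The dendrite is a single passive compartment; gap-junction coupling
  is available but not part of the shipped scenarios.
* The autoreceptor/volume scenarios use at most three neurons; the
  configuration permits more, but population sweeps are out of scope.
* The volume-mode conductance uses the fitted effective kernel rather
  than re-solving the binding ODE per event pair, trading receptor
  saturation effects for O(1) per-step cost.
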
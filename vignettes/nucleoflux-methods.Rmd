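---
title: "Models and methods behind nucleoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucleoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoflux)
```

nucleoflux implements the quantitative backbone of studies asking whether
the terminus with which a protein threads the nuclear pore complex first
— N or C — changes how fast it crosses. The package covers five linked
analyses: light-gated transport kinetics in live cells, image
quantification, single-molecule force-ramp unfolding, a
transcription-factor disorder survey, and static backbone hydrogen-bond
counting on structures. Every analysis ships with a synthetic-data
generator that produces inputs with known ground truth, so the whole
pipeline can be validated end to end. This vignette explains the models,
the estimators, the defaults, and the choices made where the design was
genuinely open.

## The two-compartment transport model

An optogenetic shuttle construct (a LOV2-caged localization signal fused
to a fluorescent cargo) partitions between nucleus and cytoplasm. Under
blue light the construct is driven out of the accumulating compartment
(activation phase); in the dark it relaxes back (recovery phase). With
first-order exchange at import and export rate constants $k_I$ and
$k_E$, both compartment concentrations relax with the single rate
$k = k_I + k_E$:

$$[N](t) = [N]_e - ([N]_e - [N]_0)\,e^{-kt}, \qquad
  [C](t) = [C]_e + ([C]_0 - [C]_e)\,e^{-kt}.$$

Mass conservation couples the two pools through the relative
nucleus-to-cytoplasm volume factor
$v = ([C]_0 - [C]_e)/([N]_e - [N]_0)$. Starting from an emptied nucleus
($[N]_0 = 0$), the measured compartment ratio follows the closed form

$$\frac{[N]}{[C]}(t) \;=\; \frac{K_e\,(1 - e^{-kt})}{1 + v K_e\,e^{-kt}},$$

where $K_e = [N]_e/[C]_e = k_I/k_E$ is the steady-state accumulation
ratio. Two algebraic points deserve emphasis because they are easy to
get wrong: $K_e$ must be the *ratio* $k_I/k_E$ (fitted accumulations
regularly exceed 1, which the fraction $k_I/(k_I+k_E)$ can never do),
and both compartments must share the single relaxation rate $k$ —
attaching $k_I$ and $k_E$ separately to the two exponentials is
inconsistent with the single-rate form of the ratio equation.
`transport_params()` enforces $k = k_I + k_E$ and
$v([N]_e - [N]_0) = [C]_0 - [C]_e$ to within $10^{-9}$, normalizing
concentrations so the volume-weighted total $v[N] + [C]$ equals 1.
Export experiments track the inverse ratio $[C]/[N]$, which obeys the
same functional form with $K_e = k_E/k_I$; `rates_from_fit()` performs
the mode-appropriate decomposition, exactly.

## Fitting recovery curves

`fit_recovery()` fits the recovery-phase ratio series by weighted
nonlinear least squares (Levenberg–Marquardt via minpack.lm). Choices:

* **Weights** $w_i = 1/(y_i + 0.05\,y_{\max})^2$. Fluorescence-ratio
  noise is multiplicative, so residual scale tracks signal level; the
  additive floor keeps the near-zero early points from dominating.
* **Starting values**: $K_e^0$ from the mean of the last fifth of the
  series, $k^0 = \ln 2 / t_{1/2}$ from the time to half plateau,
  $v^0 = 1$.
* **Bounds**: $K_e \in (0, 50]$, $k \in (0, 1]\ \mathrm{s^{-1}}$,
  $v \in [0.1, 10]$. Estimates within 1% of a bound value are flagged
  and later discarded as unphysical.
* **The volume factor is fixed at $v = 1$ by default.** This was a
  genuinely open design point, and fitting $v$ freely looks more
  general. In practice $v$ is weakly identified: near $t = 0$ the ratio
  behaves as $K_e k\,t/(1 + vK_e)$, so $v$ and $k$ trade off almost
  perfectly, and only mid-curve curvature separates them. On synthetic
  cells at 10% intensity noise the free-$v$ fit leaves the accumulation
  fine but inflates the rate error several-fold (to 15–26% median
  relative error, versus 3–4% with $v$ pinned), with fitted $v$
  scattering over [0.5, 2.1]. With signals normalized by total cell
  intensity $v = 1$ is also the natural convention. `v_policy = "free"`
  remains available, and on noiseless curves it recovers all three
  parameters to $10^{-6}$ — the limitation is statistical, not a coding
  artifact.

Standard errors come from the Jacobian cross-product at the optimum;
non-convergence and degenerate inputs (an identically zero ratio,
fewer than five recovery points) raise errors that `fit_cohort()`
converts into unconverged rows.

## Quality control and cohort statistics

`qc_filter()` mirrors the semiautomatic triage applied to real cell
cohorts, with three deterministic rules applied in order:

1. **UNPHYSICAL** — non-convergence, or any parameter within 1% of a
   box constraint.
2. **POOR_ACTIVATION** — the accumulating compartment never emptied:
   end-of-activation ratio above $\theta_{act}$ (default 0.5) times the
   fitted plateau $K_e$.
3. **OUTLIER** — $K_e$ or $k_I$ further than 3.5 scaled median absolute
   deviations from the construct-group median, computed over cells that
   passed the first two rules. On cohorts with 5% planted tenfold
   outliers this removes the plants while falsely discarding at most a
   couple of percent of genuine cells (asserted in the test suite).

Group asymmetry is summarized by the split statistic
$\mathrm{Split} = 100\,(\bar{x}_N/\bar{x}_C - 1)$ (percent; positive
when the N-terminal-entry construct is larger), and group differences
are tested with the two-tailed Mann–Whitney test with tie correction
(`compare_groups()`), which also reports group means with standard
errors. Reported splits are conventionally rounded to the nearest
integer percent.

## Synthetic cells: what is emulated and what is not

`cell_sim_spec()` bundles the kinetic truth with the imaging schedule
(defaults: 10 min activation, 45 min recovery, one frame per minute —
the standard schedule). The activation phase reuses the same
first-order machinery with the dominant rate swapped: from the
dark-state steady level the nucleus relaxes toward a cytoplasm-dominant
state (`activation_K_e = 0.05`) with rate
`activation_k` $= 8\times10^{-3}\,\mathrm{s^{-1}}$, emptying it
essentially completely within the 10 min window. The recovery phase is
generated from the closed form at the specified initial condition
($[N]_0 = 0$ by default) rather than continuing from the simulated
activation endpoint; this makes the generate–fit roundtrip exact at
zero noise, at the cost of a small discontinuity between phases that
only the activation-QC check ever looks at.

Intensity noise is multiplicative lognormal with a stated coefficient
of variation (default 0.1), applied independently per frame and
compartment — fluorescence noise scales with signal. The frame
renderer (`gen_frames()`) paints uniform elliptical compartments,
distributes a fixed photon budget according to the kinetic truth, adds
an affine background plane and Poisson shot noise. Not emulated:
photobleaching, the LOV2 photocycle, camera-specific noise, cell
motion, or a point-spread function. Passing tests therefore show the
quantification and fitting machinery is correct under the stated noise
model, not that it is robust to every artifact of real microscopy;
masks for real data are supplied externally, as in manual analysis.

Quantification itself (`quantify_frame()`) integrates
background-corrected intensities over the nucleus and whole-cell masks
and normalizes by total cell signal, so $N_{norm} + C_{norm} = 1$
exactly and the result is invariant to any uniform additive background
and any global gain. The ratio uses integrated intensities; compartment
size effects are absorbed by $v$ and, for synthetic stacks, by the
area ratio, which cancels within the model family being fitted.

## Polymer elasticity and the force-ramp simulator

Unfolding releases contour length that extends under force following
the freely jointed chain:

$$x(F) = \Delta L_c\left[\coth\beta - \frac{1}{\beta}\right],
  \qquad \beta = \frac{F\,l_K}{kT},$$

with Kuhn length $l_K = 1.1\,\mathrm{nm}$ and
$kT = 4.11\,\mathrm{pN\,nm}$ fixed (`fjc_constants()`). The forward
form is evaluated by series below $\beta < 10^{-4}$ for stability;
`contour_from_step()` is its exact inverse at the rupture force. At
50 pN a 65 nm increment extends to 60 nm — the worked conversion for
the strong unfolding event of a fluorescent-protein cargo.

`gen_ramp_trajectory()` simulates a linear ramp (1 pN/s default) over
states with Bell kinetics $k(F) = k_0 e^{F\Delta x/kT}$. The rupture
force of each state is drawn exactly by inverse-CDF sampling from the
ramp survival function

$$S(F) = \exp\!\left[-\frac{k_0 kT}{r\Delta x}
  \left(e^{F\Delta x/kT} - 1\right)\right],$$

whose analytic mode $F^\ast = (kT/\Delta x)\ln(r\Delta x / k_0 kT)$
anchors the recovery tests. Default states emulate an mCherry-like
cargo: a weak state releasing 22 nm of contour near 15 pN and a strong
state releasing 65 nm near 50 pN; the Bell parameters behind those
modes are free simulator inputs, not measured quantities. Extension is
the sum of FJC extensions of already-released increments at the current
force, plus optional drift and Gaussian noise (default 1 nm at 100 Hz).
No unfolding order is imposed — each state draws independently.

Because the rupture-force distribution is broad
($kT/\Delta x \approx 16$ pN for the calibration state), a naive kernel
or histogram mode of 10,000 draws scatters by several pN.
`density_mode()` therefore evaluates the kernel mode at two enlarged
bandwidths and extrapolates the $O(h^2)$ smoothing bias away
($m = (9m_{2h} - 4m_{3h})/5$), which brings the worst-case error across
seeds under 2 pN at that sample size.

## Step detection

`detect_steps()` scores every sample with the contrast between the
medians of the flanking half-second windows and calls an event where
the contrast exceeds a threshold — the larger of `min_step` (default
5 nm) and a noise-calibrated level. Noise is estimated robustly from
first differences ($\hat\sigma = \mathrm{MAD}(\Delta x)/\sqrt2$); the
sd of a difference of two $k$-sample medians is
$\hat\sigma\sqrt{\pi/k}$, and the multiplier is chosen by a
Bonferroni-style allowance over the $\approx n/k$ effectively
independent contrasts so that a noise-only trace produces any false
event with probability at most `fp_rate` (default 0.05). Between
ruptures the elastic baseline drifts by well under 0.1 nm per window at
the default ramp, so no explicit detrending is needed at these scales.
The event force is read off the deterministic ramp at the change-point
sample, the step is the post-minus-pre window-median difference (an
instantaneous-step estimate would differ by the sub-0.1 nm growth of
the new increment across the window), and the contour-length increment
follows from the FJC inverse at that force. On two-event traces with
1 nm noise the detector finds at least 95% of events with mean
contour-length error below 1 nm, and flags essentially no events on
noise-only traces (both asserted in the test suite).

## The transcription-factor disorder survey

For each factor with a predicted nuclear localization signal, the
survey keeps one NLS (highest predictor score, earliest start on ties),
locates it by its interval midpoint, and defines the terminal region:
from the N-terminus through the NLS end when the midpoint falls in the
first half of the sequence, from the NLS start through the C-terminus
otherwise (a midpoint exactly at half length counts as N-side; NLS
residues are included — both conventions chosen for determinism and
echoed in the output metadata). Mean disorder over that region is
compared with the mean over the full sequence. Isoform groups
contribute one record each (longest sequence, lexicographic tie-break).
External predictors are consumed as inputs (per-residue scores and NLS
intervals as TSV, sequences as FASTA); the package never reimplements
them.

The published comparison style is an unpaired two-tailed Mann–Whitney
between the sets of per-protein full-sequence and region means, and
`run_survey()` reproduces exactly that by default. Statistically,
however, the two samples are paired (each record contributes to both)
and the region means form a scale mixture (regions range from a few
dozen to several hundred residues). Both features make the unpaired
rank test *conservative*: simulated at survey scale under the null its
size is roughly 0.015–0.025 rather than 0.05, and when between-protein
baseline spread dominates — as it does in real data — the coupling is
nearly total and the size collapses toward zero. The test never
over-rejects, so published significances are if anything understated,
but its type-I error is not nominal. The paired Wilcoxon signed-rank
variant (`test = "wilcoxon-paired"`, offered as a clearly labelled
extension) is exactly calibrated under the null and is the variant a
fresh analysis should prefer.

The generator (`gen_tf_dataset()`) plants a known elevation `delta`
inside the true terminal region on top of a per-protein baseline
(mean 0.45, between-protein sd 0.1, per-residue noise sd 0.12, all
clipped to [0, 1], lengths 150–1200 residues). The between-protein
baseline spread emulates the wide distribution of overall disorder
across real factors. At `delta = 0.15` and 300 records the survey
detects the elevation in the correct direction in essentially every
replicate; at `delta = 0` the unpaired test rejects at the conservative
rates described above.

## Backbone hydrogen bonds and strand anchoring

`find_backbone_hbonds()` applies static geometric criteria to parsed
PDB coordinates: backbone amide N donors (proline excluded) and
carbonyl O acceptors of residues at least two apart in sequence, a
donor–acceptor distance cutoff of 4 Å, and — when the amide hydrogen is
present in the model — a D–H···A deviation from linearity of at most
30° (i.e. the angle at the hydrogen is at least 150°, the common
contact-analysis reading of an "angle cutoff"). When no hydrogen
exists the bond is accepted on distance alone and flagged per bond, so
distance-only calls are always auditable. Counts are monotone in both
cutoffs by construction. `parse_structure()` selects one model (first
by default, for NMR ensembles) and collapses alternate locations to the
highest-occupancy conformer.

Strand segments are derived from the bond pattern itself
(`find_strands()`): two rungs of a ladder — bonds $(i,j)$ and
$(i',j')$ with $|i-i'|\le2$, $|j-j'|\le2$ at sequence separation three
or more — mark their residues as strand-like, and runs of such residues
become strands. This deliberately lightweight assignment avoids an
external DSSP dependency and is sufficient to name the terminal strands
of a small β-sandwich; resolved ranges are returned rather than
hard-coded so any counting over them is auditable.
`interstrand_count()` then counts bonds crossing two disjoint residue
sets in either direction — the mechanical-clamp count between the
terminal strands of an immunoglobulin-like domain being the canonical
use. `synthetic_beta_sheet()` constructs an ideal antiparallel
two-strand geometry (alternating doubly-bonded and non-bonded rungs,
2.9 Å N···O at perfect linearity) purely as a fixture: it is labelled
synthetic throughout and models no real protein. Real-structure counts
require the corresponding PDB entry on disk; no coordinates are bundled
with the package.

## Problem sizes and numerical conventions

The validation suite runs at the scales the analyses are designed for:
100-cell cohorts at 10% noise for parameter recovery, 1,000 ramp traces
per condition for detector sensitivity and false-positive calibration,
10,000 draws for the rupture-force distribution, and up to 1,000
replicate surveys of 300 factors for the survey's operating
characteristics. Units are fixed throughout: seconds, pN, nm,
Å for structures; rates in s$^{-1}$ (displayed as ks$^{-1}$ where
conventional); disorder scores in [0, 1] with 1 fully disordered.
All generators take integer seeds and are bit-reproducible at equal
seeds (via `withr::with_seed`, leaving the caller's RNG untouched).

## Known limitations

* The kinetic model is strictly two-pool and first-order; saturating
  transport, photoswitching kinetics and multi-compartment geometries
  are out of scope.
* The step detector assumes abrupt steps on a slowly varying baseline;
  unfolding intermediates shorter than the scoring window merge into
  single events.
* The strand finder is pattern-based, not a full secondary-structure
  assignment; for structures with irregular edge strands, inspect the
  resolved ranges it reports.
* The survey's default unpaired test is conservative by construction
  (see above); use the paired variant for calibrated inference.
* Synthetic generators validate correctness under stated noise models;
  they are not substitutes for controls on real data.
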
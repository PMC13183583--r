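# nucleoflux

Does a protein cross the nuclear pore complex faster when it enters
N-terminus first or C-terminus first? Answering that requires stitching
together several quantitative analyses: light-gated shuttling kinetics in
live cells, image quantification, single-molecule force spectroscopy of
the cargo's terminal mechanical stability, sequence-level surveys of
disorder around nuclear localization signals (NLS), and hydrogen-bond
counting on structures. nucleoflux implements that pipeline for R, with
seeded synthetic-data generators for every input so each stage can be
validated against known ground truth.

It is aimed at quantitative cell biologists and single-molecule
biophysicists who have recovery time courses, force-ramp trajectories, or
predictor outputs in hand and want the corresponding estimates with
explicit, testable conventions.

## The models at the core

**Transport kinetics.** A photoswitchable construct exchanges between
nucleus and cytoplasm by first-order import and export (rate constants
k_I, k_E). After switching the light off, the compartment ratio recovers
as

    [N]/[C](t) = K_e (1 − e^{−kt}) / (1 + v K_e e^{−kt})

with k = k_I + k_E, accumulation K_e = k_I/k_E, and volume factor v.
Fitting a recovery curve yields (K_e, k), which decompose exactly into
k_I = k·K_e/(1+K_e) and k_E = k/(1+K_e). Asymmetry between
N-terminal-entry and C-terminal-entry constructs is summarized as
`Split = 100·(mean_N/mean_C − 1)` percent, with two-tailed Mann–Whitney
group tests.

**Polymer elasticity and unfolding.** Force-ramp trajectories are scanned
for unfolding steps by a noise-calibrated change-point detector; each
step at force F converts to a contour-length increment through the
freely jointed chain, x(F) = ΔL_c [coth(β) − 1/β], β = F·l_K/kT, with
l_K = 1.1 nm and kT = 4.11 pN·nm. The ramp simulator draws rupture
forces exactly from the Bell-model survival function, so detector
sensitivity and bias are measurable against truth.

**Disorder survey.** For each transcription factor, the highest-scoring
NLS defines a region to the closest terminus (midpoint 50% rule); mean
disorder of that region is compared with the full sequence across the
cohort.

**Structure.** Backbone hydrogen bonds are detected with a 4 Å
donor–acceptor distance and 30° deviation-from-linearity cutoff, and
counted between β-strand residue ranges derived from the bond pattern
itself (for example, the mechanical clamp joining the terminal strands
of titin's Ig27 domain).

## Worked example

Simulate two 30-cell cohorts — an import-forward construct
(K_e = 1.87, k = 4.94 ks⁻¹) and a slower import-reverse construct
(K_e = 1.19) — then fit, filter and compare:

```r
library(nucleoflux)

tcs_fwd <- lapply(1:30, function(i) gen_cell_timecourse(cell_sim_spec(
  params = transport_params(K_e = 1.87, k = 4.94e-3),
  noise_cv = 0.1, seed = i)))
tcs_rev <- lapply(1:30, function(i) gen_cell_timecourse(cell_sim_spec(
  params = transport_params(K_e = 1.19, k = 3.79e-3),
  noise_cv = 0.1, seed = 100 + i)))

cohort <- qc_filter(rbind(
  fit_cohort(tcs_fwd, construct = "import-forward"),
  fit_cohort(tcs_rev, construct = "import-reverse")))
s <- summarize_cohort(cohort)
print(s$table, digits = 3)
#>        construct  n K_e_mean K_e_sem k_I_mean  k_I_sem
#> 1 import-forward 30     1.82 0.00698  0.00325 3.42e-05
#> 2 import-reverse 30     1.16 0.00517  0.00205 2.26e-05
```

The fitted accumulations and rates recover the generating truths
(k_I in s⁻¹: 3.25e-3 vs the true 3.22e-3), and the asymmetry statistics
read:

```r
cat(sprintf("accumulation split: %.0f%%  rate split: %.0f%%\n",
            s$split_accumulation, s$split_rate))
#> accumulation split: 57%  rate split: 58%
cat(sprintf("Mann-Whitney P (rate): %.2g\n", s$test_rate$p.value))
#> Mann-Whitney P (rate): 1.7e-17
```

i.e. the forward construct accumulates ~57% more and imports ~58%
faster — the per-cohort analogue of computing
`split_percent(3.22, 2.06)` = 56% from published group means.

On the single-molecule side, one simulated mCherry-like ramp trace:

```r
fjc_extension(50, 65)         # 65 nm of contour extends to ~60 nm at 50 pN
#> [1] 60.14273
traj <- gen_ramp_trajectory(ramp_sim_spec(seed = 11))
print(detect_steps(traj), digits = 3)
#>    t_s F_pN step_nm dLc_nm
#> 1 15.6 15.6    16.7   21.9
#> 2 58.0 58.0    61.3   65.5
```

Two unfolding events are detected — a weak ~22 nm contour-length release
near 15 pN and a strong ~65 nm release at higher force — matching the
generator's ground truth.

See `vignettes/nucleoflux-methods.Rmd` for the full model derivations,
estimator choices, calibration of the step detector, and known
limitations.

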
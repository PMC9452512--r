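---
title: "Occupancy models and inference for binding-site clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy models and inference for binding-site clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindclust)
```

## The problem

Eukaryotic regulatory sequences frequently contain clusters of proximal
binding sites for the same transcription factor (TF), often of low affinity,
and sometimes so dense that neighboring sites share basepairs. `bindclust`
models equilibrium TF binding to such clusters, infers binding parameters
from saturation-binding measurements of the kind produced by microfluidic
(iMITOMI-style) assays, and relates predicted occupancies to gene-expression
readouts from plate-reader induction experiments. Because the measurements it
was designed around are not publicly deposited, the package ships seeded
generators that emulate their statistical structure; every inference routine
is validated by parameter recovery against those generators.

## The equilibrium binding model

A cluster design places $n$ sites on a target (90 bp by default), each with
a dissociation constant $K_{d,i}$ (in nM). A microstate $\sigma$ is a subset
of bound sites. Its statistical weight is

$$w(\sigma) = \prod_{i \in \sigma} \frac{c}{K_{d,i}}
  \; e^{-\varepsilon_{\mathrm{clash}}\, m(\sigma)},$$

where $c$ is the free TF concentration, $m(\sigma)$ counts bound pairs that
share at least one basepair, and $\varepsilon_{\mathrm{clash}} \ge 0$ (in
$k_BT$) is the steric penalty per clashing pair. The partition function is
$Z(c) = \sum_\sigma w(\sigma)$ and the mean occupancy — the average number
of TFs bound per DNA molecule — is
$\langle N\rangle(c) = \sum_\sigma |\sigma|\, w(\sigma) / Z(c)$.

Three modes are exposed:

* **independent** — no interaction terms; $\langle N\rangle$ is the
  Langmuir sum $\sum_i c/(c + K_{d,i})$, evaluated in closed form.
* **exclusive** — full steric occlusion: states with $m(\sigma) > 0$ are
  removed (for a two-site overlapping cluster this leaves three states).
* **permissive** — all $2^n$ states, each clashing pair paying
  $\varepsilon_{\mathrm{clash}}$. Setting
  $\varepsilon_{\mathrm{clash}} = 0$ recovers independent binding;
  $\varepsilon_{\mathrm{clash}} \to \infty$ recovers the exclusive model
  (numerically indistinguishable by 30 $k_BT$).

Choices made where the formulation was genuinely open:

* **Weight convention.** Weights use the dimensionless per-site factor
  $c/K_d$ (equivalently energies $\varepsilon_{bs} = \ln(K_d/c_\mathrm{ref})$
  under a reference concentration; `kd_to_energy()` converts). This makes
  the single-site curve exactly $c/(K_d + c)$, anchoring the model to the
  standard saturation binding form.
* **Pair-additive clash.** With three or more simultaneously bound,
  mutually overlapping sites, each clashing pair contributes one penalty
  multiplicatively. This is the minimal extension of the two-site model;
  nothing in the two-site data constrains higher-order terms.
* **Per-family clash energies.** The penalty is not forced to scale with
  the overlap extent (1 vs 3 shared bp); each overlap family is fitted
  separately.
* **Coordinates.** 0-based, half-open intervals; shared basepairs are the
  interval intersection, so overlap arithmetic is exact. Sites are
  strand-agnostic: occupancy depends only on intervals and $K_d$s.
* **Enumeration cap.** State enumeration is $2^n$ and refuses $n > 16$;
  real clusters of interest have $n \le 10$. Non-specific (NS) sites carry
  zero weight and are excluded before enumeration.

Affinity classes follow the fold-weaker ladder S (1×), W (10×), W− (20×),
V (50×), V− (100×) relative to a consensus $K_d$ (10 nM by default for the
zinc-finger-like motif; motif length 9 bp, 6 bp for E-box-like sites).

## Saturation-binding inference

`fit_sbc()` fits the two-parameter curve $B(c) = B_\mathrm{max}\,c/(K_d+c)$
to per-chamber bound signals by Levenberg–Marquardt least squares.
The deliberate simplification to a single effective $K_d$ per target (rather
than per-site parameters) mirrors how multi-site saturation data are
reported. Initialization is deterministic: $K_d$ starts at the concentration
nearest half-maximal mean signal and $B_\mathrm{max}$ at the maximum mean
signal. When a DNA-signal column is present the bound signal is first
normalized by the per-chamber DNA signal relative to its mean, the assay's
convention for removing chamber-to-chamber DNA loading variability.

**Credible intervals.** The published interval convention ("5 to 95%
confidence intervals" from an MCMC sampler) is implemented as posterior
percentile (credible) intervals. The sampler works on
$(\log K_d, \log B_\mathrm{max}, \log\sigma)$ with flat priors inside broad
bounds (±9 natural-log units around the point fit), Gaussian likelihood,
and $\sigma$ estimated as a free parameter. Kernels alternate between a
symmetric random walk (proposal covariance from the numeric Hessian at the
mode, scalar scale adapted during burn-in only) and an independence
Metropolis–Hastings step whose proposal is the Laplace approximation with
covariance inflated 1.5×; the composition keeps the chain exact while
giving near-independent draws on this well-behaved 3-parameter posterior.
Defaults: 4 chains, 1000 burn-in + 2000 kept iterations, split-R-hat
convergence gate at 1.01 — if any parameter exceeds the gate the intervals
are withheld with a warning rather than reported. All randomness flows
through one integer seed.

**Occupancy calibration.** $B_\mathrm{max}$ grows linearly with the number
of identical saturating sites; the slope of the ordinary least-squares line
$B_\mathrm{max}(n)$ (`calibrate_occupancy()`) is the fluorescence per bound
TF. The intercept is free by default (a through-origin option exists, since
the published regression's handling of the intercept is not stated);
`to_occupancy()` divides by the step only, so zero signal maps to zero
occupancy. Restricted fit ranges (e.g. sites 1–3) support libraries whose
largest members do not saturate.

**Cross points.** `cross_point()` finds where a cluster's occupancy curve
reaches a reference curve by scanning 400 log-spaced points on
$[10^{-3}, 10^{6}]$ nM for sign changes and bisecting with `uniroot` on
log-concentration. Multiple crossings produce a warning and all roots; a
missing sign change raises a typed "no crossing" condition and coincident
curves a "degenerate" condition. For $n$ identical independent weak sites
against one strong site the root is checked against the closed form
$c^* = (K_w - nK_s)/(n-1)$.

**Clash-energy fitting.** With per-site $K_d$s fixed from independent
single-site characterization, `fit_clash_energy()` fits
$\varepsilon_{\mathrm{clash}}$ (the signal scale is profiled analytically)
by least squares. The RSS profile in $\varepsilon_{\mathrm{clash}}$ is not
guaranteed unimodal — the free scale trades off against curve shape — so a
121-point grid on $[0, 30]$ $k_BT$ is scanned before local refinement; if
the upper boundary fits essentially as well as the interior optimum the
data carry no evidence against full exclusion and the boundary value is
reported. The CI is a profile-likelihood interval (Gaussian RSS profile,
$\chi^2_1$ cutoff). The exclusive model (scale only) is fitted alongside,
and both carry AIC/BIC in the Gaussian forms
$n\ln(\mathrm{RSS}/n) + 2k$ and $n\ln(\mathrm{RSS}/n) + k\ln n$, with $k$
counting the noise variance in both models so the criterion difference
isolates the clash parameter.

## In-vivo response processing and thresholded activation

Plate-reader series are blank-subtracted per channel and divided by OD600
at each time point; points with blank-subtracted OD below 0.01 are masked
to avoid division blow-ups. Expression is summarized as the mean over the
closed window 8.5–9.5 h after induction (7 readings at the 10-minute
cadence, assumed aligned to induction at time zero). The TF-specific
response is the induced-minus-uninduced difference of window means; the
non-specific response is the uninduced difference against a designated
reference strain (the no-site NS promoter, or an ablated-ablated promoter
for native-promoter libraries) and may be negative. Replicates are
summarized per replicate then averaged, unpaired across conditions.

Nuclear TF concentrations are derived from copy numbers by
$c = \mathrm{copies}/(N_A V)$ with the nuclear volume an explicit
parameter: 4.2 fL reproduces the published yeast conversions
(538 copies ≈ 213 nM, 3334 ≈ 1318 nM), and is back-derived rather than
reported, hence never hidden inside a constant. Documented reference
values: ≈355 nM for Pho4, and a 213–1322 nM sweep for zinc-finger
activators, over which occupancy predictions should be examined for
sensitivity.

`fit_threshold_model()` fits the hinge
$\mathrm{expr} = b + s\,\max(0, \langle N\rangle - \theta)$: expression
silent up to an occupancy threshold $\theta$ (empirically around one bound
TF), then increasing with occupancy rather than affinity. The published
relationship is described only as thresholded; the continuous hinge with a
free baseline is the minimal implementation. $\theta$ is profiled over a
200-point grid (the other two parameters are linear given $\theta$) and
refined by golden-section search; the CI is a promoter-resampling
bootstrap. The threshold is declared unidentifiable when occupancies do not
straddle the fitted value or when the hinge explains less than half the
expression variance — the signature of a library whose promoters all sit
below the true threshold, where expression is flat and carries no
information about $\theta$. Note that $\theta$ is expressed in predicted
occupancy units, so it rescales with the assumed nuclear concentration;
the thresholded shape, not the numeric $\theta$, is the
concentration-robust feature.

## What the synthetic generators emulate

`simulate_imitomi()` emulates the multiplexed chip geometry: each target
measured in replicate chambers (default 30, within the instrument's typical
20–84) across 8 log-spaced concentration sections spanning 1–30000 nM. Per
chamber, the DNA signal has lognormal variability (sdlog 0.1) and the bound
signal is `step_rfu * <N>_true(c) * (dna/dna_ref)` plus Gaussian noise with
SD a fraction (default 5%) of the single-site saturation signal
(`step_rfu` default 500 RFU). The generating model is independent binding
unless the design contains overlapping sites, in which case it is
permissive with a configurable clash energy; an explicit mode override
supports exclusive-truth simulations for model-selection studies. The free
concentration is treated as exactly known — the assay measures it directly,
and measurement error on concentration is out of scope.

`simulate_platereader()` produces logistic OD600 growth with GFP
proportional to OD at a production level
`baseline + leak_per_site * n_sites`, plus the hinge
`slope * max(0, <N> - theta)` when induced, Gaussian reading noise, and
additive channel blanks, every 10 min over 20 h. The leak term encodes the
observed non-specific activation that scales with site count.

Features of real data deliberately **not** emulated: kinetics and dwell
times (equilibrium only), photobleaching and optical artifacts,
concentration-measurement error, cell-to-cell expression noise beyond
Gaussian reading noise, nucleosome dynamics, and TF cooperativity. Passing
recovery tests therefore demonstrates the correctness and calibration of
the inference machinery under the stated noise model — not robustness to
every artifact of real measurements.

`fixture_library()` assembles the design families the analyses exercise:
S1/S3/S6, W1–W6, V−3/V−6, W−6, the mixed cluster W3V−3 with a reordering,
a two-site spacing series (gaps 0–20 bp), overlap series with exactly 1 or
3 shared bp (strong and weak, 2–4 sites), a no-site NS target, and
PHO5-style two-region promoters with native/ablated/cluster (N/A/C)
combinations. The exact coordinates of the original in-vitro library are
not published; these fixtures reproduce its structure, not its sequences.

## Problem sizes and verification

The test suite checks the enumeration engine bit-for-bit against an
independent brute-force subset loop and the two-site closed form
$Z = 1 + x_1 + x_2 + x_1x_2e^{-\varepsilon}$ (tolerance $10^{-12}$), the
independence/exclusivity limits ($10^{-10}$ / $10^{-8}$), and the solver
contracts of the cross-point and threshold fitters. Stochastic claims use
fixed seeds and deliberately modest problem sizes chosen to make the suite
quick to run end-to-end: K_d recovery uses 50 datasets of 8 × 20
observations at 5% noise (median relative error < 10%); interval
calibration uses 100 datasets of 8 × 5 observations with 3 chains each
(5–95% intervals cover the truth in a central binomial band around 90%);
clash-energy recovery uses 2% noise (±0.3 $k_BT$); threshold recovery uses
20 promoters at 10% noise (±0.15); and model selection uses 50
permissive-truth and 20 exclusive-truth datasets of 8 × 10 observations.
The `analysis/` scripts run the same machinery at library scale (57
targets, ~14k chambers) with a fixed seed.

## Known limitations

* The permissive model's pair-additive clash is an assumption beyond the
  two-site data that motivate it.
* A single effective $(K_d, B_\mathrm{max})$ per target compresses
  mixed-affinity clusters into one midpoint; per-site inference from
  cluster data is intentionally out of scope.
* Credible-interval calibration is demonstrated under the generator's
  Gaussian, constant-variance noise; heavy-tailed chamber artifacts would
  require a different likelihood.
* The hinge threshold is reported in predicted-occupancy units and
  inherits any bias in the assumed nuclear concentration and in-vitro
  $K_d$s.
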
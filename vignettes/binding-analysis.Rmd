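---
title: "Quantitative binding and transport analysis for ferroportin inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative binding and transport analysis for ferroportin inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpnbind)
```

## The problem

Ferroportin (FPN) is the only known cellular iron exporter; the hormone
hepcidin and the small molecule vamifeport inhibit it by occupying an
overlapping site. Quantifying how tightly such ligands bind — for wild-type
FPN and for binding-site point mutants — rests on a fluorescence-polarization
(FP) displacement assay: a TMR-labeled hepcidin tracer tumbles slowly when
bound to the transporter, raising its polarization, and unlabeled competitors
lower the signal again as they displace it. This package implements that
analysis chain end to end, together with the auxiliary assays used to show
the protein is folded and functional: a melting-temperature (Tm) assay, a
proteoliposome Co^2+^ transport assay, and surface plasmon resonance (SPR)
kinetics for nanobody binders.

## The FP inference chain

Each well yields parallel and perpendicular intensities, combined as

$$FP = 1000\,\frac{F_{par} - g\,F_{perp}}{F_{par} + g\,F_{perp}} \quad
  \text{(mP)},$$

with an optional instrument G-factor (default 1 — plate readers typically
export G-corrected channels, and the assay this emulates reports none).

**Stage 1 (direct binding).** Titrating protein $x$ against a fixed 10 nM
tracer follows a one-site isotherm plus a linear nonspecific term:

$$Y = B_{max}\frac{x}{x + K_D} + NS\,x + \text{background}.$$

All constructs are fitted globally with $B_{max}$ and the background
constrained to common values — the tracer is the same molecule in every
titration, so its free-tracer FP and its bound-state signal should not vary
by construct — while $K_D$ and $NS$ are per construct. Wells blocked with
30 µM vamifeport contain no specific signal and are co-fitted as
$NS\,x + \text{background}$, anchoring the nonspecific component.

**Stage 2 (displacement).** With protein fixed at $L_{dis}$ (400 nM, or
800 nM for constructs that bind tracer weakly) and competitor $x$ titrated,
two fits are run:

1. An empirical four-parameter Hill fit on the FP scale with Top/Bottom
   shared across competitors of the same construct, yielding an IC~50~.
   Because displacement *lowers* FP, the logistic argument is implemented as
   $(\log_{10}x - \log IC_{50})\,n$ so that a positive Hill coefficient
   describes the decreasing curve; this equals the textbook increasing form
   with $n$ negated, a choice verified numerically (the increasing-argument
   variant evaluated at $x$ above the IC~50~ returns values near Top, which
   contradicts a displacement read).
2. A mechanistic competition fit. FP is first converted to fractional
   saturation through the stage-1 parameters,
   $y = (FP - \text{background} - NS \cdot L_{dis})/B_{max}$ — the
   conversion is a linear inversion; at fixed $L_{dis}$ the nonspecific term
   is a constant offset, so the stage-2 KD is invariant to it — then fitted
   to
   $$Y = \frac{L_{dis}}{L_{dis} + K_{D(dis)}\left(1 + x/K_{D(x)}\right)},$$
   with $L_{dis}$ and the stage-1 tracer $K_{D(dis)}$ fixed and the
   competitor $K_{D(x)}$ free. Free-ligand depletion is neglected
   (free ≈ total), the standard approximation for this plate layout; the
   model is implemented exactly as written.

The two stage-2 routes are linked by an identity this package exploits for
validation: against $\log_{10}x$ the competition curve *is* a Hill curve
with $n = 1$ and
$IC_{50} = K_{D(x)}\,(1 + L_{dis}/K_{D(dis)})$. `implied_ic50()` is that
closed form, `kd_from_ic50()` its inverse, and the test suite checks both
against a bisection root-finder and against Hill refits of noiseless
competition-generated data. With the wild-type numbers
($K_{D(dis)} = 100$ nM, $L = 400$ nM) a 25 nM vamifeport KD implies a
125 nM IC~50~ and a 150 nM hepcidin-25 KD implies 750 nM — consistent with
the empirical IC~50~s of roughly 130 and 700 nM.

Stage order is strict: competition fits refuse to run without stage-1
parameters rather than fall back to defaults. Constructs whose specific
signal at the top of the titration is smaller than twice its delta-method SE
are reported "no specific binding" and excluded from stage 2 — that mirrors
how titrations overlapping the blocked control are treated.

```{r pipeline-example}
plate <- gen_study_plate(seed = 42, noise_sd = 5)
report <- run_pipeline(plate, study_config(seed = 42))
report$table[, c("construct", "k_d_tracer", "k_d_vamifeport")]
```

## The fitting engine

All stages share one unweighted least-squares engine (Levenberg–Marquardt
via minpack.lm) supporting shared, fixed, and bounded parameters.
Unweighted residuals match the defaults of the commercial packages this
analysis is usually run in, and no weighting scheme is implied by the assay.
Numerical choices:

* Concentration-scale parameters ($K_D$, IC~50~, $K_M$, rate constants) are
  fitted internally as log~10~ values: positivity holds by construction, the
  optimizer sees a well-scaled axis, and linear-scale SEs are recovered by
  the delta method ($se = v \ln 10\, se_{\log}$).
* Multi-start: besides the data-derived initial guess, seven log-spaced
  restarts of the log-scale parameters spanning the observed concentration
  range; lowest residual sum of squares wins, ties broken by iteration
  count. Dose-response surfaces are mildly multimodal when plateaus are
  weakly determined, and restarts cost little at these problem sizes.
* Convergence at 1e-10 relative RSS change, at most 10,000 function
  evaluations per start; solutions on a box bound are flagged.
* Asymptotic covariance from a forward-difference Jacobian at the optimum,
  $\hat\sigma^2 (J^\top J)^{-1}$, with a pseudo-inverse fallback for
  rank-deficient cases. A replicate-level case bootstrap (`bootstrap_se()`)
  is available as a cross-check; the reported ± values are asymptotic fit
  SEs (published ± values of this kind are sometimes SEMs across
  experiments instead — both are computable here, and they agree in order
  of magnitude at these designs).
* Replicates are fitted as pooled individual points; means are for display
  only.

## Auxiliary assays

**Thermal stability.** Monomer-peak heights normalized to the 4 °C
reference (100%) are fitted with a free-plateau logistic in temperature,
top initialized at 100, bottom bounded at 0. Per-condition normalization is
used (each series carries its own 4 °C reference). A series that does not
decrease raises "no transition detected"; a midpoint outside the sampled
range is flagged extrapolated. `delta_tm()` propagates SEs under
independence.

**Transport.** The calcein-quench trace is flat until CoCl~2~ is added,
then quenches as Co^2+^ enters the liposomes; calcimycin defines the
full-quench endpoint. The initial rate is the linear-fit slope over the
first 30 s after CoCl~2~ (configurable; 60 s baseline window), normalized by
the quenchable span so the result is a fraction of quenchable signal per
second — invariant to gain and offset of the raw fluorescence. The rate
extraction window is a design choice (the source protocol does not state
one): 30 s is long enough for a stable slope at 4 s sampling and short
enough that the exponential approach biases the slope by under 5% at the
default $v_{max}$. Rates minus the zero-substrate blank are fitted with
standard Michaelis–Menten kinetics — the simplest saturable single-substrate
law, which is all a reported "apparent $K_M$" presumes.

**SPR.** Sensorgram ladders are fitted globally to the 1:1 Langmuir model —
one $k_{on}$, $k_{off}$, $R_{max}$ across all analyte concentrations, the
dissociation of each curve starting from the model's own end-of-association
response — and $K_D = k_{off}/k_{on}$ is reported in nM with a
full-covariance delta-method SE.

## What the synthetic data emulate — and what they do not

The generators (`gen_direct_titration()`, `gen_displacement()`,
`gen_melt()`, `gen_transport_trace()`, `gen_spr()`, and the study-level
`gen_study_plate()`) are deterministic functions of a design and a seed and
are exact inverses of the fitters in the zero-noise limit. The default
designs are the study conditions: 24-point titrations from 13 nM to 6 µM
against 10 nM tracer, three replicates, Gaussian FP noise of 5 mP mapped to
intensity pairs at fixed total intensity, two-fold competitor dilutions from
30 µM with a zero-competitor well, melting series up to 75 °C, 4 s transport
sampling, and the published analyte ladders for SPR. Shared signal truths
($B_{max} = 100$ mP, background 220 mP, $NS = 0.0125$ mP/nM) are chosen so
the displacement plateaus land near the published shared Top/Bottom values
(307/225 mP at 400 nM protein). An intensity-level noise mode (per-channel
CV) exists because real plate noise lives on intensities; FP-level noise is
the default because that is the scale on which assay noise is usually
quoted.

The generators do not emulate instrument drift, well-position or edge
effects, tracer depletion at high protein, liposome size heterogeneity, or
mass-transport-limited SPR. Passing recovery tests therefore demonstrates
that the inference chain is correct and well calibrated under the assay's
idealized statistical model — not that it is robust to systematic artifacts
real plates can show.

## Problem sizes and validation

The test suite validates each model against independent oracles (bisection
root-finding for the IC~50~ identity, lattice search for the optimizer,
closed-form identities for the rest) and runs a 200-repetition seeded
recovery study of the full two-stage pipeline at the study design — six
constructs, ~1,400 wells per repetition — checking that each of the 16
ground-truth KDs falls within 3 asymptotic SEs of its estimate in at least
95% of repetitions. That study is the package's calibration claim for the
reported uncertainties; it completes in about a minute on one core. The
per-KD reading of coverage is deliberate: jointly requiring all 16
intervals to cover simultaneously would test a different (and stricter)
property than the per-parameter SEs claim.

## Known limitations

* The FP-to-saturation conversion is the linear stage-1 inversion; if the
  true conversion involved tracer depletion or intensity weighting, stage-2
  KDs would shift accordingly.
* Stage-2 SEs treat the stage-1 parameters as known; the recovery study
  shows coverage survives this at the study's noise level, but at much
  higher noise the neglected propagation would bite.
* Ligand-depletion-exact (quadratic) isotherms and cooperative multi-site
  models are out of scope, as are parsers for instrument-native exports.
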
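---
title: "Methods: preclinical-to-human PK extrapolation of E0703"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preclinical-to-human PK extrapolation of E0703}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(e0703pk)
```

E0703 is an estradiol-derived steroid developed as a radioprotectant. Its
oral pharmacokinetics are extreme in two ways that drive every modelling
choice in this package: it is very lipophilic (logP 5.13) and essentially
insoluble (5e-5 mg/mL at pH 7), and its absolute oral bioavailability is
below one percent in both Rhesus monkeys and humans. The package
implements the full inference chain from animal and in vitro data to a
predicted human concentration-time profile: non-compartmental analysis
(NCA), in vitro ADME parameter derivation, interspecies clearance scaling,
tissue-composition partition-coefficient (Kp) prediction, and a whole-body
perfusion-limited PBPK model with a compartmental absorption-and-transit
(CAT) oral module. This vignette records the modelling conventions, the
open design choices and why they were resolved the way they were, and what
the synthetic-data machinery can and cannot demonstrate.

## Non-compartmental analysis

`nca()` computes Cmax/Tmax directly from the samples, AUC by trapezoid
(linear by default; `linear_up_log_down` applies the log-trapezoid only to
segments with positive, declining endpoints), and extrapolates with
`AUC0-inf = AUC0-t + Clast/lambda_z`. The terminal slope search
(`estimate_lambda_z()`) fits every suffix of at least three
positive-concentration points after Tmax and keeps the best adjusted
R-squared, excluding the Cmax sample itself for extravascular profiles;
ties go to the longer subset so the estimate uses as much of the terminal
phase as the fit quality allows. This mirrors the automatic terminal-phase
selection of standard NCA software, which the source study used but did
not parameterise.

Three conventions matter for reproducing published parameter tables:

* Apparent clearance per kg is `1000 x dose(mg/kg) / AUC0-inf(ng.h/mL)`
  (`cl_per_kg_from_auc()`), which lands exactly on the published mouse
  values (e.g. 5 mg/kg with AUC 560.7 gives 8.92 L/h/kg).
* `Vss/F` is reported as `(CL/F) x MRT` including absorption time
  (`vss_per_kg_from_cl_mrt()`): the published tables obey this identity
  to the printed precision (9.03 x 5.44 = 49.12), so the package adopts it
  rather than subtracting an absorption correction it cannot verify.
* Below-quantification values are entered as `NA` and dropped, never
  zero-imputed mid-profile; a pre-dose zero is retained for oral data.

Per-kg normalisation of human data uses 70 kg, and the monkey intravenous
study 4.5 kg; both choices reproduce the arithmetic of the published
parameter tables and are arguments, not hard-coded constants.

## In vitro ADME chain

Caco-2 permeability uses `Papp = (dCr/dt) Vr / (A C0)` with the receiver
slope from ordinary least squares over all samples; recovery and efflux
ratios are direct formula evaluations. Fraction unbound is the equilibrium
buffer/plasma ratio without volume-shift correction, appropriate for the
single-read 5 h dialysis design.

Microsomal depletion gives `kappa` from the log-linear slope of the
remaining fraction and `T1/2 = 0.693/kappa`. Intrinsic clearance scales as

```
CLint = 0.693/T1/2 x incubation(mL)/protein(mg)
        x microsomal protein(mg)/liver(g) x liver(g)/BW(kg)
```

with 2 mL incubation per mg protein (0.5 mg/mL) and 45 mg microsomal
protein per g liver, and species liver weights (87.5/40/32.1/30/25.7 g/kg
for mouse/rat/beagle/monkey/human) stored as editable physiology
constants; with these factors the chain reproduces the reported
species table (CLint 15.3 mL/min/kg for human, 78.8 for mouse, and so on)
from the measured half-lives. Hepatic clearance uses the standard
well-stirred form `CLh = Qh CLint/(Qh + CLint)`; the degenerate form that
appears in print (numerator and denominator both `Qh x CLint`) is a
typesetting casualty, and the standard form reproduces every tabulated
CLh and extraction ratio. CYP phenotyping is the total-normalised-rate
method: rate times hepatic abundance per isoform, expressed as percent of
the sum.

## Interspecies clearance scaling

Four predictors are implemented: simple allometry (`CL = a BW^b` by
log-log least squares), single-species scaling from the monkey with the
fixed exponent 0.75, two-species (rat-monkey) scaling with the optimised
fixed exponent 0.650, and IVIVE (the well-stirred human CLh converted to
L/h). Only the single-species value (21.4 L/h under 4 kg to 60 kg weights)
is reproducible from published inputs; the published simple-allometry
(39.0 L/h), IVIVE (36.09 L/h) and two-species (44.5 L/h) predictions
depend on an unpublished rat clearance and body-weight conventions, so
they ship as named constants (`CL_SA_PUBLISHED`, `CL_IVIVE_PUBLISHED`,
`CL_TS_PUBLISHED`) and feed the human PBPK scenarios as inputs. The
default body weights (mouse 0.02, rat 0.25, beagle 10, monkey 4, human
60 kg for scaling; 70 kg for per-kg normalisation) are function arguments.

## Tissue partitioning

`predict_kp()` offers the Poulin-Theil and Berezhkovskiy
lipid/water-solubility methods and a Rodgers-type mechanistic method in
two variants (`rodgers_rowland`, `rodgers_single`). E0703 carries no
ionisable group with a relevant pKa, so it is treated as neutral at pH
7.4; the code paths that would distinguish the two Rodgers variants
(acidic-phospholipid binding of ionised bases) are never triggered and
the variants coincide, which matches the study's report of identical Vss
under both.

For a neutral compound with logP above 5, applying octanol-based lipid
affinities to tissue lipids while using the measured fraction unbound on
the plasma side produces adipose Kp values in the thousands and a
whole-body Vss far beyond anything observed - the two sides of the ratio
are then computed on inconsistent affinity scales. The package therefore
anchors the drug-membrane affinity on a measured quantity of the compound
itself: the erythrocyte partition coefficient implied by the
blood:plasma ratio, `Kpu_BC = (Rb/p - (1-hct))/(hct fu_p)`. A single
scalar multiplying the composition-based lipid affinity is chosen so that
erythrocyte composition reproduces `Kpu_BC`, and plasma binding in excess
of membrane partitioning is attributed to albumin and carried into
tissues by tissue:plasma albumin ratios (clamped at zero if membrane
partitioning already explains the measured binding). Two properties
follow by construction: a hypothetical tissue with plasma composition and
equal binding has Kp exactly 1, and Kp never decreases with logP in
lipid-containing tissues. With literature tissue compositions this places
the monkey whole-body Vss within a few percent of the value the study
predicted with proprietary software; exact replication is impossible
without that software's internal composition tables, hence the wide
(30%) acceptance band used in testing.

`vss_from_kp()` is the plasma-referenced sum `V_plasma + sum Kp_t V_t`,
and `ratio_corrected_vss()` applies the study's observed/predicted monkey
ratio to the human prediction. In the PBPK model this correction enters
as a global Kp scale factor, which scales Vss identically up to the small
plasma term.

## The whole-body PBPK model

Perfusion-limited, blood-flow connected: venous and arterial pools, lung
in series, and per-tissue compartments (adipose, brain, gut, heart,
kidney, liver, muscle, skin, spleen, reproductive organs, rest) with
outflow concentration `C_t Rb/p / Kp_t`. The liver receives the hepatic
artery (25% of hepatic blood flow) plus portal outflow from gut and
spleen (85/15 split of the remaining 75%); cardiac-output closure is
validated at model assembly. Liver and kidney are the only elimination
sites. The hepatic intrinsic clearance is back-calculated from the
requested systemic plasma clearance through the well-stirred relation
(and likewise the renal hook against kidney blood flow, default renal
fraction 0), so a simulated intravenous dose returns `dose/AUC` equal to
the input clearance - a property the test suite checks to 1%.

Physiology defaults are literature-standard volumes and flow fractions
per species, with hepatic blood flows forced to the same per-species
values used in the in vitro chain (90/55.2/30.9/43.6/20.7 mL/min/kg) so
clearance bounds are consistent across modules.

Oral absorption is a deliberately simplified CAT chain: seven lumen
compartments with transit rate `7/SITT`, solid and dissolved drug both
transiting, first-order dissolution capped by the solubility limit
(intrinsic solubility times a cyclodextrin solubilisation factor,
reflecting the 1:6 beta-cyclodextrin complex in the formulation), and
first-order absorption with the rate derived from the Caco-2 permeability
through the jejunal-permeability correlation and lumen radius. Absorbed
drug passes a lumped gut first-pass factor `Fg` before entering the
liver, so `F = Fa x Fg x Fh` emerges mechanistically. Regional pH
effects, bile micelles, P-gp efflux and enterohepatic recirculation are
out of scope; the observed secondary plasma peaks are therefore not
reproduced, and simulated Tmax tends to exceed the observed one.

`Fg` and the solubilisation factor cannot be fixed from in vitro data;
both are calibrated once (`calibrate_absorption()`) against the monkey
3 mg/kg oral study (Cmax and AUC0-inf, squared log-error objective,
Nelder-Mead on logit/log transforms, solubilisation bounded to 1-100) and
reused across species - following the study's statement that the
intestinal first-pass was set to match observations. The two parameters
are partially confounded (their product is what the low bioavailability
constrains), which is acceptable because only the composite absorption
behaviour is transferred. Mouse disposition has no intravenous anchor, so
`calibrate_mouse()` fits the systemic clearance and a global Kp scale to
oral profiles with absorption fixed, using bounded multi-start
optimisation under a fixed seed (20240306).

Numerics: `deSolve::lsoda` with rtol 1e-8 and atol 1e-12 on amounts, a
0.05 h dense output grid refined logarithmically just after each dose
(an intravenous bolus mixes out of the venous pool within minutes and
that spike carries real AUC; without refinement the clearance round-trip
is biased by several percent). Dose events are applied inside a single
integration, so multiple dosing needs no solver restart. States are
checked for negativity beyond tolerance, and a mass ledger (in-body,
lumen, eliminated hepatic/renal/gut, unabsorbed) closes to well below
0.01% of dose.

The solubility cap makes oral absorption saturable by design - that is
the package's reading of the very low, weakly dose-proportional oral
exposure - so dose-linearity and superposition are exact for intravenous
dosing and for oral dosing below the solubility limit, and hold for
separated oral doses once the lumen has cleared (the 24 h double-dose
scenario); the test suite exercises exactly those regimes.

## Synthetic data

The raw individual-animal profiles exist only in an unavailable appendix,
so `generate_profiles()` regenerates serial-sampling datasets with the
study's structure: the published sampling schedules (15-point mouse,
16-point monkey oral and intravenous; the unpublished human schedule is
stood in for by the monkey oral schedule), six (mouse) or five
(monkey/human) subjects per time point, mean-one log-normal proportional
error with a default CV of 0.20 (a stand-in - the study reports SDs only
in the appendix), and a small additive floor (0.01 ng/mL) for
quantification noise. The generator emulates residual variability only;
it deliberately omits inter-individual physiological variability,
enterohepatic double peaks and any dose-dependent absorption saturation
beyond what the PBPK truth curve itself contains. Passing recovery tests
on these data therefore demonstrates estimator correctness under the
stated noise model, not robustness to the full biology of the real
datasets.

## Problem sizes and tolerances in the test suite

The suite favours short, deterministic runs: monkey simulations out to
400-600 h at 0.1 h resolution where extrapolated AUC or moment identities
are checked (integration error well below the 1-2% assertions), 500
subjects for the Monte-Carlo check of the error-model CV, six subjects at
CV 0.2 for the noisy calibration-recovery case, and the quick variant of
the study pipeline for the determinism check. Printed-value comparisons
use 1% relative tolerance to absorb the source tables' rounding of
intermediates (e.g. 3.74/1.68 printed as 2.22).

## Known limitations

* Parameter-level, not curve-level, validation: observed data enter as
  published NCA parameters, so fold errors are computed against those
  parameters rather than against raw concentration points.
* The published monkey bioavailabilities (0.35/0.76/0.87%) are not
  reproducible from the published group-mean AUCs (the formula gives
  0.25-0.77%); they were presumably computed per animal. The package
  computes bioavailability from its own AUCs and does not force
  agreement.
* The published human 40 mg AUC0-inf appears once as 4.11 and once as
  6.22 ng.h/mL in the source; the reference table ships the tabulated
  values unmodified and no test anchors on the conflicting number.
* No P-gp kinetics, enterohepatic recirculation, food effect, saturable
  metabolism or irradiated-physiology scenarios; the human Vss after
  ratio correction is computed but has no published value to compare to.
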
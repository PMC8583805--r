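---
title: "Methods: clustered DNA damage, excision repair and quality metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustered DNA damage, excision repair and quality metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdamage)
```

This vignette documents the model assumptions, parameters, numerical choices
and design decisions behind the package. Numbers quoted as defaults are the
package's own choices; users can override all of them.

## 1. Damage induction model

### Assumptions

Energy deposition by ionising radiation is represented as discrete *damage
sites* on the DNA, occurring at a rate `site_rate` per Gy per Gbp. Each site
is a short segment of `segment_length` base pairs (default 25 bp) carrying

- a lesion count of `1 + Poisson(lesion_multiplicity)`, capped at the segment
  length (a site exists because at least one lesion was formed; extra lesions
  reflect the local clustering of ionisations),
- independent uniform positions within the segment, independent fair-coin
  strand assignments, and
- an independent `Bernoulli(sb_fraction)` choice of strand break versus base
  damage per lesion.

Two lesions may not occupy the same (position, strand) slot; colliding draws
are redrawn. This is a *generator*, not measured data: real site geometries
follow track structure, whereas the model compresses all of that into four
scalar parameters which are then **calibrated** so that the seven-category
yield spectrum matches published tables.

### Classification

Lesions are chained into clusters wherever consecutive sorted positions are
at most `cluster_gap` = 10 bp apart (strand-blind), then classified:

- **DSB**: two opposite-strand breaks ≤ 10 bp apart. Multiple breaks are
  paired greedily left-to-right into *disjoint* pairs; an exhaustive sweep
  (`verify_classifier()`) proves this greedy pairing equals the true maximum
  matching for every configuration of up to 4 lesions on a 30 bp window.
- Categories: `BD` (base damage only), `SSB` (one break), `SSBp` (one break
  plus ≥ 1 extra lesion, same strand breaks only), `twoSSB` (breaks on both
  strands but none within pairing distance), `DSB`, `DSBp` (DSB + extra
  lesions), `DSBpp` (≥ 2 DSBs).

Yields are category counts scaled by `site_rate / n_sites`, so the totals
identities (`total_damage = BD + total_SSB + total_DSB`, etc.) hold exactly.

### Calibration

`calibrate_induction()` minimises the weighted squared *relative* error of
simulated versus target column yields. Choices:

- **Common random numbers**: each objective evaluation re-simulates with the
  same seed, making the objective a deterministic function of the parameters
  and Nelder–Mead applicable.
- **Transformed parameters**: log for `site_rate`/`lesion_multiplicity`,
  logit for `sb_fraction`, plus a box penalty — keeps the search
  unconstrained and well scaled.
- **Multi-start screening**: the surface has local minima that trade lesion
  multiplicity against break fraction. Nine grid starts (plus a
  moment-matching start) are screened at a reduced site count, and the best
  is polished at the full count.
- Default problem sizes (`n_sites` = 2 × 10⁵ per evaluation for calibration,
  10⁶ for production runs) balance Monte Carlo noise on the rare `DSBpp`
  category against runtime; these are package choices.

The carbon K-shell reference row is internally inconsistent (its constituent
columns do not sum to its printed totals, while the totals columns are
mutually consistent); `read_damage_spectra()` flags it and the pipeline
calibrates carbon against the totals columns only.

## 2. Oxygen response

Hypoxia reduces yields because oxygen fixes radical damage. Each category's
yield is scaled by a Hill function of the oxygen percentage, **normalised at
21 % O₂** so that the aerobic reference tables are reproduced identically:

\[ s(p) = s_\min + (1 - s_\min)\,\frac{p^h}{p^h + k^h} \Big/ \text{(same at
} p = 21\text{)} . \]

`calibrate_oxygen()` fits `s_min`, `k`, `h` per category by least squares to
the 21 / 2 / 0.1 % tables, with a penalty enforcing an **anoxic plateau**
(≤ 2 % change between 0.001 and 0.05 % O₂) so extrapolation below the lowest
measured level is stable. `hrf_curve()` recomputes the aerobic baseline
through the same scaling path, so HRF(21 %) is exactly 1 even when printed
table totals differ from recomputed sums in the last digit.

## 3. Excision-repair state machine

Non-DSB clusters (BD, SSB, SSBp, twoSSB) are repaired lesion by lesion:

1. **Selection**: when both strand breaks and base damages remain, a break is
   chosen first with probability `p_first_strand_break` (default 0.8),
   uniformly within its class.
2. **Excision** opens a *transient single-strand gap*: short-patch BER
   removes 1 nt; long-patch BER removes a uniform 2–13 nt patch 3′ of the
   lesion; NER (used for base damage in the combined pathways) removes a
   uniform 2–13 nt patch placed two-sided around the lesion, `(L−1) ÷ 2` to
   the left. Same-strand lesions inside the patch are co-excised. Gaps are
   **sequential**: only one gap is open at a time.
3. **Conversion**: if an unrepaired opposite-strand break lies within
   `inhibition_distance` = 8 bp of the gap span, the cluster becomes a de
   novo DSB and the run ends.
4. **Resynthesis**: mis-insertion occurs with `p_misinsert_damaged` = 0.75
   when the template span opposite the gap holds a damaged base, otherwise
   with the polymerase error (`err_sp` = 10⁻⁴ short-patch,
   `err_lp_ner` = 10⁻⁶ long-patch/NER).
5. **Outcome**: conversion dominates; otherwise any committed mis-insertion
   gives a mutation; otherwise correct repair.

The C++ Monte Carlo (`cpp_repair_mc`) is verified against an **independent
analytic oracle** (`tests/testthat/helper-oracles.R`) that enumerates the
branch tree exactly and memoises on the surviving-lesion set. Structurally
certain outcomes must match exactly; stochastic ones are compared with exact
binomial intervals. Because thousands of comparisons are made, the acceptance
test uses a two-stage criterion: per-comparison intervals at the two-sided
3σ probability level, a chance-consistent budget for the number of
exceedances, and a hard 5σ-level guard per comparison. Demanding that *every*
comparison pass at 3σ would reject a *correct* implementation with high
probability.

Aggregate outcome probabilities weight per-category probabilities by yield
fraction (`aggregate_outcomes()`); DSB-bearing categories contribute their
accompanying base-damage repair (or certain-correct when none). The enzymatic
DSB yield is `total_damage × p_conversion`.

## 4. Electron spectra and LET

- **Stopping power**: below 1 keV an analytic expression
  `let_low_energy(T) = (4376 ln T − 19803)/T + 129622/T²` (eV/nm, T in eV);
  at and above 1 keV, log–log interpolation of a liquid-water table. The
  crossover mismatch at 1 keV is ~16 % and is tested to stay below 25 %.
  Evaluation is restricted to ≥ 50 eV, below which LET is ill-defined in
  this framework (sub-excitation electrons).
- **Photoelectrons**: ultrasoft X-ray lines (< 20 keV) map one-to-one to
  photoelectron lines (binding energies are negligible at the precision of
  the yield tables).
- **Compton electrons**: for photon energies ≥ 100 keV, the Klein–Nishina
  differential cross section gives the initial electron spectrum up to the
  Compton edge.
- **Slowing-down fluence**: under the continuous-slowing-down approximation
  the equilibrium track fluence is φ(E) = Q(E)/LET(E), with Q(E) the number
  of electrons started above E. The default grid is logarithmic with
  endpoints clamped exactly to [50 eV, E_max].

`dose_weighted_average()` integrates yield(E) against the dose kernel
φ(E)·LET(E) by trapezoid on the union grid; line spectra collapse to exact
weighted sums. The construction is scale-invariant in the fluence and exact
in the delta-line and constant-yield limits, which the tests check
analytically; grid refinement from 80 to 800 points changes results by
< 1 %.

## 5. Pipeline and reproducibility

`run_pipeline()` chains spectra → calibration → production simulation →
oxygen scaling → repair → report per quality. Every stochastic stage draws
its seed via `derive_seed(seed, tag)` (a polynomial hash of the stage tag
modulo 2³¹ − 1), so a run is reproducible from one integer and inserting a
stage does not shift the randomness of the others. Stage failures are
wrapped with the stage and quality names; stage timings are returned as a
log tibble. Configurations round-trip through YAML or JSON.

## 6. Limitations

- The induction generator is phenomenological: four parameters per quality,
  no explicit track structure, no chromatin geometry. It reproduces
  seven-category yield *tables*, not microdosimetric detail; with four
  parameters against seven categories some residual per-category error is
  irreducible (the rare `DSBpp` category is the worst constrained).
- The oxygen model scales categories independently; it does not re-cluster
  lesions under hypoxia.
- Repair parameters are shared across qualities; only the damage spectrum
  differs. Pathway choice is per-run, not per-lesion-context.
- The stopping-power model is for liquid water only, and photoelectron
  emission ignores Auger-electron cascades.
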
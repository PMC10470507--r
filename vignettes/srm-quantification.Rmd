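---
title: "Quantifying thiamin vitamers by SRM: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thiamin vitamers by SRM: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmquant)
```

`srmquant` turns per-transition SRM chromatograms into recovery-corrected,
detection-classified concentrations of thiamin (B1) and its vitamers. This
vignette is the package's own account of the science behind each stage: the
signal and calibration models, the rules that decide what is reportable, the
parameters a user may want to move, and the places where the design was
genuinely open and a choice had to be made.

## The measurement chain

A dissolved-phase sample of volume $V_s$ (mL) passes through solid-phase
extraction with compound-specific efficiency $e \in (0,1]$, is resuspended in
$V_r$ µL of buffer, and $V_i$ µL are injected. A sample at concentration $c$
(pM) therefore puts

$$\mathrm{fmol\ on\ column} = c \, V_s \, e \, \frac{V_i}{V_r}$$

on the column (pM × mL is numerically fmol). Quantification inverts this
chain: peak area → on-column fmol (calibration slope) → in-sample pM (volume
chain) → reported pM (recovery correction, which is where $e$ re-enters as a
measured percent recovery).

## Signal model and integration

Each fragment transition of a compound is modelled as a Gaussian peak on a
uniform time grid:

$$I_k(t) = \rho \, G \, f \, r_k \exp\!\left(-\frac{(t - \mathrm{RT})^2}{2\sigma^2}\right) + B + \varepsilon_t,$$

with $f$ the on-column amount, $r_k$ the fragment's relative intensity
($\sum_k r_k = 1$), $G$ a response gain, $B$ a constant baseline,
$\varepsilon_t \sim \mathcal{N}(0, \tau^2)$ i.i.d. additive noise, and
$\rho$ a per-injection response factor, $\log\rho \sim \mathcal{N}(0, s^2)$,
shared by every transition of one injection. The common-mode factor $\rho$
is what makes injection-to-injection area variability realistic and what a
heavy internal standard can cancel; the additive term is what drives
detection limits.

Integration subtracts a linear baseline interpolated between the two
intensities at the window edges, applies the trapezoidal rule to the
residual, and clamps negative results to zero. The default window half-width
of 0.2 min equals the retention-time tolerance of the sub-LOQ rule, so one
constant governs both. Signal-to-noise is the baseline-corrected apex over a
robust noise scale, $1.4826 \times \mathrm{MAD}$ of the out-of-window
intensities — robust to the peak leaking slightly past the window. Both the
linear baseline and the MAD-based S/N are this package's choices: they are
parameter-free and standard for targeted assays, but they are choices, and
real processing software exposes many alternatives.

## Quantifier selection

Among a compound's transitions, the quantifier is the fragment maximising
$\overline{\mathrm{S/N}} / (1 + \mathrm{interference})$ over the calibration
injections, where interference is the mean blank area divided by the mean
area at the lowest non-zero addition level — a dimensionless measure of how
much of the "signal" is already there without analyte. Ties break on the
lower fragment index, keeping selection deterministic. All fragments are
retained as qualifiers for the identity checks below. The pipeline sums
areas over the selected quantifier set (by default the single best
fragment); summing over all fragments is equivalent for linearity but mixes
in the noisier transitions.

## Standard addition and internal-standard normalization

Calibration is per (compound, matrix grouping), fitted on the QC pool — a
mix of equal portions of the group's samples — spiked at 0/25/50/250 fmol
(0/5/10/50 for HET, whose response saturates lower). Duplicate injections
enter the ordinary-least-squares fit as individual points, preserving
degrees of freedom for the residual SD. The intercept-to-slope ratio
estimates the pool's endogenous amount; a non-positive slope flags the curve
invalid and quantification refuses it.

Two decisions here were genuinely open:

* **Slope-only sample quantification.** Samples convert as
  $\hat f = y / b$. The pool's endogenous level is a property of the pool,
  not of any one sample, so it is not subtracted by default; a
  blank-subtraction mode (`response_to_amount(..., blank_response =)`) is
  provided for workflows that prefer it.
* **Unweighted OLS.** With four levels spanning one order of magnitude,
  weighting changes little; `weights = "1/x"` is available for strongly
  heteroscedastic responses.

Normalization to the heavy internal standard is decided per compound, not
assumed: the pipeline compares the relative SD of raw areas against the RSD
of area/IS ratios across replicate unspiked QC injections (at least three)
and normalizes only when the ratio RSD is strictly smaller. Under
common-mode injection jitter the ratios win; when variability is dominated
by independent noise, dividing by a noisy IS only adds variance and the rule
correctly declines. The heavy standard receives no authentic-standard
additions — it is the one species whose amount must stay constant across the
calibration series — and co-elutes exactly with its light analogue, as
isotope physics dictates.

## Detection limits and the sub-LOQ rule

With at least three blank determinations, LOD and LOQ on the amount scale
are $\bar b + 3 s_b$ and $\bar b + 10 s_b$, converted to concentration
through the sample's volume chain. A calibration-residual alternative
($3\,s_{res}/b$, $10\,s_{res}/b$) is selectable when blanks are scarce.

A concentration between LOD and LOQ is reported only when four criteria all
hold: (i) apex retention time within ±0.2 min of the authentic standard;
(ii) at least two daughter fragments present with apexes within the same
tolerance of each other; (iii) fragment intensities in the standard's rank
order — with exactly two near-equal fragments, ties within 5% relative area
are treated as order-compatible rather than failing on noise; (iv) summed
area at least twice the mean blank area in the window. Acceptance is the
strict conjunction; there is no partial credit. Failing candidates are `nq`,
and anything below LOD is `nd`. Classification uses the recovery-corrected
concentration by default (the reported scale), with
`classify_on = "uncorrected"` exposed since the alternative convention is
equally defensible.

## Recovery

Percent recovery is measured from a spiked/unspiked pair:
$100\,(c_\mathrm{spiked} - c_\mathrm{unspiked})/c_\mathrm{spike}$, computed
on uncorrected concentrations so the estimate is independent of itself.
Values outside [10%, 150%] are flagged suspect — a package QC bound, wide
enough to pass real SPE behaviour and narrow enough to catch unit mistakes.
Where no pair exists for a matrix, `assumed_recovery()` lets a recovery
established elsewhere be asserted (FAMP's ~50% is stable across SPE
methods); such values are flagged `assumed` in every output rather than
silently blended with measured ones.

## Mass balances and display

Spent-medium minus medium-blank changes are differences of replicate means.
Two uncertainty propagations are kept: quadrature $\sqrt{s_1^2+s_2^2}$ (the
default, correct for independent errors) and the plain sum $s_1+s_2$
(conservative, and the convention some published budget tables follow —
e.g. a 57 ± 9.8 vs 39 ± 1.6 nM pair displays as "18 ± 11" only under sum
mode). Displays use two significant figures; SDs are suppressed when fewer
than three independent replicates back them, so technical duplicates print
as a bare mean.

## What the generator emulates — and what it does not

The synthetic module reproduces the features the downstream statistics
actually consume: compound-specific retention times and fragment intensity
ratios, amount-linear Gaussian peaks, constant baseline, additive noise,
common-mode injection jitter, duplicate injections, the standard-addition
series on a QC pool mixed from the batch's own samples, spiked/unspiked
pairs with tunable extraction efficiency, and blanks. It deliberately does
not model ion suppression dynamics, gradient chemistry, retention-time
drift, co-eluting isomers, carryover, or non-Gaussian peak shapes. Passing
parameter-recovery tests therefore demonstrates that the *statistical
machinery* is correct and unbiased under its stated assumptions — not that
any real extract will behave this well. The gain (1000 counts/fmol), noise
SD (10), and baseline (50) defaults are arbitrary in absolute terms, since
real instrument response is unknowable from published tables; only their
ratios matter to the pipeline, and all are settable in `batch_design()`.

## Numerical choices and problem sizes

The 12-min run sampled at 0.5 s puts ≈50 points across a ±4σ window at the
default σ = 0.05 min, enough for the trapezoidal rule to track the
closed-form Gaussian area to well under 0.5%. Retention times in the default
panel sit on grid points, making apex checks exact. Negative baseline-
corrected areas clamp to zero so downstream amounts stay physical. All
stochastic draws in a batch flow from a single integer seed, and seeded runs
are byte-identical.

The test suite and the acceptance script run simulations sized for a
laptop-scale check: batches of ~25 injections with a single-analyte panel,
50 seeds for the parameter-recovery study at 5/20/100/500 pM and 5% response
noise, 100–200 seeds for the Monte-Carlo rules (quantifier selection,
normalization decision, S/N distribution). These sizes give the medians and
proportions the tests assert with comfortable margins while keeping a full
run under a minute.

## Known limitations

* The panel's m/z and retention-time constants are synthetic fixtures —
  plausible, overridable configuration, not reference values.
* No mzML reader; chromatograms exchange as long-format CSV
  (`read_traces()`/`write_traces()`).
* No drift correction over injection order, no nonlinear (saturating)
  calibration, no peak deconvolution: batches that need these need more than
  this package models.
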
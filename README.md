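# srmquant

Targeted LC-MS/MS (selected reaction monitoring, SRM) quantification of
vitamin B1 (thiamin) and its vitamers — FAMP, AmMP, HMP, cHET and HET — in
seawater and culture samples.

Dissolved B1 and its degradation/precursor compounds occur in the ocean at
picomolar levels, close to instrument detection limits and embedded in a
heavy, variable matrix. Reliable numbers therefore require more than a peak
area: matrix-matched calibration by **standard addition**, normalization to a
co-injected **heavy isotope-labelled internal standard** where it helps,
blank-based **detection limits** with an explicit rule for reporting values
between LOD and LOQ, and correction for the **percent recovery** of the
solid-phase extraction step. `srmquant` implements that whole chain as
composable, tested R functions, together with a synthetic SRM-chromatogram
generator whose ground-truth ledger lets every stage be verified by parameter
recovery — no instrument data needed.

## The method

For each compound and matrix grouping, a quality-control (QC) pool is mixed
from equal portions of the samples and spiked with authentic standard at
added amounts x (0/25/50/250 fmol on column; 0/5/10/50 fmol for HET),
injected in duplicate. The response is fitted by ordinary least squares,

    y = a + b x,

and the pool's endogenous on-column amount is a/b. Sample responses convert
to amounts through the matrix-matched slope b, then to in-sample
concentration through the volume chain

    conc [pM] = fmol × (V_resuspension / V_injection) × dilution / V_sample [mL],

and finally to a reported value via the recovery correction
`conc_corrected = conc × 100 / recovery%`, with
`recovery% = 100 (measured_spiked − endogenous) / spike` from a
spiked/unspiked sample pair.

Detection limits follow the blank-based rule LOD = mean_blank + 3 s_blank,
LOQ = mean_blank + 10 s_blank. A result between LOD and LOQ is reported only
if all four acceptance criteria hold: retention time within ±0.2 min of the
authentic standard, at least two co-occurring daughter fragments, fragment
intensities in the standard's order, and a summed area at least twice the
blank average; otherwise it is flagged `nq` (or `nd` below LOD).
Spent-medium minus medium-blank mass balances propagate uncertainty either in
quadrature or as a plain sum of the two SDs.

## Worked example

Simulate a small estuarine batch (two dissolved samples, a recovery spike
pair, triplicate medium blanks, and a QC pool carrying the standard-addition
series), then quantify it:

```r
library(srmquant)
panel <- make_default_panel()["FAMP"]
samples <- list(
  sample_design("NRE_A", "environmental_dissolved", c(FAMP = 30), 20, 0.5, 100),
  sample_design("NRE_B", "environmental_dissolved", c(FAMP = 120), 20, 0.5, 100),
  sample_design("NRE_B_spiked", "environmental_dissolved", c(FAMP = 120), 20, 0.5, 100,
                spikes = c(FAMP = 150)),
  sample_design("Blank1", "medium_blank", c(), 20, 1, 100),
  sample_design("Blank2", "medium_blank", c(), 20, 1, 100),
  sample_design("Blank3", "medium_blank", c(), 20, 1, 100)
)
pool   <- make_qc_pool(samples[1:2], "QC", compounds = "FAMP")
design <- batch_design(c(samples, list(pool)), noise_sd = 5,
                       response_rel_sd = 0.05, seed = 2024)
batch  <- simulate_batch(design, panel)

quant <- quantify_batch(batch)
rec   <- recovery_from_pair(quant, "FAMP", "NRE_B_spiked", "NRE_B", 150)
rec
#> <recovery_estimate> FAMP [NA]: 45.9%

quant <- quantify_batch(batch, recoveries = list(FAMP = rec))
quant$curves$FAMP
#> <cal_curve> FAMP [QC]
#>   slope 64.08 area/fmol, intercept 2215, r2 0.99883
#>   endogenous 34.57 fmol on column; 8 points

render_report(quant$results[quant$results$sample_id != "NRE_B_spiked", ])
#> sample  FAMP
#> Blank1  nd
#> Blank2  nd
#> Blank3  nd
#> NRE_A   34 ± 0.45
#> NRE_B   130 ± 0.46
```

The samples were generated at 30 and 120 pM with a 50% extraction
efficiency: the measured spike recovery (45.9%, true 50%) corrects the
50%-attenuated raw concentrations back to 34 and 130 pM — parameter recovery
within the batch's 5% injection-response noise. The blanks classify `nd`
(below the blank-derived LOD), and `± ` terms are duplicate-injection SDs at
two significant figures.

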
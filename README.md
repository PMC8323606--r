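# naContrast

Forward modeling of sodium (23Na) MRI contrast in white matter, for
researchers using relaxation-weighted sodium sequences to disentangle the
microstructural sources of tissue sodium concentration (TSC) change in
demyelinating disease.

A TSC elevation measured by density-weighted sodium MRI is ambiguous: it
can arise from intracellular concentration change, intra-/extracellular
volume redistribution, demyelination, or edema. `naContrast` implements
the chain of models needed to predict how *differently weighted* sodium
sequences respond to each mechanism:

1. **Spin-3/2 simulator** (`na_environment`, `evolve`,
   `steady_state_signal`, `relaxation_weighting`) — the sodium density
   operator on the 15 irreducible tensor coefficients, with Redfield
   quadrupolar relaxation from spectral densities `J0, J1, J2`
   (`R2f = J0+J1`, `R2s = J1+J2` at 60/40; `R1f = 2*J1`, `R1s = 2*J2` at
   20/80), residual quadrupole splitting `fQ`, and steady-state signal
   through three preset sequences: density-weighted **NaDW** (30°,
   TR 85 ms), coherent-magnetization **NaPACMAN** (110°, 4 ms pulse,
   TR 25 ms), and soft inversion recovery **NaSIRFLA** (TI 37 ms,
   TR 150 ms).
2. **Compartment model** (`control_volumes`, `apply_demyelination`,
   `sodium_contributions`) — myelin water / intracellular / extracellular /
   edema volumes per liter of tissue, with myelin water at
   `(12.5 + 145)/2 = 78.75 mM`; demyelination removes myelin water plus
   `k = 1.5` times its volume of solids (atrophy), edema adds 145 mM free
   water.
3. **Signal model** (`build_contrast_table`) — per-compartment relative signal
   `q_x * RW[seq][x]`, normalized to the control intracellular entry, with
   percent differences of NAWM and lesion states vs control.
4. **Image analysis** (`psf_kernel`, `expand_csf_mask`, `roi_statistics`,
   `intensity_to_tsc`) — center-out T2* point-spread-function kernels, CSF
   mask expansion at the 2.5% partial-volume threshold, ROI statistics
   with CSF exclusion, 64 mM agar-referenced TSC calibration.
5. **Synthetic phantom + cohort** (`build_phantom`,
   `render_sodium_image`, `simulate_cohort`) — seeded brain-like labeled
   volumes with agar tubes and 1–70 voxel lesions, forward-rendered
   per-sequence images with PSF blurring and Rician noise, and tidy
   per-subject ROI tables.
6. **Group statistics** (`unpaired_t`, `paired_t`, `bh_fdr`,
   `partial_pearson`, `regression_slope`) — the analysis layer with
   Benjamini–Hochberg FDR and age/sex partial correlations.

## Worked example

```r
library(naContrast)

# healthy control white matter sodium budget
sodium_contributions(control_volumes())
#> <na_contributions mmol/L-tissue>  myelin 6.81 | intra 6.19 | extra 24.94 | edema 0.00 | TSC 37.94

# demyelination with atrophy (NAWM): small TSC increase
nawm <- tissue_state("nawm")
attr(nawm, "volume_change")      # -0.043 (4.3% atrophy)
sodium_contributions(nawm)
#> <na_contributions mmol/L-tissue>  myelin 5.70 | intra 6.47 | extra 26.07 | edema 0.00 | TSC 38.23

# full contrast table: relative signals and percent differences vs control
t3 <- build_contrast_table()
t3[t3$state != "control", c("sequence", "state", "total_printed",
                            "pct_diff_printed")]
#>   sequence  state total_printed pct_diff_printed
#> 2     NaDW   nawm          6.08              1.1
#> 3     NaDW lesion          7.82             30.0
#> 5 NaPACMAN   nawm          5.28              4.4
#> 6 NaPACMAN lesion          7.66             51.0
#> 8 NaSIRFLA   nawm          6.51             -0.3
#> 9 NaSIRFLA lesion          6.36             -2.6

intensity_to_tsc(0.62)   # measured control WM ratio -> TSC
#> [1] 39.68
```

Reading the table: myelin water holds ~6.8 of the 37.9 mmol in a liter of
healthy white matter, as much as the entire intracellular pool, because its
concentration (78.75 mM) is six times intracellular. Demyelination with
atrophy barely moves TSC (+0.8%) but moves the sequences apart: the
coherent-magnetization sequence, blind to myelin sodium, gains +4.4% while
the fluid-suppressed inversion recovery sequence stays flat. A lesion
(stronger demyelination plus edema) raises the density-weighted signal by
~30% but the coherent-magnetization signal by ~51% — the experimental
signature that relaxation, not just sodium density, changes in lesions.

A thin command-line wrapper ships in `inst/cli/na-contrast`
(`weights`, `tissue`, `contrast-table`, `phantom`, `analyze`, `stats`
subcommands).

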
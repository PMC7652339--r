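# tcellkin

Kinetic analysis of imaging-based T-cell killing assays: disentangling
antigen-dependent cytotoxicity from proliferation in live-cell co-cultures.

## The problem

Engineered T cells (CAR-T, TCR-T) are characterised preclinically by
co-culturing them with peptide-loaded target cells and measuring a response.
Conventional endpoint assays conflate two phenotypes that matter separately:
how fast the cells *kill* and how fast they *proliferate*. Live-cell imaging
assays resolve both over time in the same well — each scan yields a live
effector count `E_live` (green vital dye, red-negative), a red pixel area
(Annexin V / propidium iodide, dead and dying cells) and a phase-contrast
occupied area (target confluency) — but the raw series need careful
normalisation before they say anything per cell.

`tcellkin` implements that analysis for assay developers and computational
biologists:

* **Kinetics** on a 6-hour grid anchored at the 2 h settling scan:
  fold proliferation `P(t,c) = E_live(t,c)/E_live(2,c)`;
  death fraction `T_dead(t,c) = 100·Σred_px/Σphase_px`;
  specific killing `K(t,c) = T_dead(t,c)/T_dead(t,0)` (the 0 µM control
  removes nonspecific killing);
  per-T-cell killing `S(t,c) = [T_dead(t,c)/E_live(t−6,c)] /
  [T_dead(t,0)/E_live(t−6,0)]`;
  proliferation rate `P′ = 100·4·ΔE/E` (%·day⁻¹) and kill rate
  `K′ = ΔK/E(t−6)/6 h` (T cell⁻¹·h⁻¹).
* **Dose-response summaries**: responses at the assay's peak-time
  conventions (proliferation at ~72 h, killing at ~48 h, rate maxima in the
  30–72 h window) fitted with a four-parameter logistic
  `r(c) = bottom + (top−bottom)/(1+(EC50/c)^slope)` in log-dose space;
  EC50/Emax per construct × E:T ratio, with flat-response flagging and
  High/Mid/Low concentration banding relative to the fitted EC50.
* **A stochastic co-culture simulator** with ground truth (dose-dependent
  killing and proliferation, effector-density-dependent specific hazard,
  background death, logistic target growth, counting noise, and an inverse
  proliferation/killing coupling), so every stage is testable without
  instrument data.
* **A synthetic frame renderer and transparent segmentation**
  (threshold → connected components → size/shape/red-exclusion gate, the
  size gate being a 5–15 µm equivalent diameter) validated against known
  label maps.

See the methods vignette (`vignettes/cytotoxicity-kinetics.Rmd`) for the
model, parameter rationale and limitations.

## Worked example

Simulate a default-condition plate (2000 targets/well, E:T 3:1/1:1/1:3,
21-dose 3-fold titration from 100 µM plus control, 2 h scans to 96 h),
compute the kinetic profiles and fit the dose-responses:

```r
library(tcellkin)

cfg     <- sim_config(rng_seed = 42)
plate   <- plate_map(constructs = "HPV-TCR",
                     et_ratios = cfg$effector_to_target_ratios,
                     concentrations = cfg$concentrations, replicates = 2)
truth   <- simulate_plate(cfg, plate)
profiles <- build_profiles(truth$measurements)
fits    <- fit_dose_response(profiles)
subset(as.data.frame(summarize_fits(fits)),
       readout %in% c("proliferation", "specific_killing"),
       select = c(construct, et_ratio, readout, ec50_uM, emax, converged))
#>    construct et_ratio          readout ec50_uM emax converged
#> 1    HPV-TCR      1:3    proliferation 0.00745 2.51      TRUE
#> 2    HPV-TCR      1:3 specific_killing 0.06163 2.00      TRUE
#> 5    HPV-TCR      1:1    proliferation 0.00520 2.23      TRUE
#> 6    HPV-TCR      1:1 specific_killing 0.06066 3.10      TRUE
#> 9    HPV-TCR      3:1    proliferation 0.00506 2.09      TRUE
#> 10   HPV-TCR      3:1 specific_killing 0.05093 3.69      TRUE
```

The generative killing EC50 is 0.05 µM and the proliferation EC50 0.0071 µM:
both are recovered within ~1.5-fold at every E:T ratio. Per-T-cell killing
Emax falls from 3.69 at 3:1 to 2.00 at 1:3 — more effectors per target kill
more per cell relative to the control — while the EC50s stay within ~1.2-fold
of each other, and proliferation Emax runs the other way (higher at lower
E:T). One fit in detail, and the dose banding it implies:

```r
f <- fits$fit[[which(fits$readout == "specific_killing" & fits$et_ratio == 3)]]
f
#> <tk_4pl>
#> EC50 = 5.093e-08 M (0.05093 uM), Emax = 3.689, slope = 2.04, bottom = 0.9842
#> n = 21, rss = 0.03908, converged = TRUE
band_concentrations(f$ec50, c(1e-4, 1e-6, 1e-9))
#> # A tibble: 3 × 2
#>   concentration band
#> 1  0.0001       High
#> 2  0.000001     Mid
#> 3  0.000000001  Low
```

`autoplot(profiles, "s_per_tcell")` and `plot_dose_response(fits)` draw the
time courses and fitted curves; `tidy()`/`glance()` give broom-style fit
tables. `run_pipeline()` orchestrates the same steps from a config file, a
counts CSV or rendered frames, and writes CSV/JSON artifacts plus a run
manifest; a thin command-line wrapper ships in `inst/scripts/tcellkin-cli.R`.

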
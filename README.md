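# nmrbind

Solution NMR and calorimetry analysis of how tandem RNA-recognition motifs
(RRMs) engage an RNA element. The package implements, as a tested and
reusable pipeline, the quantitative chain used to characterise a weakly
binding tandem-RRM protein:

- **Chemical shift perturbation (CSP) mapping** of HSQC titrations, with
  the conventional weighted amide combination
  `Δδ(¹⁵N,¹H) = sqrt(½(ΔδH² + (0.14 ΔδN)²))`, strict classification of
  large shifts (> 0.025 ppm), and projection onto a structure through the
  PDB B-factor column.
- **Dissociation constants in fast exchange** from the population-averaged
  shift `δobs = δfree + (δbound − δfree)·fb`, with the bound fraction from
  the exact single-site depletion quadratic
  `fb = ((P+L+Kd) − sqrt((P+L+Kd)² − 4PL)) / 2P`.
- **Rotational correlation times** from ¹⁵N relaxation,
  `τc = (1/4πνN)·sqrt(6 T1/T2 − 7)`, compared against an empirical
  molecular-weight prediction with `η(T)/T` temperature scaling — the
  rigid-versus-flexible test for whether two domains tumble as one body.
- **Residual dipolar coupling (RDC) tensor fits**: SVD solution of the
  five-element Saupe tensor directly in Hz, the quality factor
  `R = 100·sqrt(⟨(Dobs − Dcalc)²⟩ / 2⟨Dobs²⟩)`, and the per-domain versus
  joint fit comparison that detects interdomain flexibility.
- **ITC isotherm models**: the one-site (Wiseman) model and a sequential
  two-site binding polynomial with exact free-ligand mass balance,
  Levenberg–Marquardt fitting, equivalence-point location, and dilution
  controls.
- **A synthetic-data module** that generates every input class (toy
  backbone structures, peak lists, relaxation tables, RDC tables,
  isotherms) from the corresponding forward models, so the entire chain is
  verifiable without downloading anything.

All user-facing functions take a data frame first and return tibbles;
fitted objects have `tidy()`, `glance()`, `augment()` and `autoplot()`
methods.

## Worked example

Simulate a weak-binding titration (Kd = 52 µM, 200 µM protein, ligand
ratios 0–3) with intermediate-exchange broadening and 0.002 ppm shift
noise, then fit the shared dissociation constant:

```r
library(nmrbind)
set.seed(1)
ref  <- tibble::tibble(residue_number = 1:8, residue_name = "ALA",
                       dH_ppm = round(runif(8, 7.5, 9.3), 3),
                       dN_ppm = round(runif(8, 108, 128), 3), intensity = 1e6)
ends <- tibble::tibble(residue_number = 1:8,
                       ddH_bound_ppm = round(runif(8, -0.15, 0.15), 3),
                       ddN_bound_ppm = round(runif(8, -1.2, 1.2), 3))
ser <- gen_titration(ref, exchange_spec(52, ends, kex_s = 2000),
                     protein_conc_uM = 200, noise_sd = 0.002, seed = 2)
fit_kd_from_titration(ser, P_total_uM = 200)
#> <binding_curve_fit> Kd = 49.46 uM (se 2.77), global mode, 8 residues x 6 points
```

The recovered 49.5 ± 2.8 µM brackets the generating 52 µM; the residual
norm (0.014 ppm across 8 residues × 6 points) is consistent with the
injected noise.

Tumbling analysis of a simulated rigid 10.57 ns tumbler at 500 MHz,
compared with the prediction for a 21,854 Da protein at 25 °C:

```r
set <- gen_relaxation_set(10.57, 500, 30)
tumbling_estimate(set, 500, MW_Da = 21854, temperature_K = 298.15)
#>   tau_c_calc_ns tau_c_pred_ns ratio  verdict
#> 1         10.47         13.44 0.779  independent/flexible
```

A measured τc ~78% of the molecular-weight prediction is the signature of
domains reorienting independently rather than tumbling as one rigid body.

Per-domain versus joint RDC fits on a synthetic two-domain structure whose
domains carry *different* alignment tensors (1 Hz noise):

```r
s <- gen_structure(20, "two_domain", rotation_deg = 90)
tensors <- list(D1 = alignment_tensor(10.6, 0.23),
                D2 = alignment_tensor(9.2, 0.55, euler_deg = c(0, 90, 0)))
rdcs <- gen_rdc_set(s, tensors, noise_sd = 1, seed = 3)
fit_domains(rdcs, s)
#>  domain n_rdcs   Da_Hz rhombicity r_factor
#>      D1     20   13.22       0.44     6.05
#>      D2     20    7.46       0.51     8.65
#>   joint     40  -10.81       0.56    15.66
#> joint R-factor exceeds weighted per-domain mean by 113.0%
```

Each domain alone fits well; forcing a single tensor across both degrades
the R-factor by far more than 50% — the flexible-linker signature.

One-site ITC fit at a low Wiseman c (c ≈ 5, a shallow weak-binding
isotherm; 0.3 µcal heat noise):

```r
sch <- default_schedule(syringe_conc_uM = 7000, cell_conc_uM = 800)
iso <- gen_isotherm(list(n = 0.9, Kd_uM = 139, dH_kcal = -5), sch,
                    noise_sd = 0.3, seed = 4)
fit_isotherm(iso)
#>     term    estimate           se
#>        n   0.8996       0.00064
#>    Kd_uM 138.53         0.49
#>  dH_kcal  -4.994        0.0053
#> Wiseman c = 5.2
```

`run_pipeline(demo_config())` chains all four stages
(titration → relaxation → RDC → ITC) and writes tabular results plus a
`summary.txt` log; output is byte-identical for a fixed seed.

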
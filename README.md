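# telemocc

Passive acoustic telemetry is the workhorse for tracking endangered fish —
such as Atlantic Sturgeon — through offshore habitat slated for wind-energy
development. A grid of moored receivers logs coded transmissions from
tagged fish; the analytical questions are when fish are present, how they
move through the site, and which environmental cues drive their seasonal
occurrence. `telemocc` implements that analysis chain as a tested,
reusable R package, for movement ecologists and biostatisticians working
with fixed receiver arrays:

1. **Detection QC** — removal of spurious detections that are impossible
   given each fish's spatio-temporal chronology (two-sided implied-speed
   rule plus a lone-orphan rule, iterated to a fixed point).
2. **Event classification** — residence events (≥ 2 detections at one
   station spanning ≥ 2 h, terminated by a station change or a 12 h
   timeout) and movement events (station-to-station transitions completed
   in < 5 days), with rate of movement (ROM) from a WGS84 geodesic
   receiver-distance matrix.
3. **Kinematics** — ROM summaries and the minimum transit time through the
   array, `max(distance matrix) / max(ROM)`.
4. **Daily covariates** — unique daily counts (UDC), photoperiod `P`
   (NOAA solar position algorithm), moon fraction `M`, daily-mean river
   temperature and discharge, buoy SSTs, pairwise temperature differences,
   IDW temperature surfaces.
5. **Occurrence model** — a quasi-Poisson GAM with log link on thin-plate
   splines,

   ```
   UDC ~ s(HR_temp, P) + HR_discharge        (selected form)
   ```

   fitted by `occurrence_gam()`, reduced from a full candidate set by
   stepwise backwards elimination on the GCV criterion
   `n·D/(n − edf)²` with smooths collapsed to linear terms when their
   edf approaches one, and checked by a final-vs-full F-ratio test
   `F = [(D_final − D_full)/(edf_full − edf_final)] / φ_full`.
6. **Biology** — NMFS fork-length life stages and inverse von Bertalanffy
   age-at-capture, `t = t0 − ln(1 − L/L∞)/K`.
7. **Synthetic data** — `simulate_telemetry()` generates a complete
   synthetic study (24-station wedge grid at 3.43 km spacing, 15-month
   deployment with one lost station, 70–150 s tag delays, seasonal
   occupancy peaking November–January, river temperature lagging
   photoperiod by 35 days) with known ground truth, so every stage is
   testable without field data.

## Worked example

```r
library(telemocc)

res <- run_pipeline(list(sim = list(seed = 42, n_tags = 80,
                                    start = "2016-11-10",
                                    end = "2017-06-30")))
res$qc_report
#> <qc_report> 62754 in, 62724 retained (30 speed, 0 orphan removals;
#>   0 unverifiable single-detection tag(s))

s <- res$residence_summary
sprintf("residence: n = %d, mean (SD) = %.1f (%.1f) h", s$n, s$mean, s$sd)
#> "residence: n = 580, mean (SD) = 4.4 (3.0) h"

res$rom_summary
#> max = 0.71 m/s, mean (SD) = 0.28 (0.16) m/s

res$gam_final
#> Quasi-Poisson occurrence GAM (log link)
#>   UDC ~ s(HR_temp,P) + HR_discharge
#>   n = 233 (0 incomplete row(s) dropped)
#>   total edf = 14.27, dispersion phi = 0.816
#>   deviance explained = 90.0%, GCV = 0.8564

res$gam_ftest
#> F-ratio test: F(2.11, 216.62) = 0.575, p = 0.5727
```

The selected model keeps the temperature-by-photoperiod interaction smooth
and a negative linear discharge term — the planted structure of the
synthetic occupancy intensity — and the insignificant F-ratio confirms the
reduced model loses no meaningful residual deviance. The 30 removed
detections are exactly the spurious records planted by the simulator.

Two closed-form figures the package reproduces from published study
inputs:

```r
min_transit_time(matrix(c(0, 40600, 40600, 0), 2), max_rom = 0.86)
#> 13.11  # hours: minimum transit across a 40.6 km array at 0.86 m/s

age_at_capture(757)   # 757 mm total length, New York Bight VBGF params
#>   age  age_raw
#> 1   4 4.286187
```

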
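# zahnreihen

Quantitative analysis of tooth replacement in fossil reptile dentitions,
built around three questions palaeontologists ask of a polyphyodont (ever-
replacing) dentition:

1. **In what order are teeth replaced?** Teeth are replaced in waves
   (*Zahnreihen*) that sweep along the jaw. Each tooth gets a
   **replacement index**: a fully grown tooth with no successor scores
   1.0; a replacement tooth scores its total length divided by the length
   of its functional tooth, `RI = L_repl / L_funct ∈ (0, 1)`; the
   functional tooth then carries `1 + RI`. Plotting index against tooth
   position reveals degressive (decreasing) runs — the Zahnreihen — and
   the horizontal distance between successive runs, the **Z-spacing**,
   diagnoses the wave direction: `Z > 2.0` rostral→caudal, `Z = 2.0`
   simple alternation of odd and even positions, `Z < 2.0` reversed.
2. **How fast are teeth replaced?** Dentine grows by daily increments
   (von Ebner lines). Counting couplets gives the tooth formation time in
   days; mean couplet width is the daily dentine apposition rate (DDAR,
   µm/day). For a newly erupted tooth with no successor, the replacement
   rate is bounded above by its formation time; with two sectioned
   generations of one family it is exactly the difference of their
   increment counts.
3. **How did replacement patterns evolve?** The number of replacement-
   tooth generations is a discrete character on a phylogeny. The package
   time-calibrates a topology from first-appearance dates with the
   'equal' branch-sharing method, fits Mk rate models (ER/SYM/ARD) by
   maximum likelihood, weights them by Akaike weight
   `w_m = exp(-Δ_m/2) / Σ exp(-Δ/2)`, and samples stochastic character
   maps in proportion to those weights; per-node state frequencies across
   the maps estimate ancestral states.

Everything is data-frame-first and pipe-friendly: tooth tables in,
tibbles out, with `autoplot()` methods, `tidy()`/`glance()` for fitted
objects, and ground-truthed simulators (`simulate_dentition()`,
`simulate_increments()`, `simulate_mk_tips()`) so every stage can be
validated without fossil material.

## Worked example

Per-side Z-spacing values for six *Jeholosaurus* skulls ship with the
package; `summarize_jaw()` reproduces the published table layout and the
per-element averages:

```r
library(zahnreihen)
ztab <- readr::read_csv(system.file("extdata", "jeholosaurus_zspacing.csv",
                                    package = "zahnreihen"))
js <- summarize_jaw(ztab)
as.data.frame(js$element_means[, c("element", "n_values",
                                   "grand_mean_2dp", "grand_mean_3dp")])
#>      element n_values grand_mean_2dp grand_mean_3dp
#> 1 premaxilla        4           2.34          2.338
#> 2    maxilla       12           2.53          2.533
#> 3    dentary       12           2.48          2.478
```

The maxillary mean of 2.53 tooth positions (> 2.0) indicates a
rostral-to-caudal replacement wave with new teeth erupting caudally to
rostrally in alternate alveoli; the dentary mean of 2.478 matches it,
implying upper and lower jaws share one replacement rhythm.

From raw per-tooth measurements the whole chain runs in one call — here
on a simulated maxilla whose true wave period is 2.5 positions:

```r
d <- simulate_dentition(n_positions = 15, period = 2.5,
                        noise_cv = 0.03, seed = 1)
z_spacing(d)
#>   specimen_id element side  n_zahnreihen n_measurements mean_z z_spacing direction
#> 1 SIM1        maxilla left             7              7   2.50      2.50 rostral_to_caudal
```

Histology works the same way. The bundled synthetic increment series
carry the published couplet counts and mean widths:

```r
inc <- read_increment_table(system.file("extdata",
        "vonebner_increments_synthetic.csv", package = "zahnreihen"))
increment_summary(inc)
#>   specimen_id tooth_id section_plane formation_days ddar_um_4dp
#> 1 CUGW VH132  rPM5     mesiodistal               25     12.7401
#> 2 YLSNHM01797 lPM4     coronal                   33     13.7688
#> 3 YLSNHM01797 rM8      coronal                   46     11.7178

infer_replacement_rate(46, newly_erupted = TRUE,
                       family_has_replacement = FALSE)
#>   formation_days replacement_rate_days rate_qualifier
#> 1             46                    46 upper_bound_newly_erupted
```

The maxillary tooth formed in 46 days and was newly erupted with no
successor, so the maxillary replacement rate is at most (and probably
about) 46 days; the premaxillary bound rises from 25 days in an early
juvenile to 33 days in a subadult — replacement slowed through ontogeny
while daily dentine deposition stayed similar.

For ancestral-state reconstruction, see `calibrate_equal()`,
`fit_mk_models()` and `model_averaged_maps()`; the methods vignette
(`vignettes/tooth-replacement-analysis.Rmd`) walks through the full
pipeline on the bundled synthetic ornithischian dataset, and
`inst/cli/zahnreihen-cli.R` exposes each stage as a shell command.

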
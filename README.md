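# iebind

Binding free-energy analysis for protein–RNA complexes in R: MM/GBSA
enthalpies with per-residue decomposition, interaction-entropy (IE)
estimation of −TΔS, free-energy perturbation (FEP) over a λ schedule, and
the structural diagnostics that usually accompany such studies (RMSD/RMSF,
hydrogen-bond occupancy, salt-bridge and CH–π distance distributions).

The package is aimed at desk-scale method work: every stage is exercised on
deterministic synthetic inputs — toy hexamer-ring protein complexes bound to
short single-stranded RNA, energy time series with known statistical
structure, exactly solvable harmonic FEP systems — so each estimator can be
validated against closed forms and construction ground truth without running
molecular dynamics. The worked example mirrors the analysis of the Hfq
chaperone hexamer bound to A-rich OxyS sRNA fragments (the Ads/Aus systems
and their N48A mutants).

## The model

The binding free energy is split end-state style:

    ΔG_bind = G_complex − G_protein − G_RNA = ΔH − TΔS
    ΔH      = ΔE_vdw + ΔE_ele + ΔG_gb + ΔG_np

with gas-phase Lennard-Jones and Coulomb cross terms, generalized-Born
(OBC-II) polar solvation, and the empirical non-polar term
`ΔG_np = γ·SASA + β` (γ = 0.005 kcal/(mol·Å²), β = 0). Under the
single-trajectory protocol all four Δ terms are evaluated on complex frames
only, so internal bonded terms cancel.

The entropic part comes from the interaction-entropy estimator applied to
the gas-phase interaction energy E_int(t):

    −TΔS = kT ln ⟨ exp(ΔE_int / kT) ⟩,   ΔE_int = E_int − ⟨E_int⟩

computed on the 10-ns window with the smallest energy fluctuation
(RMSF(t) = sqrt⟨(E_int − ⟨E_int⟩)²⟩), after a single-pass 3σ noise filter.
For a Gaussian E_int the closed form is −TΔS = σ²/2kT, which the tests use
as an oracle.

Relative free energies use exponential averaging over λ-windows,

    ΔΔG = Σ_λ ΔG_λ,   ΔG_λ = −kT ln ⟨ exp(−(V_{λ+Δλ} − V_λ)/kT) ⟩_λ

with 11 equally spaced λ values, `V_λ = (1−λ)V_wt + λV_mut`, and
Beutler-form softcore mixing for mutated atoms.

## Worked example

```r
library(iebind)

# 1. Published per-trajectory (dH, -TdS) rows for Hfq-OxyS -> dG, averages, ddG
ref <- hfq_oxys_reference()
binding_free_energy(ref$dh[1], ref$minus_tds[1])$dg
#> [1] -28.6
round(average_and_ddg(ref$dg[ref$system == "Ads"])$wild_avg, 1)
#> [1] -27.7

# 2. Synthetic end-to-end run
dir <- tempfile()
cfg <- make_fixtures(dir, seed = 2)        # toy complexes + series + FEP toy
res <- run_pipeline(cfg, file.path(dir, "out"))
res$hbonds$occupancy[1]                    # constructed at 5/6 frames
#> [1] 83.33333

# 3. IE on a generated series (sigma^2 = 2kT -> exactly 1 kcal/mol)
s <- gen_energy_series(series_spec(n_points = 1e6, mean = -60,
                                   sigma = sqrt(2 * KB * 300), seed = 2024))
ie_entropy(s)$minus_t_delta_s
#> [1] 1.000716

# 4. FEP on the exactly solvable harmonic mutation (analytic: (kT/2) ln 2 = 0.2066)
total_ddg(gen_fep_samples(1, 2, n_per_window = 1e5, seed = 3))$total
#> [1] 0.2073096
```

A command-line front end with one verb per stage
(`simulate`, `energy`, `ie`, `mmgbsa`, `fep`, `hbonds`, `report`) is
installed at `inst/cli/iebind.R`, e.g.

```sh
Rscript inst/cli/iebind.R ie --series fx/wild_series_1.csv --window-ns 1
# -TdS = 2.3138 kcal/mol (window [1953, 2952] ps, 998 used, 2 discarded)
```

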
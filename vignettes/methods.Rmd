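---
title: "Methods: MM/GBSA, interaction entropy and FEP at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MM/GBSA, interaction entropy and FEP at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iebind)
```

## Scope and intent

`iebind` implements the analysis layer of an end-state binding free-energy
study of a protein–RNA complex — the kind of workflow applied to the Hfq
hexamer bound to A-rich OxyS sRNA fragments — without the molecular-dynamics
layer underneath it. Sampling is out of scope by design: trajectories enter
as multi-model PDB files plus a per-atom parameter table, energy traces as
two-column text. What the package owns is everything downstream: the MM/GBSA
enthalpy and its per-residue decomposition, the interaction-entropy (IE)
estimator with its window selection and noise filter, exponential-averaging
FEP, and the geometric trajectory analyses. A synthetic-data module generates
every input class with known ground truth, which is what makes the estimators
testable at desk scale.

## The enthalpy: single-trajectory MM/GBSA

Per frame, `ΔH = ΔE_vdw + ΔE_ele + ΔG_gb + ΔG_np`, each term a
complex-minus-receptor-minus-ligand difference evaluated on the *same*
complex frame (single-trajectory protocol). Consequences we rely on and
assert in tests:

* the gas-phase differences collapse exactly to cross-partition pair sums,
  so `pair_vdw()`/`pair_coulomb()` across the receptor/ligand masks *are*
  `ΔE_vdw`/`ΔE_ele` (checked against a brute-force double loop at 1e-10);
* bonded terms never appear — they cancel identically.

Pair sums use no cutoff. The MD engine that produced a real trajectory would
have used one, but end-state rescoring conventionally evaluates full sums;
the cutoff belongs to the simulation stage, which this package does not
reimplement.

**GB flavor.** The source analyses say only "Generalized Born". We use
OBC-II (HCT pairwise descreening with the tanh correction, α = 1.0, β = 0.8,
γ = 4.85; dielectric offset 0.09 Å; uniform descreening scale 0.8; interior
dielectric 1, exterior 80) because it is the AMBER-ecosystem default a reader
would assume. The oracles that gate correctness — the Born-ion closed form
−½·332.0637·(1−1/ε)·q²/R, the exact null at ε = 1, the two-distant-ions
asymptote, rotational invariance — hold for any sane GB flavor, which is
precisely why absolute ΔG_gb values are not reproduction targets. No
salt/Debye screening term is included (none is mentioned in the source
protocol).

**Non-polar term.** `ΔG_np = γ·SASA + β` with γ = 0.005 kcal/(mol·Å²),
β = 0. SASA is Shrake–Rupley on a deterministic golden-spiral grid
(default 960 points/atom, probe 1.4 Å, atomic radius = `rmin_half`). The
fixed spatial grid makes SASA — and hence ΔH — rotation-invariant only to
quadrature accuracy (~0.05 kcal/mol at 120 points on the demo complex);
tests assert the gas and GB terms tightly and ΔH at that looser tolerance.

**Per-residue decomposition.** Every cross pair term is split half to each
partner residue; GB self terms go to their owner and cross terms half-half;
non-polar by per-atom SASA difference. Summing over *all* residues (both
partners) therefore reproduces each total to 1e-6, which is the conservation
test. Output tables carry vdW, ele, GB, np, the conventional ele+GB
grouping, and the total, so either convention for "total contribution"
(with or without np) is recoverable from the same file.

## The entropy: interaction entropy

`−TΔS = kT ln ⟨exp(ΔE_int/kT)⟩` with `ΔE_int = E_int − ⟨E_int⟩`, evaluated
via log-sum-exp. Decisions where the prose left room:

* **Order of operations**: the minimum-fluctuation window is selected on the
  *raw* series (the fluctuation measure is the RMSF of the energy within a
  sliding window, implemented as the square root of the mean squared
  deviation — the printed formula it implements is a variance under a
  missing radical, and "root mean square" names the root); the 3σ filter is
  then applied *once*, non-iteratively, to the selected window, with mean
  and SD computed on that same window. Nothing in the source suggests
  iteration or out-of-window statistics.
* **Sign convention**: the exponent is +βΔE_int as printed. Since ΔE_int is
  mean-centered, the sign does not change the value for symmetric
  fluctuation distributions; for skewed series it would, and we follow the
  printed form rather than guessing.
* **Degenerate input**: a constant series has SD 0; the filter keeps all
  points and the estimator returns exactly 0.
* **Jensen bound**: the estimate is ≥ 0 analytically; round-off can produce
  −1e-16, which is clamped to 0.
* **Uncertainty**: IE is a nonlinear functional, so no SEM exists; a
  block-bootstrap SD (50 blocks) is provided (`ie_bootstrap_sd()`). The
  reference table prints "± 0.0" for this column, consistent with a very
  small but not strictly zero spread.

The Gaussian closed form −TΔS = σ²/2kT anchors the tests, including the
calibrated case σ² = 2kT → 1.00 kcal/mol at n = 10⁶. Tolerances for larger σ
grow with the lognormal delta-method Monte-Carlo error kT·e^{(σ/kT)²/2}/√n —
the exponential average converges slowly for σ ≳ 2 kcal/mol, which is
exactly why the quiet-window selection exists.

## FEP

Forward exponential averaging per window, summed over an 11-point equally
spaced λ schedule (10 forward windows sampled at λ = 0.0 … 0.9). The source
states only "11 λ-windows"; forward-only equally spaced FEP is the minimal
reading, and the harmonic toy's schedule-invariance test (11 vs 21 windows)
shows nothing hinges on it. Validation is against exactly solvable systems:
the harmonic mutation k → 2k with analytic ΔΔG = (kT/2)ln 2 = 0.2066
kcal/mol, the Gaussian identity ΔG = μ − s²/2kT, and forward/reverse
antisymmetry. Sampling is delegated to the exact Boltzmann sampler in the
synthetic module — the estimator, not the sampler, is the computation under
test. Softcore mixing uses the Beutler form with α_sc = 0.5 on LJ only and
linearly scaled charges; it is property-tested (endpoint identity to
1e-12, boundedness at r = 0 for a vanishing apolar atom), not value-tested,
because no softcore parameters are stated in the source protocol.

## Structural analyses

RMSD/RMSF use Kabsch superposition (SVD with reflection guard). The
hydrogen-bond criterion defaults to donor–acceptor ≤ 3.5 Å and D–H⋯A angle
≥ 135°, the conventional trajectory-analysis defaults; both are
configurable because the source never states its cutoffs. Reported mean
distance and angle are averaged over **all** frames, not only satisfying
ones — the reference occupancy table lists an 11.9 Å "bond length" for a
0 %-occupancy pair, which only an all-frames average can produce. "Lowest
energy structure" means the frame minimizing per-frame MM/GBSA ΔH within
the analysis window (ties → earliest); total potential energy is not
recoverable post hoc. Distance histograms use 0.2 Å bins.

## The synthetic world, and what a green test establishes

`gen_energy_series()` emulates the statistical features the IE workflow has
to survive: stationary Gaussian fluctuations, optional AR(1) autocorrelation
(the simplest stationary process that stresses convergence), regime changes
for the window scan, and symmetric two-sided outliers (the filter itself is
two-sided) at ≥ `outlier_scale`·σ. The source gives no noise model for its
real energy traces; Gaussian/AR(1) is a test assumption, not an inference.

`gen_toy_complex()` builds a ring of identical placeholder protein chains
(six by default, Sm-like) with an RNA-like single strand docked above the
ring face, and *imposes* contacts geometrically: each requested hydrogen
bond / salt bridge / CH–π contact is realized at its target distance in an
exactly counted, seeded subset of frames, moving only ligand-side atoms
(mirroring the observation that the protein barely changes conformation on
binding). Occupancy recovery is therefore exact by construction — including
fixtures parameterized by the published 95.5 % and 62.1 % occupancies — and
that is all it shows: the analysis counts correctly. The toys are not
force-field-realistic (placeholder chemistry, unbalanced charges, no
solvent), so green energy tests establish the *estimators'* correctness
against closed forms, never the reproduction of published absolute
enthalpies, which would require the original 100-ns explicit-solvent
trajectories.

Defaults that define the stated world: T = 300 K (the heating target of the
source protocol), k_B = 0.0019872041 kcal/(mol·K), 1 ps frame spacing
("saved every 1 ps"), 10-ns analysis windows, k_σ = 3, 11 λ-windows,
heptamer RNA. Jitter (0.05–0.08 Å) and series lengths in fixtures are sized
for runtime, stated in the generators' specs, and not tuned to outcomes.

## The worked-example aggregation layer

The published per-trajectory (ΔH, −TΔS) rows for Ads/Aus and their N48A
mutants ship as `hfq_oxys_reference()` and drive the aggregation tests:
ΔG = ΔH + (−TΔS) per row, unweighted averages across the three independent
trajectories, ΔΔG = mutant − wild. One caveat is inherent to the source
table: its columns were rounded independently, so two of twelve rows have a
printed ΔG differing by exactly 0.1 kcal/mol (one printed ulp) from the sum
of their printed addends, and one column average differs by 0.1 in the last
digit from the mean of its printed entries. No arithmetic on the printed
inputs can reproduce every printed number simultaneously; the package
therefore validates the identity at one printed ulp and reports unrounded
averages, which land within 0.07 kcal/mol of every published average and
difference.

## Known limitations

* GB radii/flavor and SASA radii are conventions, not fits; absolute
  solvation terms are only as meaningful as the toy parameters behind them.
* The IE estimator inherits its well-known slow convergence for
  high-variance interaction energies; the convergence trace is exposed so
  users can see it.
* Softcore charges are scaled linearly, so a *charged* vanishing atom still
  diverges at r → 0; use neutral end states for annihilation toys.
* The PDB reader covers the coordinate subset it writes (no altlocs,
  insertion codes, or header metadata — rejected explicitly).
* `rmsf_coords()` aligns on the analysis mask itself; the 6 rigid DOF
  absorb ~2/N of the apparent motion per axis, visible in the test oracle.
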
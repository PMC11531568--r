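# fretarch

Tools for determining the in-situ architecture of ligand-mediated receptor
dimers from camera-based single-molecule FRET, built around the MET:InlB
system: the hepatocyte growth factor receptor MET bound by internalin B, the
invasion protein of *Listeria monocytogenes*, assembles into 2:2 signaling
dimers on the plasma membrane, and two crystallographic assemblies ("form I"
and "form II") with contrasting ligand orientations are candidates for the
structure that actually forms in cells.

`fretarch` implements the full quantitative chain that discriminates such
candidates:

* **ALEX-FRET trace analysis** — automated curation of three-channel
  intensity traces by photobleaching-step detection, estimation of the four
  correction factors (leakage α, direct excitation δ, detection factor γ,
  excitation balance β), corrected efficiency/stoichiometry

      F_corr = I_DA − α·I_DD − δ·I_AA
      E = F_corr / (γ·I_DD + F_corr)
      S = (γ·I_DD + F_corr) / (γ·I_DD + F_corr + I_AA/β)

  and Gaussian population fitting in the stoichiometry-selected band.
* **Förster photophysics** — quantum yield φ_D = k_F·τ_L, Förster radius
  R₀ = 0.211·(κ²·n⁻⁴·φ_D·J)^(1/6) Å, distance conversion
  R = R₀·(1/E − 1)^(1/6), and first-order distance uncertainties.
* **Accessible-volume engine** — grid-based 1AV/3AV simulation of all
  sterically allowed dye positions around a labelling site (geodesic linker
  paths on a 26-connected grid, Rcpp Dijkstra kernel), with mean and
  FRET-averaged inter-dye distances for candidate dimer structures.
* **Photon distribution analysis (PDA)** — exact shot-noise-limited
  photon-ratio histograms (binomial over the empirical photon-count
  distribution, Poisson background) and single-state fits, to separate
  conformational heterogeneity from noise.
* **Structural metrics** — inter-domain θ angle, radius of gyration with
  extended/collapsed classification (45 Å threshold), RMSD after
  superposition, Shrake–Rupley SASA and buried interface areas.
* **SMLM cluster density** — NeNA localization precision, temporal linking
  (6×NeNA / 5 dark frames), DBSCAN (2×NeNA, min. 10 localizations) and
  clusters-per-area densities from dSTORM-style localization tables.
* **Model discrimination** — chi-square scoring of measured distances
  (with censored "no FRET" lower bounds) against per-form predictions,
  plus bootstrap uncertainties of mean distances.
* **Synthetic data generators** for all of the above, with ground-truth
  sidecars, so the whole chain is testable without experimental downloads.

## Worked example

Simulate a cohort of ALEX traces at a known donor–acceptor distance,
recover the efficiency through the full correction pipeline, convert to a
distance, and score the two candidate assemblies:

```r
library(fretarch)

pair <- fluorophore_pair("cy3b_T")   # Cy3B donor, tail-labelled variant
pair
#> Fluorophore pair 'cy3b_T': phi_D = 0.6214, R0 = 6.353 nm

params <- trace_sim_params(true_distance = 4.8, pair = pair, seed = 42)
cohort <- simulate_trace_cohort(240, params,
                                donor_only_fraction = 0.15,
                                acceptor_only_fraction = 0.15)
analysis <- analyze_trace_set(cohort)
analysis$factors
#> correction_factors: alpha=0.0843 delta=0.0661 gamma=0.8466 beta=1.3503
analysis$population
#> FRET population: E = 0.839 +/- 0.003 (n = 111, S in [0.30, 0.70])
```

The fitted mean efficiency of the doubly-labelled population (0.839, for
traces simulated at 4.8 nm with α = 0.08, δ = 0.06, γ = 0.85, β = 1.2)
converts back to a distance:

```r
round(efficiency_to_distance(0.84, pair$R0), 1)   # nm
#> 4.8
round(distance_uncertainty(0.84, 0.06, pair$R0), 1)
#> 0.4
```

Scoring the measured fixed-cell distances — 4.8 ± 0.3 nm (T-T),
6.2 ± 0.4 nm (T-H/H-T), and no detectable FRET for H-H (treated as a
censored lower bound at a detection threshold of E = 0.1) — against the
AV-predicted distances of the two crystal assemblies:

```r
measured <- measured_distance_set(
  pairs = c("T-T", "T-H/H-T", "H-H"),
  R_nm = c(4.8, 6.2, NA), sigma_nm = c(0.3, 0.4, NA),
  E_detect = 0.1, R0 = 6.30)

form_I  <- structure(data.frame(pair = c("T-T", "T-H/H-T", "H-H"),
                                R_E_nm = c(7.6, 7.1, 7.6)),  form = "form I")
form_II <- structure(data.frame(pair = c("T-T", "T-H/H-T", "H-H"),
                                R_E_nm = c(5.9, 6.0, 12.2)), form = "form II")
select_form(measured, list(form_I, form_II))
#> Candidate dimer forms ranked by chi-square:
#>     form     chisq dof delta_chisq
#>  form II  13.69444   2     0.00000
#>   form I 110.20388   2    96.50944
#> Best form is favoured but shows no quantitative agreement (reduced chi-square above threshold).
```

Form II is clearly favoured, and the flag on the best form reproduces the
observation that the crystal form II matches qualitatively while its T-T
distance deviates from the in-situ measurement — the discrepancy that
motivates structural refinement.

A YAML-configurable pipeline (`run_pipeline()`) chains the stages
(simulate → analyze → PDA → discriminate, plus localization-field → density)
with per-stage seeds derived from one global seed and writes a run manifest.
The methods vignette (`vignettes/dimer-architecture.Rmd`) documents the
models, defaults and numerical choices.

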
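---
title: "Inferring receptor-dimer architecture from single-molecule FRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring receptor-dimer architecture from single-molecule FRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretarch)
```

## The scientific problem

Ligand-bound cell-surface receptors often signal as 2:2 dimers, but crystal
contacts do not always reveal which of several plausible assemblies exists in
the membrane of a living cell. For the MET receptor bound to the bacterial
invasion protein InlB, two crystallographic 2:2 assemblies with contrasting
ligand orientations have been proposed ("form I" and "form II"). `fretarch`
implements the quantitative chain by which camera-based single-molecule FRET
(smFRET) with alternating laser excitation (ALEX) discriminates between such
candidate assemblies:

1. **Trace correction** — per-complex intensity traces in three channels
   (`I_DD`, `I_DA`, `I_AA`) are curated by photobleaching-step analysis and
   corrected for leakage ($\alpha$), direct excitation ($\delta$), detection
   imbalance ($\gamma$) and excitation balance ($\beta$), yielding accurate
   FRET efficiencies $E$ and stoichiometries $S$:
   $$F_{corr} = I_{DA} - \alpha I_{DD} - \delta I_{AA}, \qquad
     E = \frac{F_{corr}}{\gamma I_{DD} + F_{corr}}, \qquad
     S = \frac{\gamma I_{DD} + F_{corr}}
              {\gamma I_{DD} + F_{corr} + I_{AA}/\beta}.$$
2. **Distance conversion** — population efficiencies become donor–acceptor
   distances through Förster theory, $R = R_0 (1/E - 1)^{1/6}$ with
   $R_0 = 0.211\,(\kappa^2 n^{-4} \phi_D J)^{1/6}$ Å and
   $\phi_D = k_F \tau_L$.
3. **Structure-based prediction** — accessible-volume (AV) simulations place
   the dye, on its flexible linker, at every sterically allowed position
   around each labelling site of a candidate structure and predict the
   distance and efficiency each assembly would produce.
4. **Shot-noise modelling (PDA)** — the expected photon-ratio histogram for
   a single narrow distance state is computed exactly from binomial
   statistics, so excess width in measured histograms can be attributed to
   conformational heterogeneity rather than noise.
5. **Model discrimination** — measured distances (including "no FRET"
   observations treated as censored lower bounds) are scored against each
   candidate's predictions with a chi-square statistic.

A companion dSTORM module estimates receptor cluster densities (NeNA
precision, temporal linking, DBSCAN) to select cell lines sparse enough for
single-complex imaging.

## Synthetic data as the testbed

Every stage consumes inputs that the package can generate itself with known
ground truth.

**ALEX traces** (`simulate_alex_trace`, `simulate_trace_cohort`). Each
alternation cycle draws Poisson photon counts around the closed-form channel
expectations; the true efficiency is set by a ground-truth distance and the
dye pair's Förster radius. Both dyes photobleach in a single step with
geometric waiting times, and donor-only/acceptor-only contaminant species
can be mixed in. Default study conditions: 200 cycles per trace at 100 ms
exposure, a mean donor photon budget of 300 photons per frame, crosstalk
$\alpha = 0.08$, $\delta = 0.06$, detection factor $\gamma = 0.85$,
excitation balance $\beta = 1.2$, per-frame bleach probabilities 0.004
(donor) and 0.010 (acceptor), and 2 background photons per channel and
frame. The photon budget and background are not printed for the original
experiment, so these defaults were chosen once as typical of EMCCD-TIRF
imaging of organic dyes at this exposure; they are exposed in
`trace_sim_params()`. Camera noise is simplified to shot noise plus optional
Gaussian read noise — the EMCCD excess-noise factor is omitted, so simulated
variances slightly underestimate a real camera's. Blinking is not simulated
in FRET traces.

What passing recovery tests on these traces shows is that the *correction
chain is unbiased under its own generative model* (cohorts simulated across
$E \in [0.1, 0.9]$ are recovered with $|$bias$| < 0.02$); it does not
certify robustness to effects the generator omits (multiplicative camera
noise, diffusion, spectral fluctuations).

**Localization fields** (`simulate_localization_field`). Receptor clusters
follow a homogeneous spatial Poisson process; each cluster is re-localized
(default mean 60 localizations, in blinking bursts of mean length 3 frames)
with 10 nm Gaussian precision, plus uniform noise localizations. Sixty
localizations per cluster keeps roughly twenty linked events per cluster,
comfortably above the 10-localization DBSCAN threshold, which is what a
well-labelled receptor cluster yields in dSTORM.

**Toy structures** (`make_toy_structure`). Small PDB files written through
the standard writer stand in for crystallographic inputs in tests; dye
anchor points are dummy cysteine CB atoms.

## Estimating the correction factors

$\alpha$ and $\delta$ come from singly labelled species (pre-bleach ratios
$I_{DA}/I_{DD}$ and $I_{DA}/I_{AA}$). $\gamma$ is measured across each
acceptor bleach step as $\Delta I_{DA}'/\Delta I_{DD}$. The spec of the
procedure leaves one choice open: how to average trace-wise $\gamma$
estimates. `estimate_gamma()` defaults to the plain mean of per-trace
ratios (the convention of applying mean correction factors), with a median
option; `analyze_trace_set()` instead uses the *pooled* estimator
$\sum_i \Delta I_{DA,i}' / \sum_i \Delta I_{DD,i}$. The two agree for
well-resolved FRET, but for weak-FRET samples the per-trace donor rise is
only a few photons and the ratio becomes heavy-tailed; weighting each trace
by its rise keeps the estimator stable there.

$\beta$ normalizes acceptor-excitation to donor-excitation intensity. Its
denominator is implemented as the FRET-corrected total donor-excitation
signal $\mathrm{avg}(\gamma I_{DD} + F_{corr})$ rather than the bare
$\mathrm{avg}(\gamma I_{DD})$: the bare form equals the corrected one only
in the absence of energy transfer, and applying it to a high-FRET species
would inflate $\beta$ by $1/(1-E)$ and push the doubly-labelled population
out of its own stoichiometry window. With this convention the FRET species
sits at $S = 0.5$ and the default acceptance window $S \in [0.3, 0.7]$
(the band between the donor-only $S \approx 1$ and acceptor-only
$S \approx 0$ populations) selects it cleanly.

Background is handled per trace: each donor-excitation channel is at
background only after the *donor* has bleached, so `I_DD` and `I_DA` use
the window after the last donor step, while `I_AA` uses the window after
its own terminal step; a channel whose fluorophore never bleaches inside
the trace falls back to zero subtraction. This leaves a small residual bias
(about $-0.005$ in $E$ at the default 2-photon background) for traces whose
donor outlives the recording.

## Bleach-step detection

Steps are found by a two-window mean-shift statistic (window = `min_dwell`
= 5 frames) thresholded at 3 local noise standard deviations. The noise
scale is the MAD of first differences in a 20-frame neighbourhood, floored
by the Poisson standard error $\sqrt{2\mu/\mathrm{min\_dwell}}$ — the local
floor matters because an empirical MAD collapses on quiet post-bleach
stretches and would otherwise flag shot noise as steps. One guard frame on
each side of a detected step absorbs ±1-frame localization error in the
windows used for $\gamma$ and $E$. Accepted traces must show exactly one
acceptor-channel bleach step dropping to near background (a residual level
indicates a second acceptor), no donor loss before it, at most one donor
step after it, and an anticorrelated donor rise.

## Accessible-volume construction

`compute_av()` builds a cubic grid (default spacing 1 Å) centred on the
attachment atom — the CB of the mutated residue by default; the dye replaces
the side chain, so side-chain atoms beyond CB are not obstacles. Grid nodes
whose linker path would clash (protein van der Waals radius + half linker
width) are removed and geodesic path lengths are computed by Dijkstra's
algorithm on the 26-connected grid graph, letting the linker bend around
obstacles rather than requiring line-of-sight. A node belongs to the dye's
accessible volume if its path length is within the linker length and a
sphere of the dye radius placed there clears all protein atoms. The
ellipsoidal dye is approximated by the union of three single-radius volumes
with equal 1/3 weights and uniform weights within each sub-volume; no
contact-surface reweighting is applied. Dye geometries ship as presets
(`av_dye_preset`): Cy3B maleimide (linker 18.5 Å, radii 3.4/8.2/3.0 Å) and
ATTO 647N maleimide (linker 21.0 Å, radii 7.15/4.5/1.5 Å), both with 4.5 Å
linker width.

`pair_distance_stats()` reports both the mean inter-dye distance
$\langle r \rangle$ and the FRET-averaged distance
$R_E = R_0(1/\langle E \rangle - 1)^{1/6}$ with
$\langle E \rangle = \langle 1/(1 + (r/R_0)^6) \rangle$ under static
isotropic ($\kappa^2 = 2/3$) averaging, because published AV distances are
not always explicit about which average they quote; the two differ by
Jensen's inequality wherever the efficiency curve is convex. Pairing is
exhaustive up to 4×10⁶ point pairs and falls back to seeded stratified
subsampling beyond that. Mixed donor/acceptor placements (T-H and H-T) are
predicted separately and averaged, as the two arrangements are
experimentally indistinguishable; for the mixed pair the donor-T Förster
radius (6.34 nm) is the default since the experiment does not state which
value it used.

## Photon distribution analysis

`pda_predict()` computes the ratio histogram exactly: for each total photon
count $N$ (taken from the empirical per-window distribution) and each
equal-probability quadrature node of the Gaussian distance state, acceptor
counts are Binomial$(N, \varepsilon(r))$, where
$\varepsilon(r) = \frac{\gamma E + \alpha(1-E) + \delta\beta\gamma}
{\gamma E + \alpha(1-E) + \delta\beta\gamma + (1-E)}$ folds the correction
factors and the mean direct-excitation rate into the apparent acceptor
fraction. Per-channel Poisson background is convolved over a truncated
support (mass cutoff 10⁻¹⁰). Windows are per-trace pre-bleach aggregates,
matching trace-based histograms rather than diffusion bursts.
`pda_fit()` optimizes distance and width against the observed histogram
with a smooth floored-Pearson objective and reports a goodness-of-fit
chi-square on bins merged to at least five expected counts. One limited
width state is supported; dynamic (interconverting) PDA is out of scope.

## Structural metrics

The inter-domain angle $\theta$ is defined by two centre-of-mass difference
vectors over four residue ranges; the published default ranges for the
Sema–IPT1 angle are 182–200/464–479 and 561–657/655–657. The second pair
overlaps as printed — almost certainly a typo in the source — but the
definition is kept verbatim, configurable, and flagged with a warning.
Centres of mass are mass-weighted with unit-mass fallback. $R_g$ is computed
on C$\alpha$ atoms with unit masses by default, and conformations are
classified extended strictly above the 45 Å threshold. RMSD uses standard
least-squares superposition (via bio3d). SASA is Shrake–Rupley with 960
deterministic golden-spiral points and a 1.4 Å probe; interface areas use
the buried-surface-per-side convention
$(\mathrm{SASA}_A + \mathrm{SASA}_B - \mathrm{SASA}_{AB})/2$ with
whole-protomer chain groups.

## Cluster density

The dSTORM recipe is reproduced with its published constants: localization
precision by NeNA (nearest-neighbour distances between consecutive frames,
fitted with the two-localization Rayleigh model plus a linear background
term), temporal linking with radius $\min(6\sigma_{NeNA}, 0.45\,\mathrm{px})$
and 5 tolerated dark frames, DBSCAN with
$\varepsilon = \min(2\sigma_{NeNA}, 0.15\,\mathrm{px})$ and minimum 10
localizations, and density = clusters / cell area. The pixel caps are
applied as nm ceilings at 157 nm/px. Linking is the transitive closure of
the pairwise rule; DBSCAN border points join the first core cluster that
reaches them in scan order (a documented deterministic tie-break). The cell
area is an input, not segmented from images.

## Model discrimination

The experiment argues its assembly assignment from a distance table and an
absent signal; the package formalizes this as
$\chi^2 = \sum ((R_{meas} - R_{pred})/\sigma_R)^2$ over uncensored pairs,
with "no FRET detected" encoded as a censored lower bound
$R_{min} = R_0 (1/E_{detect} - 1)^{1/6}$ at a detection threshold
$E_{detect} = 0.1$ (the threshold is this package's choice; none is stated
for the original measurement). Predictions above the bound contribute
nothing; violations are penalized with a configurable `sigma_floor`
(default: mean uncensored $\sigma_R$). No p-values are attached —
$\Delta\chi^2$ is reported descriptively, and a best form whose reduced
chi-square exceeds 3 is flagged as qualitative-only agreement. Bootstrap
uncertainties of mean distances resample with replacement (default 1000
resamples) and can convert efficiency series to distances before or after
averaging.

## Numerical choices and degenerate inputs

* Efficiencies at or outside $(0,1)$ cannot be converted to distances and
  raise an explicit error; censoring is the caller's mechanism for such
  observations.
* Recomputing $R_0$ from the printed constants gives 6.353/6.312 nm versus
  the printed 6.34/6.30 nm — a ≤0.3% residual consistent with unrounded
  lifetimes upstream; comparisons therefore allow 1%.
* The population Gaussian is fitted by least squares on a histogram binned
  over the population core (median ± 6 robust SD, 25 bins) so single
  stray traces cannot dictate bin width; a moments fallback is available
  but off by default.
* An AV site whose every sub-volume is sterically excluded reports
  "buried" distinctly from a missing attachment atom.
* Internal length units are nm in photophysics and Å in structure modules;
  `pair_distance_stats` converts at its boundary.
* Every stochastic pipeline stage draws from
  `derive_seed(global_seed, stage_name)`, so a run is reproducible from one
  integer.

## Problem sizes used in the shipped checks

The test-suite and the reproduction script use cohorts of 200–240 traces of
200 frames, localization fields of ~100 µm² at 3 clusters/µm², PDA windows
of ~60 photons × 1000 windows, and AV grids of ≤ 43³ nodes — sizes at which
every stochastic recovery in the suite is stable while the whole suite runs
in minutes on one CPU core.

## Known limitations

* Rotamer-library dye models (conformational-ensemble FRET prediction from
  MD trajectories) are out of scope; the AV model is static and ignores
  dye–surface interactions ("trapped dye" states).
* The trace simulator omits EMCCD excess noise, blinking and diffusion.
* Trace-wise background estimation is impossible for channels whose dye
  never bleaches; those traces carry a small residual background bias.
* MD-derived quantities (replica distance tables, angle time series,
  collapse kinetics) require trajectory sampling that is not reproducible
  at desk scale; the package ships the metric implementations,
  oracle-checked on constructed frames, not the trajectory results.
* The chi-square discrimination statistic is a formalization of a
  qualitative argument; it is labelled as such in reports and carries no
  sampling-theory guarantees when predictions come from a single static
  structure.
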
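---
title: "The coupled Notch-Delta-Jagged / EMT circuit: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled Notch-Delta-Jagged / EMT circuit: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchemt)
```

## The biological question

Carcinoma cells can undergo a partial epithelial-mesenchymal transition
(EMT) and stop in a hybrid epithelial/mesenchymal (E/M) state that retains
cell-cell adhesion while gaining motility — the state thought to underlie
collectively migrating clusters of circulating tumour cells. Whether a cell
stays epithelial (E), goes hybrid (E/M) or completes EMT (M) is decided by
a small intracellular circuit; whether *neighbourhoods* of cells make the
same decision together is decided by juxtacrine Notch signalling, because
the Notch ligands Delta and Jagged are wired to that circuit with opposite
signs. `notchemt` implements this coupled system as a quantitative
simulator: a per-cell ODE model, tools for mapping its multistability, and
a hexagonal-lattice tissue simulator with pattern metrics.

## The per-cell model

Each cell carries eleven species: Notch receptor $N$, Delta $D$, Jagged
$J$, the cleaved Notch intracellular domain (NICD) $I$, the two
EMT-inhibiting microRNAs miR-34 and miR-200, SNAIL mRNA and protein, ZEB
mRNA and protein, and (optional, off by default) the glycosyltransferase
Fringe $F$.

**Regulation primitives.** Every transcriptional edge uses the shifted
Hill function
$$H^S(X) = \frac{1 + \lambda\,(X/X_0)^n}{1 + (X/X_0)^n},$$
which equals 1 with no regulator and saturates at the fold change
$\lambda$ ($\lambda<1$ represses, $\lambda>1$ activates). MicroRNA action
on a target mRNA with $n_b$ binding sites uses binomial occupancy weights
$M_i(\mu) = \binom{n_b}{i}\,(\mu/\mu_0)^i/(1+\mu/\mu_0)^{n_b}$: occupancy
level $i$ translates at factor $l_i$ (non-increasing in $i$), degrades the
mRNA at rate $\gamma_{m,i}$, and consumes the microRNA at rate
$i\,\gamma_{\mu,i}$.

**Circuit topology.** NICD activates Notch, Jagged and SNAIL and represses
Delta. SNAIL activates ZEB and represses both microRNAs; ZEB activates
itself, and the microRNAs silence their targets: miR-200 represses ZEB
mRNA (6 sites) and Jagged translation; miR-34 represses SNAIL mRNA
(2 sites) and Notch/Delta translation. An external lumped EMT-inducing
signal `I_ext` (e.g. TGF-$\beta$/Wnt) activates SNAIL transcription. The
miR-34/SNAIL pair acts as a noise-buffering monostable integrator (SNAIL
also self-inhibits), while the miR-200/ZEB pair is the tristable switch
whose miR-200 level defines the phenotype: E (high), E/M (intermediate),
M (low).

**Cell-cell coupling.** The receptor binds ligand presented by
neighbouring membranes: the trans flux $k_t N (D_{ext}+J_{ext})$ consumes
receptor, consumes the neighbour's ligand ($k_t D\,N_{ext}$,
$k_t J\,N_{ext}$) and produces NICD. Receptor and ligand in the *same*
cell mutually inactivate (cis-inhibition, $k_c N D$ and $k_c N J$).
Soluble ligands `sD_ext`/`sJ_ext` trans-activate with the same $k_t$ but,
not being membrane-bound, engage neither cis-inhibition nor the
neighbour-receptor drain. Because NICD represses Delta but activates
Jagged, Delta-mediated signalling is lateral *inhibition* (neighbours
adopt opposite Sender/Receiver roles, checkerboard-like patterns) while
Jagged-mediated signalling is lateral *induction* (neighbours adopt the
same hybrid Sender/Receiver state, clusters).

**Ligand-specific trans affinity.** External Delta and Jagged would
otherwise enter only through the symmetric sum $D_{ext}+J_{ext}$, making
one-cell analyses blind to ligand identity — yet the biology of Notch
glycosylation says the affinities differ (unmodified Notch binds Jagged
more readily; Fringe shifts the balance toward Delta). The model therefore
carries baseline affinity factors `affinityD` (default 0.8) and
`affinityJ` (default 1.0) on all trans terms; the optional Fringe module
makes them NICD-dependent (Delta scaled up, Jagged down, by shifted-Hill
functions of $F$). This is what makes the Epithelial-Sender range wider
under a Delta sweep than under a Jagged sweep, and the two-parameter
phase diagram asymmetric. Cis-inhibition stays ligand-symmetric.

## Parameters: units, defaults, provenance

All abundances are molecule counts, rates are per hour. The packaged
defaults (`inst/extdata/default_params.yaml`, loaded by
`default_parameters()`) come in three groups:

* **EMT core** (microRNA/SNAIL/ZEB productions, degradations, Hill edges,
  binding-site ladders): the canonical tristable-switch parameterisation
  of this circuit family, with one global choice of ours — a kinetic
  scale factor of 0.5 applied to all twelve production/degradation rates
  and the microRNA-machinery rates. A uniform scale leaves every steady
  state and bifurcation identical and only sets the relaxation clock; we
  chose it so that partial-EMT transients in tissue run over the 100-200 h
  window at which tissue snapshots are analysed.
* **Notch module** (`gN = 80`, `gD = 2000`, `gJ = 200` one-cell defaults,
  `kt = 5e-5`, `kc = 2e-4`, `gamma = 0.1`, `gammaI = 0.5`, NICD edges
  with $X_0$ 15-28 and $n$ 4-6): calibrated once so that the model's
  stated operating points hold simultaneously — a single cell facing
  `N_ext = 5000`, `J_ext = 600` is bistable between an epithelial Sender
  (low N, high D) and an epithelial Receiver (high N, low D); rising
  `J_ext` drives the adiabatic staging E to E/M to M; and a resting
  tissue cell carries $N \approx 850$, so six neighbours together present
  roughly the `N_ext = 5000` of the one-cell convention.
* **Coupling** (`hill_I_ms`: $X_0 = 75$, $n = 2$, $\lambda = 8$;
  `hill_Iext_ms`: $X_0 = 50$, $n = 2$, $\lambda = 10$): the NICD threshold
  is pinned from both sides — low enough that fully Jagged-activated
  neighbourhoods hold each other past the EMT fold (lateral-induction
  cluster persistence), high enough that the reference Receiver at
  `J_ext = 600` stays epithelial.

Every value can be overridden through `default_parameters(...)` or a YAML
config validated by `load_config()`.

## Phenotype classification

`classify_emt()` reads the miR-200 band: E above `mir200_upper`, M below
`mir200_lower`, E/M between. The packaged boundaries are *derived from the
model itself* by `derive_thresholds()`: the Notch-decoupled core is swept
in `I_ext` until exactly three branches coexist (here at
`I_ext` $\approx$ 50-54, branches near 19,000 / 10,500 / 1,300 molecules)
and the boundaries are placed at the geometric midpoints (3,886 and
14,830). `classify_sr()` compares N, D and J against "high" boundaries:
Notch and Delta boundaries are geometric means of the Sender and Receiver
branch values at the reference bistable point; the Jagged boundary is the
geometric mean between the largest epithelial and the smallest post-EMT
Jagged level along a `J_ext` sweep, because Jagged separates phenotypes
across the EMT transition, not across the Sender/Receiver pair.

## Multistability analysis

`find_stable_states()` enumerates attractors by multi-start relaxation:
random starts drawn per species over twice its unregulated steady scale
(the ZEB arm additionally carries its self-activation fold so that
mesenchymal basins are covered), plus a deterministic set of canonical
compositions (quiescent / Sender / Receiver / hybrid signalling crossed
with epithelial / hybrid / mesenchymal cores) that make the enumeration
reproducible when a basin is narrow. A state is accepted when its
scale-free residual $\max_X |\dot X|/(\gamma_X X + 1)$ falls below `tol`
(default $10^{-3}$) after the trajectory's relative change over a 10 h
window falls below $10^{-6}$; duplicates are merged at 1% relative
L-infinity distance, keeping the smaller residual. Relaxation cannot land
on saddles, so reported states are stable by construction; unstable fixed
points are exposed by `nullclines_nd()`, which operationalises the
reduced (N, D)-plane picture by clamping one of the two species on a grid
and relaxing everything else to quasi-steady state, intersecting the two
curves, and classifying each crossing by releasing the clamp from a 1%
perturbation (flee distances measured on a mixed scale so that near-empty
species do not dominate).

`sweep_parameter()` and `phase_diagram()` are brute-force continuations:
stable sets are recomputed per grid point, with the previous point's
branches re-used as extra starts. Fold positions are therefore located
only to grid resolution, and no attempt is made to classify bifurcation
types.

## The tissue simulator

`build_lattice()` uses odd-r offset hexagonal indexing; periodic
boundaries require an even number of rows (the offset stencil is not
symmetric across the row seam otherwise) and are the default, because
they remove edge artefacts from cluster statistics. Each synchronous step
freezes the per-cell environments computed from the current tissue state,
then advances all cells by one RK4 step (`dt = 0.1` h by default; the
integrator floors species at zero, which guards non-negativity against
rare undershoot). Neighbour aggregation defaults to the **sum** over the
six neighbours: six membranes each present ligand, and the sum convention
makes a resting tissue's aggregated receptor ($6 \times \approx 850$)
match the one-cell boundary value `N_ext = 5000`, keeping one-cell and
tissue analyses on the same scale. Mean aggregation remains available.

**Initial conditions.** `random_initial_states()` draws each species
independently and log-uniformly across three decades up to twice its
steady scale. The log-uniform choice is deliberate: it represents every
phenotype composition in the starting tissue (linear-uniform draws sit
almost entirely in the epithelial basin because epithelial microRNA
levels dominate the linear range), which is what makes the 120 h tissue
snapshots carry a mix of E, E/M and M cells whose spatial organisation
the pattern metrics then quantify.

## What the simulations show — and what they do not

With the frozen defaults the package reproduces, end to end (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`):

* bistable Sender/Receiver coexistence at the reference point, both
  epithelial;
* a tristable window of the decoupled EMT core with exactly three states
  separated by the miR-200 bands;
* adiabatic E to E/M to M staging under rising external Jagged, with a
  wider Epithelial-Sender range under external Delta (ratio
  `affinityJ/affinityD` = 1.25);
* Jagged-dominated tissues (`gD = 20, gJ = 70`) whose hybrid-cell
  clusters at 120 h dissolve completely by 240 h without external
  signals, while a mesenchymal/hybrid tissue under the same production
  rates *persists* through 360 h — lateral induction acts as an
  intercellular phenotypic-stability factor with genuine tissue-level
  bistability (finite clusters erode from their boundaries; a fully
  non-epithelial tissue has no boundary);
* soluble Jagged (`sJ_ext = 4000`) raising the hybrid E/M fraction
  specifically (mesenchymal fraction unchanged), the lumped inducer
  `I_ext = 70` driving a mostly-M tissue under either ligand regime, and
  a monotone tissue mean-NICD dose response.

Two limitations are worth stating plainly. First, in this calibration
sustained *Delta*-driven EMT at `gD = 70` is structurally impossible: the
Delta field a cell can receive (six neighbours' Delta after NICD
repression, cis-inhibition and ligand trans-endocytosis) stays below the
`J_ext = 600` reference at which the Receiver must remain epithelial, and
the two constraints pin the NICD-to-SNAIL threshold from both sides.
Delta-dominated tissues therefore show only sparse, dispersed non-E
remnants at 120 h — their mean non-E cluster size is smaller than in
Jagged-dominated tissues (as expected for lateral inhibition), but their
unlike-neighbour fraction, which scales with non-E abundance under its
all-pairs definition, is generally *lower*, not higher. The corresponding
acceptance assertion is left failing rather than weakened. Second, in
global multi-start enumeration the mesenchymal attractor's basin opens
slightly (about 100 molecules of `J_ext`) before the hybrid branch, so
the staging property holds along the adiabatic path from the epithelial
state — the protocol the staging narrative describes — not as a statement
about global fold ordering.

The synthetic tissues also idealise real epithelia in ways the tests do
not probe: cells neither move, divide nor die; the update is synchronous
and deterministic (no transcriptional noise); and the lumped `I_ext`
stands in for all paracrine EMT-inducing signalling. Passing tests
demonstrate the circuit-level mechanism, not tissue-scale realism.

## Numerical choices and problem sizes

Fixed-step RK4 at `dt = 0.1` h keeps every rate term well below the
stability limit (fastest rates $\approx 2\,h^{-1}$); halving the step
changes 120 h endpoints by well under 0.5%. Steady-state detection
integrates to at most 2000 h with the 10 h / $10^{-6}$ convergence
window. The packaged experiment presets default to the 50 x 50 lattices
and 40-point-per-axis diagrams of the reference protocols; the test suite
exercises tissue claims at 50 x 50 where the claim is about a 50 x 50
tissue (transience, patterning contrast) and 24 x 24 for dose-response
style comparisons, completing in about two minutes in total.

## Worked example

```{r example, eval = FALSE}
p <- default_parameters(gD = 20, gJ = 70)   # Jagged-dominated tissue
th <- default_thresholds(p)
lat <- build_lattice(50, 50, "periodic")
st0 <- random_initial_states(lat, p, seed = 1)
run <- simulate_tissue(lat, st0, p, t_end = 240,
                       snapshot_times = c(120, 240), thresholds = th)
pattern_summary(run[[1]])$fractions      # mixed phenotypes at 120 h
pattern_summary(run[[2]])$fractions      # all epithelial at 240 h
plot_tissue(run[[1]])
```
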
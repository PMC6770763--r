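---
title: "Kinetic modeling of PD-L1 regulation in neuroblastoma signaling networks"
author: "pdl1net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of PD-L1 regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdl1net)
```

## The biological question and the model

Neuroblastoma tumors bearing the activating ALK-F1174L mutation signal
constitutively through the kinase cascades (RAS/MAPK, PI3K/AKT) that feed
the transcription of PD-L1 (CD274), the ligand that tumors use to blunt a
T-cell attack and the target of checkpoint immunotherapy. `pdl1net` models
this regulation as a compartmentalized reaction network turned into a
system of ordinary differential equations: one state per molecular species
(gene, mRNA, protein, simple molecule, drug, and a degradation sink), one
rate law per reaction.

Three rate-law families cover every reaction class the curation uses:

* **Mass action** for degradation and simple conversions:
  $v = k_1\prod_i [S_i] - k_2\prod_j [P_j]$, with $k_2$ present only for
  reversible steps (for example a basal re-activation paired with an
  inactivation).
* **Henri–Michaelis–Menten (HMM)** for transcription, translation and
  enzyme-driven activation: $v = k_{cat}\,[E]\,\frac{[S]}{K_m+[S]}$; when
  no enzyme species is referenced, $k_{cat}$ plays the role of $V_{max}$.
* **Modified HMM** for interactions whose driver is not consumed and acts
  proportionally — the form used for drug-mediated inactivation:
  $v = k_{cat}\,[M]\,\frac{[S]}{K_m+[S]}$, linear in the modifier
  concentration $[M]$ (e.g. crizotinib inactivating mutant ALK).

Each species' derivative is the signed-stoichiometry sum of its reactions'
rates. Compartment volumes are constant in time, so they multiply both
sides of every amount-balance equation and cancel from the concentration
dynamics; the engine therefore integrates concentrations directly and is
checked by a volume-invariance test (volume 1 vs 10 gives identical
trajectories). Units are nominal labels — mmol/mL for concentrations,
seconds for time — carried in metadata and never converted; the engine is
unit-agnostic by design because curated networks of this kind mix
literature constants of heterogeneous provenance.

Activation is represented as a pair of species: an inactive pool (seeded
from expression data via `applyExpressionInitials()`, or from the
generator's defaults) and an active counterpart that starts at
concentration zero — activity must be produced by the dynamics, not
assumed. `validateNetwork()` enforces this zero-initialization rule along
with the structural rules (degradation goes to the sink, transcription
produces mRNA, translation needs mRNA and produces protein, a
modified-HMM modifier must be declared as a reaction modifier), returning
violations as data rather than exceptions so malformed models can be
inspected.

### Repression and the drug interventions

The modified-HMM law is implemented in activator form only. Repression is
expressed topologically: an inhibitor is the *modifier* of a reaction that
converts its target into an inactive or inhibited species. This is exactly
how the two drugs enter:

* `applyCrizotinib(model, dose)` adds the drug species at the dose as its
  initial concentration, a modified-HMM reaction consuming the
  constitutively active mutant ALK with crizotinib as modifier, and a
  first-order drug decay into the sink (one species, two reactions).
* `applyGefitinib(model, dose)` adds gefitinib, an
  `EGFR_free → EGFR_inhibited` modified-HMM conversion with gefitinib as
  modifier, and first-order drug decay (two species, two reactions).

Drugs enter as initial concentrations with first-order decay; there is no
dosing schedule or pharmacokinetic absorption layer, and no event
handling. The ALK-F1174L mutant itself (`applyAlkMutation()`) is a
constitutively active species with nonzero initial concentration — it is
only ever consumed, never synthesized, matching a model in which the
mutation renders the expressed receptor pool ligand-independent. Its
default initial concentration is the wild-type inactive pool's
concentration. All surgeries are pure functions: the input model is never
mutated, and crizotinib/gefitinib application commutes.

## Simulation engine

`simulateNetwork()` integrates with LSODA (via `deSolve::lsoda`), which
switches automatically between stiff and non-stiff methods. The settings
object mirrors a COPASI-style deterministic time-course block (duration,
interval size, interval count, relative/absolute tolerance, maximum
internal steps, and the mass-conservation reduction flag). Numerical
choices worth knowing:

* The three grid fields are redundant; when they disagree by more than 1%
  the interval count is re-derived from duration/interval size with a
  warning (published settings blocks sometimes carry a typo in one
  field). `presetSettings()` exposes the two conventional frames — short
  (1e-5 s, interval 2.328304971e-11 s, 429,497 intervals) and long
  (2e5 s, interval 4.656609941 s, 42,950 intervals) — with an optional
  thinned output grid, since output sampling is dense interpolation and
  does not affect solver accuracy.
* `maxInternalSteps` defaults to 1e5; tiny values are passed through for
  fidelity but warned about, because an LSODA-class solver rarely
  completes a stiff integration on a budget of 10 internal steps.
* The reduction flag is accepted and ignored: the engine always
  integrates the full state and instead *verifies* conservation (each
  inactive/active pair connected only by interconversion keeps a constant
  total within 10× the absolute tolerance).
* Solver round-off can leave concentrations marginally negative; values
  above −10× the absolute tolerance are clipped to zero on trajectory
  construction, anything worse would surface in the non-negativity tests.
* Default tolerances are 1e-6 relative / 1e-12 absolute. Tests that probe
  quantities near the numerical floor (finite-difference zeros,
  conservation drift) tighten the relative tolerance to 1e-9 so the noise
  floor sits well below the assertion thresholds.

Trajectory summaries: `trajectoryAUC()` is the trapezoidal integral over
the sampled grid (the arm-comparison statistic); `findPlateau()` returns
the earliest sampled time after which every subsequent interval's absolute
slope is at most a threshold fraction (default 1%) of the trajectory's
maximum absolute slope — a constant curve plateaus at $t=0$, a linearly
rising curve never does (reported as `NA`, "not reached"). The threshold
rule is this package's own operationalization of "reaching plateau";
nothing in the modeled chemistry defines one. `steadyState()` runs a
damped Newton search with a long-horizon integration fallback and returns
failure as a first-class outcome: densely connected networks with
constitutive drives often have no reachable steady state, which is
precisely why sensitivity analysis works on a simplified network and an
endpoint readout. Sink species are excluded from the steady-state
criterion; they are accounting nodes that grow monotonically by design.

## Sensitivity analysis

`localSensitivities()` perturbs every kinetic parameter ($k_1$, $k_2$,
$k_{cat}$, $K_m$) of every reaction by a relative central difference
(default $\delta = 1\%$):
$s = \frac{c(p_0(1+\delta)) - c(p_0(1-\delta))}{2\delta p_0}$, evaluated
on the readout's endpoint concentration (AUC is available as an
alternative readout). The scaled variant multiplies by $p_0/c(p_0)$,
giving dimensionless elasticities. Central differences were chosen over
forward ODE sensitivities for solver-independence; a δ-halving
convergence test (every reported sensitivity changes by <5% when δ drops
from 1% to 0.5%) guards the approximation. Parameters with baseline zero
cannot be perturbed relatively and are marked skipped; a failed perturbed
simulation flags the entry rather than reporting a silent zero. Positive
sign means the parameter induces the readout. `simplifyNetwork()` takes
an explicit keep-list (no automatic model-reduction algorithm is
implemented: reduction of a curated network is a scientific choice, not a
mechanical one), retains exactly the reactions whose participants all
survive, always keeps sink species, and refuses to drop the readout.

## Parameter estimation

The estimation stage interprets "fit the constants to data" as bounded
nonlinear least squares over simulated trajectories — the kinetic laws are
nonlinear in $K_m$, so no literal linear regression can produce them.
`fitParameters()` minimizes $\sum_i w_i (\mathrm{sim}_i-\mathrm{obs}_i)^2$
with Levenberg–Marquardt (`minpack.lm::nls.lm`) under box constraints,
simulating at exactly the observation times. A candidate whose simulation
fails receives a large finite loss instead of crashing the optimizer;
non-convergence is a flag on the result, not an exception; the returned
estimate never has a worse loss than the starting guess, and observations
are canonically re-ordered so the fit is order-invariant.
`applyExpressionInitials()` performs the upstream step of seeding inactive
pools from relative expression values through a single global linear scale
factor (default 1 — no normalization formula is imposed), zeroing each
mapped species' active counterpart.

## SBML import and the native format

`readSBML()` accepts SBML Level 2/3. Rate laws are recognized
structurally on the MathML tree after inlining user-defined function
definitions: a product of constants and the reactants maps to mass action
(a difference of two such products to reversible mass action); the
rational form $\frac{a\,S}{b+S}$ maps to HMM, or to modified HMM when the
extra species factor is declared a modifier of the reaction. One leading
compartment-volume factor is stripped (SBML kinetic laws are amount
rates; the engine works in concentrations), species declared in amounts
are divided by their compartment size, and boundary/constant species are
held fixed during integration. Anything unrecognized is retained as an
*opaque* rate expression evaluated symbolically — never silently dropped —
and listed in the `ImportReport`; rate rules become opaque
pseudo-reactions; events and non-rate rules raise explicit
unsupported-feature errors. The native on-disk format is a versioned YAML
schema (`pdl1net-network/1`) that round-trips every law variant including
opaque expression text.

The curated 93-species/85-reaction neuroblastoma network this machinery
targets is deposited in BioModels under accession MODEL1812070002 and is
not redistributed here; the import layer is exercised by constructed
fixtures, and a dedicated check (species/reaction counts, validation)
activates when a local copy of the deposit is provided.

## The synthetic-data generator: what it emulates, what it does not

`generateCascadeNetwork()` builds the layered shape the analysis assumes:
EGF and NGF ligand inputs, ALK and EGFR receptor pairs
(inactive + active), `nLayers` kinase layers, and a terminal HMM
transcription reaction producing the PD-L1 mRNA readout, plus translation
and first-order degradations into one sink. The species count is
closed-form, $10 + 2\,n_{layers}\,s_{perlayer}$. Parameters are drawn
uniformly from documented ranges under a seed; generation is a pure
function of spec + seed and never disturbs the caller's RNG stream.

The default ranges encode the study conditions rather than arbitrary
numbers: receptor activation is slow relative to deactivation (a few
percent of the pool active under ligand) and each kinase layer has gain
near one, so the readout responds approximately linearly to ALK drive.
Ligands decay with a ~4 h half-life, so the wild-type drive is transient
while the mutant's constitutive drive is not — this is what produces the
qualitative phenotype pair the package's tests pin down on the frozen
reference cascade (`referenceCascade()`, spec defaults with seed
20190831): the wild-type readout plateaus within the long time frame
(at 9.1e4 s under the 1% slope rule) while the mutant rises linearly; the
mutant endpoint exceeds wild-type by ~900×; crizotinib at 1.4e-3 mM
collapses the AUC to ~0.2% of control; gefitinib at 3e-3 mM changes it by
less than 1% (the EGFR branch feeds the first kinase layer at a weight of
5e-4 relative to ALK); and the combination tracks crizotinib within 1%.
These parameters were chosen once to realize that ALK-dominated regime
and are frozen.

What the cascade does *not* emulate: the real network's breadth (93
species across MAPK, PI3K/AKT/mTOR, JAK/STAT and MYCN arms vs 16 here),
crosstalk and feedback loops, literature-derived rate constants, or
absolute concentration scales. Passing the qualitative tests therefore
shows the machinery — surgery, integration, summaries — behaves correctly
in the regime the biology implies; it does not reproduce the deposited
model's printed endpoint values, which depend on the full
parameterization available only in the BioModels deposit.

Noise models are stated so recovery tests are well-posed: time-course
observations get multiplicative Gaussian noise on the relative scale
(`generateObservations()`, truth retained alongside), and expression
matrices get additive Gaussian noise on the log2 scale with per-probe
baselines from $N(8, 2^2)$ and planted log2 effects per
(probe, culture, treatment) cell (`generateExpressionMatrix()`).

## Expression validation stage

The validation design crosses culture (2D, 3D) with treatment (DMSO,
crizotinib, alectinib at 1 µM for 24 h) in the NB39nu ALK-amplified line,
emulating the public GSE107354 microarray series. Processing is log2
transform then quantile normalization (delegated to
`limma::normalizeQuantiles` with average-tie handling; rank order within
columns is preserved and the operation is idempotent). Fold *reduction*
is mean(control)/mean(treated) on the linear scale — de-logged first —
so a value of 4.33 means treatment lowered expression 4.33-fold; group
summarization is the arithmetic mean, and multiple probes for one gene
are averaged after normalization. `syntheticValidationMatrix()` plants
the study's effect sizes (4.33-fold under crizotinib in 3D, 3.26-fold in
2D, milder 2-fold alectinib effects) at noise sd 0.05 and n = 3 per cell.
Its default of 1000 probes is deliberate: quantile normalization maps
values through rank-indexed reference quantiles, and with too few probes
that discretization alone perturbs a single probe's planted effect by
more than the sampling noise (the emulated platform carries ~60K probes,
so denser is the more faithful choice). Direct fold-change recovery is
accurate to sampling noise; the post-normalization estimate carries extra
spread, which is why the pipeline-level checks assert the marked,
crizotinib-dominant down-regulation rather than a tight band.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic
inputs generated at run time. Simulations use thinned output grids
(tens to hundreds of points) because dense output sampling adds nothing
to solver accuracy; arm comparisons use the long frame at 200 intervals;
recovery studies use a two-step chain (20 noisy replicates) where the
Monte-Carlo loop is cheap and identifiability is provable. Every source
of randomness flows through an explicit seed, and `runPipeline()` writes
a manifest (settings, seed, output checksums, package version) next to
each stage's TSV outputs so identical config + seed yields byte-identical
primary outputs.

## Known limitations

* No stochastic (Gillespie) simulation, no events or timed dosing, no
  spatial/thermodynamic modeling, and no global (Sobol/Morris)
  sensitivity analysis — the modeled workflow is deterministic and local.
* No Bayesian inference or identifiability analysis beyond an
  underdetermination warning in `fitProblem()`.
* No differential-expression statistics in the validation stage; the
  readout is fold change only.
* SBML export is not implemented (the native YAML format is the output
  side); CellDesigner annotations and COPASI `.cps` files are out of
  scope.
* The short preset frame (1e-5 s) resolves receptor-proximal kinetics
  only when the model's constants put receptor activation on that scale,
  as the deposited parameterization does; the synthetic cascade's
  dynamics live on slower scales and are exercised on the long frame.
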
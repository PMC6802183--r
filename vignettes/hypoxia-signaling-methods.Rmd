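---
title: "Methods: an integrated hypoxia-tumor signaling model and its virtual-cell analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrated hypoxia-tumor signaling model and its virtual-cell analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hypoxsig` couples two classical signaling sub-models through two
hypoxia-sensing mechanisms and analyzes the coupled system over a virtual
population of tumor cells.

**HIF module.** An oxygen-controlled switch: HIF-1&alpha; is synthesized
constitutively, hydroxylated in an O<sub>2</sub>- and PHD-dependent
reaction, and degraded through VHL binding; the stabilized fraction
translocates, binds ARNT and a hypoxia-response element (HRE), and drives
transcription of a generic hypoxia-responsive mRNA (read here as VEGF
mRNA). A HIF-induced PHD negative feedback produces the adaptive,
partially transient mRNA response. Oxygen enters as a clamped species
whose value is the environment's `o2_fraction` (oxygen as a fraction of
normoxia; 100% corresponds to 21% atmospheric O<sub>2</sub>), so absolute
oxygen never appears in any equation.

**Tumor signaling module.** A VEGF/EGF receptor network in the
Zhang/Kholodenko/Sasagawa style: ligand binding, receptor dimerization and
autophosphorylation, adapter recruitment (Shc, Grb2-SOS, Gab,
PLC&gamma;), Ras activation with GAP turnover and ERK&rarr;SOS negative
feedback, the RAF&rarr;MEK&rarr;ERK cascade with an Akt&rarr;RAF
inhibitory crosstalk, and the PI3K&rarr;PIP3&rarr;Akt axis with PDK-bound
intermediates, plus mTOR/S6K downstream. The readouts are pERK and pAkt.

**Coupling.** Three constructions tie the modules together, each chosen so
that the integrated model behaves exactly like the originals at normoxia:

1. *VEGF synthesis* becomes
   $k_{syn} \cdot ([mRNA]/[mRNA_0])^{k_\alpha}$ with $k_\alpha = 2$
   (protein response amplified relative to transcript), where $[mRNA_0]$
   is the HIF module's normoxic steady state, computed by equilibration at
   assembly time, never hard-coded. At normoxia the rate is exactly
   $k_{syn}$.
2. *ATP-dependent phosphorylation.* Every phosphorylation uses the ordered
   bi-substrate law
   $V_{max}[ATP][P] / (K_{M,ATP}K^{AB} + K^{AB}[ATP] + [ATP][P])$, with
   ATP set algebraically from oxygen by
   $[ATP] = [ATP]_{norm} f/(0.033 + f)$ (half-maximal ATP at 3.3% of
   normoxic oxygen; $[ATP]_{norm} = 3000\,\mu M$). $K^{AB}$ is calibrated
   per reaction so that $(K_{M,ATP}/[ATP]_{cal} + 1)K^{AB} = K'$, the
   original ATP-implicit constant. We calibrate at
   $[ATP]_{cal} = [ATP](f{=}1)$, the value the ATP map actually returns at
   normoxia, rather than at the 3000 &mu;M parameter itself; the two
   differ by 3.3%, and only the former makes the normoxic rates match the
   original model to the 1e-9 relative tolerance the construction is
   meant to guarantee. The choice is recorded in the assembly metadata and
   is configurable.
3. *VEGF re-baselining.* The VEGF degradation constant is set to
   $k_{syn}/[VEGF]_0$ so the normoxic free-VEGF steady state equals the
   original model's tabulated baseline. The network deliberately conserves
   VEGF inside receptor complexes (no internalization of VEGF-containing
   species), which makes this analytic rule exact.

Drugs enter in two ways: ATP-competitive kinase inhibition multiplies the
$K_{M,ATP}K^{AB}$ term by $(1 + [D]/K_i)$ (targets: RAF, MEK and Akt
phosphorylation), and VEGF-binding inhibition divides the association term
of the binding reaction by $(1 + [D]/K_i)$. $[D]/K_i$ is the only drug
quantity anywhere in the package. The competitive law has a documented
floor: at saturating $[ATP][P]$ the rate tends to
$V_{max}[P]/(K^{AB}+[P])$, not zero.

## The model tables are a reconstruction

The original supplementary tables of the study this package re-implements
were not available when the package was built. The shipped tables
(`inst/extdata/model/*_synthetic.tsv`) are therefore a *reconstruction* at
the published size — 189 species and 86 reactions — with the network
topology and kinetics rebuilt from the methods text and the cited source
models, and calibrated so the population-level response structure
(category fractions across oxygen levels, tree features) reproduces the
reported behavior qualitatively. Every row carries
`provenance = reconstructed`. Two consequences matter for interpretation:

* Published *numeric* population fractions (e.g. "96% of cases show no
  pERK change at 5% oxygen") are targets of qualitative, not quantitative,
  comparison: orderings and multimodality are reproduced; exact
  percentages depend on the unrecoverable supplementary parameters.
* The printed value $K_{M,ATP} = 100$ nM is kept as the constructor
  default, but the reconstruction sets per-reaction values on the
  micromolar scale (1e5-6e5 nM). With 100 nM the factor
  $(K_{M,ATP}/[ATP]+1)$ never deviates from 1 by more than 0.2% even at
  0.1% oxygen, which cannot produce any reported ATP-depletion phenotype;
  kinase ATP Michaelis constants in the literature the study cites are
  tens to hundreds of micromolar, so the printed nanomolar unit is treated
  as a transcription slip and the per-reaction override (a column of the
  reaction table) carries the working values.

The species table also carries "inventory" species that participate in no
reaction (constant concentrations): enzymes referenced by rate laws (PP2A,
PTEN, MKP3, RasGAP) and pathway components that the published species
inventory lists without dynamics. Sampled inventory species act as genuine
nuisance features in the decision-tree analysis.

## Numerical methods

* **Integration**: `deSolve::lsoda` on the compiled right-hand side
  (an Rcpp evaluator over a flattened reaction plan). A pure-R reference
  evaluator implements the same contract and the two are asserted equal in
  the tests; the stoichiometry-matrix product and per-reaction
  accumulation are also cross-checked.
* **Tolerances**: `rtol = 1e-8`, `atol = 1e-10` (nanomolar scale) for all
  full-model work. Steady state is declared when the scaled derivative
  norm $\max_i |\dot x_i|/(1+|x_i|)$ stays below `ss_tol = 1e-8` at two
  consecutive checkpoints of a doubling-chunk schedule (initial chunk 50
  time units, horizon $10^6$). The scaled-derivative criterion is robust
  to slow species; a trajectory-flatness criterion is not. With looser
  `rtol` the achievable residual floors at an `rtol`-dependent level well
  above `ss_tol`, which is why the solver tolerances are kept below it
  for full-model work.
* **Negative concentrations**: entries below zero but within ten times the
  absolute tolerance are clamped to zero before rate evaluation;
  larger negatives abort with the species named. Inside the integrator the
  compiled evaluator floors negatives at zero and convergence is judged
  afterwards.
* **Solver failures** (step-size collapse on stiff Latin-hypercube
  corners) trigger chunk-splitting retries and, if persistent, flag the
  case non-converged; ensemble batches never abort. Non-converged cases
  are excluded from phenotype fractions and counted in the convergence
  report, whose denominator every summary carries.

## The virtual population

Each "cell" is one draw of initial concentrations: every biomolecule of
the tumor signaling module (complexes included) is sampled by Latin
hypercube over a 100-fold log-spaced range centered on its tabulated
nominal — $[x_0/10,\, 10x_0]$, keeping the nominal as the population
median — then equilibrated to its own normoxic steady state before any
stimulus. HIF- and ATP-module variables are held fixed. The published
study used 20,000 cells; the package default (`ensemble_config()`) keeps
that number, and the scaled-down runs used by the tests (120 cells) and
the analysis scripts (500 cells) pass smaller `n_cases` explicitly. The
equilibration step reconciles any inconsistency between independently
sampled complexes and their components; conserved totals (tAkt, tERK)
thereby vary across cells, which is precisely the variability the
phospho/total features exploit.

What the generator emulates: log-scale cell-to-cell abundance variability
spanning the ranges reported for tumor tissue, uncorrelated across
species. What it does not emulate: correlated expression programs,
transcriptional dynamics, growth/death selection, spatial oxygen
gradients. Passing tests therefore show that the *mechanistic coupling*
produces divergent phenotypes over realistic abundance ranges, not that
real tumors realize those frequencies.

## Phenotyping and trees

Responses are steady-state perturbed/baseline ratios. The no-change band
is the closed interval $[0.9, 1.1]$ ("within &plusmn;10%"); decrease and
increase lie outside it. The closed boundary is a determinism choice; at
float precision it is immaterial. Derived features pAkt/tAkt and
pERK/tERK count complexed forms toward the total (PIP3-bound Akt pools
belong to tAkt), which keeps the ratios in $[0,1]$. VEGF response
magnitude is additionally available as the maximal transient fold change,
mirroring how large-versus-small VEGF responses are classified.

Explanation trees are shallow recursive partitions (depth &le; 3, minimum
leaf fraction 5%, Gini impurity, no surrogate or competitor splits) over
the *pre-stimulus* steady-state concentrations plus the derived ratios.
The phrase "initial biomolecule concentrations" in the source protocol is
interpreted as pre-stimulus (equilibrated) values because the reported
trees split on steady-state quantities; a switch (`use_initials`) exposes
the raw sampled values instead. The two-stage pAkt procedure first
separates change from no-change, then splits the change subset into
increase versus decrease. In this reconstruction the pAkt/tAkt ratio
appears as a split feature of the two-stage procedure (thresholds in the
0.6-0.75 range at desk scale, reported by the acceptance suite on every
run), while the root of the change/no-change stage falls to the total Gab
adapter level — the feature competition at the root is a knife-edge
property of the reconstructed kinetics; the governing role of the ratio
(increases only below it, decreases only above) is robust.

## Drug experiments

Dose grids are log-spaced $[D]/K_i$ values (13 points over
$10^{-1}..10^5$ by default); classification doses follow the published
histograms (RAF 100, MEK 2000, Akt 200, VEGF binding 1000). Ratios are
always normalized to the *same-oxygen* no-drug steady state so hypoxia
and drug effects are not conflated; a zero dose reproduces that state
bit-identically. Sensitivity classes: sensitive at &ge;40% readout
reduction, ineffective at <10%, intermediate between. Half-inhibition
doses are obtained by log-linear interpolation at ratio 0.5 and compared
across oxygen levels as fold shifts.

Two robust directional results follow from the ATP-competitive law:
inhibition of RAF/MEK/Akt phosphorylation bites harder under hypoxia
(the $(1+[D]/K_i)$ term multiplies $K_{M,ATP}K^{AB}$, whose weight grows
as ATP falls), and the half-inhibition dose of a VEGF-binding inhibitor
shifts right as hypoxia raises VEGF. A known limitation: the reported
*attenuation* of VEGF-binding inhibition's fixed-dose pAkt effect under
hypoxia does not emerge from this reconstruction — with same-oxygen
normalization, the hypoxic VEGF&rarr;PI3K push makes the fixed-dose
effect larger, not smaller, at every oxygen level we examined; see the
acceptance suite, where that assertion is left failing rather than
weakened.

## Problem sizes

Desk-scale runs used throughout the package: 120-cell ensembles with
three oxygen conditions in the acceptance tests, 500-cell ensembles in
the analysis scripts, 12-40-case drug subsets, and n = 4000-5000 rows for
planted-threshold tree oracles. These sizes keep binomial uncertainty on
category fractions near &plusmn;4-9% and are stated here as the package's
own reproducibility choices; the full published scale (20,000 cells) is a
single `ensemble_config(n_cases = 20000)` away.

## Known limitations

* The model tables are a synthetic reconstruction (above); quantitative
  fraction-level agreement with the published figures is out of reach in
  principle without the original supplement.
* No SBML export; the tabular schema plus the assembly metadata is the
  interchange format.
* No spatial drug penetration, no pharmacokinetics, no combination
  dosing, no bifurcation analysis; severe-hypoxia "sustained" responses
  are reported at the integration horizon with `t_elapsed` recorded, so
  slow transients remain auditable.
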
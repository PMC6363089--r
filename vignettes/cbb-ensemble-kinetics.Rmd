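---
title: "Ensemble kinetic modeling of the Calvin-Benson-Bassham cycle"
author: "cbbkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble kinetic modeling of the Calvin-Benson-Bassham cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbbkin)
```

## The problem

Kinetic models of metabolism need one rate constant per binding site, and
for cyanobacteria most of those constants have never been measured. Rather
than fitting a single parameter set to noisy data, `cbbkin` takes the
ensemble route: it keeps the *structure* of a 29-reaction model of the
Calvin-Benson-Bassham (CBB) cycle in *Synechocystis* sp. PCC 6803 fixed,
samples everything uncertain — steady-state metabolite concentrations and
all binding/regulation constants — from wide, thermodynamically constrained
ranges, and asks which dynamical properties are robust across the whole
admissible ensemble: how often the steady state is locally stable, which
metabolite levels and enzyme saturations favor stability, and how flux
control is distributed over the enzymes.

The workflow is: sample feasible metabolomes -> sample kinetic constants
around each -> calibrate Vmax so every parameter set reproduces one input
steady-state flux exactly -> classify local stability via the reduced
Jacobian -> compute control coefficients for the stable sets -> aggregate.

## The model structure

The network covers the 13 catalytic CBB steps (Rubisco through
phosphoribulokinase), lower glycolysis from 3PG to acetyl-CoA, the
phosphoketolase shunt (xfpk1/xfpk2/pta), lumped photosystem supplies of ATP
and NADPH, a mass-action phosphate supply from an abstract phosphate pool
(PPool), and six irreversible Michaelis-Menten biomass sinks — 29 reactions
over 36 metabolites with 149 kinetic parameters (98 binding/regulation
constants, 29 Vmax or rate constants, 22 equilibrium constants).

```{r}
model <- cbb_model()
model
```

Three structural choices deserve explanation, because the package's
definition (`cbb_definition()`, shipped as
`inst/extdata/cbb_synechocystis.model`) is a literature-based
reconstruction rather than an export of a curated laboratory model:

* **Sink placement.** Lumped biomass sinks drain 3PG, GAP, F6P, R5P, PYR
  and ACCOA. A sink on acetyl-CoA is required: it is the terminus of the
  downstream pathway, and without a drain no strictly positive steady-state
  flux exists. PEP needs no sink of its own since pyruvate kinase drains it.
  The ACCOA sink releases CoA, which closes the CoA/acetyl-CoA moiety.
* **NAD/NADH.** Pyruvate dehydrogenase is the only NAD(H)-coupled reaction
  in the network, so NAD and NADH cannot be mass-balanced with 29 reactions.
  They are treated as sampled boundary species: their concentrations are
  drawn per metabolome (and constrained by the NADH/NAD ratio bound) but
  they are not rows of the stoichiometric matrix.
* **Regulators.** No single curated regulator table exists for this
  network, so the package ships a documented literature-default set: the classical chloroplast-model
  inhibitions (Rubisco inhibited by 3PG, FBP, SBP, Pi and NADPH at the RuBP
  site, and by O2 competing with CO2; FBPase by F6P and Pi; SBPase by Pi;
  phosphoribulokinase by 3PG, Pi and a second ADP site), reported bacterial
  regulations (pyruvate kinase inhibited by Pi and ATP, activated by FBP and
  R5P; phosphoketolase inhibited by PEP; pyruvate dehydrogenase and
  phosphotransacetylase inhibited by ATP), and NADPH-activation of FBPase,
  SBPase and prk as a proxy for their light/thioredoxin activation.

Enzyme promiscuity (one protein catalyzing FBPase/SBPase, fba/ald,
tkt1/tkt2, xfpk1/xfpk2) is modeled as cross-competitive inhibition by the
partner reaction's distinct reactants, with the binding constant *shared*
with the partner's Michaelis constant — shared constants are stored, counted
and sampled exactly once.

## Rate laws

All reactions except the two bisphosphatases, the sinks and the phosphate
supply follow reversible Michaelis-Menten kinetics in convenience form; for
a 1:1 conversion

$$v \;=\; V_{max}\,\frac{(A/K_A)\,\bigl(1 - \tfrac{Q}{K_{eq}}\bigr)}
  {1 + A/K_A + B/K_B},$$

with the mass-action ratio $Q$ evaluated in molar units and $K_{eq} =
\exp(-\Delta G'^{\circ}/RT)$. Multi-substrate reactions multiply the
substrate saturation terms in the numerator and use the convenience-kinetics
denominator (product of per-reactant geometric sums over both pools);
competitive inhibitors add $I/K_I$ terms to the denominator; allosteric
modifiers multiply the rate by $a/(K_a+a)$ or $K_i/(K_i+i)$ (Hill
coefficient 1). FBPase, SBPase and the sinks are irreversible (no product
pool, no thermodynamic factor), and the phosphate supply is symmetric mass
action, $v = k\,(\mathrm{PPool} - \mathrm{P_i})$.

By construction the sign of every reversible rate equals the sign of
$1 - Q/K_{eq}$, which ties the kinetics to the thermodynamic filter below:
on a feasible metabolome every calibrated rate is positive in the reaction's
defined direction, and $V_{max} = v^0/f > 0$ always exists.

### Thermodynamic defaults

Standard transformed Gibbs energies (kJ/mol at 298.15 K, pH ~7.5) are
shipped as overridable defaults informed by standard compilations
(e.g. component-contribution estimates): strongly exergonic steps such as
Rubisco (-35), prk (-21.6), pyk (-27), pdh (-33.4) and the phosphoketolases
(-52); near-equilibrium interconversions (tpi -5.5, rpe +0.9, rpi +2.0,
tkt1 +4.0, tkt2 +1.5, pgm +4.2); and the endergonic pgk step (+18.5) that
is driven by high 3PG, low BPG and a high ATP/ADP ratio. The two photosystem
supplies carry an *effective* -35 kJ/mol because the photon driving force is
lumped into them. These constants shape the feasible-metabolome geometry
(e.g. they force 3PG high and BPG low), and the acceptance rate of the
sampler depends on them; they are defaults, not measured values.

## Sampling feasible metabolomes

```{r}
model <- set_fluxes(model, generate_flux_vector(model))
ranges <- default_ranges(model)
head(as.data.frame(ranges), 4)
```

Each candidate metabolome draws every sampled metabolite log-uniformly
within its range (roughly two orders of magnitude around literature
values), plus a PPool/Pi multiplier log-uniform in [1.1, 5]. A candidate is
kept — becoming a feasible metabolite concentration set (fMCS) — iff

1. every reaction with thermodynamic data has $\Delta G = \Delta G'^\circ +
   RT\ln Q < 0$ in its defined flux direction (sinks and the phosphate
   supply are exempt: they carry no product thermodynamics),
2. the summed sampled concentration stays below 100 mM, reserving the rest
   of the cellular osmotic budget for metabolites outside the model,
3. the cofactor ratios ATP/ADP and NADPH/NADP lie in [1, 10] and NADH/NAD
   in [0.1, 1] (documented growth-compatible defaults),
4. the PPool multiplier is in range (true by construction).

Rejection sampling is vectorized in fixed blocks of $10^5$ rounds with one
RNG stream per `(seed, block)` pair, so results are bit-identical no matter
how rounds are chunked or parallelized.

```{r}
fmcs <- generate_fmcs(model, ranges, max_rounds = 2e5, seed = 1)
fmcs
```

With the shipped defaults the acceptance rate is of order $10^{-3}$ to
$10^{-4}$; the dominant rejections come from the near-equilibrium
transketolase/aldolase steps and the cofactor-ratio constraint.

## Parameter sampling and Vmax calibration

Every binding, inhibition and activation constant is drawn log-uniformly
from $[0.01, 100] \times$ the concentration of its metabolite in the fMCS,
i.e. enzyme saturations span 1-99%:

```{r}
100 * saturation_fraction(1, 0.01)   # K at 0.01 x [S]
100 * saturation_fraction(1, 100)    # K at 100 x [S]
```

The input steady-state flux $v^0$ is a strictly positive vector in the
nullspace of the stoichiometric matrix. The package generates it on the
model's own 29-reaction stoichiometry (the closest point of the flux
polytope $\{S v = 0,\ 10^{-3} \le v \le 2\}$ to a stoichiometrically shaped
target, found by Dykstra's alternating projections — a deterministic convex
program replacing the genome-scale flux balance analysis of the source
study; all downstream mathematics depends only on $S v^0 = 0$ and the
directions). A published flux table can be supplied instead and is
validated against the same conditions.

$V_{max}$ is then *calibrated*, not sampled: $V_{max} = v^0/f(X^0, K,
K_{eq})$ per reaction, so every parameter set reproduces the input flux
exactly at its generating metabolome (residual at machine precision), and
$S\,v(X^0) = S\,v^0 = 0$.

## Stability

Conserved moieties (ATP+ADP, NADPH+NADP, CoA+ACCOA) make the full Jacobian
structurally singular, so stability is read off the reduced Jacobian

$$J' = S'\,\frac{\partial v}{\partial X}\Big|_{X^0}\,L, \qquad S = L\,S',$$

where the rows of $S'$ are a maximal independent subset of the rows of $S$
(selected by exact fraction-free integer elimination, so the factorization
is deterministic) and the elasticities $\partial v/\partial X$ are computed
from closed-form derivatives of the rate laws (finite differences are kept
as a test oracle only). A state is stable iff every eigenvalue of $J'$ has
real part below $-\varepsilon$ with $\varepsilon = 10^{-9}(1 + \rho(J'))$;
eigenvalues inside the tolerance band are conservatively classified
unstable and tallied as "marginal" (a deliberate, conservative package
choice).

An independent ODE oracle cross-checks the classification: the state is
perturbed by $10^{-4}$ (relative) inside the stoichiometric subspace — so
conserved totals are untouched — and $dX/dt = S v(X)$ is integrated with a
stiff solver (rtol $10^{-8}$, atol $10^{-10}$), checkpoint by checkpoint on
a log-spaced grid, until the displacement falls below 10% of its initial
size (returned) or grows 20-fold (diverged). The default horizon is $10^6$
characteristic times, long enough for eigenvalues of magnitude down to
$\sim 10^{-5}$ (in flux units) to express themselves; genuinely marginal
sets near the tolerance boundary are the residual source of disagreement,
which the test suite bounds at 5%.

## Control analysis

For every stable set, scaled concentration and flux control coefficients

$$C_X = -D_{X^0}^{-1} L J'^{-1} S' D_{v^0}, \qquad
  C_J = I + D_{v^0}^{-1}\,\frac{\partial v}{\partial X}\Big|_{X^0} D_{X^0} C_X$$

are computed by direct linear solves. Because $S' v^0 = 0$, the summation
theorems ($\sum_e C_X = 0$ per metabolite, $\sum_e C_J = 1$ per target
flux) hold to numerical precision and are asserted ensemble-wide at
$10^{-6}$. Sets whose reduced Jacobian has condition number above $10^{12}$
are excluded from control analysis and tallied rather than silently kept.
An independent re-equilibration oracle (scale one Vmax by $1 \pm 10^{-3}$,
re-solve the steady state by damped Newton on the conserved-moiety
subspace, central log-log difference) agrees with the matrix expressions to
better than 1%.

## Ensemble statistics and clustering

`sample_ensemble()` runs the per-set loop with per-`(seed, set)` RNG
streams; postprocessing provides

* per-fMCS stable fractions and their distribution,
* log10-concentration densities of the most- vs least-stable fMCS deciles
  (Gaussian kernel, Silverman bandwidth; ties broken deterministically by
  fMCS index; both deciles hold exactly `floor(n/10)` metabolomes),
* saturation ($\log_{10}[S]/K$) densities split by stability,
* element-wise median and raw median absolute deviation of the flux control
  coefficients over all stable sets,
* control-pattern clustering: FCCs below $10^{-6}$ in magnitude are set to
  zero, asinh-transformed, a random tenth of the pattern dimensions is
  subsampled, columns are scaled (constant columns dropped and logged),
  the patterns are rotated onto their principal components, and the
  reactions are clustered with correlation distance and average linkage,
  separately for control *exerted* (effector patterns) and control
  *experienced* (target patterns). Cluster confidence is an ordinary
  bootstrap: the pre-PCA pattern dimensions are resampled with replacement
  and the whole scale-PCA-cluster pipeline is re-run per replicate
  (multiscale bootstrap AU p-values are deliberately out of scope). All
  finite principal components are retained — the rotation is used as a
  decorrelating compression, not for dimension selection.

## Reduced-scale study conditions

At full scale this kind of analysis runs $\sim 5\times10^7$ sampling
rounds (yielding a few thousand fMCSs) and 1000 parameter sets per fMCS;
the package defaults keep those semantics (`sets_per_fmcs = 1000`), while
the shipped tests and the acceptance script run a reduced ensemble — 100 fMCSs $\times$ 200 parameter sets, a few
hundred thousand sampling rounds — sized so the whole suite completes on a
single CPU in minutes. Stable-fraction medians and FCC medians are
ensemble statistics and are already well resolved at this scale; the
absolute fMCS *yield* of a full-scale run additionally depends on the
exact thermodynamic constants and ranges used, so with the shipped
defaults it is comparable in order of magnitude, not in count.

What the synthetic generators do and do not emulate: the flux vector has
the correct directions, steady-state property and rough flux hierarchy but
not the genome-scale magnitudes; the concentration ranges bracket
literature values but are not the published network-embedded-thermodynamics
ranges; the regulator set is a documented literature default. Passing tests
therefore demonstrate that the *method* — filtering, calibration, stability
classification, control analysis — behaves correctly and that the
qualitative biology (broad intrinsic stability, RuBP-instability
association, distributed flux control concentrated in energy supply and the
bisphosphatases, inert phosphoketolase shunt) emerges from the
reconstruction; they do not certify exact percentages, which are tied to
the particular thermodynamic constants, ranges and regulators used.

## Numerical choices

* Rank decisions and conservation relations: exact integer elimination;
  the link matrix is solved in doubles and verified to $10^{-12}$.
* Stability tolerance $\varepsilon = 10^{-9}(1+\rho(J'))$, marginal counted
  separately; condition cutoff $10^{12}$ for control analysis.
* Newton re-equilibration: damped steps keeping concentrations positive,
  convergence at $\|S'v\|_\infty < 10^{-12}\max v^0$.
* All tabular outputs are written with fixed formatting; reruns of the same
  configuration are byte-identical, and every stochastic stage derives its
  stream from `(master seed, stage, block)` so stages can be re-run or
  parallelized without changing results.

## Limitations

No isoenzyme-specific kinetics, no bifurcation or global stability
analysis, no response coefficients to external effectors, no
compartmentalization, and no genome-scale reconstruction. The shipped
thermodynamic constants and regulator table are defensible defaults, not
measurements; both are overridable in the model file, and a published flux
or range table can be dropped in without code changes.
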
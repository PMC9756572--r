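---
title: "Methods: mechanistic dermal PBPK and virtual bioequivalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanistic dermal PBPK and virtual bioequivalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermvbe)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, the choices made where the
physics is under-determined, and what a green test does and does not
establish.

## 1. The problem

A topical product's bioavailability is governed jointly by the drug, the
skin, and the formulation — and the formulation changes after application:
volatile solvents evaporate within minutes, leaving a "tertiary"
formulation whose composition, volume and drug concentration differ from
what left the container. The package asks the regulatory question in
mechanistic form: *over what range of formulation attributes (drug
solubility in the continuous phase, viscosity, volatile fraction,
evaporation rate) does a test product remain bioequivalent to the
reference?* The answer — the safe space — is computed by virtual
bioequivalence (VBE) trials on simulated populations, under different
skin physiologies and dose intensities.

## 2. Formulation model

A formulation is a single-continuous-phase solution: components with mass
fractions $w_i$ and densities $\rho_i$. All derived quantities are ratios
and therefore insensitive to the overall normalisation of a printed
composition table:

* volume fractions $v_i = (w_i/\rho_i) / \sum_j (w_j/\rho_j)$,
* mixture density $\rho = \sum_i w_i / \sum_i (w_i/\rho_i)$,
* tertiary composition: volatile components removed, remainder
  renormalised (volatiles are retained with fraction zero so reports keep
  the full ledger),
* continuous-phase fractions: the tertiary volume fractions of the named
  phase members renormalised to 100%.

**Metamorphosis.** Evaporation is zero-order in volume at rate $E$ (ml/h,
default 5), capped when the evaporated volume reaches the volatile volume
fraction of the initial dose (25.17% v/v for the reference spray, derived
from its composition). The drug is non-volatile: its amount is conserved
and its concentration rises by the factor $1/(1-f_{volatile})$. Whether
$E$ is per applied dose or per cm² is not determined by a single printed
rate; both readings are supported (`evaporation_basis`), per-dose being
the default. At the default rate the film finishes its metamorphosis
within minutes — consistent with treating the tertiary state as the one
that controls most of the absorption window — but the rate is a swept
parameter, and at very low rates the film remains primary for the whole
study, which is exactly the low edge of the evaporation-rate safe space.

**Supersaturation.** After volatile loss the drug concentration in the
reference film (≈2.8 mg/ml) exceeds the continuous-phase solubility
parameter (0.55 mg/ml). The drug is assumed to stay dissolved — the state
is flagged `supersaturated`, but there is no precipitation model. This
mirrors the source data situation (the product is described as a solution
in both primary and tertiary states) and means the solubility parameter
acts on partitioning, not as a concentration cap.

**Vehicle diffusivity.** Stokes–Einstein,
$D = k_B T / (6\pi\eta r)$ with the solute radius from the drug's molar
volume ($M/\rho$, 289.6 cm³/mol → $r$ = 4.86 Å). This one assumption
makes vehicle-film diffusion inversely proportional to viscosity, so the
film becomes rate-limiting only at viscosities orders of magnitude above
the reference 100 cP — the mechanism behind the very wide viscosity safe
space.

## 3. Skin permeation model

The skin under the film is a one-dimensional chain of well-mixed
compartments: vehicle, $N$ stratum-corneum (SC) layers, viable epidermis,
dermis, and a terminal boundary (receptor sink in vitro; dermal perfusion
uptake in vivo). Transport is written on a water-anchored
thermodynamic-activity scale: a compartment with amount $A$, volume $V$
and partition coefficient $K$ (tissue:water) has activity $a = A/(VK)$,
and the flux across an interface is $J = G\,(a_i - a_j)$ with the
conductance $G$ from the two half-layer resistances in series,
$1/G = h_i/(2 A K_i D_i) + h_j/(2 A K_j D_j)$. At partition equilibrium
all activities are equal and every diffusive flux vanishes.

Per SC layer, two parallel pathways:

* **lipid**: conductance $A\,K_{sclip:w} D_{sclip}/h$, where
  $K_{sclip:w} = K_{sclip:v}\cdot K_{v:w}$ and
  $K_{v:w} = S_{vehicle}/S_{water}$;
* **transcellular**: a water-referenced permeability $P_{cell}$ (cm/h).

$K_{sclip:v}$ and $P_{cell}$ are the two calibrated parameters.

**SC storage vs conduction.** Conduction uses the lipid partition, but
storage attributes only a lipid volume fraction `f_sc_lipid` (default
0.1) to that phase; the corneocyte remainder stores drug at a fixed
`K_corneocyte_water` (default 3). Without this split the SC would behave
as an unbounded reservoir at high partition coefficients: drug would load
into the SC faster than it leaves, and the cumulative receptor amount at
finite time would *decrease* with increasing $K_{sclip:v}$. With the
split, receptor uptake is monotone in $K_{sclip:v}$ across the swept
range (asserted in the tests on 0.5–8, and via solubility on 0.1–1
mg/ml); a residual reservoir transient remains below ~0.1 mg/ml
solubility, which is outside the BE sweep range.

**How solubility enters (a deliberate modelling choice).** Two readings
are possible. Full thermodynamic covariation — vehicle activity
$\propto 1/S$ together with $K_{sclip:v} = K_{ref} S_{ref}/S$ — leaves
the SC:water partition invariant, making the flux response to a
solubility change *exactly* independent of skin physiology. That
contradicts the observed interaction in which a reduced SC barrier
flattens the solubility sensitivity because the SC stops being
rate-limiting. The package therefore follows the second reading: a
solubility change in a sweep acts through the partition coefficient
(`partition_from_solubility()`, $K \propto 1/S$) on the SC entry
resistance, while the vehicle activity scale stays anchored at the
calibrated reference solubility (`solubility_anchor`). The sensitivity to
solubility then carries the SC's share of the total resistance — large
when the SC dominates, plateauing when it does not — which is what makes
the safe space widen in the reduced-barrier scenarios. The cost is a
known thermodynamic inconsistency for large excursions from the
reference; it is the same one implicit in treating solubility as a pure
partition lever.

**Vehicle-side resistance.** The film is a diffusion layer of thickness
$h_v = V(t)/A$ (the spec-level choice of the full current film thickness)
with Stokes–Einstein diffusivity, so the boundary resistance grows
linearly in viscosity and shrinks as the film evaporates.

**In-vivo termination.** Dermis→blood flux is one-way,
$J = Q_{blood} A \, (f_{u,dermis}/f_{u,blood})\, C_{dermis}$ with
$f_{u,blood} = f_{u,plasma}/(B\!:\!P)$; venous return to the dermis is
neglected because plasma concentrations are ~10³-fold below dermis
concentrations. Blood flow is
$Q = Q_{base}\cdot s_r^2 \cdot s_p$: flow proportional to capillary
cross-sectional area, so a two-fold radius reduction gives the four-fold
flow reduction of steroid vasoconstriction, and halving the perfused
fraction too gives eight-fold. (Poiseuille $r^4$ scaling would give
16-fold and is *not* used — the four-fold factor is the stated anatomy.)

**Systemic disposition.** A two-compartment model (defaults: central 40
L, peripheral 60 L, inter-compartment clearance 20 L/h) with the drug's
intravenous clearance 16.95 L/h stands in for whole-body PBPK
distribution. Absolute plasma concentrations are therefore not endpoints;
BE ratios are, and those are insensitive to the shared distribution model
— a property the test suite checks by doubling the volumes and comparing
GMRs, not an assumption.

## 4. Numerics

The model is linear, so no ODE solver is used. Within any interval where
the coefficients are constant, the state advances by the exact propagator
$e^{M\Delta t}$: a hand-rolled Padé(13) scaling-and-squaring matrix
exponential (validated against `Matrix::expm` in the suite), or — for
segments containing many output times — one spectral decomposition of
$M$ emitting every output state at once, with a reconstruction check and
an automatic fallback to stepwise exponentials if the eigenbasis is
ill-conditioned. During active evaporation the vehicle-dependent
coefficients are refreshed on substeps limited to ~5% volume change.
Because $M$ is Metzler with zero column sums (sinks are explicit
compartments), the propagator is non-negative and conserves mass to
machine precision; the suite asserts a mass-balance error below $10^{-6}$
of dose across the full scenario × dose matrix, and observed errors are
~$10^{-13}$. Sub-roundoff negative amounts are clipped to zero; anything
beyond $10^{-9}$ of dose aborts.

## 5. IVPT, tape stripping, calibration

The in vitro design is 5 µL on 0.5 cm² (≈3.5 sprays/cm² equivalent,
10.4 µg drug), receptor as a perfect sink, 24 h. The sampling schedule
(0, 2, 4, 6, 8, 12, 24 h) is not part of the published design and is a
configuration default. At end of study the first three SC layers are
removed as discarded tape strips; the remaining SC content plus viable
epidermis is reported as "epidermis", matching how such data are
assayed.

Calibration replaces manual optimisation with a reproducible procedure:

1. a joint log-grid scan over $(K_{sclip:v}, P_{cell})$ (13 × 11) on a
   combined objective (receptor sum of squares, normalised, plus relative
   squared errors of the two local amounts) selects the basin;
2. the two prescribed stages — $K$ on the receptor profile, $P_{cell}$ on
   the local amounts — are iterated with a ±0.5-decade trust region and
   accepted only when the combined objective improves;
3. a Nelder–Mead polish refines both parameters jointly.

Step 2's guard exists because the two parameters compensate along a ridge
in the receptor objective alone: with noisy replicates a pure sequential
fit can walk to a distant $(K, P)$ pair that fits the receptor marginally
better while missing the local amounts badly. The objective supports
per-replicate weights (weight 0 drops a divergent replicate) and a
per-time-point mask (for sampling artefacts). Fits pinned at a search
bound warn and record the fact in the result.

## 6. Populations, NCA, BE statistics

Inter-individual variability is lognormal with median-1 multipliers:
CV 30% on the two SC pathway parameters, 20% on dermal blood flow, 25% on
systemic clearance. These defaults are declared, not fitted — the true
population variability behind the published power figures is proprietary
— so all power statements in the tests are properties (monotone in n,
dermis CIs narrower than plasma) rather than reproductions of printed
percentages.

NCA: Cmax; AUC by linear-up/log-down trapezoid; $\lambda_z$ by log-linear
regression on the last four positive samples (configurable);
AUC$_\infty$ = AUC$_{last}$ + $C_{last}/\lambda_z$, flagged missing when
no negative terminal slope exists.

BE: parallel design; metrics log-transformed; Welch (unpooled-variance)
two-sample 90% CI exponentiated to the GMR scale; pass iff the CI lies in
80–125%; a trial "shows BE" in a matrix when Cmax, AUC$_{last}$ and
AUC$_\infty$ all pass. Two arm-sampling modes:

* `paired = TRUE` (safe-space sweeps, scenario matrix): both arms use the
  *same* subjects, so all differences are formulation-driven and a
  reference-vs-reference comparison returns a GMR of exactly 100%. The CI
  is still computed with the parallel-design formula (it does not exploit
  the pairing), which is conservative.
* `paired = FALSE` (power analysis): independent arms — the configuration
  in which small trials genuinely fail on variability.

The default in-vivo trial: 1 spray/cm² on 50 cm², two 12-h applications
(the film is wiped off at the end of each wear; drug already in the SC
continues to absorb), 72-h study, 40 subjects per arm.

## 7. Synthetic observed data

`generate_ivpt_observations()` replaces the original patent-derived IVPT
observations, which are not redistributable. It simulates the true model
and then applies multiplicative lognormal noise *to the per-interval
receptor increments* (CV default 25%), never to the cumulative levels, so
every replicate keeps a monotone cumulative curve; local amounts get
independent lognormal noise (CV default 40%); optionally one replicate is
biased by a constant factor to emulate a divergent study that the
calibration should be able to exclude. What it does **not** emulate:
donor-to-donor skin differences with correlated structure, assay
censoring/limits of quantification, or the specific digitised values of
the source figures. A green calibration test therefore establishes that
the fitting machinery recovers known truth under the declared noise
model — not that the shipped default parameters equal the original
study's fit.

## 8. Default parameter choices

| Parameter | Default | Why |
|---|---|---|
| SC layers × thickness | 20 × 0.75 µm | ~15 µm abdominal SC; disease scenarios halve the count to 10 |
| $K_{sclip:v}$ | 2 | calibrated reference; order-unity affinity of a lipophilic steroid between SC lipids and an oil vehicle |
| $D_{sclip}$ | 3.85·10⁻⁷ cm²/h | together with $K$ gives a water-referenced SC permeability ~7·10⁻³ cm/h and a lag of ~1–2 h, consistent with the fast film depletion the source reports (≲0.4% of dose left after 12 h at the lowest dose) |
| $P_{cell}$ | 0.02 cm/h | calibrated; transcellular path ~15% of layer conductance |
| f_sc_lipid / $K_{cor:w}$ | 0.1 / 3 | storage split (Section 3) |
| VE thickness, $K$, $D$ | 100 µm, 0.6, 8.3·10⁻⁴ cm²/h | aqueous viable tissue, minor resistance |
| Dermis thickness, $K$, $D$ | 500 µm, 0.17, 3.7·10⁻³ cm²/h | upper dermis to the perfused plexus; $K$ is the measured dermis:water value |
| fu dermis / fu plasma / B:P | 0.054 / 0.145 / 0.76 | measured inputs |
| Baseline dermal blood flow | 4 ml/h/cm² | resting skin perfusion; high enough that uptake is not rate-limiting in the default scenario, so vasoconstriction shifts exposure without flipping BE ratios |
| Solubility in continuous phase | 0.55 mg/ml | calibrated reference, centre of the narrow printed safe band |
| Viscosity | 100 cP | stated assumption for the reference spray |
| Evaporation | 5 ml/h, cap 25.17% v/v | stated rate; cap derived from composition |
| Systemic | 40/60 L, Q 20 L/h, CL 16.95 L/h | plausible steroid half-life ~4 h; CL is a stated input |
| Variability CVs | 30/30/20/25% | declared defaults (Section 6) |

## 9. Known limitations

* Lumped (single-compartment) dermis, no depth-resolved gradient, no
  appendageal pathway, no skin metabolism.
* One-way dermal uptake; no venous resupply to the skin.
* No excipient penetration-enhancement effects: changing the volatile
  fraction or replacing an oil affects only volume, concentration and the
  explicitly swept parameters.
* The solubility lever is a partition lever (Section 3): large
  excursions from the reference stretch the thermodynamic consistency of
  the vehicle activity scale.
* Parallel-design statistics only; no crossover or inter-occasion
  variability (none is available to parameterise it).
* The absolute plasma scale depends on an assumed distribution model and
  is not an endpoint; only ratios and orderings are.
* No pharmacodynamic feedback of vasoconstriction on its own cause; the
  perfusion change is a static scenario property.
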
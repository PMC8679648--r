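---
title: "A united-atom force field for organosilicon liquids: model, parametrization machinery and polarization corrections"
author: "orgsil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{organosilicon-forcefield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgsil)
```

## Scope and model

`orgsil` builds fully parametrized united-atom (UA) topologies for
tetrahedrally substituted organosilicon molecules carrying alkyl
(Si&ndash;CH~x~), alkoxy (Si&ndash;O&ndash;CH~x~), silanol (Si&ndash;O&ndash;H)
and bridging siloxane (Si&ndash;O&ndash;Si) substituents.  Molecules with
Si&ndash;H bonds, aryl or halogen substituents, and deprotonated species are
outside scope and are rejected with explicit errors.

In the UA picture every aliphatic CH~x~ group is a single interaction site;
only the hydroxyl hydrogen remains explicit.  The potential is the usual sum

* rigid bond constraints (the stretching constant is effectively infinite,
  so only the constraint length $r_0$ is assigned),
* harmonic angles $\tfrac12 k_\theta (\theta - \theta_0)^2$,
* Ryckaert&ndash;Bellemans (RB) torsions
  $E(\phi) = \sum_{n=0}^{5} C_n \cos^n \psi$,
* 12-6 Lennard-Jones sites combined by Lorentz&ndash;Berthelot rules, and
* fixed point charges under the Coulomb potential with
  $f = 138.935458$ kJ mol^-1^ nm e^-2^.

All pairs separated by three bonds or fewer are excluded from the nonbonded
sums.  There is *no* 1-4 pair term: eliminating 1-4 interactions decouples
torsion parameters from the nonbonded model and improves transferability.
1-5 and farther intramolecular pairs interact normally; this matters in
alkoxysilane scans, where the terminal methoxy carbons are charged and their
1-5 Lennard-Jones and Coulomb terms are nonzero.

### Dihedral convention

The RB series is evaluated with the cosine argument $\psi = \phi - 180°$,
the convention of the exported GROMACS dialect, so that fitted coefficients
round-trip through the topology files unchanged.  The trans conformation
sits at $\phi = 180°$ ($\cos\psi = 1$).  As a self-check, the alkylsilane
backbone class C&ndash;C&ndash;Si&ndash;C evaluates to
$C_0 + C_1 + C_3 = 0.001 \approx 0$ kJ/mol at trans, which is how the
convention was confirmed: under the opposite convention that near-zero
would appear at $\phi = 0$.

## Charges: fixed substituent rules, bespoke silicon

Point charges are assigned by substituent environment, not fitted per
molecule.  The rules (in e): alkyl CH~x~ on an all-alkyl silicon &minus;0.24;
CH~3~/CH~2~ on a silicon that carries at least one oxygenated substituent
&minus;0.32/&minus;0.27; CH~x~ on an alkoxy oxygen +0.25; alkoxy oxygen
&minus;0.68; silanol oxygen &minus;0.88; hydroxyl hydrogen +0.44; bridging
oxygen &minus;0.88; chain CH~x~ not adjacent to Si or O are neutral.  The
rules derive from continuum-solvent DDEC charges averaged over similar
functional groups and rounded to two decimals.

Silicon is *bespoke*: each molecule's Si charge closes overall neutrality
after all substituent charges are placed, and is kept at full precision.
For multi-silicon molecules each silicon closes the charge of its own
substituent branch; an atom equidistant from several silicons (the bridging
oxygen) is split equally between them.  This reproduces, e.g.,

```{r}
q <- charges(buildTopology(siliconMolecule("Met6Si2O")))
unique(round(q[sites(buildTopology(siliconMolecule("Met6Si2O")))$type == "Si"], 3))
```

for hexamethyldisiloxane ($2q_{Si} + 6(-0.32) + (-0.88) = 0$), and
$q_{Si} = +0.96$ for tetramethylsilane.  The test suite checks the full set
of eleven reference molecules against the original DDEC charges; the
root-mean-square deviation over all populated table entries is below
0.05 e.  The largest single deviation is the silicon of tetraethoxysilane
(1.878 vs the rule-based 1.72); we do not attempt to force-match the
rounding of that figure.

## Lennard-Jones parameters and the silicon sigma series

CH~x~ sites use constants carried over from the UA alkane parametrization.
Those values are not part of this package's own contribution and ship as an
*editable* block of the parameter YAML, defaulting to the TraPPE-UA set
(&sigma; = 0.375/0.395/0.468/0.640 nm, &epsilon; = k~B~&middot;{98, 46, 10,
0.5 K} for CH~3~/CH~2~/CH/C).  If your alkane lineage differs, edit the
`alkane_lj` block and reload with `readParameters()`.

Silicon's collision diameter shrinks with its electron-withdrawing
environment: &sigma; is reduced by 5 % per oxygen-containing substituent,
$\sigma(\mathrm{Si}^k) = \sigma(\mathrm{Si}^0)(1 - 0.05k)$, from the base
alkylsilane value $\sigma(\mathrm{Si}^0) = 0.580$ nm (&epsilon; fixed at
0.108 kJ/mol).  A silicon with four alkoxy groups is scaled by 20 %, one
with a single alkoxy group by 5 %.  The table stores the scaled values
verbatim (0.580, 0.551, 0.522, 0.493, 0.464 nm); the scaling law is used
for validation and for extrapolation beyond the table, never to overwrite
the stored entries, to avoid rounding drift.  Oxygen types: O~C~ = O~B~
(0.235 nm, 1.344 kJ/mol; the bridging oxygen directly transfers the alkoxy
parameters) and O~H~ (0.304 nm, 1.750 kJ/mol).

The hydroxyl hydrogen carries charge only (&sigma; = &epsilon; = 0).  The
source parametrization lineage for alcohols does not give the hydroxyl
hydrogen a dispersion site, and no value is published for silanols; this is
recorded as an open choice.

Angle terms containing O~B~ at silicon are not tabulated in the source set;
the shipped YAML transfers the alkoxy analogues (e.g. C&ndash;Si&ndash;O~C~
&rarr; C&ndash;Si&ndash;O~B~), marked as transferred in a comment.  This
mirrors the O~C~ &rarr; O~B~ transfer of the Lennard-Jones parameters.

## Torsion parametrization from quantum-chemical scans

The torsion machinery reproduces the fitting stage: a dihedral is rotated
rigidly in 30&deg; steps over the full 360&deg; range (12 points), the
classical contributions that are *not* the target dihedral are evaluated
with the force-field expressions and subtracted from the quantum profile,
the residual is shifted so its minimum is zero (profiles are normalized
before fitting; $C_0$ absorbs the shift), and the six RB coefficients are
fitted by unweighted least squares.  No weights are applied because none
are defined for this protocol.

Two details matter:

* **What gets subtracted.** Along a scan of, say, the
  C&ndash;O~C~&ndash;Si&ndash;O~C~ dihedral of dimethyldimethoxysilane, the
  two C&ndash;Si&ndash;O~C~&ndash;C dihedrals sharing the rotated bond move
  with it; their (already fitted) energies are subtracted, as are the
  nonzero 1-5 Lennard-Jones and Coulomb terms.  If a companion class has no
  coefficients yet, `isolateTorsionTarget()` raises a dependency error:
  classes must be fitted in an order that respects these dependencies.
* **Conditioning.** Twelve equally spaced angles give seven distinct
  cosine values, so the six-parameter fit has full rank and profiles
  generated from the model class are recovered exactly (the suite checks
  all sixteen shipped coefficient rows to 1e-10).  Angle sets whose cosine
  powers collide raise an explicit conditioning error.  A constraint mask
  (`fixZero`) can pin chosen coefficients to zero for reproduction studies;
  by default all six are free, and rows with trailing zeros arise
  numerically rather than by constraint.

## Polarization corrections

A fixed-charge model cannot represent the electronic polarization response
of the liquid.  The package applies *post facto* corrections built from
per-compound electronic data: gas dipole $\mu_{Gas}$ (D), polarizability
volume $\alpha$ (&Aring;^3^), static dielectric constant $\varepsilon$ and
refractive index $n_D$.  The infinite-frequency dielectric constant is
always computed as $\varepsilon_\infty = n_D^2$; no independent
$\varepsilon_\infty$ input is accepted, to keep the inputs consistent.

The liquid dipole comes from the Onsager continuum with the cavity radius
eliminated self-consistently,
$$\mu_{Liq} = \mu_{Gas}\,\frac{(2\varepsilon + 1)(\varepsilon_\infty + 2)}
  {3(2\varepsilon + \varepsilon_\infty)},$$
and the polarization energy of the gas&rarr;liquid transfer is
$$E_{Pol} = \underbrace{\frac{(\mu_{Liq}-\mu_{Gas})^2}{2\alpha}}_{\text{distortion} \ge 0}
  \;-\; \underbrace{\frac{\mu_{Liq}^2}{\alpha}\,
  \frac{(\varepsilon_\infty-1)^2}{(2\varepsilon_\infty+1)(\varepsilon_\infty+2)}}_{-\text{electronic} \ge 0}.$$
Both terms vanish in the no-response limit
($\mu_{Liq} = \mu_{Gas}$, $\varepsilon_\infty = 1$).  Internally, one
conversion constant maps D^2^/&Aring;^3^ to kJ/mol (60.2214 kJ/mol per
unit); a water-like sanity input reproduces the familiar few-kJ/mol
distortion magnitude of effective-charge water models.

Downstream corrections: the enthalpy of vaporization is assembled as
$\Delta H_{Vap} = \langle U_{Gas}\rangle - \langle U_{Liq}\rangle + RT -
E_{Pol}$; solvation free energies get $E_{Pol}$ added; and the simulated
dielectric constant is corrected by
$$\varepsilon = \varepsilon_\infty +
 \left(\mu_{Liq}/\mu_{Model}\right)^2 (\varepsilon_{Simul} - 1),$$
which rescales the orientational response from the model dipole to the real
liquid dipole and restores the electronic part.  With a perfect model
dipole and $\varepsilon_\infty = 1$ the correction is the identity.  For
molecules that are nonpolar in both the model and reality the dipole ratio
is taken as 1 and the correction reduces to adding
$\varepsilon_\infty - 1$.

The shipped electronic-properties table
(`inst/extdata/electronic/electronic_properties_synthetic.tsv`) is a
documented *synthetic stand-in*: liquid dielectric constants are
experimental values, but the silanol gas dipoles are set alcohol-like
(1.70 D) and refractive indices are handbook-style approximations.  The
model dipole $\mu_{Model}$ is computed from the package's rigid equilibrium
geometry via `dipoleMoment()`.  In production these inputs should come from
a curated experimental compilation; with the stand-ins, corrected silanol
dielectric constants land in the right regime but are not quantitative
(see Limitations).

MD post-processing covers the dielectric constant from box-dipole
fluctuations, $\varepsilon_{Simul} = 1 + (\langle M^2\rangle - \langle
M\rangle^2)/(3\varepsilon_0 V k_B T)$, with block-averaged uncertainties
(five blocks, 2&times;SEM); Einstein diffusion $D = \text{slope}/6$ from
the mean-square displacement; and the finite-size correction obtained by
fitting $D$ against $1/L$ for several box lengths and extrapolating to
$1/L = 0$.

## Experimental-data curation

Literature data seldom sit at the 298 K reference state, so the curation
module implements: per-source linear regression of density against
temperature with evaluation at the reference temperature (and the average
slope reusable as a correction factor for single-temperature values);
Clausius&ndash;Clapeyron vapor-pressure fits $\ln p\,[\text{mmHg}] = A +
B/T$ fitted *independently per source* so that the spread of the derived
enthalpies estimates the experimental uncertainty directly;
$\Delta H_{Vap} = -RB$ tagged with the mean temperature of each fitted
window; first-order temperature corrections of the enthalpy under
selectable strategies (a constant correlation derivative, or the gas-liquid
heat-capacity difference &mdash; the step order of the original decision
cascade is not fully published, so the strategies are selectable rather
than hard-wired); vapor pressure at the reference temperature from the
normal boiling point, integrating Clausius&ndash;Clapeyron with
$p(T_b) = 1$ atm; and the self-solvation free energy
$$\Delta G_{Solv} = -RT\,\ln\frac{\rho R T}{M_W\, p_{Vapor}},$$
which is zero when the vapor and liquid molar concentrations coincide and
changes by $RT\ln 2$ per halving of the pressure.  Aggregation reports the
mean with 2&times;SEM when two or more values exist and explicitly no
uncertainty for a single value.  Outliers are removed by manual flag only
(the module deliberately implements no automatic rejection rule).
Pressure conversions use 1 bar = 750.062 mmHg and
$R = 8.314462618$ J mol^-1^ K^-1^ throughout.

## Lennard-Jones optimization

New LJ parameters are found by the response-surface procedure: a
full-factorial design over &sigma; &times; &epsilon; levels (the shipped
grids are the published ones, e.g. 6&times;6 for the alkylsilane silicon
and 6&times;7 for the alkoxy oxygen), coded onto $[-1, +1]$ from the level
extremes, a second-order surface with cross term per (molecule, property)
fitted by least squares, and the objective
$$F(x_1, x_2) = \frac{1}{N_{mol} N_{prop}} \sum_k
 \left(f_k(x_1, x_2) - y^{exp}_k\right)^2$$
minimized by a two-stage steepest descent: at most 4000 iterations with a
variable step (grown 1.2&times; on acceptance, halved on rejection,
starting at 0.1 coded units), then a refinement of at most 100 iterations
starting from the best point with one tenth of the final step.  The exact
normalization of the published objective is not recoverable from the text;
we default to absolute squared deviations averaged over the terms, with
`relative = TRUE` available when properties of different units are mixed.
Likewise the published step-adaptation rule is unspecified; backtracking
halving is the minimal scheme consistent with "variable step length"
followed by "smaller step lengths".  On exactly quadratic convex surface
sets the descent reaches the analytic minimizer to better than 1e-3 coded
units from arbitrary starts, which is the accuracy regime the meta-models
themselves support.

Responses enter through a plain matrix (one column per molecule/property,
one row per design point), so tests plug in synthetic surfaces while
production use plugs in MD-summary tables.

## Geometry embedding and numerical choices

Torsion scans and model dipoles need coordinates.  `buildConformation()`
embeds a topology from internal coordinates by natural extension: bonds at
their constraint lengths, angles at their equilibrium values, successive
branches staggered 120&deg; apart.  A four-substituent center whose
pairwise angle parameters are all equal (tetramethylsilane-like) is placed
at exact tetrahedral directions so its symmetry &mdash; and zero dipole
&mdash; is preserved; mixed centers use the tabulated angles, which cannot
all be satisfied simultaneously at a tetrahedral center, so child-child
angles may deviate from their equilibrium values by a few degrees.  The
embedding is a starting structure for rigid scans, not a minimized
geometry.  Rigid dihedral rotation moves the component on the far side of
the central bond and refuses bonds on rings.

Other numerical conventions: angles are degrees at every interface and
radians internally; coordinates are nm; site overlaps below 1e-6 nm are
reported as errors rather than returned as infinities; exported topology
text uses fixed formats so identical inputs are byte-identical; box packing
rejects placements with any minimum-image site-site distance below the
threshold (default 0.2 nm) and fails loudly after a bounded number of
attempts.

## What the synthetic generators emulate

`generateFixtures()` plants ground truth and writes it alongside the data:
torsion scans assembled from a known RB target plus the molecule's real
classical 1-5 and companion-torsion terms (what a DFT scan would contain if
the classical model were exact); quadratic property surfaces over the
published design grids with the minimum inside the grid; density series
from a planted line with one flagged outlier (mimicking the manual
exclusion workflow); and exact Clausius&ndash;Clapeyron pressure series.
Passing these tests shows the machinery inverts its own generative model
exactly; it does not show that DFT scans are free of non-classical
contributions, that real property surfaces are quadratic, or that real
measurement scatter is well behaved &mdash; those are properties of data,
not of the code.  Problem sizes are kept small (12-point scans, 36&ndash;56
point grids, tens of packed molecules), matching the scale of the
procedures being emulated.

## Limitations

* Bulk properties (density, $\Delta H_{Vap}$, $\varepsilon_{Simul}$, $D$)
  require running the exported topologies in an external MD engine; the
  package writes topologies, packs starting boxes and post-processes
  summary tables, but does not integrate equations of motion.  Run-setting
  templates mirroring the documented protocol ship under
  `inst/templates/`.
* The default alkane CH~x~ constants are a carried-over stand-in; MD-level
  validation requires the alkane set the silicon parameters were tuned
  against.
* The shipped electronic-property inputs are synthetic stand-ins, so
  corrected silanol dielectric constants are indicative only; supply
  curated $\mu_{Gas}$, $\alpha$, $\varepsilon$, $n_D$ for quantitative
  work.
* Single-molecule energetics only: no cutoffs, periodicity or Ewald sums in
  the internal evaluator; no free-energy estimator (the decoupling schedule
  ships as a documented template).
* No SiH~x~, aryl or halogen substituents, and no protonation-state
  inference.
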
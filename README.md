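# orgsil

A united-atom force-field toolkit for organosilicon molecules in the liquid
phase: alkylsilanes, alkoxysilanes, silanols and siloxanes — the compound
classes at the heart of sol–gel silica chemistry (TMOS, TEOS), silicone
synthesis and biosilicification. No general-purpose force field covers these
molecules, and the experimental record is thin and scattered; `orgsil`
packages both sides of the problem: building simulation-ready molecular
models, and curating the experimental data needed to parametrize and
validate them.

## What it does

**Topology generation.** From a molecule graph (programmatic constructors,
a YAML spec format, or the built-in registry of common organosilicates),
the package perceives united-atom CH_x sites, types every atom (O_C alkoxy,
O_H silanol, O_B bridging siloxane, Si^k silicon with k oxygenated
substituents), assigns point charges by substituent environment with the
silicon charge closing overall neutrality exactly, enumerates rigid-bond
constraints, harmonic angles and Ryckaert–Bellemans torsions

E(φ) = Σₙ Cₙ cosⁿ(ψ),  ψ = φ − 180°,

assigns 12-6 Lennard-Jones parameters — silicon following the
per-oxygenated-substituent reduction σ(Si^k) = σ(Si⁰)(1 − 0.05k) — builds
the ≤3-bond exclusion list (no 1-4 interactions), and exports
GROMACS-dialect `.itp/.top` files plus packed `.gro` starting boxes.

**Polarization corrections.** The model is nonpolarizable; polarization
enters through *post facto* corrections built from electronic data: the
Onsager liquid dipole μ_liq = μ_gas(2ε+1)(ε∞+2)/[3(2ε+ε∞)], the
distortion + electronic polarization energy E_Pol, the corrected enthalpy
of vaporization ΔH_vap = ⟨U_gas⟩ − ⟨U_liq⟩ + RT − E_Pol, corrected
solvation free energies and dielectric constants
ε = ε∞ + (μ_liq/μ_model)²(ε_simul − 1), plus MD post-processing
(dipole-fluctuation dielectric, Einstein diffusion with 1/L finite-size
extrapolation).

**Parametrization machinery.** Torsion fitting against quantum-chemical
dihedral scans (isolate the torsional residual by subtracting classical 1-5
and companion-torsion terms, min-shift, least-squares RB fit), and a
response-surface Lennard-Jones optimizer (full-factorial coded design,
quadratic meta-models with cross term, two-stage variable-step steepest
descent).

**Experimental-data curation.** Per-source density regression to 298 K,
independent Clausius–Clapeyron vapor-pressure fits (ln p[mmHg] = A + B/T,
ΔH_vap = −RB), temperature-correction strategies, vapor pressure from the
normal boiling point, self-solvation free energies
ΔG_solv = −RT ln(ρRT/M_W p), and mean ± 2·SEM aggregation.

## Worked example

```r
library(orgsil)

top <- buildTopology(siliconMolecule("Met3SiOH"))   # trimethylsilanol
top
#> UATopology 'trimethylsilanol': 6 sites, 5 constraints, 7 angles, 3 torsions
#>   net charge -1.11e-16 e; 15 excluded pairs; validated: TRUE

round(sites(top)$charge, 3)
#> [1]  1.40 -0.32 -0.32 -0.32 -0.88  0.44
```

Six united-atom sites: silicon, three methyl CH3 sites, the silanol oxygen
and its explicit hydrogen. The substituent charges are the tabulated rules
(−0.32 per CH3 on an oxygenated silicon, −0.88/+0.44 for O–H) and silicon
takes +1.40 e, the unique value that makes the molecule exactly neutral.
The silicon σ series follows the oxygenation scaling rule:

```r
siliconSigma(defaultParameters(), 0:4)
#> [1] 0.580 0.551 0.522 0.493 0.464
```

Curation side — a vapor-pressure series fitted per source, with the
enthalpy of vaporization from the Clausius–Clapeyron slope, and a
self-solvation free energy from density, molecular weight and vapor
pressure:

```r
T <- seq(273, 313, 10)
vp <- propertySeries("tetramethylsilane", "vapor_pressure",
                     T, exp(17.5 - 3031.6 / T))
hvapFromFit(fitVaporPressure(vp))
#>    source    dHvap meanT
#> 1 unknown 25.20612   293

gsolvFromVaporPressure(rho = 758.4, MW = 162.38, p = 0.0555)
#> [1] -18.94683
```

A slope of −3031.6 K maps to 25.2 kJ/mol (−RB), tagged with the window's
mean temperature; the free-energy example corresponds to a
hexamethyldisiloxane-like liquid at 298.15 K. Export for simulation:

```r
writeGromacsTopology(top, "met3sioh.itp")
pk <- packBox(top, count = 200, box = 3.1, seed = 1)
writeGro(pk$coords, pk$names, pk$box, "box.gro", resids = pk$resids)
```

A thin command-line front end with the same functionality ships at
`inst/scripts/orgsil` (subcommands `build`, `pack`, `fixtures`).

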
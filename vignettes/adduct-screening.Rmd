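---
title: "Screening nucleoside binders by post-column addition LC-MS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening nucleoside binders by post-column addition LC-MS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adductscreen)
```

## The measurement

G-quadruplexes are four-stranded nucleic-acid structures built from stacked
guanine tetrads; small molecules that stabilize them are of interest as
anticancer leads. Because 2'-deoxyguanosine (dG) and guanosine (G) are the
building blocks of the tetrads, the gas-phase stability of a non-covalent
complex between a candidate ligand M and a protonated nucleoside is a cheap,
chromatography-compatible proxy for quadruplex affinity.

The experiment this package models: a nucleoside solution is infused into the
LC eluent *after* the column (post-column addition), so proton-bound complexes
[M+dG+H]⁺ and [M+G+H]⁺ form during electrospray ionization while each analyte
elutes. On a single-quadrupole instrument the sampling-cone voltage drives
collision-induced dissociation in the source region ("in-source CID"): as the
voltage ramps up, the weakly bound complex falls apart while the free [M+H]⁺
ion only gains abundance. The abundance ratio

$$ R(E) = \frac{[\mathrm{M{+}dG/G{+}H}]^+}{[\mathrm{M{+}H}]^+} $$

as a function of collision energy is therefore a relative stability
(survival-yield) curve for the complex: ligands whose curves sit higher and
decay later bind the nucleoside more strongly. Because the nucleoside's
proton affinity far exceeds a phenol's, dissociation is taken to release the
neutral ligand and the protonated nucleoside, so the ratio cleanly tracks
complex survival.

## Energy axis: center-of-mass energy with a DOF correction

The cone voltage $E_{lab}$ (V, numerically eV for a singly charged ion) is a
laboratory-frame energy. The maximum energy transferable into internal modes
in a single collision with a gas molecule of mass $m_g$ (N₂, 28 amu) is the
center-of-mass energy, and complexes of different size are made comparable by
a vibrational degrees-of-freedom correction:

$$ E_{com\delta} = \delta\, E_{lab}\, \frac{m_g}{m_p + m_g},
   \qquad \delta = \frac{DOF_{ref}}{DOF_{adduct}},
   \qquad DOF = 3N - 6, $$

where $m_p$ is the adduct ion mass and $N$ its total atom count (including
the added proton — the convention counts all atoms of the analyzed ion).
`ecom()` and `delta_factor()` implement exactly this; `energy_axis()` spans
the cone-voltage ramp for one adduct.

Design choices here:

* **Reference adduct.** $\delta = 1$ must hold for exactly one adduct per
  experiment. `select_reference_dof()` picks the minimum-DOF adduct of the
  analyzed set automatically, so every $\delta \in (0, 1]$ and
  $E_{com\delta} < E_{lab}$ always. With the built-in five-compound panel the
  smallest nucleoside adducts are those of the dehydrokawain glycoside
  (C20H22O9; 84 and 85 atoms with dG and G), giving reference DOF 246 and 249.
  A caller may force a different reference; a $\delta > 1$ is then computed
  but warned about.
* **Mass bookkeeping.** $m_p$ is the adduct ion's monoisotopic mass in Da
  treated as amu; the electron mass (±0.00055 Da per charge) is ignored, far
  below unit resolution.
* **Nominal masses** are sums of integer isotope mass numbers
  (C=12, H=1, N=14, O=16, Cl=35), never a rounded monoisotopic float — the
  two diverge for large compositions, and the integer route is what
  reproduces printed unit-resolution m/z values. The chloride adduct uses
  ³⁵Cl; formate is CHO₂. Only |charge| = 1 is supported; multiply charged
  species are out of scope.

```{r energy-example}
a <- make_adduct("C20H22O9", "nucleoside_proton_add", "dG")
a
energy_axis(a, collision_settings(reference_dof = a$dof))
```

## From peak lists to curves

Runs are long-format centroided peak lists (CSV columns `scan_time_min`,
`cone_voltage_V`, `polarity`, `mz`, `intensity`; an optional mzML reader uses
the mzR package). For each compound and cone voltage, `build_curve()`
extracts ion chromatograms of [M+H]⁺ and [M+Nuc+H]⁺ at ±0.5 Da (the default
tolerance, matching single-quadrupole unit resolution), integrates them over
the compound's retention-time window by the trapezoidal rule, and forms the
survival ratio. Integrated areas are the default abundance measure — robust
to scan-rate changes — with apex heights available via `mode = "apex"`.
A zero free-ion abundance yields an explicit undefined-ratio error, never a
silent infinity; an undefined point is dropped with a warning and never
silently shifts the ranking grid.

## Summaries and ranking

The experiment compares curves; to make that reproducible the package fits a
three-parameter logistic

$$ R(E) = \frac{r_0}{1 + e^{s(E - E_{50})}} $$

with free low-energy plateau $r_0$, midpoint $E_{50}$ (eV) and steepness $s$
(1/eV), by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) from the
fixed initializer $r_0 = \max R$, $E_{50} = \mathrm{median}(E)$,
$s = 4/\mathrm{range}(E)$ — fits are therefore deterministic.
Non-convergence and flat (degenerate) curves are flagged, not thrown. The
logistic shape is this package's summary device, the standard form of
energy-resolved breakdown curves; the underlying experiment makes no
functional-form claim.

`rank_compounds()` offers two modes. `pointwise` (default) scores each
compound by its mean ratio on a common $E_{com\delta}$ grid built by linear
interpolation over the curves' shared support only — no extrapolation.
`e50` ranks by the fitted midpoint. Ties break lexicographically by compound
name so reports are stable. dG and G curve sets are never ranked against each
other: the two nucleosides are infused from different solvents and their
absolute ratios are not comparable.

## The simulator: what it emulates, and what it does not

`simulate_run_set()` generates the whole experiment with known ground truth:

* Gaussian elution of each [M+H]⁺ (defaults put all compounds in the 5–6 min
  window of a 4–7 min segment, scan interval 0.02 min ≈ 1.2 s, ~150 scans);
* nucleoside infusion confined to 4.5–6.5 min, during which the adduct
  appears with intensity $I_{free} \cdot f \cdot S(E_{com\delta})$, where
  $f \in (0,1)$ is the compound's adduct fraction at zero energy and
  $S(E) = 1/(1+e^{s_{true}(E - E_{50,true})})$ its survival function, with
  $E_{com\delta}$ computed by the same energetics code the analyzer uses;
* multiplicative lognormal intensity noise with CV 0.05 by default — the
  run-to-run variation the experiment reports staying under 5% — with the
  mean-one parameterization $\mu_{log} = -\sigma_{log}^2/2$, and a mandatory
  seed whenever noise is on, so runs are reproducible byte for byte.

The built-in `reference_panel()` holds the five screening compounds — a
flavonol glycoside (C22H22O12), a dehydrokawain glycoside (C20H22O9), a
dicaffeoylquinic acid (C25H24O12), and the standards isoquercitrin
(C21H20O12) and rutin (C27H30O16) — with ground-truth binding ordered so the
three plant phenolics outrank both standards and rutin outranks
isoquercitrin, the qualitative finding the screen is meant to recover. Their
$E_{50,true}$ values (0.45–0.85 eV) sit inside the $E_{com\delta}$ range
swept by the 10–30 V ramp; the strong binders get steeper survival slopes
(8 vs 4 eV⁻¹), so their curves start higher *and* fall faster without ever
crossing below the standards' — matching the observed curve morphology.

What the simulator deliberately omits: isotope envelopes, chromatographic
tailing, ion suppression, detector saturation, m/z calibration error, and
any fragmentation of the ligand itself (the low cone-voltage range is chosen
in the real experiment precisely to avoid it). Passing tests on simulated
data therefore validate the *bookkeeping and statistics* of the pipeline —
mass arithmetic, energy conversion, integration, fitting, ranking — not the
chemistry of a real extract.

## Validation scale and numerical choices

The test suite validates at desk scale: 5 cone voltages, ~150 scans per run,
five compounds, 20 seeded replicates for the stochastic properties
(midpoint recovery within 10% at 5% noise; correct ranking in at least 19 of
20 replicates), and 1000 random compositions for the mass-algebra
properties. Monoisotopic additivity is asserted to 1e-9 Da, nominal-mass
additivity exactly, the energy formula against literal arithmetic to 1e-12
relative, and noise-free generator/analyzer consistency to 1e-6 relative.

Other numerical conventions: times are minutes throughout; windows are
closed intervals; a retention-time window with fewer than two scans
integrates to zero; `3N − 6` is applied to every ion and rejected for
N < 3, where the convention is undefined.

## Known limitations

* Unit-resolution m/z matching (±0.5 Da default) cannot separate isobars;
  the compound panel's retention-time windows must do that.
* The logistic midpoint is a *relative* stability summary; no absolute
  binding constants or gas-phase thermochemistry are estimated.
* High nucleoside affinity does not guarantee G-quadruplex affinity: sites
  available on a free nucleoside may be occupied in the assembled tetrad.
  The screen is a filter, not a confirmation.
* Single-polarity, singly charged ions only; profile-mode data must be
  centroided upstream.
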
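---
title: "Models and methods behind famespec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind famespec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famespec)
```

`famespec` implements the computational chain used to characterize
temperature-induced changes in bacterial lipids and whole-cell biochemistry:
internal-standard GC–FID quantification of fatty acid methyl esters (FAMEs),
structural classification of fatty acids, FTIR spectral preprocessing and
band-ratio analysis, and exploratory chemometrics. This vignette explains the
underlying models, the parameters that matter, and the design decisions that
were genuinely open.

## Internal-standard quantification

FID response is, to good approximation, proportional to analyte mass, so a
known mass of a compound absent from the samples converts areas to masses:

$$m_i = \frac{A_i}{A_{IS}} \, m_{IS} \, RRF_i, \qquad
TL\% = 100 \frac{\sum_i m_i}{m_{biomass}}.$$

Two quantities require care:

* **The internal-standard mass.** The standard is added as
  1,2-dinonadecanoyl-sn-glycero-3-phosphocholine (0.5 mg, i.e. 50 µL of a
  10 mg/mL solution). Only the two C19:0 acyl chains become FAME during acid
  methanolysis, so the quantifiable mass is
  $m_{IS} = 0.5 \times 2 M_{C19:0}/M_{PC} \approx 0.365$ mg, with molar
  masses computed from the molecular formulas (PC C₄₆H₉₂NO₈P ≈ 818.2 g/mol,
  nonadecanoic acid C₁₉H₃₈O₂ ≈ 298.5 g/mol). `is_mass_c19_pc()` performs the
  conversion; the free-acid basis is the default and a methyl-ester basis
  (C₂₀H₄₀O₂ ≈ 312.5 g/mol) is available, because which basis a published
  workflow uses is rarely stated. Both are overridable.
* **Relative response factors.** No RRF table ships with the package;
  factors default to 1 and published FID response tables can be supplied via
  `rrf_table()`. Masses are linear in both areas and RRFs, and all derived
  percentages are invariant to a global area rescaling — properties the test
  suite checks exactly.

Peaks whose labels the parser cannot interpret are still quantified and
surface as *unknown FAs*; dropping them would bias totals.

## Fatty-acid grammar and classification

Chromatography software emits several label dialects for the same acid. The
parser accepts their union — branching prefixes (`a-`, `aC15:0`,
`anteiso-`), `iso`/`i`, `cyclo`/`cy`, hydroxyl prefixes (`2OH-`),
and unsaturation suffixes (`n7c`, `cis7`, bare `c`/`t`) — case-insensitively,
normalizes to one canonical rendering, and refuses anything else with an
error naming the offending token. Descriptors enforce chemical invariants
(anteiso needs ≥ 5 carbons for an ω−3 methyl; a stated geometry needs a
double bond).

Classification uses a fixed precedence (cyclic > hydroxy > PUFA > n-MUFA >
br-SFA > n-SFA) so that every acid lands in exactly one of the disjoint
groups that profile summaries report. Branched *and* unsaturated acids fit
none of the conventional groups and are carried as a separate
`br_UFA_unknown` class rather than being forced into one — how such acids
should be allocated is not standardized, and a visible class keeps totals
closing to 100 %.

Chain-length bounds are SCFA < 6, MCFA 7–12, LCFA 13–21, VLCFA 22–24
carbons. C6 falls between the stated SCFA and MCFA bounds; we assign it to
MCFA to keep the classes contiguous (configurable via `c6_class`).

Minor acids — relative abundance ≤ 1 % by default, strictly interpreted so
that only acids *above* the threshold enter the analysis — are pooled into a
minor-FA pool and excluded from class sums, mirroring common reporting
practice. The threshold applies per sample on relative weight percent.

## FTIR preprocessing

Two paths serve two purposes:

* **PCA path**: Savitzky–Golay second derivative (polynomial order 2,
  window 11 points ≈ 21 cm⁻¹ at the 1.928 cm⁻¹ digital spacing), removal of
  uninformative regions (4000–3100, 2800–1800, 900–400 cm⁻¹), then EMSC.
  Differentiation suppresses broad baselines and sharpens overlapping bands;
  EMSC removes what differentiation cannot — per-spectrum multiplicative
  gain from scattering/thickness and residual smooth baselines.
* **Ratio path**: Savitzky–Golay smoothing (same order/window) and selection
  of the informative 1900–900 cm⁻¹ region. The derivative order of this path
  is genuinely ambiguous in practice; smoothing (order 0) is the default
  because band ratios are conventionally read as absorbance peak heights,
  and a second-derivative variant (with magnitudes at the bands) is a
  configuration option rather than a guess.

Numerical choices: the filter delegates to `signal::sgolayfilt`, which is
exact for polynomials up to the fitted degree and computes edge points from
the one-sided window fit; edges are flagged in the processing log. Region
boundaries follow a closed-retained convention — the retained regions are the
closed gaps between removed intervals, so a grid point exactly at 3100 cm⁻¹
survives the default cut. Instrument grids are stored in descending
wavenumber order and must be uniform to 10⁻⁶ relative tolerance for
filtering (non-uniform grids raise an error asking for resampling).

### EMSC

Each spectrum $y$ is regressed on a constant, linear and quadratic Legendre
polynomial in the wavenumber mapped affinely to $[-1, 1]$ (for conditioning)
plus a reference spectrum $r$:

$$y = a_0 P_0 + a_1 P_1 + a_2 P_2 + b\,r + e,$$

and corrected as $(y - \sum_k a_k P_k)/b$. The default reference is the
arithmetic mean of the derivative, region-cut set; an external reference can
be supplied. The correction exactly removes any degree-≤ 2 baseline and any
positive gain (an algebraic identity the tests verify to 10⁻⁸ over random
constructions), is idempotent, and refitting a corrected spectrum returns
$b = 1$, $a = 0$. Spectra with $|b|$ below tolerance cannot be normalized;
they are excluded with a warning and their ids recorded, and the FTIR run
reports the exclusion count. EMSC is fitted per dataset (all spectra against
one reference), not per replicate group.

## Band ratios

Relative lipid content is estimated as L/P = A(1742)/A(1656) — the ester
C=O stretching band against amide I, the latter chosen as a comparatively
stable protein reference — and relative phosphorus-compound content as
P/P = A(1083)/A(1656) from the P–O–C symmetric stretch. Reported band
positions for these features vary by a few cm⁻¹ between instruments and
studies (1734–1743 for the ester band, 1654–1656 for amide I); the package
defaults to 1742 and 1656 and finds the local extremum within ±8 cm⁻¹, which
makes the estimate robust to such shifts. All centers, the half-width and
the height-at-center alternative are configurable.

Technical replicates are averaged **after** ratio computation: the ratio of
a mean spectrum is not the mean of ratios, and per-spectrum ratios keep
outlier replicates visible. A vanishing reference band flags the spectrum
invalid instead of producing an unbounded ratio.

## Chemometrics

GC class profiles are autoscaled (per-column mean-centering and division by
the standard deviation) before PCA, because class abundances span an order
of magnitude; zero-variance columns are dropped with a warning. Preprocessed
FTIR spectra enter PCA mean-centered only — derivative + EMSC output is
already on a common scale, and autoscaling would inflate noise-only
wavenumbers. PCA itself is a deterministic SVD of the centered matrix;
component signs are fixed by making the largest-magnitude loading positive,
so runs are bit-reproducible. Explained variance fractions are
$\lambda_k/\sum\lambda$. Replicates enter FTIR PCA as individual rows.

Grouped Pearson correlations (L/P against total lipid content) are reported
for the whole dataset and within Gram groups, phyla, genera and
temperatures; groups with fewer than two pairs or zero variance get an
undefined coefficient with an explanatory flag. The GC and FTIR branches are
joined at the biological-replicate level after technical averaging.

## The synthetic panel

The generator emulates the study design the pipeline targets: 18
cold-habitat genera (6 Gram-negative including one Bacteroidetes, 12
Gram-positive split between Actinobacteria and Firmicutes), grown at
5/15/25 °C with two biological replicates and three technical FTIR
replicates; psychrophilic genera never receive 25 °C. Per strain ×
temperature:

* the fatty-acid composition is a Dirichlet draw (concentration 400, i.e.
  ~2–5 % relative scatter on major components) around a Gram-specific
  template — Gram-negative dominated by C16:1/C18:1n7c/C16:0,
  Gram-positive by a-C15:0/a-C17:0/i-C15:0 — shifted on the log scale by a
  temperature-response vector: Gram-negative monounsaturates rise in the
  cold, Gram-positive branched saturates rise with warmth (anteiso favored
  over iso in the cold). Effect size 0 switches the response off.
* the true lipid fraction is uniform on [0.04, 0.19] per strain — the
  realistic whole-cell range for these organisms — with a mild increase at
  colder growth (+15 % per 10 °C of cooling below 15 °C).
* FTIR spectra are sums of Gaussian bands at 2924, 2853, 1742, 1725, 1709,
  1656, 1640, 1548, 1400, 1240 and 1083 cm⁻¹ (widths 8–14 cm⁻¹, consistent
  with a 6 cm⁻¹ instrument resolution) on the 4000–400 cm⁻¹ grid at
  1.928 cm⁻¹ spacing. Lipid-band amplitudes are proportional to the *same*
  latent lipid fraction the GC truth uses, protein bands to a log-normal
  protein factor, and phosphorus bands to a uniform phosphorus factor — so
  the L/P-vs-lipid-content correlation has a known positive population value
  for the recovery tests.
* each spectrum gets a multiplicative gain (uniform 0.7–1.3) and a degree-2
  baseline (a₀ ∈ [0, 0.2], a₁ ∈ [−0.05, 0.05], a₂ ∈ [−0.03, 0.03] on the
  mapped axis, i.e. up to ~20 % of the amide I height) — exactly the family
  EMSC removes — plus additive Gaussian noise (sd 0.01 ≈ 1 % of amide I).
  GC areas get multiplicative log-normal noise with a 5 % CV by default.

Every random draw derives from one panel seed; renderers derive per-spectrum
sub-seeds from it, so individual spectra are reproducible in isolation and
the whole pipeline is bit-identical across runs with the same seed.

What the generator does **not** emulate: Mie-type dispersive scattering,
water-vapor lines, detector nonlinearity, chromatographic co-elution, or
Voigt band shapes. Passing the recovery tests therefore demonstrates the
correctness of the computational chain under the stated artifact model, not
instrument-grade robustness on real spectra.

## Problem sizes and runtime

The default panel (18 genera × ≤ 3 temperatures × 2 biological × 3
technical replicates ≈ 312 spectra of 1868 points, 104 GC samples) runs end
to end in a few seconds on one CPU; the test suite uses the same scale or
smaller. These sizes were chosen to exercise every code path at the study's
own design dimensions.

## Known limitations

* The FA grammar covers the dialects listed above; exotic notations
  (Δ-nomenclature, oxo/epoxy acids) are rejected rather than guessed.
* L/P and P/P are relative, instrument-dependent estimates; they are not
  calibrated to absolute lipid or phosphorus mass.
* PCA sign conventions are internally fixed but arbitrary; compare loadings
  by magnitude and relative sign only.
* The ratio path applies no scatter correction, matching common practice;
  strong baseline artifacts therefore propagate into the ratios (the
  generator's defaults keep them within the realistic range stated above).
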
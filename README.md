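# famespec

Chemometrics for bacterial temperature-response lipidomics: GC–FID FAME
quantification, fatty-acid chemotaxonomy, and FTIR band-ratio analysis.

## What problem this solves

Bacteria remodel their membrane lipids when the growth temperature changes —
Gram-negative species shift acyl-chain unsaturation and length, Gram-positive
species shift methyl branching (anteiso/iso). Characterizing this requires a
chain of routine but error-prone computations that `famespec` packages as
tested, reusable functions for microbiologists and analytical chemists:

1. **GC quantification** (`quantify_fames`, `total_lipid_content`): convert
   integrated GC–FID peak areas of fatty acid methyl esters (FAMEs) into
   masses via an internal standard and relative response factors (RRF):

   `mass_i = (area_i / area_IS) × m_IS × RRF_i`,
   `TL% = 100 × Σ mass_i / m_biomass`

   The default internal standard is C19:0 released from 0.5 mg of
   di-C19:0 phosphatidylcholine; the PC-to-acyl mass conversion is computed
   from molecular formulas (`is_mass_c19_pc()`).

2. **Fatty-acid classification** (`parse_fa_label`, `structural_class`,
   `chain_length_class`, `summarize_profile`): parse labels such as
   `a-C15:0`, `C18:1n7c`, `2OH-C14:0`, `cyclo-C17:0` into structural
   descriptors, and sum relative abundances into disjoint classes (PUFAs,
   n-SFAs, br-SFAs, n-MUFAs, hydroxy-FAs, cyclic-FAs), chain-length classes
   (SCFA < 6 C, MCFA 7–12, LCFA 13–21, VLCFA 22–24), cis/trans and
   iso/anteiso sums, pooling acids ≤ 1 % into a minor-FA pool.

3. **FTIR preprocessing** (`savgol`, `cut_regions`, `emsc_fit`,
   `emsc_correct`): Savitzky–Golay filtering (order 2, window 11), removal
   of uninformative regions (4000–3100, 2800–1800, 900–400 cm⁻¹), and
   extended multiplicative signal correction (EMSC) of second-derivative
   spectra — ordinary least squares of each spectrum on
   {1, ν̃, ν̃², reference}, then `corrected = (y − baseline)/b`.

4. **Band ratios** (`compute_ratios`): relative lipid and phosphorus content
   as L/P = A(1742)/A(1656) (ester C=O over amide I) and
   P/P = A(1083)/A(1656) (P–O–C over amide I), with extremum search within
   ±8 cm⁻¹ of each nominal center.

5. **Chemometrics** (`autoscale`, `pca_fit`, `pearson_by_group`):
   autoscaled PCA of the fatty-acid class matrix, mean-centered PCA of the
   preprocessed spectra, and Pearson correlations between L/P and total
   lipid content — overall and by Gram group, phylum, genus and temperature.

6. **Synthetic panel generator** (`generate_panel`, `render_peak_table`,
   `render_spectrum`): a seeded panel of 18 cold-habitat genera grown at
   5/15/25 °C with Gram-specific temperature responses, known lipid
   fractions, and FTIR spectra with gain/baseline artifacts that EMSC is
   designed to remove — the ground truth every stage is tested against.

## Worked example

```r
library(famespec)

pt <- peak_table("strain_A_5C",
                 fa_label = c("a-C15:0", "i-C15:0", "C16:0", "C16:1n7c", "C19:0"),
                 area     = c(5200, 2100, 3100, 1400, 2500),
                 biomass_dry_mg = 20)
prof <- quantify_fames(pt)
prof
#>     sample_id fa_label mass_mg percent
#> 1 strain_A_5C  a-C15:0  0.7589   44.07
#> 2 strain_A_5C  i-C15:0  0.3065   17.80
#> 3 strain_A_5C    C16:0  0.4524   26.27
#> 4 strain_A_5C C16:1n7c  0.2043   11.86

total_lipid_content(prof)
#> [1] 8.61   # percent of cell dry weight

summarize_profile(prof)[, c("br_SFAs", "n_SFAs", "n_MUFAs", "anteiso_FAs", "iso_FAs")]
#>   br_SFAs n_SFAs n_MUFAs anteiso_FAs iso_FAs
#> 1   61.86  26.27   11.86       44.07    17.8
```

The C19:0 internal-standard peak (2500 area counts ≙ 0.365 mg of acyl
material) anchors the mass scale: a-C15:0 with area 5200 becomes
5200/2500 × 0.365 ≈ 0.76 mg. The class summary shows the branched-saturate
dominance (62 %) typical of a Gram-positive profile.

A full synthetic-panel run:

```r
res <- run_pipeline(default_config(seed = 1, out_dir = "out"))
res$correlations[res$correlations$grouping == "all", ]
#>   grouping group   n     r flag
#> 1      all   all 104 0.981
```

or from the shell:

```sh
Rscript inst/scripts/famespec-cli.R all --seed 1 --out out
```

which writes tidy TSV tables (total lipid, class summaries, genus ×
temperature aggregates with sd only for groups of ≥ 2 members, PCA
scores/loadings/variance, band ratios, grouped correlations) plus the
resolved `config.yaml`.

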
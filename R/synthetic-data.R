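#' Genus roster of the synthetic strain panel
#'
#' Eighteen cold-habitat genera spanning three phyla and both Gram groups.
#' Psychrophilic genera (restricted to low growth temperatures) do not grow
#' at 25 degrees C; the rest are psychrotrophs.
#'
#' @return Data frame `genus`, `phylum`, `gram`, `lifestyle`.
#' @export
default_genus_roster <- function() {
  data.frame(
    genus = c("Polaromonas", "Pseudomonas", "Psychrobacter", "Shewanella",
              "Acinetobacter", "Flavobacterium",
              "Agrococcus", "Arthrobacter", "Brachybacterium", "Cryobacterium",
              "Leifsonia", "Micrococcus", "Paeniglutamicibacter",
              "Rhodococcus", "Salinibacterium",
              "Facklamia", "Sporosarcina", "Carnobacterium"),
    phylum = c(rep("Proteobacteria", 5), "Bacteroidetes",
               rep("Actinobacteria", 9), rep("Firmicutes", 3)),
    gram = c(rep("negative", 6), rep("positive", 12)),
    lifestyle = c("psychrophile", "psychrotroph", "psychrophile",
                  rep("psychrotroph", 15)),
    stringsAsFactors = FALSE)
}

# Gram-specific fatty-acid template compositions (fractions summing to 1).
# Gram-negative membranes are dominated by straight-chain monounsaturates
# (C16:1, C18:1n7c) with C16:0; Gram-positive by anteiso/iso branched
# saturates (a-C15:0, a-C17:0, i-C15:0).
#' @keywords internal
fa_templates <- function() {
  list(
    negative = c("C16:1n7c" = 0.23, "C18:1n7c" = 0.22, "C16:0" = 0.20,
                 "C14:0" = 0.05, "C12:0" = 0.03, "C15:0" = 0.03,
                 "C17:1n8c" = 0.03, "2OH-C12:0" = 0.03, "3OH-C14:0" = 0.04,
                 "cyclo-C17:0" = 0.05, "C20:5n3" = 0.03, "C18:0" = 0.06),
    positive = c("a-C15:0" = 0.34, "i-C15:0" = 0.14, "a-C17:0" = 0.15,
                 "i-C16:0" = 0.07, "C16:0" = 0.10, "i-C14:0" = 0.05,
                 "C14:0" = 0.04, "a-C13:0" = 0.03, "i-C13:0" = 0.03,
                 "C16:1cis9" = 0.03, "C18:1n9c" = 0.02))
}

# Per-label log-weight shift applied per unit of "coldness" (15 - T)/10 and
# unit effect size. Encodes the temperature-response rules: Gram-negative
# raise straight-chain monounsaturates in the cold at the expense of
# saturates; Gram-positive raise branched saturates at warmer growth
# temperatures, shifting anteiso over iso in the cold.
#' @keywords internal
fa_temperature_directions <- function() {
  list(
    negative = c("C16:1n7c" = 0.2, "C18:1n7c" = 0.2, "C17:1n8c" = 0.2,
                 "C16:0" = -0.2, "C18:0" = -0.2, "C14:0" = -0.2,
                 "C12:0" = 0, "C15:0" = 0, "2OH-C12:0" = 0, "3OH-C14:0" = 0,
                 "cyclo-C17:0" = 0, "C20:5n3" = 0.1),
    positive = c("a-C15:0" = -0.1, "i-C15:0" = -0.3, "a-C17:0" = -0.1,
                 "i-C16:0" = -0.3, "a-C13:0" = -0.1, "i-C13:0" = -0.3,
                 "i-C14:0" = -0.3,
                 "C16:0" = 0.15, "C14:0" = 0.15,
                 "C16:1cis9" = 0.25, "C18:1n9c" = 0.25))
}

#' @keywords internal
rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  stats::setNames(g / sum(g), names(alpha))
}

#' Band roster of the synthetic FTIR forward model
#'
#' Gaussian band centers (cm^-1), their Gaussian sigma (cm^-1) and the latent
#' factor each amplitude is tied to: `lipid` (CH stretching 2924/2853, ester
#' C=O 1742 with its 1725/1709 shoulders), `protein` (amide I 1656/1640,
#' amide II 1548), `phosphorus` (P=O 1240, P-O-C 1083) and a constant
#' carboxylate/CH bending band at 1400 cm^-1.
#'
#' @return Data frame `center`, `sigma`, `factor`, `weight`.
#' @export
synthetic_band_roster <- function() {
  data.frame(
    center = c(2924, 2853, 1742, 1725, 1709, 1656, 1640, 1548, 1400, 1240, 1083),
    sigma  = c(  14,   14,    8,    8,    8,   10,   10,   10,    9,   10,   11),
    factor = c("lipid", "lipid", "lipid", "lipid", "lipid",
               "protein", "protein", "protein", "constant",
               "phosphorus", "phosphorus"),
    weight = c(6.0, 3.5, 4.0, 1.2, 0.8, 1.0, 0.35, 0.55, 0.30, 0.5, 0.9),
    stringsAsFactors = FALSE)
}

#' Instrument wavenumber grid of the synthetic panel
#'
#' @param high,low span in cm^-1.
#' @param spacing digital spacing in cm^-1 (default 1.928).
#' @return Descending numeric grid.
#' @export
ftir_grid <- function(high = 4000, low = 400, spacing = 1.928) {
  seq(high, low, by = -spacing)
}

#' Generate a synthetic strain panel with a ground-truth ledger
#'
#' Builds a seeded panel of bacterial strains (Gram-positive and
#' Gram-negative genera grown at 5/15/25 degrees C) together with everything
#' needed to render GC peak tables and FTIR spectra, plus the latent truth
#' the analysis is meant to recover:
#'
#' * per (strain, temperature): a fatty-acid composition drawn around the
#'   Gram-specific template with a temperature shift (Gram-negative
#'   monounsaturates rise in the cold; Gram-positive branched saturates rise
#'   with warmth) and Dirichlet compositional noise;
#' * a true total lipid fraction of biomass, sampled uniformly on
#'   `lipid_range` per strain and mildly increased at colder growth;
#' * true FTIR band amplitudes coupled to the same latent lipid fraction
#'   (so the L/P-vs-lipid correlation has a known positive population value),
#'   a protein factor and a phosphorus factor;
#' * per-spectrum multiplicative gain and degree-2 baseline coefficients —
#'   exactly the artifact family EMSC removes.
#'
#' Psychrophilic strains are never assigned 25 degrees C. The same seed
#' reproduces the panel bit-identically.
#'
#' @param n_strains_per_genus strains per roster genus (default 1).
#' @param temperatures growth temperatures offered, degrees C.
#' @param bio_replicates biological replicates per (strain, temperature).
#' @param tech_replicates technical FTIR replicates per biological replicate.
#' @param effect_size multiplier on the temperature-response log-weight
#'   shifts (0 switches the temperature effect off).
#' @param dirichlet_conc Dirichlet concentration of the compositional noise
#'   (larger = tighter around the template).
#' @param lipid_range sampling interval for the true lipid fraction
#'   (default `c(0.04, 0.19)`, the realistic whole-cell range).
#' @param lipid_temp_slope relative increase of the lipid fraction per 10
#'   degrees of cooling below 15 degrees C.
#' @param roster genus roster, see [default_genus_roster()].
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_truth`: `strains`, `conditions`
#'   (one row per strain x temperature, with lipid/protein/phosphorus
#'   factors), `composition` (matrix of FA fractions), `spectra` (one row per
#'   rendered spectrum with its gain/baseline truth), `bands`, `params`,
#'   `seed`.
#' @export
generate_panel <- function(n_strains_per_genus = 1,
                           temperatures = c(5, 15, 25),
                           bio_replicates = 2, tech_replicates = 3,
                           effect_size = 1, dirichlet_conc = 400,
                           lipid_range = c(0.04, 0.19),
                           lipid_temp_slope = 0.15,
                           roster = default_genus_roster(), seed = 1) {
  stopifnot(n_strains_per_genus >= 1, bio_replicates >= 1,
            tech_replicates >= 1, dirichlet_conc > 0,
            length(lipid_range) == 2, lipid_range[1] > 0,
            diff(lipid_range) >= 0)
  if (!all(c("genus", "phylum", "gram", "lifestyle") %in% names(roster)))
    stop("generate_panel: roster needs genus/phylum/gram/lifestyle columns",
         call. = FALSE)
  if (!all(roster$gram %in% c("negative", "positive")))
    stop("generate_panel: roster 'gram' must be negative/positive",
         call. = FALSE)
  seed <- as.integer(seed)

  strains <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    data.frame(strain_id = sprintf("%s_%02d", substr(roster$genus[i], 1, 3),
                                   seq_len(n_strains_per_genus) +
                                     (i - 1) * n_strains_per_genus),
               genus = roster$genus[i], phylum = roster$phylum[i],
               gram = roster$gram[i], lifestyle = roster$lifestyle[i],
               stringsAsFactors = FALSE)
  }))
  rownames(strains) <- NULL

  templates <- fa_templates()
  directions <- fa_temperature_directions()
  all_labels <- unique(c(names(templates$negative), names(templates$positive)))

  with_sub_seed(seed, {
    conditions <- NULL
    comp <- NULL
    for (i in seq_len(nrow(strains))) {
      st <- strains[i, ]
      temps <- temperatures
      if (st$lifestyle == "psychrophile") temps <- setdiff(temps, 25)
      base_lipid <- stats::runif(1, lipid_range[1], lipid_range[2])
      for (T in temps) {
        coldness <- (15 - T) / 10
        tem <- templates[[st$gram]]
        dir <- directions[[st$gram]][names(tem)]
        w <- tem * exp(effect_size * coldness * dir)
        w <- w / sum(w)
        frac <- rdirichlet_one(dirichlet_conc * w)
        lipid <- base_lipid * (1 + lipid_temp_slope * coldness)
        lipid <- min(max(lipid, 0.02), 0.25)
        protein <- stats::rlnorm(1, 0, 0.05)
        phosphorus <- stats::runif(1, 0.3, 0.8)
        conditions <- rbind(conditions, data.frame(
          strain_id = st$strain_id, genus = st$genus, phylum = st$phylum,
          gram = st$gram, lifestyle = st$lifestyle, temperature = T,
          lipid_fraction = lipid, protein_factor = protein,
          phosphorus_factor = phosphorus, stringsAsFactors = FALSE))
        row <- stats::setNames(numeric(length(all_labels)), all_labels)
        row[names(frac)] <- frac
        comp <- rbind(comp, row)
      }
    }
    rownames(conditions) <- NULL
    rownames(comp) <- paste(conditions$strain_id, conditions$temperature,
                            sep = "@")

    # per-spectrum instrument artifacts (the family EMSC removes)
    spectra <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(k) {
      expand.grid(condition = k, bio_replicate = seq_len(bio_replicates),
                  tech_replicate = seq_len(tech_replicates))
    }))
    n_sp <- nrow(spectra)
    spectra <- cbind(conditions[spectra$condition,
                                c("strain_id", "genus", "phylum", "gram",
                                  "lifestyle", "temperature")],
                     spectra[c("bio_replicate", "tech_replicate")],
                     data.frame(gain = stats::runif(n_sp, 0.7, 1.3),
                                base0 = stats::runif(n_sp, 0, 0.2),
                                base1 = stats::runif(n_sp, -0.05, 0.05),
                                base2 = stats::runif(n_sp, -0.03, 0.03)))
    rownames(spectra) <- NULL
    spectra$spectrum_id <- sprintf("%s_T%02d_b%d_t%d", spectra$strain_id,
                                   spectra$temperature,
                                   spectra$bio_replicate,
                                   spectra$tech_replicate)

    structure(list(strains = strains, conditions = conditions,
                   composition = comp, spectra = spectra,
                   bands = synthetic_band_roster(),
                   params = list(n_strains_per_genus = n_strains_per_genus,
                                 temperatures = temperatures,
                                 bio_replicates = bio_replicates,
                                 tech_replicates = tech_replicates,
                                 effect_size = effect_size,
                                 dirichlet_conc = dirichlet_conc,
                                 lipid_range = lipid_range,
                                 lipid_temp_slope = lipid_temp_slope),
                   seed = seed),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$strains), " strains, ",
      nrow(x$conditions), " strain x temperature conditions, ",
      nrow(x$spectra), " spectra planned (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @keywords internal
truth_condition <- function(truth, strain_id, temperature) {
  k <- which(truth$conditions$strain_id == strain_id &
               truth$conditions$temperature == temperature)
  if (length(k) != 1L)
    stop("no synthetic-truth entry for strain '", strain_id, "' at ",
         temperature, " degrees C", call. = FALSE)
  k
}

#' Render a GC-FID peak table from the synthetic truth
#'
#' Inverse of the quantification stage: true per-acid masses (lipid fraction
#' x biomass x composition) are turned into peak areas through the response
#' factors and an arbitrary detector gain, the internal-standard row is added
#' consistently with `is_mass_mg`, and multiplicative log-normal noise with
#' coefficient of variation `noise_cv` is applied per peak. Rendering is
#' deterministic given the panel seed and the (strain, temperature,
#' replicate) coordinates.
#'
#' @param truth a [generate_panel()] result.
#' @param strain_id,temperature condition coordinates.
#' @param bio_replicate biological replicate index (only used to decorrelate
#'   the noise streams).
#' @param noise_cv coefficient of variation of the multiplicative area noise.
#' @param rrf an [rrf_table()] or `NULL` (all 1).
#' @param gain arbitrary detector gain applied to every area.
#' @param biomass_dry_mg dry biomass per extraction, mg (default 20).
#' @param is_label,is_mass_mg internal-standard specification.
#' @return A [peak_table()].
#' @export
render_peak_table <- function(truth, strain_id, temperature,
                              bio_replicate = 1, noise_cv = 0, rrf = NULL,
                              gain = 1, biomass_dry_mg = 20,
                              is_label = "C19:0",
                              is_mass_mg = is_mass_c19_pc()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  k <- truth_condition(truth, strain_id, temperature)
  frac <- truth$composition[k, ]
  frac <- frac[frac > 0]
  mass <- truth$conditions$lipid_fraction[k] * biomass_dry_mg * frac
  areas <- gain * c(mass / rrf_lookup(rrf, names(mass)),
                    stats::setNames(is_mass_mg, is_label))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    areas <- with_sub_seed(
      sub_seed(truth$seed, strain_id, temperature, bio_replicate, 17L),
      areas * stats::rlnorm(length(areas), -sdlog^2 / 2, sdlog))
  }
  peak_table(sprintf("%s_T%02d_b%d", strain_id, temperature, bio_replicate),
             names(areas), unname(areas), biomass_dry_mg,
             is_label = is_label, is_mass_mg = is_mass_mg)
}

# Analytic artifact-free signal: sum of Gaussian bands with amplitudes tied
# to the condition's latent factors.
#' @keywords internal
synthetic_signal <- function(truth, k, wavenumbers) {
  cond <- truth$conditions[k, ]
  bands <- truth$bands
  fac <- c(lipid = cond$lipid_fraction, protein = cond$protein_factor,
           phosphorus = cond$phosphorus_factor, constant = 1)
  amps <- bands$weight * fac[bands$factor]
  sig <- numeric(length(wavenumbers))
  for (j in seq_len(nrow(bands)))
    sig <- sig + amps[j] * exp(-(wavenumbers - bands$center[j])^2 /
                                 (2 * bands$sigma[j]^2))
  sig
}

#' True band amplitudes of a synthetic condition
#'
#' @param truth a [generate_panel()] result.
#' @param strain_id,temperature condition coordinates.
#' @return Named numeric vector of Gaussian amplitudes per band center.
#' @export
true_band_amplitudes <- function(truth, strain_id, temperature) {
  k <- truth_condition(truth, strain_id, temperature)
  cond <- truth$conditions[k, ]
  bands <- truth$bands
  fac <- c(lipid = cond$lipid_fraction, protein = cond$protein_factor,
           phosphorus = cond$phosphorus_factor, constant = 1)
  stats::setNames(bands$weight * fac[bands$factor], bands$center)
}

#' Render an FTIR spectrum from the synthetic truth
#'
#' Evaluates the condition's Gaussian-band signal on the instrument grid,
#' applies the spectrum's stored multiplicative gain and degree-2 polynomial
#' baseline (on the wavenumber axis mapped to `[-1, 1]`), and adds Gaussian
#' noise of standard deviation `noise_sd`. With `artifacts = FALSE` the
#' clean signal is returned, which is what EMSC-corrected preprocessing
#' should recover up to gain normalization.
#'
#' @param truth a [generate_panel()] result.
#' @param strain_id,temperature,bio_replicate,tech_replicate spectrum
#'   coordinates (must exist in `truth$spectra`).
#' @param noise_sd additive noise standard deviation (absorbance units;
#'   default 0.01, about 1 percent of the amide I height).
#' @param artifacts apply the stored gain/baseline truth.
#' @param wavenumbers instrument grid (default [ftir_grid()]).
#' @return A [spectra_set()] holding the single spectrum, metadata included.
#' @export
render_spectrum <- function(truth, strain_id, temperature, bio_replicate = 1,
                            tech_replicate = 1, noise_sd = 0.01,
                            artifacts = TRUE, wavenumbers = ftir_grid()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  k <- truth_condition(truth, strain_id, temperature)
  sp <- truth$spectra
  r <- which(sp$strain_id == strain_id & sp$temperature == temperature &
               sp$bio_replicate == bio_replicate &
               sp$tech_replicate == tech_replicate)
  if (length(r) != 1L)
    stop("render_spectrum: no such replicate in the truth ledger",
         call. = FALSE)
  sig <- synthetic_signal(truth, k, wavenumbers)
  if (artifacts) {
    x <- 2 * (wavenumbers - min(wavenumbers)) /
      (max(wavenumbers) - min(wavenumbers)) - 1
    sig <- sp$gain[r] * sig + sp$base0[r] + sp$base1[r] * x + sp$base2[r] * x^2
  }
  if (noise_sd > 0) {
    sig <- with_sub_seed(
      sub_seed(truth$seed, strain_id, temperature, bio_replicate,
               tech_replicate, 31L),
      sig + stats::rnorm(length(sig), 0, noise_sd))
  }
  spectra_set(wavenumbers, sig, sp[r, c("spectrum_id", "strain_id", "genus",
                                        "phylum", "gram", "lifestyle",
                                        "temperature", "bio_replicate",
                                        "tech_replicate"), drop = FALSE])
}

#' Render the whole panel
#'
#' Convenience wrapper producing every GC peak table (one per strain x
#' temperature x biological replicate) and the full FTIR [spectra_set()]
#' (biological x technical replicates) from a truth ledger.
#'
#' @param truth a [generate_panel()] result.
#' @param noise_cv GC area noise, see [render_peak_table()].
#' @param noise_sd FTIR additive noise, see [render_spectrum()].
#' @param rrf,biomass_dry_mg,is_label,is_mass_mg forwarded to
#'   [render_peak_table()].
#' @return List with `peak_tables` (list of [peak_table()]), `spectra`
#'   (a [spectra_set()]) and `gc_meta` (per-peak-table metadata).
#' @export
render_panel <- function(truth, noise_cv = 0.05, noise_sd = 0.01,
                         rrf = NULL, biomass_dry_mg = 20,
                         is_label = "C19:0", is_mass_mg = is_mass_c19_pc()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cond <- truth$conditions
  nb <- truth$params$bio_replicates
  gc_meta <- do.call(rbind, lapply(seq_len(nrow(cond)), function(k)
    data.frame(sample_id = sprintf("%s_T%02d_b%d", cond$strain_id[k],
                                   cond$temperature[k], seq_len(nb)),
               strain_id = cond$strain_id[k], genus = cond$genus[k],
               phylum = cond$phylum[k], gram = cond$gram[k],
               lifestyle = cond$lifestyle[k],
               temperature = cond$temperature[k],
               bio_replicate = seq_len(nb),
               biomass_dry_mg = biomass_dry_mg,
               stringsAsFactors = FALSE)))
  rownames(gc_meta) <- NULL
  peak_tables <- lapply(seq_len(nrow(gc_meta)), function(i)
    render_peak_table(truth, gc_meta$strain_id[i], gc_meta$temperature[i],
                      gc_meta$bio_replicate[i], noise_cv = noise_cv,
                      rrf = rrf, biomass_dry_mg = biomass_dry_mg,
                      is_label = is_label, is_mass_mg = is_mass_mg))
  names(peak_tables) <- gc_meta$sample_id

  grid <- ftir_grid()
  sp <- truth$spectra
  vals <- matrix(NA_real_, nrow(sp), length(grid))
  for (i in seq_len(nrow(sp))) {
    s <- render_spectrum(truth, sp$strain_id[i], sp$temperature[i],
                         sp$bio_replicate[i], sp$tech_replicate[i],
                         noise_sd = noise_sd, wavenumbers = grid)
    vals[i, ] <- s$values[1, ]
  }
  spectra <- spectra_set(grid, vals,
                         sp[, c("spectrum_id", "strain_id", "genus", "phylum",
                                "gram", "lifestyle", "temperature",
                                "bio_replicate", "tech_replicate")])
  list(peak_tables = peak_tables, spectra = spectra, gc_meta = gc_meta)
}
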
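#' Quantifiable internal-standard acyl mass from di-C19:0 phosphatidylcholine
#'
#' The internal standard is added as 1,2-dinonadecanoyl-sn-glycero-3-
#' phosphocholine (di-C19:0 PC); only its two acyl chains are released as
#' C19:0 methyl ester during transesterification. This helper converts the
#' added PC mass into the equivalent quantifiable C19:0 mass using molar
#' masses computed from molecular formulas: PC C46H92NO8P, free acid C19H38O2,
#' methyl ester C20H40O2.
#'
#' @param pc_mass_mg mass of PC added, mg (default 0.5, i.e. 50 uL of a
#'   10 mg/mL solution).
#' @param basis report the standard on the free-acid (`"acid"`) or methyl
#'   ester (`"fame"`) mass basis.
#' @return C19:0 mass in mg.
#' @export
is_mass_c19_pc <- function(pc_mass_mg = 0.5, basis = c("acid", "fame")) {
  basis <- match.arg(basis)
  amu <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974)
  m_pc   <- 46 * amu["C"] + 92 * amu["H"] + amu["N"] + 8 * amu["O"] + amu["P"]
  m_acid <- 19 * amu["C"] + 38 * amu["H"] + 2 * amu["O"]
  m_fame <- 20 * amu["C"] + 40 * amu["H"] + 2 * amu["O"]
  unname(pc_mass_mg * 2 * (if (basis == "acid") m_acid else m_fame) / m_pc)
}

#' GC-FID peak table for one sample
#'
#' Bundles the integrated peak areas of one chromatogram with the sample's
#' dry-biomass mass and the internal-standard specification.
#'
#' @param sample_id sample identifier.
#' @param fa_label character vector of peak labels.
#' @param area numeric vector of integrated peak areas (arbitrary detector
#'   units, nonnegative).
#' @param biomass_dry_mg dry biomass weighed into the extraction, mg (> 0).
#' @param is_label label of the internal-standard peak (default `"C19:0"`).
#' @param is_mass_mg quantifiable internal-standard mass, mg; default derived
#'   from 0.5 mg of di-C19:0 PC via [is_mass_c19_pc()].
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(sample_id, fa_label, area, biomass_dry_mg,
                       is_label = "C19:0", is_mass_mg = is_mass_c19_pc()) {
  stopifnot(length(fa_label) == length(area))
  if (any(is.na(area)) || any(area < 0))
    stop("peak_table: areas must be nonnegative", call. = FALSE)
  if (!is.numeric(biomass_dry_mg) || biomass_dry_mg <= 0)
    stop("peak_table: biomass_dry_mg must be positive", call. = FALSE)
  if (is_mass_mg <= 0)
    stop("peak_table: is_mass_mg must be positive", call. = FALSE)
  structure(
    list(sample_id = as.character(sample_id),
         rows = data.frame(fa_label = as.character(fa_label), area = area,
                           stringsAsFactors = FALSE),
         biomass_dry_mg = biomass_dry_mg,
         is_label = is_label, is_mass_mg = is_mass_mg),
    class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", x$sample_id, ": ", nrow(x$rows), " peaks, ",
      x$biomass_dry_mg, " mg biomass, IS ", x$is_label,
      " (", signif(x$is_mass_mg, 4), " mg)\n", sep = "")
  invisible(x)
}

#' Relative response factor lookup table
#'
#' FID response differs slightly between analytes; relative response factors
#' (RRFs) correct peak areas to the internal-standard response. Published RRF
#' tables can be supplied; unlisted labels fall back to `default`.
#'
#' @param labels character vector of fatty-acid labels (may be empty).
#' @param factors positive numeric vector, same length as `labels`.
#' @param default factor applied to unlisted labels (default 1).
#' @return An object of class `rrf_table`; use [rrf_lookup()] to query it.
#' @export
rrf_table <- function(labels = character(), factors = numeric(), default = 1) {
  stopifnot(length(labels) == length(factors))
  if (any(factors <= 0) || default <= 0)
    stop("rrf_table: response factors must be positive", call. = FALSE)
  structure(list(map = stats::setNames(as.numeric(factors), labels),
                 default = default),
            class = "rrf_table")
}

#' @rdname rrf_table
#' @param rrf an `rrf_table` (or `NULL` for all-1 factors).
#' @param label labels to look up.
#' @export
rrf_lookup <- function(rrf, label) {
  if (is.null(rrf)) return(rep(1, length(label)))
  stopifnot(inherits(rrf, "rrf_table"))
  out <- unname(rrf$map[label])
  out[is.na(out)] <- rrf$default
  out
}

#' Convert peak areas to fatty-acid masses via the internal standard
#'
#' Implements internal-standard quantification: for every non-standard peak,
#' `mass_i = (area_i / area_IS) * is_mass_mg * rrf_i`. The internal-standard
#' row is consumed by the calculation and removed from the output. Peaks whose
#' labels the parser rejects are still quantified (they surface later as
#' unknown fatty acids); nothing is silently discarded.
#'
#' @param pt a [peak_table()].
#' @param rrf an [rrf_table()] or `NULL` (all factors 1).
#' @return Data frame (`sample_id`, `fa_label`, `mass_mg`, `percent`) with the
#'   biomass carried in attribute `biomass_dry_mg`.
#' @export
quantify_fames <- function(pt, rrf = NULL) {
  stopifnot(inherits(pt, "peak_table"))
  is_idx <- which(pt$rows$fa_label == pt$is_label)
  if (length(is_idx) == 0L)
    stop("quantify_fames: internal-standard peak '", pt$is_label,
         "' not found in sample '", pt$sample_id, "'", call. = FALSE)
  is_area <- sum(pt$rows$area[is_idx])
  if (is_area <= 0)
    stop("quantify_fames: internal-standard area is zero in sample '",
         pt$sample_id, "'", call. = FALSE)
  rows <- pt$rows[-is_idx, , drop = FALSE]
  mass <- rows$area / is_area * pt$is_mass_mg * rrf_lookup(rrf, rows$fa_label)
  total <- sum(mass)
  out <- data.frame(sample_id = rep(pt$sample_id, nrow(rows)),
                    fa_label = rows$fa_label,
                    mass_mg = mass,
                    percent = if (total > 0) 100 * mass / total else 0 * mass,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "biomass_dry_mg") <- pt$biomass_dry_mg
  out
}

#' Total lipid content as percent of cell dry weight
#'
#' Sum of all quantified FAME masses (the internal standard is already
#' excluded by [quantify_fames()]) divided by the dry biomass.
#'
#' @param profile output of [quantify_fames()].
#' @param biomass_dry_mg dry biomass in mg; defaults to the value carried on
#'   the profile.
#' @return Percent of cell dry weight (w/w), a nonnegative scalar.
#' @export
total_lipid_content <- function(profile,
                                biomass_dry_mg = attr(profile, "biomass_dry_mg")) {
  stopifnot(is.data.frame(profile))
  if (is.null(biomass_dry_mg) || !is.numeric(biomass_dry_mg) ||
      biomass_dry_mg <= 0)
    stop("total_lipid_content: biomass_dry_mg must be positive", call. = FALSE)
  100 * sum(profile$mass_mg) / biomass_dry_mg
}

#' Read GC peak tables from delimited text
#'
#' Expects a long table with header `sample_id, fa_label, area` and a metadata
#' table carrying `sample_id, biomass_dry_mg` (extra metadata columns are
#' ignored here and joined downstream).
#'
#' @param peaks_file path to the delimited peak file (tab- or comma-separated,
#'   autodetected from the extension).
#' @param metadata data frame or path with at least `sample_id` and
#'   `biomass_dry_mg`.
#' @param is_label,is_mass_mg internal-standard specification, see
#'   [peak_table()].
#' @return List of [peak_table()] objects, one per sample.
#' @export
read_peak_tables <- function(peaks_file, metadata,
                             is_label = "C19:0",
                             is_mass_mg = is_mass_c19_pc()) {
  peaks <- read_delim_auto(peaks_file)
  stopifnot(all(c("sample_id", "fa_label", "area") %in% names(peaks)))
  if (is.character(metadata)) metadata <- read_delim_auto(metadata)
  stopifnot(all(c("sample_id", "biomass_dry_mg") %in% names(metadata)))
  lapply(split(peaks, peaks$sample_id), function(p) {
    sid <- p$sample_id[1]
    bm <- metadata$biomass_dry_mg[match(sid, metadata$sample_id)]
    if (is.na(bm))
      stop("read_peak_tables: no biomass metadata for sample '", sid, "'",
           call. = FALSE)
    peak_table(sid, p$fa_label, p$area, bm, is_label, is_mass_mg)
  })
}
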
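#' Define an absorption band
#'
#' @param name band name (e.g. `"ester_CO"`, `"amide_I"`).
#' @param center nominal band center, cm^-1.
#' @param search_halfwidth half-width of the search window around `center`,
#'   cm^-1 (default 8; must be at least one grid step for extremum search).
#' @param mode `"local_extremum_in_window"` (default; robust to a few cm^-1 of
#'   band-position drift) or `"height_at_center"` (value at the grid point
#'   nearest the center).
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, center, search_halfwidth = 8,
                            mode = c("local_extremum_in_window",
                                     "height_at_center")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(center), center > 0, search_halfwidth >= 0)
  structure(list(name = name, center = center,
                 search_halfwidth = search_halfwidth, mode = mode),
            class = "band_definition")
}

#' Evaluate a band on every spectrum of a set
#'
#' In extremum mode the band value is the maximum (of the absolute value when
#' `magnitude = TRUE`, appropriate for second-derivative spectra) within the
#' search window; in height mode it is the value at the grid point nearest
#' the band center. The wavenumber actually selected is reported alongside
#' the value.
#'
#' @param set a [spectra_set()] (ratio-path preprocessed).
#' @param band a [band_definition()].
#' @param magnitude use `|value|` (second-derivative convention).
#' @return Data frame `spectrum_id`, `band`, `value`, `wavenumber`.
#' @export
band_value <- function(set, band, magnitude = FALSE) {
  stopifnot(inherits(set, "spectra_set"), inherits(band, "band_definition"))
  w <- set$wavenumbers
  if (band$mode == "height_at_center") {
    if (band$center > max(w) || band$center < min(w))
      stop("band_value: band center ", band$center,
           " cm-1 outside the spectrum span", call. = FALSE)
    idx <- rep(which.min(abs(w - band$center)), n_spectra(set))
  } else {
    win <- which(abs(w - band$center) <= band$search_halfwidth)
    if (!length(win))
      stop("band_value: search window around ", band$center,
           " cm-1 contains no grid points", call. = FALSE)
    v <- set$values[, win, drop = FALSE]
    pick <- apply(if (magnitude) abs(v) else v, 1, which.max)
    idx <- win[pick]
  }
  val <- set$values[cbind(seq_len(n_spectra(set)), idx)]
  if (magnitude) val <- abs(val)
  data.frame(spectrum_id = set$meta$spectrum_id, band = band$name,
             value = val, wavenumber = w[idx], stringsAsFactors = FALSE)
}

#' Lipid/protein and phosphorus/protein band ratios
#'
#' Computes the two compositional estimates per spectrum: the lipid-to-
#' protein ratio L/P from the ester C=O stretching band against the amide I
#' band (defaults 1742/1656 cm^-1), and the phosphorus-to-protein ratio P/P
#' from the P-O-C symmetric stretching band against amide I (defaults
#' 1083/1656 cm^-1). Spectra with a vanishing reference band are flagged
#' invalid rather than dropped. When technical replicates are averaged, the
#' ratios are averaged (not the spectra): the ratio of a mean spectrum is not
#' the mean of ratios.
#'
#' @param set ratio-path preprocessed [spectra_set()].
#' @param lp_bands numerator/denominator centers for L/P, cm^-1.
#' @param pp_bands numerator/denominator centers for P/P, cm^-1.
#' @param search_halfwidth,mode,magnitude see [band_value()].
#' @param denom_tol minimum admissible reference-band value.
#' @param average_by optional metadata columns; when given, ratios are
#'   averaged over the groups they define (e.g. technical replicates).
#' @return Data frame with the spectrum metadata, band values and selected
#'   wavenumbers, `L_over_P`, `P_over_P`, and a logical `valid` flag (or the
#'   grouped averages when `average_by` is set).
#' @export
compute_ratios <- function(set, lp_bands = c(1742, 1656),
                           pp_bands = c(1083, 1656),
                           search_halfwidth = 8,
                           mode = "local_extremum_in_window",
                           magnitude = FALSE, denom_tol = 1e-12,
                           average_by = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  bv <- function(center, nm)
    band_value(set, band_definition(nm, center, search_halfwidth, mode),
               magnitude = magnitude)
  lp_num <- bv(lp_bands[1], "lp_num"); lp_den <- bv(lp_bands[2], "lp_den")
  pp_num <- bv(pp_bands[1], "pp_num"); pp_den <- bv(pp_bands[2], "pp_den")

  valid <- abs(lp_den$value) > denom_tol & abs(pp_den$value) > denom_tol
  out <- cbind(set$meta,
               data.frame(
                 lp_num = lp_num$value, lp_num_wavenumber = lp_num$wavenumber,
                 lp_den = lp_den$value, lp_den_wavenumber = lp_den$wavenumber,
                 pp_num = pp_num$value, pp_num_wavenumber = pp_num$wavenumber,
                 pp_den = pp_den$value, pp_den_wavenumber = pp_den$wavenumber,
                 L_over_P = ifelse(valid, lp_num$value / lp_den$value, NA_real_),
                 P_over_P = ifelse(valid, pp_num$value / pp_den$value, NA_real_),
                 valid = valid))
  rownames(out) <- NULL
  if (!any(valid))
    warning("compute_ratios: no valid spectra (reference band below tolerance)",
            call. = FALSE)
  if (is.null(average_by)) return(out)

  stopifnot(all(average_by %in% names(out)))
  key <- interaction(out[average_by], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(out, key), function(g) {
    v <- g$valid
    data.frame(g[1, average_by, drop = FALSE],
               L_over_P = mean(g$L_over_P[v]),
               P_over_P = mean(g$P_over_P[v]),
               n_spectra = nrow(g), n_valid = sum(v))
  })
  agg <- do.call(rbind, agg)
  rownames(agg) <- NULL
  agg
}
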
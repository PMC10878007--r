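#' Savitzky-Golay filtering of a spectra set
#'
#' Local least-squares polynomial filtering (smoothing or differentiation)
#' applied per spectrum via `signal::sgolayfilt`. With `deriv_order = 2` the
#' result is the second derivative with respect to wavenumber, scaled by the
#' grid spacing; edge points come from the one-sided window fit (the filter's
#' standard edge mode) and are flagged in the processing log.
#'
#' @param set a [spectra_set()].
#' @param window odd filter window length in points (default 11).
#' @param poly_order local polynomial degree (default 2, must be < window).
#' @param deriv_order derivative order, 0 (smoothing) or 2 (second
#'   derivative).
#' @param uniformity_tol maximum allowed relative deviation of the grid
#'   spacing from uniformity.
#' @return A [spectra_set()] of filtered spectra.
#' @export
savgol <- function(set, window = 11, poly_order = 2, deriv_order = 0,
                   uniformity_tol = 1e-6) {
  stopifnot(inherits(set, "spectra_set"))
  if (window %% 2 != 1 || window <= poly_order)
    stop("savgol: 'window' must be odd and greater than 'poly_order'",
         call. = FALSE)
  if (!deriv_order %in% c(0, 2))
    stop("savgol: 'deriv_order' must be 0 or 2", call. = FALSE)
  d <- diff(set$wavenumbers)
  spacing <- abs(mean(d))
  if (max(abs(abs(d) - spacing)) > uniformity_tol * spacing)
    stop("savgol: wavenumber grid is not uniform; resample the spectra ",
         "onto an even grid first", call. = FALSE)
  out <- set
  out$values <- t(apply(set$values, 1, function(y)
    signal::sgolayfilt(y, p = poly_order, n = window, m = deriv_order,
                       ts = spacing)))
  log_step(out, sprintf("savgol(window=%d, order=%d, deriv=%d; edges one-sided)",
                        window, poly_order, deriv_order))
}

#' Default uninformative regions removed before EMSC
#'
#' @return List of `(high, low)` cm^-1 pairs: 4000-3100 (water/OH), 2800-1800
#'   (signal-free gap) and 900-400 cm^-1.
#' @export
default_remove_regions <- function() {
  list(c(4000, 3100), c(2800, 1800), c(900, 400))
}

#' Remove spectral regions
#'
#' Drops the grid points covered by the removal intervals. The retained
#' regions are the closed gaps between removed intervals (and between them
#' and the grid span), so a point shared between a removed and a retained
#' interval — e.g. 3100 cm^-1 with the defaults — is kept, while points
#' strictly inside a removed interval are always dropped.
#'
#' @param set a [spectra_set()].
#' @param remove list of `c(high, low)` wavenumber pairs in cm^-1.
#' @return A [spectra_set()] restricted to the retained grid.
#' @export
cut_regions <- function(set, remove = default_remove_regions()) {
  stopifnot(inherits(set, "spectra_set"))
  if (length(remove) == 0) return(set)
  w <- set$wavenumbers
  iv <- lapply(remove, function(r) c(hi = max(r), lo = min(r)))
  iv <- iv[order(-vapply(iv, `[[`, 0, "hi"))]
  keep <- rep(FALSE, length(w))
  cur_hi <- max(w)
  for (r in iv) {
    if (r["hi"] < cur_hi)
      keep <- keep | (w <= cur_hi & w >= r["hi"])
    cur_hi <- min(cur_hi, r["lo"])
  }
  if (cur_hi >= min(w)) keep <- keep | (w <= cur_hi)
  if (!any(keep))
    stop("cut_regions: no grid points left after removal", call. = FALSE)
  out <- set
  out$wavenumbers <- w[keep]
  out$values <- set$values[, keep, drop = FALSE]
  log_step(out, sprintf("cut_regions(%s)",
                        paste(vapply(remove, function(iv)
                          sprintf("%g-%g", max(iv), min(iv)), ""),
                          collapse = ", ")))
}

#' Select a single spectral region
#'
#' Keeps grid points in the closed interval `[low, high]`.
#'
#' @param set a [spectra_set()].
#' @param span `c(high, low)` in cm^-1.
#' @return A [spectra_set()].
#' @export
select_region <- function(set, span = c(1900, 900)) {
  stopifnot(inherits(set, "spectra_set"))
  hi <- max(span); lo <- min(span)
  keep <- set$wavenumbers >= lo & set$wavenumbers <= hi
  if (!any(keep))
    stop("select_region: no grid points inside [", lo, ", ", hi, "]",
         call. = FALSE)
  out <- set
  out$wavenumbers <- set$wavenumbers[keep]
  out$values <- set$values[, keep, drop = FALSE]
  log_step(out, sprintf("select_region(%g-%g)", hi, lo))
}

# Legendre polynomials on the wavenumber grid affinely mapped to [-1, 1];
# well-conditioned baseline basis for EMSC.
#' @keywords internal
emsc_poly_basis <- function(wavenumbers, degree) {
  x <- 2 * (wavenumbers - min(wavenumbers)) /
    (max(wavenumbers) - min(wavenumbers)) - 1
  P <- matrix(NA_real_, length(x), degree + 1)
  P[, 1] <- 1
  if (degree >= 1) P[, 2] <- x
  if (degree >= 2) for (k in 2:degree)
    P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
  colnames(P) <- paste0("a", 0:degree)
  P
}

#' Fit an extended multiplicative signal correction (EMSC) model
#'
#' For every spectrum `y` in the set, fits the ordinary least squares model
#' `y = a0*P0 + ... + ad*Pd + b*reference + e`, where `P0..Pd` are Legendre
#' polynomials on the wavenumber axis mapped to `[-1, 1]` and `reference` is
#' a common reference spectrum. The multiplicative coefficient `b` captures
#' scatter/thickness gain, the polynomial part captures the baseline.
#'
#' @param set a [spectra_set()] (typically second-derivative, region-cut).
#' @param reference `"mean"` (arithmetic mean spectrum of the set) or a
#'   numeric vector on the same grid.
#' @param poly_degree baseline polynomial degree (default 2).
#' @return An object of class `emsc_model`: the reference, the basis, and a
#'   coefficient matrix with columns `a0..ad`, `b` plus per-spectrum residual
#'   norms.
#' @export
emsc_fit <- function(set, reference = "mean", poly_degree = 2) {
  stopifnot(inherits(set, "spectra_set"), n_spectra(set) >= 1)
  if (is.character(reference)) {
    stopifnot(identical(reference, "mean"))
    reference <- colMeans(set$values)
  }
  stopifnot(length(reference) == length(set$wavenumbers))
  P <- emsc_poly_basis(set$wavenumbers, poly_degree)
  X <- cbind(P, b = as.numeric(reference))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("emsc_fit: singular design (reference collinear with the baseline ",
         "polynomials)", call. = FALSE)
  coef <- t(qr.coef(qrX, t(set$values)))
  fitted <- coef %*% t(X)
  resid_norm <- sqrt(rowSums((set$values - fitted)^2))
  structure(list(reference = as.numeric(reference),
                 wavenumbers = set$wavenumbers,
                 poly_degree = poly_degree, basis = P,
                 coefficients = coef, residual_norm = resid_norm,
                 spectrum_id = set$meta$spectrum_id),
            class = "emsc_model")
}

#' @export
print.emsc_model <- function(x, ...) {
  cat("<emsc_model> degree ", x$poly_degree, ", ",
      nrow(x$coefficients), " spectra, b in [",
      signif(min(x$coefficients[, "b"]), 4), ", ",
      signif(max(x$coefficients[, "b"]), 4), "]\n", sep = "")
  invisible(x)
}

#' Apply an EMSC correction
#'
#' Subtracts each spectrum's fitted baseline polynomial and divides by its
#' multiplicative coefficient: `corrected = (y - P a) / b`. Spectra whose
#' `|b|` falls below `b_tol` cannot be corrected; they are excluded from the
#' returned set with a warning (their ids are kept in attribute
#' `"excluded"`), never silently dropped.
#'
#' @param set the [spectra_set()] the model was fitted to (or any set on the
#'   same grid).
#' @param model an [emsc_fit()] result.
#' @param b_tol minimum admissible `|b|`.
#' @return The corrected [spectra_set()]; per-spectrum `emsc_b` is added to
#'   the metadata.
#' @export
emsc_correct <- function(set, model, b_tol = 1e-8) {
  stopifnot(inherits(set, "spectra_set"), inherits(model, "emsc_model"))
  if (!isTRUE(all.equal(set$wavenumbers, model$wavenumbers)))
    stop("emsc_correct: set and model grids differ", call. = FALSE)
  coef <- model$coefficients
  if (nrow(coef) != n_spectra(set))
    stop("emsc_correct: model was fitted to a different number of spectra",
         call. = FALSE)
  d <- model$poly_degree
  baseline <- coef[, seq_len(d + 1), drop = FALSE] %*% t(model$basis)
  b <- coef[, "b"]
  ok <- abs(b) >= b_tol
  out <- set
  out$values <- (set$values - baseline) / b
  out$meta$emsc_b <- b
  if (!all(ok)) {
    warning("emsc_correct: excluding ", sum(!ok),
            " uncorrectable spectra (|b| < ", b_tol, "): ",
            paste(set$meta$spectrum_id[!ok], collapse = ", "), call. = FALSE)
    excluded <- set$meta$spectrum_id[!ok]
    out <- out[ok]
    attr(out, "excluded") <- excluded
  }
  log_step(out, sprintf("emsc(degree=%d)", d))
}

#' FTIR preprocessing pipeline for PCA
#'
#' Savitzky-Golay second derivative (order 2, window 11), removal of the
#' uninformative regions (4000-3100, 2800-1800, 900-400 cm^-1), then EMSC
#' against the mean of the derivative, region-cut set.
#'
#' @param set raw absorbance [spectra_set()].
#' @param window,poly_order Savitzky-Golay settings.
#' @param remove removal intervals, see [cut_regions()].
#' @param reference,poly_degree EMSC settings, see [emsc_fit()].
#' @return Corrected [spectra_set()]; the fitted [emsc_fit()] model is
#'   attached as attribute `"emsc_model"`.
#' @export
pipeline_pca <- function(set, window = 11, poly_order = 2,
                         remove = default_remove_regions(),
                         reference = "mean", poly_degree = 2) {
  out <- savgol(set, window = window, poly_order = poly_order, deriv_order = 2)
  out <- cut_regions(out, remove)
  model <- emsc_fit(out, reference = reference, poly_degree = poly_degree)
  out <- emsc_correct(out, model)
  attr(out, "emsc_model") <- model
  out
}

#' FTIR preprocessing pipeline for band-ratio analysis
#'
#' Savitzky-Golay filtering (order 2, window 11; smoothing by default) and
#' selection of the informative 1900-900 cm^-1 region. A second-derivative
#' variant is available via `deriv_order = 2`, in which case band values are
#' read as derivative magnitudes downstream.
#'
#' @param set raw absorbance [spectra_set()].
#' @param window,poly_order,deriv_order Savitzky-Golay settings.
#' @param span retained region, `c(high, low)` cm^-1.
#' @return Filtered, region-selected [spectra_set()].
#' @export
pipeline_ratio <- function(set, window = 11, poly_order = 2, deriv_order = 0,
                           span = c(1900, 900)) {
  out <- savgol(set, window = window, poly_order = poly_order,
                deriv_order = deriv_order)
  select_region(out, span)
}
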
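#' A set of spectra on a shared wavenumber grid
#'
#' Container for FTIR absorbance (or derivative) spectra: a strictly
#' monotonic wavenumber grid, a samples-by-wavenumbers value matrix, and
#' per-row metadata. Instrument grids are stored in descending wavenumber
#' order (spectroscopic convention); an ascending input grid is reversed on
#' construction.
#'
#' @param wavenumbers numeric grid in cm^-1, strictly monotonic.
#' @param values numeric matrix, one row per spectrum, `length(wavenumbers)`
#'   columns. A single spectrum may be given as a vector.
#' @param meta data frame of per-spectrum metadata with at least
#'   `spectrum_id`; a bare character vector of ids is accepted.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, values, meta = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  stopifnot(is.numeric(wavenumbers), ncol(values) == length(wavenumbers))
  d <- diff(wavenumbers)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("spectra_set: wavenumber grid must be strictly monotonic",
         call. = FALSE)
  if (all(d > 0)) {            # normalize to descending order
    wavenumbers <- rev(wavenumbers)
    values <- values[, rev(seq_len(ncol(values))), drop = FALSE]
  }
  if (is.null(meta))
    meta <- data.frame(spectrum_id = paste0("s", seq_len(nrow(values))),
                       stringsAsFactors = FALSE)
  if (is.character(meta))
    meta <- data.frame(spectrum_id = meta, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(meta), nrow(meta) == nrow(values),
            "spectrum_id" %in% names(meta))
  rownames(values) <- meta$spectrum_id
  colnames(values) <- NULL
  structure(list(wavenumbers = as.numeric(wavenumbers), values = values,
                 meta = meta, processing = character()),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$values), " spectra x ", ncol(x$values),
      " points, ", sprintf("%.1f-%.1f cm-1", max(x$wavenumbers),
                           min(x$wavenumbers)), "\n", sep = "")
  if (length(x$processing))
    cat("  processing: ", paste(x$processing, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
`[.spectra_set` <- function(x, i, ...) {
  out <- x
  out$values <- x$values[i, , drop = FALSE]
  out$meta <- x$meta[i, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Number of spectra in a set
#' @param x a [spectra_set()].
#' @export
n_spectra <- function(x) nrow(x$values)

#' @keywords internal
log_step <- function(set, step) {
  set$processing <- c(set$processing, step)
  set
}

#' Read spectra from delimited text
#'
#' Wide layout: first column the wavenumber, one column per spectrum (header
#' row holds spectrum ids). Long layout: header `spectrum_id, wavenumber,
#' absorbance`.
#'
#' @param path file path (`.csv` comma-separated, otherwise tab-separated).
#' @param layout `"wide"` or `"long"`.
#' @param meta optional data frame with `spectrum_id` plus metadata columns,
#'   joined by id.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, layout = c("wide", "long"), meta = NULL) {
  layout <- match.arg(layout)
  df <- read_delim_auto(path)
  if (layout == "wide") {
    w <- df[[1]]
    values <- t(as.matrix(df[, -1, drop = FALSE]))
    ids <- names(df)[-1]
  } else {
    stopifnot(all(c("spectrum_id", "wavenumber", "absorbance") %in% names(df)))
    ids <- unique(df$spectrum_id)
    w <- sort(unique(df$wavenumber), decreasing = TRUE)
    values <- matrix(NA_real_, length(ids), length(w))
    for (k in seq_along(ids)) {
      sub <- df[df$spectrum_id == ids[k], ]
      values[k, ] <- sub$absorbance[match(w, sub$wavenumber)]
    }
    if (anyNA(values))
      stop("read_spectra: long input does not cover a common grid", call. = FALSE)
  }
  m <- data.frame(spectrum_id = ids, stringsAsFactors = FALSE)
  if (!is.null(meta)) m <- merge(m, meta, by = "spectrum_id", sort = FALSE)
  spectra_set(w, values, m)
}

#' Write spectra as wide delimited text
#'
#' @param set a [spectra_set()].
#' @param path output path (tab-separated).
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  df <- data.frame(wavenumber = set$wavenumbers, t(set$values),
                   check.names = FALSE)
  names(df)[-1] <- set$meta$spectrum_id
  write_tsv_plain(df, path)
}
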
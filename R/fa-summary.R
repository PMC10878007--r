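#' Columns of a fatty-acid class summary
#' @keywords internal
fa_summary_columns <- function() {
  c("PUFAs", "n_SFAs", "br_SFAs", "n_MUFAs", "hydroxy_FAs", "cyclic_FAs",
    "br_UFA_unknown", "unknown_FAs", "minor_FA_pool",
    "SCFAs", "MCFAs", "LCFAs", "VLCFAs",
    "cis_FAs", "trans_FAs", "iso_FAs", "anteiso_FAs")
}

#' Summarize a fatty-acid weight profile into class abundances
#'
#' Converts per-acid weights into relative percentages of the total fatty-acid
#' weight and sums them into the disjoint structural classes (PUFAs, n-SFAs,
#' br-SFAs, n-MUFAs, hydroxy-FAs, cyclic-FAs), plus chain-length, geometry
#' (cis/trans) and branching (iso/anteiso) sums. Acids whose relative
#' abundance does not exceed `minor_threshold_pct` are pooled into
#' `minor_FA_pool` and excluded from every class sum ("only FAs with content
#' higher than the threshold enter the analysis"). Labels the parser cannot
#' interpret are never dropped: their weight is carried as `unknown_FAs`, so
#' structural classes + unknown + minor always account for 100%.
#'
#' @param profile data frame with columns `fa_label` and `mass_mg` (any
#'   nonnegative weight works; percentages are scale-invariant), and
#'   optionally `sample_id` for multi-sample input.
#' @param minor_threshold_pct pooling threshold in percent (default 1; strict:
#'   acids at exactly the threshold are pooled).
#' @param c6_class passed to [chain_length_class()].
#' @return Data frame, one row per sample: `sample_id`, the structural-class
#'   percentages, `unknown_FAs`, `minor_FA_pool`, chain-length sums and
#'   cis/trans and iso/anteiso sums (all percent of total fatty-acid weight).
#' @export
summarize_profile <- function(profile, minor_threshold_pct = 1,
                              c6_class = "MCFA") {
  stopifnot(is.data.frame(profile),
            all(c("fa_label") %in% names(profile)))
  wcol <- intersect(c("mass_mg", "weight", "mass"), names(profile))[1]
  if (is.na(wcol))
    stop("summarize_profile: profile needs a 'mass_mg' (or 'weight') column",
         call. = FALSE)
  if (any(profile[[wcol]] < 0))
    stop("summarize_profile: negative weights", call. = FALSE)
  if (!"sample_id" %in% names(profile)) profile$sample_id <- "sample"

  res <- lapply(split(profile, profile$sample_id), function(p) {
    total <- sum(p[[wcol]])
    if (total <= 0)
      stop("summarize_profile: all-zero profile for sample '",
           p$sample_id[1], "'", call. = FALSE)
    pct <- 100 * p[[wcol]] / total
    desc <- lapply(p$fa_label, function(l) tryCatch(parse_fa_label(l),
                                                    error = function(e) NULL))
    parsed <- !vapply(desc, is.null, logical(1))
    minor <- pct <= minor_threshold_pct

    out <- stats::setNames(numeric(length(fa_summary_columns())),
                           fa_summary_columns())
    out["minor_FA_pool"] <- sum(pct[minor])
    out["unknown_FAs"] <- sum(pct[!parsed & !minor])
    keep <- parsed & !minor
    for (i in which(keep)) {
      d <- desc[[i]]
      sc <- fa_class_plural(structural_class(d))
      out[sc] <- out[sc] + pct[i]
      cl <- chain_length_class(d, c6_class)
      if (cl != "out_of_range")
        out[paste0(cl, "s")] <- out[paste0(cl, "s")] + pct[i]
      if (d$geometry == "cis") out["cis_FAs"] <- out["cis_FAs"] + pct[i]
      if (d$geometry == "trans") out["trans_FAs"] <- out["trans_FAs"] + pct[i]
      if (d$branch == "iso") out["iso_FAs"] <- out["iso_FAs"] + pct[i]
      if (d$branch == "anteiso")
        out["anteiso_FAs"] <- out["anteiso_FAs"] + pct[i]
    }
    cbind(data.frame(sample_id = p$sample_id[1], stringsAsFactors = FALSE),
          as.data.frame(as.list(out)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# structural_class() returns singular names; summaries use pluralized column
# names. Map here so both sides stay readable.
#' @keywords internal
fa_class_plural <- function(cls) {
  ifelse(cls == "br_UFA_unknown", cls, paste0(cls, "s"))
}

#' Reshape a class summary to tidy long format
#'
#' @param summary output of [summarize_profile()].
#' @return Data frame with columns `sample_id`, `class`, `percent`.
#' @export
fa_class_long <- function(summary) {
  cols <- setdiff(names(summary), "sample_id")
  out <- do.call(rbind, lapply(cols, function(cl)
    data.frame(sample_id = summary$sample_id, class = cl,
               percent = summary[[cl]], stringsAsFactors = FALSE)))
  out[order(out$sample_id, out$class), , drop = FALSE]
}
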
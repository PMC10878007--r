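#' Default run configuration
#'
#' Nested list of every stage parameter. The defaults reproduce the study
#' conditions the synthetic panel emulates: 18 genera grown at 5/15/25
#' degrees C with 2 biological replicates (GC) and 3 technical FTIR
#' replicates each, Savitzky-Golay order 2 / window 11, EMSC degree 2, band
#' ratios 1742/1656 and 1083/1656 cm^-1, 1 percent minor-FA pooling.
#'
#' @param seed integer seed for the synthetic panel and all noise.
#' @param out_dir optional output directory; when set, every table is written
#'   as tab-separated text and the resolved config as YAML.
#' @return Configuration list, merge-overridable field by field.
#' @export
default_config <- function(seed = 1, out_dir = NULL) {
  list(
    seed = seed,
    out_dir = out_dir,
    panel = list(n_strains_per_genus = 1, temperatures = c(5, 15, 25),
                 bio_replicates = 2, tech_replicates = 3,
                 effect_size = 1, dirichlet_conc = 400,
                 lipid_range = c(0.04, 0.19), lipid_temp_slope = 0.15,
                 noise_cv = 0.05, noise_sd = 0.01),
    gc = list(minor_threshold_pct = 1, is_label = "C19:0",
              biomass_dry_mg = 20, rrf = NULL),
    ftir = list(window = 11, poly_order = 2, ratio_deriv_order = 0,
                lp_bands = c(1742, 1656), pp_bands = c(1083, 1656),
                search_halfwidth = 8, emsc_poly_degree = 2),
    groupings = c("gram", "phylum", "genus", "temperature"))
}

#' Load a configuration from a YAML file
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @keywords internal
merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

# Group means with sd reported only for groups of two or more members
# (singletons get NA, never 0).
#' @keywords internal
aggregate_stats <- function(df, value_cols, by) {
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, key), function(g) {
    row <- g[1, by, drop = FALSE]
    row$n <- nrow(g)
    for (v in value_cols) {
      row[[paste0(v, "_mean")]] <- mean(g[[v]], na.rm = TRUE)
      row[[paste0(v, "_sd")]] <-
        if (sum(!is.na(g[[v]])) >= 2) stats::sd(g[[v]], na.rm = TRUE)
        else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(key[!duplicated(key)]), , drop = FALSE]
}

#' Run the GC branch of the pipeline
#'
#' Quantifies every peak table against the internal standard, computes total
#' lipid content (% of cell dry weight), summarizes fatty-acid classes,
#' aggregates by genus and temperature (standard deviation only for groups
#' represented by two or more members), and runs PCA on the autoscaled
#' structural-class matrix. Samples whose metadata join fails are reported
#' and skipped; the run continues for the valid ones.
#'
#' @param peak_tables list of [peak_table()] objects.
#' @param metadata data frame keyed by `sample_id` with at least `genus` and
#'   `temperature`.
#' @param config configuration list, see [default_config()].
#' @return List of tables: `total_lipid`, `class_summary`, `class_long`,
#'   `class_aggregate`, `lipid_aggregate`, `pca` (a [pca_fit()] result),
#'   `pca_scores`, `pca_loadings`, `pca_variance`, `errors`.
#' @export
run_gc <- function(peak_tables, metadata, config = default_config()) {
  stopifnot(is.list(peak_tables), is.data.frame(metadata))
  errors <- data.frame(sample_id = character(), error = character())
  profiles <- list(); tl <- list()
  for (pt in peak_tables) {
    res <- tryCatch({
      prof <- quantify_fames(pt, config$gc$rrf)
      list(profile = prof,
           tl = data.frame(sample_id = pt$sample_id,
                           total_lipid_pct = total_lipid_content(prof)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(sample_id = pt$sample_id,
                                         error = conditionMessage(res)))
    } else {
      profiles[[pt$sample_id]] <- res$profile
      tl[[pt$sample_id]] <- res$tl
    }
  }
  if (!length(profiles))
    stop("run_gc: no sample could be quantified", call. = FALSE)
  tl <- do.call(rbind, tl); rownames(tl) <- NULL

  missing <- setdiff(tl$sample_id, metadata$sample_id)
  if (length(missing)) {
    errors <- rbind(errors, data.frame(sample_id = missing,
                                       error = "no metadata entry"))
    tl <- tl[!tl$sample_id %in% missing, , drop = FALSE]
    profiles <- profiles[tl$sample_id]
  }
  tl <- merge(metadata, tl, by = "sample_id", sort = TRUE)

  summary <- summarize_profile(do.call(rbind, profiles),
                               config$gc$minor_threshold_pct)
  summary <- merge(metadata, summary, by = "sample_id", sort = TRUE)

  class_cols <- c("PUFAs", "n_SFAs", "br_SFAs", "n_MUFAs", "hydroxy_FAs",
                  "cyclic_FAs", "br_UFA_unknown", "unknown_FAs")
  agg_class <- aggregate_stats(summary, class_cols, c("genus", "temperature"))
  agg_lipid <- aggregate_stats(tl, "total_lipid_pct", c("genus", "temperature"))

  feat <- as.matrix(summary[, class_cols])
  rownames(feat) <- summary$sample_id
  pca <- pca_fit(suppressWarnings(autoscale(feat)))
  scores <- cbind(summary[, intersect(c("sample_id", "genus", "phylum",
                                        "gram", "temperature"),
                                      names(summary))],
                  as.data.frame(pca$scores))

  list(total_lipid = tl, class_summary = summary,
       class_long = fa_class_long(summary[, c("sample_id", class_cols,
                                              "minor_FA_pool")]),
       class_aggregate = agg_class, lipid_aggregate = agg_lipid,
       pca = pca, pca_scores = scores,
       pca_loadings = data.frame(feature = rownames(pca$loadings),
                                 as.data.frame(pca$loadings)),
       pca_variance = data.frame(
         component = colnames(pca$scores),
         explained_variance_fraction =
           pca$explained_variance_fraction[seq_len(ncol(pca$scores))]),
       errors = errors)
}

#' Run the FTIR branch of the pipeline
#'
#' Applies the PCA-path preprocessing (second derivative, region cutting,
#' EMSC) and runs mean-centered PCA on the corrected matrix; applies the
#' ratio-path preprocessing (smoothing, 1900-900 cm^-1) and computes the
#' L/P and P/P band ratios, averaged over technical replicates.
#'
#' @param spectra raw absorbance [spectra_set()] whose metadata carries
#'   `strain_id`, `genus`, `phylum`, `gram`, `temperature`, `bio_replicate`,
#'   `tech_replicate`.
#' @param config configuration list, see [default_config()].
#' @return List: `ratios` (per spectrum), `ratios_bio` (averaged over
#'   technical replicates), `ratio_aggregate` (by genus x temperature),
#'   `pca`, `pca_scores`, `pca_variance`, `corrected` (the EMSC-corrected
#'   set), `n_excluded` (uncorrectable spectra count).
#' @export
run_ftir <- function(spectra, config = default_config()) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (n_spectra(spectra) == 0)
    stop("run_ftir: empty spectra set", call. = FALSE)
  f <- config$ftir

  corrected <- pipeline_pca(spectra, window = f$window,
                            poly_order = f$poly_order,
                            poly_degree = f$emsc_poly_degree)
  n_excluded <- length(attr(corrected, "excluded") %||% character())
  if (n_excluded > 0)
    message("run_ftir: ", n_excluded, " uncorrectable spectra excluded")
  pca <- pca_fit(corrected$values,
                 n_components = min(10, n_spectra(corrected) - 1,
                                    ncol(corrected$values)))
  keep_meta <- intersect(c("spectrum_id", "strain_id", "genus", "phylum",
                           "gram", "temperature", "bio_replicate",
                           "tech_replicate"), names(corrected$meta))
  scores <- cbind(corrected$meta[, keep_meta, drop = FALSE],
                  as.data.frame(pca$scores))

  ratio_set <- pipeline_ratio(spectra, window = f$window,
                              poly_order = f$poly_order,
                              deriv_order = f$ratio_deriv_order)
  ratios <- compute_ratios(ratio_set, lp_bands = f$lp_bands,
                           pp_bands = f$pp_bands,
                           search_halfwidth = f$search_halfwidth,
                           magnitude = f$ratio_deriv_order == 2)
  by_bio <- intersect(c("strain_id", "genus", "phylum", "gram", "lifestyle",
                        "temperature", "bio_replicate"), names(ratios))
  ratios_bio <- compute_ratios(ratio_set, lp_bands = f$lp_bands,
                               pp_bands = f$pp_bands,
                               search_halfwidth = f$search_halfwidth,
                               magnitude = f$ratio_deriv_order == 2,
                               average_by = by_bio)
  agg <- aggregate_stats(ratios_bio, c("L_over_P", "P_over_P"),
                         intersect(c("genus", "temperature"), by_bio))

  list(ratios = ratios, ratios_bio = ratios_bio, ratio_aggregate = agg,
       pca = pca, pca_scores = scores,
       pca_variance = data.frame(
         component = colnames(pca$scores),
         explained_variance_fraction =
           pca$explained_variance_fraction[seq_len(ncol(pca$scores))]),
       corrected = corrected, n_excluded = n_excluded)
}

#' Run the whole pipeline on the default synthetic panel
#'
#' Generates the seeded panel, renders peak tables and spectra, runs the GC
#' and FTIR branches, joins them at the biological-replicate level (after
#' technical-replicate averaging) and computes the grouped Pearson
#' correlations between the L/P ratio and total lipid content for the whole
#' dataset, by Gram group, phylum, genus and temperature. The run is
#' deterministic: the same configuration and seed reproduce every output
#' bit-identically.
#'
#' @param config configuration list, see [default_config()]. When
#'   `config$out_dir` is set, all tables are written there as tab-separated
#'   text together with the resolved configuration (`config.yaml`).
#' @return List: `truth`, `gc`, `ftir`, `correlations`, `joined`, `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  p <- config$panel
  truth <- generate_panel(n_strains_per_genus = p$n_strains_per_genus,
                          temperatures = p$temperatures,
                          bio_replicates = p$bio_replicates,
                          tech_replicates = p$tech_replicates,
                          effect_size = p$effect_size,
                          dirichlet_conc = p$dirichlet_conc,
                          lipid_range = p$lipid_range,
                          lipid_temp_slope = p$lipid_temp_slope,
                          seed = config$seed)
  panel <- render_panel(truth, noise_cv = p$noise_cv, noise_sd = p$noise_sd,
                        rrf = config$gc$rrf,
                        biomass_dry_mg = config$gc$biomass_dry_mg,
                        is_label = config$gc$is_label)
  gc <- run_gc(panel$peak_tables, panel$gc_meta, config)
  ftir <- run_ftir(panel$spectra, config)

  joined <- merge(ftir$ratios_bio,
                  gc$total_lipid[, c("strain_id", "temperature",
                                     "bio_replicate", "total_lipid_pct")],
                  by = c("strain_id", "temperature", "bio_replicate"),
                  sort = TRUE)
  correlations <- rbind(
    pearson_by_group(joined, "L_over_P", "total_lipid_pct"),
    do.call(rbind, lapply(intersect(config$groupings, names(joined)),
                          function(g)
                            pearson_by_group(joined, "L_over_P",
                                             "total_lipid_pct", g))))
  rownames(correlations) <- NULL

  out <- list(truth = truth, gc = gc, ftir = ftir,
              correlations = correlations, joined = joined, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' @keywords internal
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_tsv_plain(df, file.path(out_dir, name))
  w(res$truth$strains, "metadata_strains.tsv")
  w(res$truth$conditions, "truth_conditions.tsv")
  w(res$gc$total_lipid, "gc_total_lipid.tsv")
  w(res$gc$class_summary, "gc_class_summary.tsv")
  w(res$gc$class_long, "gc_class_long.tsv")
  w(res$gc$class_aggregate, "gc_class_aggregate.tsv")
  w(res$gc$lipid_aggregate, "gc_lipid_aggregate.tsv")
  w(res$gc$pca_scores, "gc_pca_scores.tsv")
  w(res$gc$pca_loadings, "gc_pca_loadings.tsv")
  w(res$gc$pca_variance, "gc_pca_variance.tsv")
  w(res$ftir$ratios, "ftir_ratios.tsv")
  w(res$ftir$ratios_bio, "ftir_ratios_biological.tsv")
  w(res$ftir$ratio_aggregate, "ftir_ratio_aggregate.tsv")
  w(res$ftir$pca_scores, "ftir_pca_scores.tsv")
  w(res$ftir$pca_variance, "ftir_pca_variance.tsv")
  w(res$correlations, "correlations.tsv")
  cfg <- res$config
  cfg$out_dir <- NULL
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
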
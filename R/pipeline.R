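# End-to-end orchestration: read -> quantify -> differential -> reversion
# -> QC (-> PRM), with a deterministic manifest. Outputs are staged and
# copied only on success so a failing run leaves no partial result tables.

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full quantification and differential pipeline
#'
#' Executes every stage on one PSM dataset: protein roll-up from unique
#' non-phosphorylated peptides, total-intensity normalization,
#' phosphosite-localization filtering and phosphopeptide roll-up,
#' phospho normalization by the non-phosphorylated proteome,
#' transfection-effect filtering, the differential z-test + BH calling
#' chain for each comparison on both layers, protein-level adjustment of
#' phospho ratios, reversion classification, group-profile PCA, and PRM
#' quantification when transition data are supplied. All result tables,
#' the normalization factors and a run manifest are written to `out_dir`;
#' identical inputs and configuration give byte-identical outputs.
#'
#' @param psms PSM table or path to one (see [read_psm_table()]).
#' @param design Design data frame or path (see [read_design()]).
#' @param prm Optional PRM transition table or path.
#' @param out_dir Output directory (created if needed).
#' @param localization Phosphosite localization acceptance threshold
#'   (default 0.75).
#' @param distinct Distinct-site threshold (default 0.99).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param transfection_window Log2 half-width of the transfection filter
#'   (default 0.2).
#' @param reversion_band Reversion band as fraction of SC-IL (default
#'   `c(0.5, 0.7)`).
#' @param dot_threshold PRM dot-product acceptance threshold (default 0.95).
#' @param comparisons List of [comparison()]s (default
#'   [canonical_comparisons()]).
#' @param seed Seed echoed into the manifest and table headers (the
#'   pipeline itself is deterministic; the seed documents how the inputs
#'   were generated).
#' @param quiet Suppress stage messages (default TRUE).
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(psms, design, prm = NULL, out_dir,
                         localization = 0.75, distinct = 0.99,
                         alpha = 0.05, transfection_window = 0.2,
                         reversion_band = c(0.5, 0.7),
                         dot_threshold = 0.95,
                         comparisons = canonical_comparisons(),
                         seed = NA, quiet = TRUE) {
  stopifnot(localization >= 0, localization <= 1,
            alpha > 0, alpha < 1, transfection_window >= 0,
            all(reversion_band > 0), all(reversion_band < 1),
            dot_threshold >= 0, dot_threshold <= 1)
  note <- if (quiet) suppressMessages else identity

  psms <- pipeline_stage("read", {
    if (is.character(psms)) read_psm_table(psms) else annotate_psms(psms)
  })
  design <- pipeline_stage("read", {
    if (is.character(design)) read_design(design) else validate_design(design)
  })
  if (!is.null(prm) && is.character(prm))
    prm <- pipeline_stage("read", read_prm_table(prm))

  stage_dir <- tempfile("phosphoTMT_run_")
  dir.create(stage_dir)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  manifest <- list(
    pipeline_version = as.character(utils::packageVersion("phosphoTMT")),
    seed = seed, localization_threshold = localization,
    distinct_threshold = distinct, adjusted_p_threshold = alpha,
    transfection_window = transfection_window,
    reversion_band = paste(reversion_band, collapse = ","),
    dot_product_threshold = dot_threshold,
    groups = paste(unique(design$group), collapse = ","),
    comparisons = paste(vapply(comparisons, `[[`, character(1), "name"),
                        collapse = ","),
    n_psms = nrow(psms))

  # --- quantify ---------------------------------------------------------
  protein_raw <- pipeline_stage("quantify", note(rollup_proteins(psms, design)))
  protein <- pipeline_stage("quantify", normalize_total_intensity(protein_raw))
  manifest$n_proteins <- nrow(protein$values)

  has_phospho <- any(psms$n_phospho > 0)
  phospho <- NULL
  if (has_phospho) {
    loc <- pipeline_stage("quantify",
                          filter_phospho_localization(psms, localization,
                                                      distinct))
    phospho_raw <- pipeline_stage(
      "quantify", note(rollup_phosphopeptides(loc$accepted, design)))
    phospho <- pipeline_stage(
      "quantify", normalize_phospho_by_nonphospho(phospho_raw, protein_raw))
    ov <- pipeline_stage("quantify", overlap_summary(phospho, protein))
    manifest$n_phosphopeptides <- nrow(phospho$values)
    manifest$n_phosphosites <- unname(loc$summary["n_phosphosites"])
    manifest$n_phosphoproteins <- unname(loc$summary["n_phosphoproteins"])
    manifest$overlap_fraction <- signif(ov$overlap_fraction, 6)
    write_result_table(
      data.frame(metric = names(unlist(ov)), value = unlist(ov)),
      file.path(stage_dir, "overlap.tsv"), seed)
    write_result_table(
      data.frame(metric = names(loc$summary), value = unname(loc$summary)),
      file.path(stage_dir, "phospho_filter_summary.tsv"), seed)
  }
  write_quant_matrix(protein, file.path(stage_dir, "protein_matrix.tsv"))
  if (!is.null(phospho))
    write_quant_matrix(phospho, file.path(stage_dir, "phospho_matrix.tsv"))

  # --- differential -----------------------------------------------------
  layers <- list(protein = protein)
  if (!is.null(phospho)) layers$phosphopeptide <- phospho
  results <- list()
  transfection <- list()
  for (ly in names(layers)) {
    tf <- pipeline_stage("differential", note(
      transfection_filter(layers[[ly]], design, transfection_window)))
    transfection[[ly]] <- tf
    write_result_table(tf, file.path(stage_dir,
                                     paste0("transfection_", ly, ".tsv")),
                       seed)
    for (cmp in comparisons) {
      res <- pipeline_stage("differential", note(
        differential_test(layers[[ly]], design, cmp, tf, alpha)))
      results[[ly]][[cmp$name]] <- res
      write_result_table(
        res, file.path(stage_dir,
                       paste0("diff_", ly, "_", cmp$name, ".tsv")), seed)
      manifest[[paste0("n_significant_", ly, "_", cmp$name)]] <-
        sum(res$significant)
    }
  }

  # protein-level adjustment of phospho ratios
  if (!is.null(phospho)) {
    parents <- stats::setNames(phospho$feature_meta$protein,
                               phospho$feature_meta$feature)
    for (cmp in comparisons) {
      nm <- cmp$name
      if (!is.null(results$phosphopeptide[[nm]]) &&
          !is.null(results$protein[[nm]])) {
        adj <- pipeline_stage("differential", adjust_phospho_for_protein(
          results$phosphopeptide[[nm]], results$protein[[nm]], parents))
        results$phospho_adjusted[[nm]] <- adj
        write_result_table(
          adj, file.path(stage_dir, paste0("phospho_adjusted_", nm, ".tsv")),
          seed)
      }
    }
  }

  # --- reversion --------------------------------------------------------
  il_name <- "SC-IL_vs_SC"; kd_name <- "DMT1-KD-IL_vs_SC-IL"
  reversion <- list()
  if (all(c(il_name, kd_name) %in% names(results$protein))) {
    for (ly in names(layers)) {
      rv <- pipeline_stage("reversion", classify_reversion(
        results[[ly]][[il_name]], results[[ly]][[kd_name]],
        layers[[ly]], design, reversion_band))
      reversion[[ly]] <- rv
      write_result_table(rv, file.path(stage_dir,
                                       paste0("reversion_", ly, ".tsv")),
                         seed)
      manifest[[paste0("n_reverted_", ly)]] <-
        sum(rv$category == "reverted")
    }
  }

  # --- QC ---------------------------------------------------------------
  qc <- list()
  for (ly in names(layers)) {
    prof <- pipeline_stage("qc", note(group_profiles(layers[[ly]], design)))
    pca <- pipeline_stage("qc", pca_scores(prof))
    qc[[ly]] <- list(profile = prof, pca = pca)
    sc <- data.frame(group = rownames(pca$scores), pca$scores,
                     stringsAsFactors = FALSE, check.names = FALSE)
    write_result_table(sc, file.path(stage_dir,
                                     paste0("qc_pca_", ly, ".tsv")), seed)
    write_result_table(
      data.frame(component = paste0("PC", seq_along(pca$var_explained)),
                 var_explained = pca$var_explained),
      file.path(stage_dir, paste0("qc_pca_var_", ly, ".tsv")), seed)
  }

  # --- PRM --------------------------------------------------------------
  prm_res <- NULL
  if (!is.null(prm)) {
    prm_res <- pipeline_stage("prm", quantify_prm(prm, dot_threshold))
    write_result_table(prm_res, file.path(stage_dir, "prm_results.tsv"),
                       seed)
    if (nrow(prm_res) >= 3) {
      co <- pipeline_stage("prm", coelution_check(prm_res))
      write_result_table(
        data.frame(peptide = names(co$light_rt),
                   light_apex_rt = unname(co$light_rt),
                   heavy_apex_rt = unname(co$heavy_rt),
                   pearson_r = co$r,
                   flagged = names(co$light_rt) %in% co$flagged),
        file.path(stage_dir, "prm_coelution.tsv"), seed)
      manifest$prm_coelution_r <- signif(co$r, 6)
    }
    manifest$n_prm_peptides <- nrow(prm_res)
    manifest$n_prm_accepted <- sum(prm_res$accepted)
  }

  # --- manifest and publish --------------------------------------------
  mdf <- data.frame(key = names(manifest),
                    value = vapply(manifest, function(x)
                      paste(format(x, trim = TRUE), collapse = ","),
                      character(1)),
                    stringsAsFactors = FALSE)
  utils::write.table(mdf, file.path(stage_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c("phosphoTMT run summary",
               sprintf("%s: %s", mdf$key, mdf$value)),
             file.path(stage_dir, "summary.txt"))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(stage_dir))
    file.copy(file.path(stage_dir, f), file.path(out_dir, f),
              overwrite = TRUE)

  invisible(list(protein = protein, phospho = phospho,
                 transfection = transfection, results = results,
                 reversion = reversion, qc = qc, prm = prm_res,
                 manifest = manifest, out_dir = out_dir))
}
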
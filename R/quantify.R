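# Roll-up of PSMs to protein / phosphopeptide quantification matrices,
# total-intensity normalization and phosphosite filtering.

#' Quantification matrix
#'
#' Features x samples abundance container with normalization-factor
#' provenance. Values are non-negative reals; missing values are `NA`.
#'
#' @param values Numeric matrix, rownames = feature ids, colnames = sample
#'   ids (`group/replicate`).
#' @param layer `"protein"` or `"phosphopeptide"`.
#' @param norm_factors Optional named per-sample multiplicative factors.
#' @param feature_meta Optional data frame of per-feature annotation (e.g.
#'   parent protein of a phosphopeptide), keyed by `feature`.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, layer = c("protein", "phosphopeptide"),
                         norm_factors = NULL, feature_meta = NULL) {
  layer <- match.arg(layer)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0, na.rm = TRUE))
    stop("data error: negative abundance")
  if (!is.null(norm_factors)) {
    if (is.null(names(norm_factors)) ||
        !setequal(names(norm_factors), colnames(values)))
      stop("norm_factors must be named by sample")
    norm_factors <- norm_factors[colnames(values)]
  }
  structure(list(values = values, layer = layer,
                 norm_factors = norm_factors, feature_meta = feature_meta),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix [%s]: %d features x %d samples; %s\n",
              x$layer, nrow(x$values), ncol(x$values),
              if (is.null(x$norm_factors)) "unnormalized" else "normalized"))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

# map PSM channel columns to design sample ids; returns a per-PSM x sample
# intensity matrix (long rows collapsed by plex membership)
psm_sample_matrix <- function(psms, design) {
  channels <- psm_channels(psms)
  absent <- setdiff(unique(design$channel), channels)
  if (length(absent))
    stop("design error: design channel(s) absent from PSM table: ",
         paste(absent, collapse = ", "))
  m <- matrix(NA_real_, nrow(psms), nrow(design),
              dimnames = list(NULL, design$sample))
  for (i in seq_len(nrow(design))) {
    in_plex <- psms$plex_id == design$plex[i]
    m[in_plex, i] <- psms[[design$channel[i]]][in_plex]
  }
  m
}

# sum with all-NA -> NA (missingness propagates; observed cells are summed)
sum_obs <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)

rollup_by <- function(psms, design, key) {
  m <- psm_sample_matrix(psms, design)
  feats <- sort(unique(key))
  idx <- split(seq_along(key), factor(key, levels = feats))
  v <- t(vapply(idx, function(i)
    apply(m[i, , drop = FALSE], 2, sum_obs), numeric(ncol(m))))
  dimnames(v) <- list(feats, design$sample)
  v
}

#' Roll PSMs up to protein abundances
#'
#' Only unique (single-protein) and non-phosphorylated peptides contribute,
#' so the resulting layer is the non-phosphorylated protein abundance used
#' downstream for normalization-factor computation. Protein abundance per
#' sample is the sum of contributing PSM intensities; missing cells are
#' skipped, and a protein unobserved in every sample is dropped (count
#' reported via `message`).
#'
#' @param psms Annotated PSM table.
#' @param design Validated `GroupDesign`.
#' @return A protein-layer [quant_matrix()].
#' @export
rollup_proteins <- function(psms, design) {
  design <- validate_design(design)
  keep <- psms$is_unique & psms$n_phospho == 0
  if (!any(keep))
    stop("pipeline error: no quantifiable proteins ",
         "(no unique non-phosphorylated peptides)")
  sub <- psms[keep, , drop = FALSE]
  attr(sub, "channels") <- psm_channels(psms)
  v <- rollup_by(sub, design, sub$protein_accessions)
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing)) {
    message(sum(all_missing), " protein(s) dropped: no observed intensity")
    v <- v[!all_missing, , drop = FALSE]
  }
  quant_matrix(v, layer = "protein")
}

#' Normalize a matrix to equal total intensity
#'
#' Per-sample factor = mean of all samples' totals divided by the sample's
#' total (totals over the sample's non-missing cells); all abundances of a
#' sample are multiplied by its factor, so post-normalization totals are
#' equal. The factors are the per-sample loading corrections expected to
#' fall in roughly \[0.9, 1.1\] for well-balanced TMT channels.
#'
#' @param qm A [quant_matrix()].
#' @return The normalized matrix with `norm_factors` recorded.
#' @export
normalize_total_intensity <- function(qm) {
  v <- qm$values
  if (ncol(v) < 2) stop("need at least two samples to normalize")
  totals <- colSums(v, na.rm = TRUE)
  if (any(totals <= 0))
    stop("data error: zero total intensity in sample(s): ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  factors <- mean(totals) / totals
  qm$values <- sweep(v, 2, factors, `*`)
  qm$norm_factors <- factors
  qm
}

#' Compute per-sample normalization factors of a matrix
#'
#' @param qm A [quant_matrix()].
#' @return Named numeric vector of factors (mean total / sample total).
#' @export
normalization_factors <- function(qm) {
  totals <- colSums(qm$values, na.rm = TRUE)
  if (any(totals <= 0))
    stop("data error: zero total intensity in sample(s): ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  mean(totals) / totals
}

#' Filter phosphopeptide PSMs by localization probability
#'
#' A PSM is accepted iff every reported phosphosite localization
#' probability reaches `threshold` (inclusive). Accepted sites whose
#' probability strictly exceeds `distinct` are additionally classed
#' "distinct" (confidently localized to a single residue). Summary counts
#' (unique phosphopeptides, phosphosites, phosphoproteins, distinct-site
#' fraction) are attached.
#'
#' @param psms Annotated PSM table (only rows with phospho annotations are
#'   considered).
#' @param threshold Acceptance cutoff (default 0.75, inclusive).
#' @param distinct Distinct-class cutoff (default 0.99, exclusive).
#' @return List with `accepted` (PSM subset), `sites` (one row per site of
#'   every phospho PSM: probabilities, accepted/distinct flags) and
#'   `summary` (named counts).
#' @export
filter_phospho_localization <- function(psms, threshold = 0.75,
                                        distinct = 0.99) {
  stopifnot(threshold >= 0, threshold <= 1)
  ph <- which(psms$n_phospho > 0)
  if (!length(ph))
    stop("data error: no phosphorylated PSMs to filter")
  sites_l <- parse_modifications(psms$modifications[ph])
  probs <- lapply(sites_l, `[[`, "probability")
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop("data error: localization probability outside [0, 1]")
  ok <- vapply(probs, function(p) all(p >= threshold), logical(1))
  site_tab <- do.call(rbind, lapply(seq_along(ph), function(k) {
    d <- sites_l[[k]]
    d$psm_id <- psms$psm_id[ph[k]]
    d$psm_accepted <- ok[k]
    d
  }))
  site_tab$distinct <- site_tab$psm_accepted & site_tab$probability > distinct
  accepted <- psms[ph[ok], , drop = FALSE]
  attr(accepted, "channels") <- psm_channels(psms)

  acc_sites <- site_tab[site_tab$psm_accepted, , drop = FALSE]
  key <- phosphopeptide_key(accepted$peptide_sequence,
                            accepted$modifications)
  uniq_parent <- accepted$protein_accessions[accepted$is_unique]
  # phosphosites: unique (peptide sequence, position) pairs among accepted
  pos_key <- unique(data.frame(
    seqn = accepted$peptide_sequence[match(acc_sites$psm_id, accepted$psm_id)],
    pos = acc_sites$position))
  summary <- c(
    n_phospho_psms = length(ph),
    n_accepted_psms = nrow(accepted),
    n_phosphopeptides = length(unique(key)),
    n_phosphosites = nrow(pos_key),
    n_phosphoproteins = length(unique(uniq_parent)),
    distinct_site_fraction =
      if (nrow(acc_sites)) mean(acc_sites$distinct) else NA_real_)
  list(accepted = accepted, sites = site_tab, summary = summary)
}

#' Phosphopeptide feature key
#'
#' Feature identity for the phosphopeptide layer: peptide sequence plus the
#' sorted phosphosite residues/positions, so the same sequence with
#' different site sets yields distinct features.
#'
#' @param sequence Peptide sequences.
#' @param modifications Modification annotation strings.
#' @return Character vector of keys, e.g. `"PEPSTIDE|S3,T5"`.
#' @export
phosphopeptide_key <- function(sequence, modifications) {
  sites <- parse_modifications(modifications)
  tag <- vapply(sites, function(d) {
    if (!nrow(d)) return("")
    o <- order(d$position)
    paste(paste0(d$residue[o], d$position[o]), collapse = ",")
  }, character(1))
  paste(sequence, tag, sep = "|")
}

#' Roll accepted phospho PSMs up to phosphopeptide features
#'
#' Aggregates by phosphopeptide key (sequence + site set) via summation;
#' only unique-protein peptides are retained. The parent protein accession
#' is carried in `feature_meta` for protein-level adjustment and overlap
#' summaries.
#'
#' @param accepted Accepted phospho PSMs (see
#'   [filter_phospho_localization()]).
#' @param design Validated `GroupDesign`.
#' @return A phosphopeptide-layer [quant_matrix()].
#' @export
rollup_phosphopeptides <- function(accepted, design) {
  design <- validate_design(design)
  keep <- accepted$is_unique
  if (!any(keep))
    stop("pipeline error: no quantifiable phosphopeptides ",
         "(no unique-protein phospho PSMs)")
  sub <- accepted[keep, , drop = FALSE]
  attr(sub, "channels") <- psm_channels(accepted)
  key <- phosphopeptide_key(sub$peptide_sequence, sub$modifications)
  v <- rollup_by(sub, design, key)
  meta <- unique(data.frame(feature = key,
                            protein = sub$protein_accessions,
                            stringsAsFactors = FALSE))
  meta <- meta[match(rownames(v), meta$feature), , drop = FALSE]
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing)) {
    message(sum(all_missing),
            " phosphopeptide(s) dropped: no observed intensity")
    v <- v[!all_missing, , drop = FALSE]
    meta <- meta[!all_missing, , drop = FALSE]
  }
  quant_matrix(v, layer = "phosphopeptide", feature_meta = meta)
}

#' Normalize the phosphopeptide layer by the non-phosphorylated proteome
#'
#' Per-sample factors are computed from the protein (non-phosphorylated)
#' layer totals, exactly as in [normalize_total_intensity()], and applied
#' to the phosphopeptide layer, so both layers share one loading
#' correction derived from protein abundance.
#'
#' @param phospho Phosphopeptide-layer [quant_matrix()].
#' @param protein Protein-layer [quant_matrix()] (pre-normalization; if it
#'   already carries `norm_factors` those are reused).
#' @return The normalized phosphopeptide matrix with the protein-derived
#'   factors recorded.
#' @export
normalize_phospho_by_nonphospho <- function(phospho, protein) {
  if (!setequal(colnames(phospho$values), colnames(protein$values)))
    stop("design error: phospho and protein layers have different samples")
  factors <- if (!is.null(protein$norm_factors)) protein$norm_factors
             else normalization_factors(protein)
  factors <- factors[colnames(phospho$values)]
  phospho$values <- sweep(phospho$values, 2, factors, `*`)
  phospho$norm_factors <- factors
  phospho
}

#' Proteome / phosphoproteome overlap summary
#'
#' Fraction of phosphoproteins (parents of quantified phosphopeptides) also
#' quantified in the protein layer, plus the Venn counts.
#'
#' @param phospho Phosphopeptide-layer [quant_matrix()] with `feature_meta`.
#' @param protein Protein-layer [quant_matrix()].
#' @return List with `overlap_fraction`, `n_phosphoproteins`, `n_proteins`,
#'   `n_shared`, `n_phospho_only`, `n_protein_only`.
#' @export
overlap_summary <- function(phospho, protein) {
  if (is.null(phospho$feature_meta))
    stop("phospho matrix lacks parent-protein metadata")
  php <- unique(phospho$feature_meta$protein)
  prt <- rownames(protein$values)
  if (!length(php) || !length(prt))
    stop("pipeline error: empty layer in overlap summary")
  shared <- intersect(php, prt)
  list(overlap_fraction = length(shared) / length(php),
       n_phosphoproteins = length(php),
       n_proteins = length(prt),
       n_shared = length(shared),
       n_phospho_only = length(setdiff(php, prt)),
       n_protein_only = length(setdiff(prt, php)))
}
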
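# Differential regulation: replicate-paired log2 ratios, robust z-test with
# Benjamini-Hochberg correction, replicate-direction and transfection-effect
# filters, protein-level adjustment of phospho changes, and classification
# of features reverted towards normal by the knock-down.

#' Define a group comparison
#'
#' @param numerator,denominator Group labels; the replicate ratio is
#'   `log2(numerator / denominator)`.
#' @param name Optional comparison name (default
#'   `"<numerator>_vs_<denominator>"`).
#' @return A `comparison` list.
#' @export
comparison <- function(numerator, denominator, name = NULL) {
  if (identical(numerator, denominator))
    stop("comparison error: numerator equals denominator")
  structure(list(numerator = numerator, denominator = denominator,
                 name = if (is.null(name))
                   paste(numerator, denominator, sep = "_vs_") else name),
            class = "comparison")
}

#' The canonical comparison set of the knock-down study
#'
#' IL-1beta induction in the scrambled control (SC-IL vs SC) and in the
#' untransfected control (CON-IL vs CON), knock-down effect at baseline
#' (DMT1-KD vs SC) and under IL-1beta (DMT1-KD-IL vs SC-IL).
#'
#' @return Named list of [comparison()] objects.
#' @export
canonical_comparisons <- function() {
  cmps <- list(comparison("SC-IL", "SC"),
               comparison("CON-IL", "CON"),
               comparison("DMT1-KD", "SC"),
               comparison("DMT1-KD-IL", "SC-IL"))
  stats::setNames(cmps, vapply(cmps, `[[`, character(1), "name"))
}

#' Replicate-paired log2 ratios
#'
#' For each feature and replicate r, `ratio_r = log2(num_r / den_r)`,
#' pairing the two groups within the biological replicate. Replicates where
#' either value is missing, or the denominator (or numerator) is zero, give
#' `NA`; zero-containing features are counted and reported via `message`,
#' never pseudocounted.
#'
#' @param qm A [quant_matrix()].
#' @param design Validated `GroupDesign`.
#' @param cmp A [comparison()].
#' @return Data frame: `feature`, `ratio_1..n`, `mean_ratio`, `n_used`,
#'   `complete`; attribute `comparison` carries the name.
#' @export
replicate_log2_ratios <- function(qm, design, cmp) {
  design <- validate_design(design)
  for (g in c(cmp$numerator, cmp$denominator))
    if (!g %in% design$group)
      stop("comparison error: group not in design: ", g)
  reps <- sort(unique(design$replicate))
  v <- qm$values
  ratios <- matrix(NA_real_, nrow(v), length(reps),
                   dimnames = list(rownames(v), paste0("ratio_", reps)))
  n_zero <- 0L
  for (k in seq_along(reps)) {
    sn <- sample_id(cmp$numerator, reps[k])
    sd_ <- sample_id(cmp$denominator, reps[k])
    if (!all(c(sn, sd_) %in% colnames(v))) next
    num <- v[, sn]; den <- v[, sd_]
    zero <- (!is.na(num) & num == 0) | (!is.na(den) & den == 0)
    n_zero <- n_zero + sum(zero)
    r <- log2(num / den)
    r[zero] <- NA_real_
    ratios[, k] <- r
  }
  if (n_zero > 0)
    message(n_zero, " zero-intensity replicate pair(s) excluded in ",
            cmp$name)
  out <- data.frame(feature = rownames(v), ratios,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$mean_ratio <- rowMeans(ratios, na.rm = TRUE)
  out$mean_ratio[is.nan(out$mean_ratio)] <- NA_real_
  out$n_used <- rowSums(!is.na(ratios))
  out$complete <- out$n_used == length(reps)
  attr(out, "comparison") <- cmp$name
  attr(out, "replicates") <- reps
  rownames(out) <- NULL
  out
}

ratio_columns <- function(tab) grep("^ratio_", names(tab), value = TRUE)

#' Robust z-test against the empirical null of all features
#'
#' Standardizes each feature's mean log2 ratio against a robust empirical
#' null estimated from all features of the comparison: location = median of
#' mean ratios, scale = 1.4826 x their median absolute deviation. Two-sided
#' p from the standard normal. At least 20 features with ratios are
#' required to estimate the null.
#'
#' @param tab Ratio table from [replicate_log2_ratios()].
#' @return The table with `z` and `p` columns appended.
#' @export
z_test <- function(tab) {
  m <- tab$mean_ratio
  obs <- !is.na(m)
  if (sum(obs) < 20)
    stop("statistical error: need >= 20 features with ratios ",
         "to estimate the null")
  loc <- stats::median(m[obs])
  scale <- stats::mad(m[obs])  # 1.4826 * MAD
  if (scale == 0)
    stop("statistical error: degenerate (constant) ratio distribution")
  tab$z <- (m - loc) / scale
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  tab
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_(i) = min_{j>=i} m p_(j) / j`, clipped at 1,
#' returned in input order); `NA`s are preserved and do not count towards m.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p) {
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop("p value outside [0, 1] at index ", bad[1])
  stats::p.adjust(p, method = "BH")
}

#' Replicate direction consistency
#'
#' TRUE iff all available replicate ratios share a strict sign (all
#' positive or all negative); a zero ratio breaks consistency, and fewer
#' than two available replicates is inconsistent by convention.
#'
#' @param tab Ratio table from [replicate_log2_ratios()].
#' @return Logical vector, one element per feature.
#' @export
direction_consistency <- function(tab) {
  r <- as.matrix(tab[, ratio_columns(tab), drop = FALSE])
  apply(r, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2 && (all(x > 0) || all(x < 0))
  })
}

#' Transfection-effect filter
#'
#' Flags features whose untransfected-vs-scrambled control ratio stays
#' within a log2 window, separately for the unchallenged pair (CON vs SC)
#' and the IL-1beta pair (CON-IL vs SC-IL), removing generic
#' siRNA-delivery artifacts.
#'
#' @param qm A [quant_matrix()].
#' @param design Validated `GroupDesign`.
#' @param window Half-width of the log2 acceptance window (default 0.2,
#'   inclusive).
#' @return Data frame: `feature`, `ctrl_log2` (mean log2 CON/SC),
#'   `il_log2` (mean log2 CON-IL/SC-IL), `pass_ctrl`, `pass_il`; the
#'   acceptance fractions are attached as attribute `acceptance`.
#' @export
transfection_filter <- function(qm, design, window = 0.2) {
  ctrl <- replicate_log2_ratios(qm, design, comparison("CON", "SC"))
  il <- replicate_log2_ratios(qm, design, comparison("CON-IL", "SC-IL"))
  out <- data.frame(feature = ctrl$feature,
                    ctrl_log2 = ctrl$mean_ratio,
                    il_log2 = il$mean_ratio[match(ctrl$feature, il$feature)],
                    stringsAsFactors = FALSE)
  out$pass_ctrl <- !is.na(out$ctrl_log2) & abs(out$ctrl_log2) <= window
  out$pass_il <- !is.na(out$il_log2) & abs(out$il_log2) <= window
  attr(out, "acceptance") <- c(ctrl = mean(out$pass_ctrl),
                               il = mean(out$pass_il))
  out
}

is_il_group <- function(g) grepl("-IL$", g)

# which transfection mask applies to a comparison: comparisons within one
# IL condition use that condition's control pair; comparisons spanning the
# two conditions accept a feature inside either window
transfection_pass_for <- function(tf, cmp, features) {
  i <- match(features, tf$feature)
  il_n <- is_il_group(cmp$numerator)
  il_d <- is_il_group(cmp$denominator)
  if (il_n && il_d) tf$pass_il[i]
  else if (!il_n && !il_d) tf$pass_ctrl[i]
  else tf$pass_ctrl[i] | tf$pass_il[i]
}

#' Differential test for one comparison
#'
#' Full calling chain on one layer and comparison: replicate log2 ratios,
#' robust z-test, BH adjustment (within this comparison and layer),
#' direction consistency, transfection filter, and the conjunctive
#' significance call `adj_p < alpha & direction_consistent &
#' passed_transfection_filter`.
#'
#' @param qm A [quant_matrix()].
#' @param design Validated `GroupDesign`.
#' @param cmp A [comparison()].
#' @param transfection Optional output of [transfection_filter()]; when
#'   `NULL` the filter is not applied (all features pass).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return `DifferentialResult` data frame with per-replicate ratios,
#'   `mean_ratio`, `z`, `p`, `adj_p`, `direction_consistent`,
#'   `transfection_pass` and `significant`.
#' @export
differential_test <- function(qm, design, cmp, transfection = NULL,
                              alpha = 0.05) {
  tab <- replicate_log2_ratios(qm, design, cmp)
  tab <- z_test(tab)
  tab$adj_p <- bh_adjust(tab$p)
  tab$direction_consistent <- direction_consistency(tab)
  tab$transfection_pass <- if (is.null(transfection)) TRUE
    else transfection_pass_for(transfection, cmp, tab$feature)
  tab$transfection_pass[is.na(tab$transfection_pass)] <- FALSE
  tab$significant <- !is.na(tab$adj_p) & tab$adj_p < alpha &
    tab$direction_consistent & tab$transfection_pass
  attr(tab, "alpha") <- alpha
  tab
}

#' Split significant features by direction
#'
#' @param res A [differential_test()] result.
#' @return List with `up` and `down` character vectors of feature ids.
#' @export
call_regulated <- function(res) {
  sig <- res$significant
  list(up = res$feature[sig & res$mean_ratio > 0],
       down = res$feature[sig & res$mean_ratio < 0])
}

#' Adjust phosphopeptide ratios for parent-protein expression
#'
#' Subtracts the parent protein's replicate log2 ratio from the
#' phosphopeptide's, per replicate, isolating phosphorylation-occupancy
#' change from protein-expression change. Features whose parent is not
#' quantified keep their raw ratios and are flagged `adjusted = FALSE`.
#'
#' @param phospho_tab Phospho-layer ratio (or differential) table.
#' @param protein_tab Protein-layer ratio table for the same comparison.
#' @param parents Named character vector: phosphopeptide feature ->
#'   parent protein accession.
#' @return `phospho_tab` with ratio columns replaced by adjusted values,
#'   `mean_ratio` recomputed and an `adjusted` flag appended.
#' @export
adjust_phospho_for_protein <- function(phospho_tab, protein_tab, parents) {
  rc <- ratio_columns(phospho_tab)
  if (!setequal(rc, ratio_columns(protein_tab)))
    stop("comparison error: replicate structure differs between layers")
  parent <- unname(parents[phospho_tab$feature])
  pi <- match(parent, protein_tab$feature)
  adjusted <- !is.na(pi)
  for (cn in rc) {
    pr <- protein_tab[[cn]][pi]
    phospho_tab[[cn]] <- ifelse(adjusted & !is.na(pr),
                                phospho_tab[[cn]] - pr, phospho_tab[[cn]])
  }
  r <- as.matrix(phospho_tab[, rc, drop = FALSE])
  phospho_tab$mean_ratio <- rowMeans(r, na.rm = TRUE)
  phospho_tab$mean_ratio[is.nan(phospho_tab$mean_ratio)] <- NA_real_
  phospho_tab$adjusted <- adjusted
  phospho_tab
}

#' Classify reversion towards normal under the knock-down
#'
#' A feature is `reverted` iff it is significant in the IL-1beta induction
#' comparison (SC-IL vs SC) and in the knock-down-under-IL comparison
#' (DMT1-KD-IL vs SC-IL) with opposite mean-ratio signs, and its
#' replicate-mean linear abundance fraction DMT1-KD-IL / SC-IL falls in
#' `band` (features up in SC-IL) or in the reciprocal band (features down
#' in SC-IL) — i.e. the knock-down pulls it 30--50% back from the IL-1beta
#' level. Features significant only in DMT1-KD-IL vs SC-IL are classed
#' `protective-up` / `protective-down` by sign; everything else is `none`.
#'
#' @param res_il [differential_test()] result for SC-IL vs SC.
#' @param res_kd [differential_test()] result for DMT1-KD-IL vs SC-IL.
#' @param qm The normalized [quant_matrix()] the results came from.
#' @param design Validated `GroupDesign`.
#' @param band Reversion band as a fraction of the SC-IL level (default
#'   `c(0.5, 0.7)`, inclusive).
#' @return `ReversionCall` data frame: `feature`, `category`,
#'   `reversion_fraction` (replicate-mean DMT1-KD-IL / SC-IL), `sig_il`,
#'   `sig_kd`.
#' @export
classify_reversion <- function(res_il, res_kd, qm, design,
                               band = c(0.5, 0.7)) {
  if (is.null(res_il) || is.null(res_kd))
    stop("pipeline error: reversion needs the SC-IL vs SC and ",
         "DMT1-KD-IL vs SC-IL results")
  design <- validate_design(design)
  feats <- res_il$feature
  ki <- match(feats, res_kd$feature)
  sig_il <- res_il$significant
  sig_kd <- res_kd$significant[ki]
  mean_il <- res_il$mean_ratio
  mean_kd <- res_kd$mean_ratio[ki]

  # replicate-mean linear fraction DMT1-KD-IL / SC-IL from the matrix
  reps <- sort(unique(design$replicate))
  v <- qm$values
  fr <- matrix(NA_real_, length(feats), length(reps))
  fi <- match(feats, rownames(v))
  for (k in seq_along(reps)) {
    skd <- sample_id("DMT1-KD-IL", reps[k])
    ssc <- sample_id("SC-IL", reps[k])
    if (all(c(skd, ssc) %in% colnames(v)))
      fr[, k] <- v[fi, skd] / v[fi, ssc]
  }
  frac <- rowMeans(fr, na.rm = TRUE)
  frac[is.nan(frac)] <- NA_real_

  in_band <- !is.na(frac) & ifelse(
    mean_il > 0,
    frac >= band[1] & frac <= band[2],
    frac >= 1 / band[2] & frac <= 1 / band[1])
  opposite <- !is.na(mean_il) & !is.na(mean_kd) &
    sign(mean_il) * sign(mean_kd) < 0
  reverted <- !is.na(sig_il) & !is.na(sig_kd) & sig_il & sig_kd &
    opposite & in_band

  category <- rep("none", length(feats))
  protective <- !is.na(sig_kd) & sig_kd & (!sig_il | is.na(sig_il)) &
    !is.na(mean_kd)
  category[protective & mean_kd > 0] <- "protective-up"
  category[protective & mean_kd < 0] <- "protective-down"
  category[reverted] <- "reverted"

  data.frame(feature = feats, category = category,
             reversion_fraction = frac,
             sig_il = sig_il, sig_kd = sig_kd,
             stringsAsFactors = FALSE)
}
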
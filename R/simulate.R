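# Synthetic-data generator: PSM tables, design tables and PRM transition
# sets with the statistical structure the downstream analysis assumes, plus
# a machine-readable ground truth for recovery testing.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults describe
#' the study layout the pipeline targets: six groups (CON, SC, DMT1-KD and
#' their IL-1beta-exposed counterparts) in three biological replicates, one
#' TMT plex per replicate, per-channel loading biases in \[0.9, 1.1\], and a
#' "regulated by IL-1beta then reverted by the knock-down" feature class
#' whose DMT1-KD-IL level falls to 50--70% of the SC-IL level.
#'
#' Intensities are log-normal: a peptide's base intensity is
#' `exp(N(base_log_intensity_mean, base_log_intensity_sd))` (natural-log
#' scale); group effects, per-feature replicate noise and per-PSM
#' measurement noise act on the log2 scale; the per-sample channel bias is
#' multiplicative.
#'
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein_mean Mean peptides per protein (>= 1; the
#'   count is `1 + Poisson(mean - 1)` so every protein has a peptide).
#' @param phospho_fraction Probability that a peptide of an ordinary protein
#'   is phosphorylated.
#' @param n_replicates Biological replicates per group.
#' @param groups Ordered group labels.
#' @param channel_bias_range Interval the per-sample multiplicative loading
#'   bias is drawn from (uniformly).
#' @param base_log_intensity_mean,base_log_intensity_sd Natural-log location
#'   and spread of peptide base intensities.
#' @param replicate_noise_sd Per feature x sample biological noise SD (log2).
#' @param psm_noise_sd Per PSM x channel measurement noise SD (log2).
#' @param effect_log2fc Magnitude of planted group effects (log2).
#' @param frac_il1b_up,frac_il1b_down Fractions of features up-/down-regulated
#'   by IL-1beta exposure (SC-IL and CON-IL versus unexposed).
#' @param frac_kd_up,frac_kd_down Fractions of features regulated by the
#'   knock-down itself (DMT1-KD and DMT1-KD-IL), drawn from the IL-null pool.
#' @param frac_reverted Fraction of IL-1beta-regulated features whose
#'   DMT1-KD-IL level is pulled back towards normal.
#' @param reversion_band Interval (fraction of the SC-IL level) the reverted
#'   DMT1-KD-IL mean is drawn from, for up-regulated features; the reciprocal
#'   band is used for down-regulated features.
#' @param frac_nonunique Fraction of peptides mapped to a second protein
#'   (excluded from quantification by the unique-peptide rule).
#' @param frac_phospho_only Fraction of proteins observed only through
#'   phosphopeptides, i.e. absent from the non-phospho protein layer.
#' @param localization_prob_mixture List with `p_confident` and Beta shape
#'   pairs `confident_shape`, `ambiguous_shape`; site localization
#'   probabilities are drawn from the two-component mixture.
#' @param missing_rate Probability that a reporter intensity cell is missing.
#' @param prm_n_peptides,prm_n_fragments PRM layout: peptides and fragments
#'   per peptide.
#' @param prm_true_ratios Optional vector of true light/heavy ratios
#'   (recycled); if `NULL`, drawn as `2^U(-1.5, 1.5)`.
#' @param prm_sigma_rt Gaussian elution peak SD (minutes).
#' @param prm_rt_window Scheduled retention-time window width (minutes).
#' @param prm_sample_interval Chromatogram sampling interval (minutes).
#' @param prm_rt_jitter_sd SD of the light-vs-heavy apex jitter (minutes).
#' @param prm_amplitude Heavy-channel apex amplitude of the strongest
#'   fragment (intensity units).
#' @param prm_noise_sd Additive chromatogram noise SD (intensity units).
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   output tables.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1000,
                       peptides_per_protein_mean = 3,
                       phospho_fraction = 0.3,
                       n_replicates = 3,
                       groups = study_groups(),
                       channel_bias_range = c(0.9, 1.1),
                       base_log_intensity_mean = log(1e6),
                       base_log_intensity_sd = 1.2,
                       replicate_noise_sd = 0.2,
                       psm_noise_sd = 0.1,
                       effect_log2fc = 1,
                       frac_il1b_up = 0.05,
                       frac_il1b_down = 0.05,
                       frac_kd_up = 0.02,
                       frac_kd_down = 0.02,
                       frac_reverted = 0.5,
                       reversion_band = c(0.5, 0.7),
                       frac_nonunique = 0.05,
                       frac_phospho_only = 0.05,
                       localization_prob_mixture = list(
                         p_confident = 0.85,
                         confident_shape = c(200, 1),
                         ambiguous_shape = c(8, 8)),
                       missing_rate = 0.02,
                       prm_n_peptides = 5,
                       prm_n_fragments = 6,
                       prm_true_ratios = NULL,
                       prm_sigma_rt = 0.1,
                       prm_rt_window = 3,
                       prm_sample_interval = 0.01,
                       prm_rt_jitter_sd = 0.01,
                       prm_amplitude = 1e6,
                       prm_noise_sd = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_proteins < 1 || cfg$peptides_per_protein_mean < 1)
    stop("configuration error: counts must be positive")
  if (!length(cfg$groups))
    stop("configuration error: empty group list")
  props <- c(cfg$phospho_fraction, cfg$frac_il1b_up, cfg$frac_il1b_down,
             cfg$frac_kd_up, cfg$frac_kd_down, cfg$frac_reverted,
             cfg$frac_nonunique, cfg$frac_phospho_only, cfg$missing_rate)
  if (any(props < 0 | props > 1))
    stop("configuration error: proportions must lie in [0, 1]")
  if (cfg$frac_il1b_up + cfg$frac_il1b_down > 1)
    stop("configuration error: frac_il1b_up + frac_il1b_down > 1")
  if (any(cfg$channel_bias_range <= 0) || diff(cfg$channel_bias_range) < 0)
    stop("configuration error: channel_bias_range must be a positive interval")
  if (any(cfg$reversion_band <= 0) || any(cfg$reversion_band >= 1) ||
      diff(cfg$reversion_band) < 0)
    stop("configuration error: reversion_band must lie within (0, 1)")
  if (cfg$replicate_noise_sd < 0 || cfg$psm_noise_sd < 0 ||
      cfg$base_log_intensity_sd < 0)
    stop("configuration error: noise SDs must be non-negative")
  if (cfg$n_replicates < 1)
    stop("configuration error: n_replicates must be positive")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_peptides <- function(n, min_len = 8, max_len = 18) {
  aas <- strsplit("ACDEFGHIKLMNPQRVW", "")[[1]]  # S/T/Y inserted on demand
  gen <- function(m) {
    lens <- sample(min_len:max_len, m, replace = TRUE)
    vapply(lens, function(l)
      paste(sample(aas, l, replace = TRUE), collapse = ""), character(1))
  }
  seqs <- gen(n)
  while (anyDuplicated(seqs)) {
    idx <- which(duplicated(seqs))
    seqs[idx] <- gen(length(idx))
  }
  seqs
}

plant_effects <- function(n, cfg) {
  # per-feature group labels and log2 group-mean offsets
  groups <- cfg$groups
  eff <- matrix(0, n, length(groups), dimnames = list(NULL, groups))
  il_dir <- rep("null", n)
  kd_dir <- rep("null", n)
  reverted <- rep(FALSE, n)
  rev_frac <- rep(NA_real_, n)

  n_up <- round(cfg$frac_il1b_up * n)
  n_down <- round(cfg$frac_il1b_down * n)
  reg <- sample.int(n, n_up + n_down)
  up <- reg[seq_len(n_up)]
  down <- setdiff(reg, up)
  il_dir[up] <- "up"; il_dir[down] <- "down"

  pool <- setdiff(seq_len(n), reg)
  n_kdu <- min(round(cfg$frac_kd_up * n), length(pool))
  kd_up <- if (n_kdu) sample(pool, n_kdu) else integer(0)
  pool <- setdiff(pool, kd_up)
  n_kdd <- min(round(cfg$frac_kd_down * n), length(pool))
  kd_down <- if (n_kdd) sample(pool, n_kdd) else integer(0)
  kd_dir[kd_up] <- "up"; kd_dir[kd_down] <- "down"

  il_groups <- intersect(c("CON-IL", "SC-IL", "DMT1-KD-IL"), groups)
  e <- cfg$effect_log2fc
  eff[up, il_groups] <- e
  eff[down, il_groups] <- -e
  eff[kd_up, intersect(c("DMT1-KD", "DMT1-KD-IL"), groups)] <-
    eff[kd_up, intersect(c("DMT1-KD", "DMT1-KD-IL"), groups)] + e
  eff[kd_down, intersect(c("DMT1-KD", "DMT1-KD-IL"), groups)] <-
    eff[kd_down, intersect(c("DMT1-KD", "DMT1-KD-IL"), groups)] - e

  n_rev <- round(cfg$frac_reverted * length(reg))
  rev_idx <- if (n_rev) sample(reg, n_rev) else integer(0)
  reverted[rev_idx] <- TRUE
  if (length(rev_idx) && "DMT1-KD-IL" %in% groups) {
    u <- runif(length(rev_idx), cfg$reversion_band[1], cfg$reversion_band[2])
    rev_frac[rev_idx] <- ifelse(il_dir[rev_idx] == "up", u, 1 / u)
    # reverted mean = SC-IL mean x u (up) or / u (down)
    eff[rev_idx, "DMT1-KD-IL"] <- eff[rev_idx, "SC-IL"] + log2(rev_frac[rev_idx])
  }
  list(eff = eff, il1b_direction = il_dir, kd_direction = kd_dir,
       reverted = reverted, reversion_fraction = rev_frac)
}

draw_localization <- function(n, mix) {
  conf <- runif(n) < mix$p_confident
  p <- numeric(n)
  p[conf] <- rbeta(sum(conf), mix$confident_shape[1], mix$confident_shape[2])
  p[!conf] <- rbeta(sum(!conf), mix$ambiguous_shape[1], mix$ambiguous_shape[2])
  round(p, 4)
}

#' Simulate a PSM-level quantification dataset
#'
#' Generates a PSM table, its group design and the planted ground truth.
#' Each peptide yields one PSM per plex (one plex per biological replicate),
#' so a feature is observed in all 18 samples of the full layout. Reporter
#' intensity of feature f in sample s is
#' `exp(base) * 2^(effect[f, group(s)] + biological noise + PSM noise) * bias_s`,
#' with cells blanked at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @return List with `psms` (PSM table), `design` (`GroupDesign`), and
#'   `truth` — a list with per-feature labels and true group means
#'   (`features`), the true per-sample channel biases (`channel_bias`), and
#'   the peptide-to-feature map (`peptides`).
#' @export
simulate_psm_dataset <- function(cfg = sim_config()) {
  cfg <- validate_sim_config(cfg)
  with_sim_seed(cfg$seed, {
    design <- default_design(cfg$n_replicates)
    design <- design[design$group %in% cfg$groups, , drop = FALSE]
    design <- validate_design(design)
    n_samp <- nrow(design)

    acc <- sprintf("PROT%05d", seq_len(cfg$n_proteins))
    phospho_only <- runif(cfg$n_proteins) < cfg$frac_phospho_only
    npep <- 1L + stats::rpois(cfg$n_proteins,
                              cfg$peptides_per_protein_mean - 1)
    pep <- data.frame(
      protein = rep(acc, npep),
      protein_idx = rep(seq_len(cfg$n_proteins), npep),
      stringsAsFactors = FALSE)
    n_pep <- nrow(pep)
    pep$sequence <- random_peptides(n_pep)
    pep$is_phospho <- ifelse(phospho_only[pep$protein_idx], TRUE,
                             runif(n_pep) < cfg$phospho_fraction)
    pep$nonunique <- runif(n_pep) < cfg$frac_nonunique

    # phospho annotations: force S/T/Y residues into the sequence, then
    # draw 1-2 sites with mixture localization probabilities
    pep$modifications <- ""
    ph <- which(pep$is_phospho)
    if (length(ph)) {
      n_sites <- sample(1:2, length(ph), replace = TRUE)
      mods <- character(length(ph))
      for (k in seq_along(ph)) {
        i <- ph[k]
        s <- strsplit(pep$sequence[i], "")[[1]]
        pos <- sort(sample(seq_along(s), n_sites[k]))
        res <- sample(c("S", "T", "Y"), n_sites[k], replace = TRUE)
        s[pos] <- res
        pep$sequence[i] <- paste(s, collapse = "")
        prob <- draw_localization(n_sites[k], cfg$localization_prob_mixture)
        mods[k] <- paste(sprintf("%s%d(%.4f)", res, pos, prob), collapse = ";")
      }
      pep$modifications[ph] <- mods
    }

    # features: proteins (non-phospho layer) and phosphopeptide keys
    pep$feature <- ifelse(pep$is_phospho,
                          phosphopeptide_key(pep$sequence, pep$modifications),
                          pep$protein)
    ph_feat <- unique(pep$feature[pep$is_phospho])
    features <- c(acc, ph_feat)
    layer <- c(rep("protein", length(acc)),
               rep("phosphopeptide", length(ph_feat)))
    nf <- length(features)

    planted <- plant_effects(nf, cfg)
    feat_idx <- match(pep$feature, features)

    bias <- runif(n_samp, cfg$channel_bias_range[1], cfg$channel_bias_range[2])
    names(bias) <- design$sample

    base <- exp(rnorm(n_pep, cfg$base_log_intensity_mean,
                      cfg$base_log_intensity_sd))
    feat_noise <- matrix(rnorm(nf * n_samp, 0, cfg$replicate_noise_sd),
                         nf, n_samp)

    grp_col <- match(design$group, colnames(planted$eff))
    inten <- matrix(NA_real_, n_pep, n_samp)
    for (s in seq_len(n_samp)) {
      log2eff <- planted$eff[feat_idx, grp_col[s]] + feat_noise[feat_idx, s] +
        rnorm(n_pep, 0, cfg$psm_noise_sd)
      inten[, s] <- base * 2^log2eff * bias[s]
    }
    if (cfg$missing_rate > 0)
      inten[runif(length(inten)) < cfg$missing_rate] <- NA_real_

    # assemble PSM rows: one per peptide per plex
    plexes <- unique(design$plex)
    channel_of <- design$channel
    psm_list <- vector("list", length(plexes))
    channels <- unique(design$channel)
    for (pi in seq_along(plexes)) {
      px <- plexes[pi]
      in_px <- which(design$plex == px)
      block <- data.frame(
        psm_id = sprintf("%s_PSM%06d", px, seq_len(n_pep)),
        peptide_sequence = pep$sequence,
        protein_accessions = ifelse(
          pep$nonunique,
          paste(pep$protein,
                acc[(pep$protein_idx %% cfg$n_proteins) + 1L], sep = ";"),
          pep$protein),
        modifications = pep$modifications,
        plex_id = px,
        stringsAsFactors = FALSE, check.names = FALSE)
      for (ch in channels) {
        s <- in_px[channel_of[in_px] == ch]
        block[[ch]] <- if (length(s) == 1) signif(inten[, s], 6) else NA_real_
      }
      psm_list[[pi]] <- block
    }
    psms <- do.call(rbind, psm_list)
    rownames(psms) <- NULL
    attr(psms, "channels") <- channels
    psms <- annotate_psms(psms)

    truth_features <- data.frame(
      feature = features, layer = layer,
      il1b_direction = planted$il1b_direction,
      kd_direction = planted$kd_direction,
      reverted = planted$reverted,
      reversion_fraction = planted$reversion_fraction,
      stringsAsFactors = FALSE)
    mu <- as.data.frame(planted$eff)
    names(mu) <- paste0("mu_", names(mu))
    truth_features <- cbind(truth_features, mu)

    list(psms = psms, design = design,
         truth = list(features = truth_features,
                      channel_bias = data.frame(sample = design$sample,
                                                bias = unname(bias),
                                                stringsAsFactors = FALSE),
                      peptides = pep[, c("sequence", "protein", "is_phospho",
                                         "nonunique", "feature")]))
  })
}

#' Simulate a PRM transition dataset
#'
#' Light (endogenous) and heavy (spiked synthetic standard) transition
#' chromatograms per peptide: co-eluting Gaussian peaks on a shared time
#' grid inside the scheduled retention-time window, per-fragment amplitudes
#' proportional to the reference fragment intensities, light amplitude =
#' heavy amplitude x the true light/heavy ratio.
#'
#' @param cfg A [sim_config()]; the `prm_*` fields control the dataset.
#' @return List with `transitions` (long PRM table, one row per peptide x
#'   fragment x channel, chromatograms as list columns `time`/`intensity`)
#'   and `truth` (true ratio, retention time and reference intensities per
#'   peptide).
#' @export
simulate_prm_dataset <- function(cfg = sim_config()) {
  cfg <- validate_sim_config(cfg)
  if (cfg$prm_n_peptides < 1) stop("data error: need at least one peptide")
  if (cfg$prm_n_fragments < 3) stop("data error: need >= 3 fragments per peptide")
  with_sim_seed(cfg$seed + 1L, {
    n_pep <- cfg$prm_n_peptides
    n_frag <- cfg$prm_n_fragments
    ratios <- if (is.null(cfg$prm_true_ratios))
      2^runif(n_pep, -1.5, 1.5)
    else rep_len(cfg$prm_true_ratios, n_pep)
    rt <- runif(n_pep, 5, 25)
    peptides <- sprintf("PEP%02d", seq_len(n_pep))
    seqs <- random_peptides(n_pep, 10, 16)
    rows <- list()
    truth <- data.frame(peptide = peptides, sequence = seqs,
                        true_ratio = ratios, true_rt = rt,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n_pep)) {
      ref <- sort(runif(n_frag, 0.1, 1), decreasing = TRUE)
      ref <- ref / max(ref)
      w0 <- rt[i] - cfg$prm_rt_window / 2
      w1 <- rt[i] + cfg$prm_rt_window / 2
      tt <- seq(w0, w1, by = cfg$prm_sample_interval)
      light_rt <- rt[i] + rnorm(1, 0, cfg$prm_rt_jitter_sd)
      for (f in seq_len(n_frag)) {
        amp_h <- cfg$prm_amplitude * ref[f]
        for (chan in c("light", "heavy")) {
          mu <- if (chan == "light") light_rt else rt[i]
          amp <- if (chan == "light") amp_h * ratios[i] else amp_h
          y <- amp * exp(-(tt - mu)^2 / (2 * cfg$prm_sigma_rt^2))
          if (cfg$prm_noise_sd > 0)
            y <- pmax(y + rnorm(length(y), 0, cfg$prm_noise_sd), 0)
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = peptides[i], charge = 2L,
            fragment = sprintf("y%d", f + 2L), channel = chan,
            rt_window_start = w0, rt_window_end = w1,
            reference_intensity = ref[f], stringsAsFactors = FALSE)
          rows[[length(rows)]]$time <- list(tt)
          rows[[length(rows)]]$intensity <- list(y)
        }
      }
    }
    transitions <- do.call(rbind, rows)
    rownames(transitions) <- NULL
    list(transitions = transitions, truth = truth)
  })
}
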
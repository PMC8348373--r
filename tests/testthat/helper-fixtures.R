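# Fixtures built in code and independent oracles used across the suite.

# Minimal 6-group x n-replicate design (one plex per replicate).
toy_design <- function(n_replicates = 3) default_design(n_replicates)

# Hand-assembled PSM table. `rows` is a list of lists with fields
# sequence, proteins (chr vector), mods (default ""), and one intensity
# vector per plex named by the design's channels.
toy_psms <- function(rows, design = toy_design(1)) {
  channels <- unique(design$channel)
  plexes <- unique(design$plex)
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    do.call(rbind, lapply(plexes, function(px) {
      d <- data.frame(psm_id = sprintf("%s_PSM%03d", px, i),
                      peptide_sequence = r$sequence,
                      protein_accessions = paste(r$proteins, collapse = ";"),
                      modifications = if (is.null(r$mods)) "" else r$mods,
                      plex_id = px, stringsAsFactors = FALSE,
                      check.names = FALSE)
      inten <- r[[px]]
      for (k in seq_along(channels))
        d[[channels[k]]] <- if (is.null(inten)) NA_real_ else inten[k]
      d
    }))
  }))
  rownames(out) <- NULL
  attr(out, "channels") <- channels
  phosphoTMT:::annotate_psms(out)
}

# Quant matrix straight from a numeric matrix with group/replicate samples.
toy_matrix <- function(values, design, layer = "protein",
                       feature_meta = NULL) {
  colnames(values) <- design$sample
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("F%03d", seq_len(nrow(values)))
  quant_matrix(values, layer = layer, feature_meta = feature_meta)
}

# Independent brute-force Benjamini-Hochberg step-up:
# q_(i) = min_{j >= i} m p_(j) / j, clipped at 1, input order restored.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(m * ps[i:m] / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force protein roll-up: loop over proteins and samples, summing
# unique non-phospho PSM intensities one cell at a time.
rollup_oracle <- function(psms, design) {
  keep <- psms$is_unique & psms$n_phospho == 0
  sub <- psms[keep, , drop = FALSE]
  prots <- sort(unique(sub$protein_accessions))
  v <- matrix(NA_real_, length(prots), nrow(design),
              dimnames = list(prots, design$sample))
  for (p in prots) for (i in seq_len(nrow(design))) {
    rows <- which(sub$protein_accessions == p &
                    sub$plex_id == design$plex[i])
    vals <- sub[[design$channel[i]]][rows]
    vals <- vals[!is.na(vals)]
    if (length(vals)) v[p, design$sample[i]] <- sum(vals)
  }
  v[rowSums(!is.na(v)) > 0, , drop = FALSE]
}

# Gaussian chromatogram on a regular grid.
gaussian_chrom <- function(rt, sigma, amplitude, window, dt = 0.005) {
  tt <- seq(window[1], window[2], by = dt)
  list(time = tt, intensity = amplitude * exp(-(tt - rt)^2 / (2 * sigma^2)))
}

# Small simulated dataset reused by several tests.
small_sim <- function(seed = 42, n_proteins = 150, ...) {
  simulate_psm_dataset(sim_config(n_proteins = n_proteins, seed = seed, ...))
}
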
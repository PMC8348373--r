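# Parallel-reaction-monitoring quantification: trapezoidal peak
# integration, light/heavy peak-area ratios, normalized dot-product
# identity scoring against reference fragment intensities, and co-elution
# checks between endogenous (light) and heavy-standard peptides.

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of intensity over time restricted to the scheduled
#' window; units are intensity x minutes. No baseline subtraction or
#' smoothing is applied.
#'
#' @param time,intensity Chromatogram vectors (time strictly increasing).
#' @param window Length-2 numeric `(start, end)` in minutes.
#' @return Peak area.
#' @export
integrate_peak <- function(time, intensity, window) {
  stopifnot(length(time) == length(intensity), length(window) == 2)
  if (window[2] <= window[1])
    stop("integration error: empty window")
  if (window[1] > max(time) || window[2] < min(time))
    stop("integration error: window outside the chromatogram time span")
  idx <- time >= window[1] & time <= window[2]
  if (sum(idx) < 2)
    stop("integration error: fewer than 2 points inside the window")
  pracma::trapz(time[idx], intensity[idx])
}

#' Light/heavy fragmentation ratio
#'
#' Ratio of summed light fragment peak areas to summed heavy (internal
#' standard) fragment peak areas.
#'
#' @param light_areas,heavy_areas Per-fragment peak areas.
#' @return The summed-area ratio.
#' @export
light_heavy_ratio <- function(light_areas, heavy_areas) {
  h <- sum(heavy_areas)
  if (!is.finite(h) || h <= 0)
    stop("quantification error: zero heavy area (internal standard absent)")
  sum(light_areas) / h
}

#' Normalized spectral dot-product score
#'
#' `sum(a b) / sqrt(sum(a^2) sum(b^2))` between measured fragment peak
#' areas and reference fragment intensities; scale-invariant, in \[0, 1\]
#' for non-negative vectors. Identity is accepted at `score >= 0.95`
#' (inclusive).
#'
#' @param measured,reference Non-negative vectors of equal length >= 2.
#' @return The score.
#' @export
dot_product_score <- function(measured, reference) {
  if (length(measured) != length(reference) || length(measured) < 2)
    stop("score error: need equal lengths >= 2")
  if (all(measured == 0) || all(reference == 0))
    stop("score error: all-zero vector — score undefined")
  sum(measured * reference) /
    sqrt(sum(measured^2) * sum(reference^2))
}

apex_rt <- function(time, intensity) time[which.max(intensity)]

#' Quantify a PRM transition dataset
#'
#' Per peptide: integrates every light and heavy fragment chromatogram over
#' the scheduled window, computes the summed-area light/heavy ratio, scores
#' the heavy (standard) and light measured areas against the reference
#' fragment intensities with the normalized dot product, and locates the
#' apex retention time of the summed-fragment trace per channel. Apexes on
#' a window boundary are flagged as truncated.
#'
#' @param transitions PRM table (from [simulate_prm_dataset()] or
#'   [read_prm_table()]).
#' @param dot_threshold Dot-product acceptance threshold (default 0.95,
#'   inclusive).
#' @return Data frame, one row per peptide: areas, `ratio`, `dotp_heavy`,
#'   `dotp_light`, `accepted`, `light_apex_rt`, `heavy_apex_rt`,
#'   `truncated`.
#' @export
quantify_prm <- function(transitions, dot_threshold = 0.95) {
  peptides <- unique(transitions$peptide)
  out <- lapply(peptides, function(pp) {
    tr <- transitions[transitions$peptide == pp, , drop = FALSE]
    frags <- unique(tr$fragment)
    if (length(frags) < 3)
      stop("data error: peptide ", pp, " has fewer than 3 fragments")
    win <- c(tr$rt_window_start[1], tr$rt_window_end[1])
    one_channel <- function(chan) {
      sub <- tr[tr$channel == chan, , drop = FALSE]
      sub <- sub[match(frags, sub$fragment), , drop = FALSE]
      areas <- mapply(function(t, y) integrate_peak(t, y, win),
                      sub$time, sub$intensity)
      # summed-fragment trace for the apex (fragments share the grid)
      tt <- sub$time[[1]]
      total <- Reduce(`+`, sub$intensity)
      list(areas = areas, apex = apex_rt(tt, total),
           ref = sub$reference_intensity,
           boundary = which.max(total) %in% c(1L, length(total)))
    }
    light <- one_channel("light")
    heavy <- one_channel("heavy")
    dotp_h <- dot_product_score(heavy$areas, heavy$ref)
    dotp_l <- dot_product_score(light$areas, light$ref)
    data.frame(peptide = pp,
               light_area = sum(light$areas),
               heavy_area = sum(heavy$areas),
               ratio = light_heavy_ratio(light$areas, heavy$areas),
               dotp_heavy = dotp_h, dotp_light = dotp_l,
               accepted = dotp_h >= dot_threshold,
               light_apex_rt = light$apex,
               heavy_apex_rt = heavy$apex,
               truncated = light$boundary || heavy$boundary,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Co-elution check between light and heavy peptides
#'
#' Correlates the apex retention times of the endogenous (light) and heavy
#' standard peptides across the peptide panel; co-eluting pairs give r near
#' 1. Pairs whose apexes differ by more than `tolerance` minutes are
#' flagged.
#'
#' @param prm_results Output of [quantify_prm()] (>= 3 peptides).
#' @param tolerance Apex-difference flag threshold in minutes (default 0.2).
#' @return List with `light_rt`, `heavy_rt`, `r` (Pearson) and `flagged`
#'   (peptide ids off by more than `tolerance`).
#' @export
coelution_check <- function(prm_results, tolerance = 0.2) {
  if (nrow(prm_results) < 3)
    stop("data error: need >= 3 peptides for the co-elution correlation")
  r <- pearson_cor(prm_results$light_apex_rt, prm_results$heavy_apex_rt)
  off <- abs(prm_results$light_apex_rt - prm_results$heavy_apex_rt) >
    tolerance
  list(light_rt = stats::setNames(prm_results$light_apex_rt,
                                  prm_results$peptide),
       heavy_rt = stats::setNames(prm_results$heavy_apex_rt,
                                  prm_results$peptide),
       r = r,
       flagged = prm_results$peptide[off])
}
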
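# Tabular I/O. Fixed dialects: tab-separated PSM/PRM/result tables,
# comma-separated design tables, decimal point ".", missing intensities as
# empty fields (zero is a legal measurement and is retained).

PSM_FIXED_COLS <- c("psm_id", "peptide_sequence", "protein_accessions",
                    "modifications", "plex_id")

#' Parse a phospho-modification annotation string
#'
#' Strings of the form `"S5(0.98);T7(0.45)"`: residue letter (S/T/Y),
#' 1-based position within the peptide, localization probability in
#' parentheses. Empty strings mean no phosphorylation.
#'
#' @param x Character vector of annotation strings.
#' @return List of data frames with columns `residue`, `position`,
#'   `probability` (zero rows for unmodified peptides).
#' @export
parse_modifications <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(residue = character(0), position = integer(0),
                        probability = numeric(0)))
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([STY])(\\d+)\\(([0-9.]+)\\)$", parts))
    bad <- vapply(m, length, integer(1)) != 4
    if (any(bad))
      stop("format error: unparseable modification annotation: ",
           paste(parts[bad], collapse = ", "))
    out <- data.frame(
      residue = vapply(m, `[`, character(1), 2),
      position = as.integer(vapply(m, `[`, character(1), 3)),
      probability = as.numeric(vapply(m, `[`, character(1), 4)),
      stringsAsFactors = FALSE)
    if (any(out$probability < 0 | out$probability > 1))
      stop("data error: localization probability outside [0, 1]")
    if (is.unsorted(out$position, strictly = TRUE))
      stop("format error: phosphosite positions must be strictly increasing")
    out
  })
}

format_modifications <- function(sites) {
  vapply(sites, function(d) {
    if (!nrow(d)) return("")
    paste(sprintf("%s%d(%.4f)", d$residue, d$position, d$probability),
          collapse = ";")
  }, character(1))
}

# derived columns used throughout: is_unique, n_phospho
annotate_psms <- function(psms) {
  psms$is_unique <- !grepl(";", psms$protein_accessions, fixed = TRUE)
  sites <- parse_modifications(psms$modifications)
  psms$n_phospho <- vapply(sites, nrow, integer(1))
  plen <- nchar(psms$peptide_sequence)
  over <- vapply(seq_along(sites), function(i)
    nrow(sites[[i]]) > 0 && max(sites[[i]]$position) > plen[i], logical(1))
  if (any(over))
    stop("data error: phosphosite position beyond peptide length in ",
         sum(over), " PSM(s)")
  psms
}

psm_channels <- function(psms) {
  ch <- attr(psms, "channels")
  if (is.null(ch)) ch <- intersect(tmt11_channels(), names(psms))
  ch
}

#' Write a PSM table
#'
#' Tab-separated, columns `psm_id`, `peptide_sequence`,
#' `protein_accessions`, `modifications`, `plex_id`, then one column per
#' reporter channel. Intensities at 6 significant digits; missing cells
#' written as empty fields.
#'
#' @param psms PSM table (as from [simulate_psm_dataset()] or
#'   [read_psm_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  channels <- psm_channels(psms)
  out <- psms[, PSM_FIXED_COLS, drop = FALSE]
  for (ch in channels)
    out[[ch]] <- ifelse(is.na(psms[[ch]]), "",
                        format(signif(psms[[ch]], 6), trim = TRUE,
                               scientific = FALSE, nsmall = 0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a PSM table
#'
#' Parses and validates the fixed tab-separated dialect written by
#' [write_psm_table()]. Unknown channel labels are a format error; empty
#' intensity cells become missing values; non-numeric intensities are
#' rejected with a per-row count.
#'
#' @param path Input file path.
#' @return Annotated PSM data frame (with `is_unique`, `n_phospho` and a
#'   `channels` attribute).
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(PSM_FIXED_COLS, names(raw))
  if (length(miss))
    stop("format error: PSM table missing column(s): ",
         paste(miss, collapse = ", "))
  channels <- setdiff(names(raw), PSM_FIXED_COLS)
  bad <- setdiff(channels, tmt11_channels())
  if (length(bad))
    stop("format error: unknown channel label(s): ",
         paste(bad, collapse = ", "))
  psms <- raw[, PSM_FIXED_COLS, drop = FALSE]
  n_bad_rows <- 0L
  for (ch in channels) {
    v <- raw[[ch]]
    v[!nzchar(v)] <- NA
    num <- suppressWarnings(as.numeric(v))
    broken <- !is.na(v) & is.na(num)
    if (any(broken)) {
      n_bad_rows <- n_bad_rows + sum(broken)
      stop("format error: ", sum(broken), " non-numeric intensity value(s) ",
           "in channel ", ch, " (first at row ", which(broken)[1], ")")
    }
    if (any(num < 0, na.rm = TRUE))
      stop("data error: negative intensity in channel ", ch)
    psms[[ch]] <- num
  }
  attr(psms, "channels") <- channels
  annotate_psms(psms)
}

#' Write a design table
#'
#' Comma-separated with columns `plex,channel,group,replicate`.
#'
#' @param design A validated design data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design[, c("plex", "channel", "group", "replicate")],
                   path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a design table
#'
#' @param path CSV with columns `plex,channel,group,replicate`.
#' @return Validated `GroupDesign` data frame (see [validate_design()]).
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, colClasses = "character",
                       stringsAsFactors = FALSE)
  validate_design(d)
}

num_list <- function(x) paste(format(x, trim = TRUE, digits = 10,
                                     scientific = TRUE), collapse = ";")

#' Write a PRM transition table
#'
#' Tab-separated, one row per peptide x fragment x channel with the
#' chromatogram time/intensity vectors as semicolon-separated lists.
#'
#' @param transitions PRM table (as from [simulate_prm_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prm_table <- function(transitions, path) {
  out <- transitions[, c("peptide", "charge", "fragment", "channel",
                         "rt_window_start", "rt_window_end",
                         "reference_intensity")]
  out$times <- vapply(transitions$time, num_list, character(1))
  out$intensities <- vapply(transitions$intensity, num_list, character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a PRM transition table
#'
#' @param path Tab-separated file written by [write_prm_table()].
#' @return PRM data frame with list columns `time` and `intensity`.
#' @export
read_prm_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("peptide", "charge", "fragment", "channel", "rt_window_start",
            "rt_window_end", "reference_intensity", "times", "intensities")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("format error: PRM table missing column(s): ",
         paste(miss, collapse = ", "))
  split_num <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  out <- raw[, setdiff(need, c("times", "intensities"))]
  out$time <- lapply(raw$times, split_num)
  out$intensity <- lapply(raw$intensities, split_num)
  npts <- vapply(out$time, length, integer(1))
  if (any(npts < 2))
    stop("data error: chromatogram with fewer than 2 time points")
  if (any(npts != vapply(out$intensity, length, integer(1))))
    stop("format error: time/intensity length mismatch")
  bad_order <- vapply(out$time, is.unsorted, logical(1), strictly = TRUE)
  if (any(bad_order))
    stop("data error: chromatogram time points must be strictly increasing")
  out
}

#' Write a quantification matrix
#'
#' TSV with the feature id in the first column and one column per sample,
#' at 6 significant digits; the normalization factors, when present, go to
#' a two-column sidecar file `<path>.factors.tsv`.
#'
#' @param qm A [quant_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(qm, path) {
  v <- qm$values
  out <- data.frame(feature = rownames(v), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (s in colnames(v))
    out[[s]] <- ifelse(is.na(v[, s]), "",
                       format(signif(v[, s], 6), trim = TRUE,
                              scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(qm$norm_factors)) {
    side <- data.frame(sample = names(qm$norm_factors),
                       factor = format(qm$norm_factors, digits = 10),
                       stringsAsFactors = FALSE)
    utils::write.table(side, paste0(path, ".factors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a quantification matrix
#'
#' @param path TSV written by [write_quant_matrix()].
#' @param layer Layer label to attach (`"protein"` or `"phosphopeptide"`).
#' @return A [quant_matrix()].
#' @export
read_quant_matrix <- function(path, layer = "protein") {
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  v <- as.matrix(raw[, -1, drop = FALSE])
  v[v == ""] <- NA
  storage.mode(v) <- "double"
  rownames(v) <- raw[[1]]
  fp <- paste0(path, ".factors.tsv")
  nf <- NULL
  if (file.exists(fp)) {
    side <- utils::read.delim(fp, sep = "\t", stringsAsFactors = FALSE)
    nf <- stats::setNames(as.numeric(side$factor), side$sample)
  }
  quant_matrix(v, layer = layer, norm_factors = nf)
}

# Results tables carry a header comment with version and seed so a run is
# self-describing; the comment is deterministic (no timestamps).
write_result_table <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("phosphoTMT"))
  writeLines(sprintf("# phosphoTMT %s; seed=%s", ver, seed), con)
  is_num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[is_num] <- lapply(df[is_num], function(x)
    ifelse(is.na(x), "", format(signif(x, 6), trim = TRUE)))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_result_table <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write the simulation ground truth
#'
#' Feature labels and true group means as a TSV keyed by feature id; the
#' channel-bias table goes to `<path>.bias.tsv`.
#'
#' @param truth The `truth` element of [simulate_psm_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$channel_bias, paste0(path, ".bias.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
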
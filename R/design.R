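# Experimental-design handling: the six-group x three-replicate TMT layout.

#' TMT 11-plex reporter channel labels
#'
#' The full label set of an 11-plex tandem-mass-tag kit. Any channel column
#' in a PSM table must come from this set.
#'
#' @return Character vector of the eleven channel labels.
#' @export
tmt11_channels <- function() {
  c("126", "127N", "127C", "128N", "128C",
    "129N", "129C", "130N", "130C", "131N", "131C")
}

#' Experimental group labels
#'
#' The six groups of the knock-down study: untransfected control (CON),
#' scrambled-siRNA control (SC) and DMT1-silenced cells (DMT1-KD), each
#' without or with IL-1beta exposure (suffix "-IL").
#'
#' @return Character vector of the six group labels, in canonical order.
#' @export
study_groups <- function() {
  c("CON", "SC", "DMT1-KD", "CON-IL", "SC-IL", "DMT1-KD-IL")
}

sample_id <- function(group, replicate) paste(group, replicate, sep = "/")

#' Default channel-to-group design
#'
#' One TMT plex per biological replicate; within a plex the six groups
#' occupy six reporter channels (CON on 126, then every second label).
#'
#' @param n_replicates Number of biological replicates (default 3).
#' @return A `GroupDesign` data frame with columns `plex`, `channel`,
#'   `group`, `replicate` and `sample` (`group/replicate`).
#' @export
default_design <- function(n_replicates = 3) {
  channels <- c("126", "127N", "128N", "129N", "130N", "131N")
  groups <- study_groups()
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(plex = paste0("plex", r),
               channel = channels,
               group = groups,
               replicate = r,
               stringsAsFactors = FALSE)
  }))
  out$sample <- sample_id(out$group, out$replicate)
  validate_design(out)
}

#' Validate a group design
#'
#' Checks channel labels, uniqueness of (plex, channel) pairs, and that
#' every group x replicate combination occurs exactly once.
#'
#' @param design Data frame with columns `plex`, `channel`, `group`,
#'   `replicate` (and optionally `sample`).
#' @return The validated design with a `sample` column, invisibly classed.
#' @export
validate_design <- function(design) {
  need <- c("plex", "channel", "group", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design$channel <- as.character(design$channel)
  design$plex <- as.character(design$plex)
  design$group <- as.character(design$group)
  design$replicate <- as.integer(design$replicate)
  bad <- setdiff(design$channel, tmt11_channels())
  if (length(bad))
    stop("unknown TMT channel label(s): ", paste(unique(bad), collapse = ", "))
  key <- paste(design$plex, design$channel)
  if (anyDuplicated(key))
    stop("duplicated (plex, channel) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  cell <- paste(design$group, design$replicate, sep = "/")
  if (anyDuplicated(cell))
    stop("duplicated group/replicate cell(s): ",
         paste(unique(cell[duplicated(cell)]), collapse = ", "))
  expected <- as.vector(outer(unique(design$group),
                              sort(unique(design$replicate)),
                              sample_id))
  gap <- setdiff(expected, cell)
  if (length(gap))
    stop("design is missing group/replicate cell(s): ",
         paste(gap, collapse = ", "))
  design$sample <- sample_id(design$group, design$replicate)
  rownames(design) <- NULL
  design
}

design_samples <- function(design, group = NULL) {
  if (is.null(group)) return(design$sample)
  design$sample[design$group == group]
}
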
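## Inclusion rules defining the final protein and phospho-site datasets.

#' Filtering configuration
#'
#' @param min_localization Localization-probability cutoff; sites must
#'   exceed it strictly (default 0.75).
#' @param require_normalizable Require phospho-sites to be normalizable to
#'   protein level at every timepoint (no missing protein value in any
#'   required channel; default `TRUE`).
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_localization = 0.75,
                          require_normalizable = TRUE) {
  if (min_localization < 0 || min_localization > 1)
    stop2("min_localization must be in [0, 1]")
  structure(list(min_localization = min_localization,
                 require_normalizable = require_normalizable),
            class = "filter_config")
}

#' Drop contaminant and reverse-database features
#'
#' @param x A `protein_data` or `phospho_data` object.
#' @return The object without flagged rows; attribute `audit` counts
#'   removals per flag (a feature carrying both flags is tallied under
#'   both but removed once).
#' @export
drop_flagged_features <- function(x) {
  f <- x$features
  drop <- f$is_contaminant | f$is_reverse
  out <- x
  out$features <- f[!drop, , drop = FALSE]
  out$intensities <- x$intensities[!drop, , drop = FALSE]
  attr(out, "audit") <- c(n_contaminant = sum(f$is_contaminant),
                          n_reverse = sum(f$is_reverse),
                          n_removed = sum(drop))
  out
}

## detection helper: per (strain, replicate), the ordered timepoint columns
strain_rep_blocks <- function(design, enrichment, strains = NULL) {
  d <- design[design$enrichment == enrichment, , drop = FALSE]
  if (!is.null(strains)) d <- d[d$strain %in% strains, , drop = FALSE]
  sp <- split(seq_len(nrow(d)), paste(d$strain, d$replicate, sep = "/"))
  lapply(sp, function(i) {
    i <- i[order(d$timepoint_min[i])]
    list(channels = d$channel_label[i], timepoints = d$timepoint_min[i])
  })
}

has_consecutive_pair <- function(detected) {
  any(detected[-length(detected)] & detected[-1L])
}

#' Detection filter for time-course datasets
#'
#' Proteins are kept when detected (intensity > 0) in at least one
#' timepoint of every replicate of every required strain. Phospho-sites
#' must additionally be detected in at least two *consecutive* timepoints
#' (adjacent in the ordered timepoint list) of every replicate of every
#' required strain, exceed the localization-probability cutoff strictly,
#' and — when `config$require_normalizable` — have no missing
#' protein-normalized value (`NA`) in any required channel.
#'
#' @param x A `protein_data` or `phospho_data` object (intensities may be
#'   the protein-normalized matrix containing `NA` for not-normalizable
#'   entries).
#' @param design A [sample_design()].
#' @param config A [filter_config()].
#' @param kind `"protein"` or `"phospho"`.
#' @param strains Strains whose replicates must all satisfy the rule;
#'   default all strains in the design.
#' @return The filtered object; attribute `audit` is a data.frame with
#'   one row per input feature giving pass/fail and the first failing
#'   rule.
#' @export
detection_filter <- function(x, design, config = filter_config(),
                             kind = c("protein", "phospho"),
                             strains = NULL) {
  kind <- match.arg(kind)
  enr <- if (kind == "protein") "N" else "PE"
  blocks <- strain_rep_blocks(design, enr, strains)
  m <- x$intensities
  missing_ch <- setdiff(unlist(lapply(blocks, `[[`, "channels")),
                        colnames(m))
  if (length(missing_ch))
    stop2("intensity matrix lacks designed channel(s): ",
          paste(missing_ch, collapse = ", "))
  n <- nrow(m)
  fail <- rep(NA_character_, n)
  if (kind == "phospho") {
    loc_fail <- !(x$features$localization_prob > config$min_localization)
    fail[is.na(fail) & loc_fail] <- "localization"
    if (isTRUE(config$require_normalizable)) {
      chans <- unlist(lapply(blocks, `[[`, "channels"), use.names = FALSE)
      norm_fail <- apply(is.na(m[, chans, drop = FALSE]), 1, any)
      fail[is.na(fail) & norm_fail] <- "not_normalizable"
    }
  }
  for (b in blocks) {
    det <- (m[, b$channels, drop = FALSE] > 0) & !is.na(m[, b$channels, drop = FALSE])
    ok <- if (kind == "protein") rowSums(det) >= 1L else
      apply(det, 1, has_consecutive_pair)
    fail[is.na(fail) & !ok] <- if (kind == "protein") "detection" else
      "sequential_detection"
  }
  keep <- is.na(fail)
  audit <- data.frame(
    feature = rownames(m) %||% as.character(seq_len(n)),
    pass = keep,
    first_failing_rule = ifelse(keep, "", fail),
    stringsAsFactors = FALSE)
  out <- x
  out$features <- x$features[keep, , drop = FALSE]
  out$intensities <- m[keep, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}

#' Detection filter for replicate-only (arrest) designs
#'
#' Keeps features with nonzero intensity in at least `min_reps` replicates
#' of *every* listed strain. For phospho data the localization cutoff of
#' `config` is applied first.
#'
#' @param x A `protein_data` or `phospho_data` object.
#' @param design A [sample_design()] whose replicates index the arrest
#'   samples.
#' @param min_reps Minimum number of detected replicates per strain.
#' @param strains Strains that must all satisfy the rule; default all.
#' @param config A [filter_config()]; localization applies to phospho
#'   data only.
#' @return The filtered object with an `audit` attribute as in
#'   [detection_filter()].
#' @export
arrest_detection_filter <- function(x, design, min_reps = 3L,
                                    strains = NULL,
                                    config = filter_config()) {
  is_phospho <- inherits(x, "phospho_data")
  enr <- if (is_phospho) "PE" else "N"
  d <- design[design$enrichment == enr, , drop = FALSE]
  if (!is.null(strains)) d <- d[d$strain %in% strains, , drop = FALSE]
  sp <- split(d$channel_label, d$strain)
  if (any(lengths(sp) < min_reps))
    stop2("min_reps (", min_reps, ") exceeds available replicates for ",
          "strain(s): ",
          paste(names(sp)[lengths(sp) < min_reps], collapse = ", "))
  m <- x$intensities
  n <- nrow(m)
  fail <- rep(NA_character_, n)
  if (is_phospho) {
    loc_fail <- !(x$features$localization_prob > config$min_localization)
    fail[is.na(fail) & loc_fail] <- "localization"
  }
  for (s in names(sp)) {
    det <- (m[, sp[[s]], drop = FALSE] > 0) &
      !is.na(m[, sp[[s]], drop = FALSE])
    ok <- rowSums(det) >= min_reps
    fail[is.na(fail) & !ok] <- paste0("detection:", s)
  }
  keep <- is.na(fail)
  audit <- data.frame(
    feature = rownames(m) %||% as.character(seq_len(n)),
    pass = keep,
    first_failing_rule = ifelse(keep, "", fail),
    stringsAsFactors = FALSE)
  out <- x
  out$features <- x$features[keep, , drop = FALSE]
  out$intensities <- m[keep, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}
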
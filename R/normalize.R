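## Reporter-channel normalization for single-plex TMT experiments.
## Zeros mean "not detected" and are excluded from every median and mean,
## then restored as zeros.

#' Median-scale reporter channels
#'
#' Each channel is multiplied by a scaling factor equal to the median of
#' all nonmissing intensities across all channels (the grand median)
#' divided by that channel's own nonmissing median. After scaling, every
#' channel's nonmissing median equals the grand median. Zeros are ignored
#' while computing medians and remain zero afterwards.
#'
#' @param m Numeric matrix, features x channels, nonnegative, 0 = missing.
#' @return A list: `intensities` (the scaled matrix) and `report`, a
#'   data.frame with per-channel scaling factor, channel median and
#'   missing-value count, plus the grand median as an attribute.
#' @export
median_scale_channels <- function(m) {
  if (any(m < 0, na.rm = TRUE)) stop2("negative intensities")
  vals <- m[m > 0 & !is.na(m)]
  if (!length(vals)) stop2("matrix has no nonmissing values")
  grand <- stats::median(vals)
  ch_med <- apply(m, 2, function(x) {
    x <- x[x > 0 & !is.na(x)]
    if (!length(x)) NA_real_ else stats::median(x)
  })
  if (any(is.na(ch_med)))
    stop2("channel(s) with no nonmissing values: ",
          paste(colnames(m)[is.na(ch_med)], collapse = ", "))
  factors <- grand / ch_med
  scaled <- sweep(m, 2, factors, `*`)
  scaled[m == 0] <- 0
  report <- data.frame(
    channel = colnames(m) %||% as.character(seq_len(ncol(m))),
    scaling_factor = unname(factors),
    channel_median = unname(ch_med),
    n_missing = apply(m, 2, function(x) sum(x == 0 | is.na(x))),
    stringsAsFactors = FALSE)
  attr(report, "grand_median") <- grand
  list(intensities = scaled, report = report)
}

#' Normalize phospho-site intensities to protein level
#'
#' Each site's phospho-enriched (PE) intensity is divided by the reporter
#' intensity of its protein in the matched non-enriched (N) channel —
#' matched on (strain, replicate, timepoint) — and multiplied by 1000.
#' A zero PE intensity stays zero (missing stays missing); where the
#' protein intensity is zero the ratio is undefined and returned as `NA`
#' (such sites are excluded downstream when a complete protein profile is
#' required).
#'
#' @param pe Site intensity matrix (PE channels).
#' @param n Protein intensity matrix (N channels).
#' @param site_protein Character vector mapping each row of `pe` to a row
#'   name of `n`.
#' @param design A [sample_design()] covering both enrichments; used to
#'   match PE channels to N channels.
#' @return Matrix like `pe` with protein-normalized values; `NA` marks
#'   not-normalizable (protein missing) entries.
#' @export
phospho_to_protein <- function(pe, n, site_protein, design) {
  if (length(site_protein) != nrow(pe))
    stop2("site_protein must map every row of pe")
  absent <- setdiff(unique(site_protein), rownames(n))
  if (length(absent))
    stop2("site(s) mapped to protein(s) absent from the protein matrix: ",
          paste(utils::head(absent, 5), collapse = ", "))
  dpe <- design[design$enrichment == "PE", , drop = FALSE]
  dn <- design[design$enrichment == "N", , drop = FALSE]
  key <- function(d) paste(d$strain, d$replicate, d$timepoint_min)
  pe_ord <- match(colnames(pe), dpe$channel_label)
  if (any(is.na(pe_ord))) stop2("pe columns not in design PE channels")
  n_idx <- match(key(dpe)[pe_ord], key(dn))
  if (any(is.na(n_idx)))
    stop2("PE channel(s) without a matched N channel")
  n_cols <- match(dn$channel_label[n_idx], colnames(n))
  if (any(is.na(n_cols))) stop2("n matrix lacks designed N channels")
  prot <- n[site_protein, n_cols, drop = FALSE]
  out <- 1000 * pe / prot
  out[pe == 0] <- 0
  out[prot == 0] <- NA_real_
  dimnames(out) <- dimnames(pe)
  out
}

#' Remove batch effects on the log2 scale
#'
#' Per feature, a least-squares fit of grand mean plus batch indicators
#' (sum-to-zero over observations) is removed from the log2 intensities:
#' batch means are equalized while the feature's grand mean of nonmissing
#' values is preserved. The result is back-transformed to the linear
#' scale; zeros are treated as missing throughout and restored afterwards.
#' Features observed in fewer than two batches are passed through
#' unchanged (and counted in the attached `skipped` attribute).
#'
#' @param m Numeric matrix, features x channels, 0/`NA` = missing.
#' @param batch Vector of batch labels, one per channel; at least two
#'   distinct batches are required.
#' @return The corrected matrix, with attribute `skipped` giving the
#'   number of pass-through features.
#' @export
correct_batch <- function(m, batch) {
  if (length(batch) != ncol(m)) stop2("one batch label per channel required")
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) stop2("at least two batches required")
  lg <- log2(m)
  lg[!is.finite(lg)] <- NA_real_   # zeros and NAs are missing
  out <- lg
  bi <- as.integer(batch)
  skipped <- 0L
  for (f in seq_len(nrow(lg))) {
    x <- lg[f, ]
    obs <- !is.na(x)
    if (length(unique(bi[obs])) < 2L) { skipped <- skipped + 1L; next }
    grand <- mean(x[obs])
    bmeans <- tapply(x[obs], bi[obs], mean)
    out[f, obs] <- x[obs] - bmeans[as.character(bi[obs])] + grand
  }
  res <- 2^out
  res[is.na(out)] <- m[is.na(out)]   # restore zeros / original NAs
  res[m == 0] <- 0
  dimnames(res) <- dimnames(m)
  attr(res, "skipped") <- skipped
  res
}
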
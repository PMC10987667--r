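## Fold-change / t-test differential calling with explicit zero policies,
## metaphase-transition classification, profile scaling and replicate
## averaging.

#' Analysis configuration for differential calling
#'
#' @param fc_threshold Fold-change cutoff; a feature qualifies when its
#'   median fold change exceeds `fc_threshold` or falls below
#'   `1/fc_threshold` (default 1.5).
#' @param alpha t-test p-value cutoff (default 0.05).
#' @param timepoints Ordered timepoints in minutes; default the 10-point
#'   prophase block-release design (0, then 45-165 at 15-min intervals).
#' @param metaphase_I,metaphase_II Anchor timepoints of the two meiotic
#'   metaphases (75 and 120 min; 135 min is the anaphase-II peak, so the
#'   timepoint just before it anchors metaphase II).
#' @param fc_clamp_display Optional display clamp for reported fold
#'   changes, e.g. `c(0.2, 2.2)`; never affects calls.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(fc_threshold = 1.5, alpha = 0.05,
                            timepoints = c(0L, seq(45L, 165L, by = 15L)),
                            metaphase_I = 75L, metaphase_II = 120L,
                            fc_clamp_display = NULL) {
  if (fc_threshold <= 1) stop2("fc_threshold must be > 1")
  if (alpha <= 0 || alpha >= 1) stop2("alpha must be in (0, 1)")
  if (!all(c(metaphase_I, metaphase_II) %in% timepoints))
    stop2("metaphase anchors must be members of timepoints")
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 timepoints = as.integer(timepoints),
                 metaphase_I = as.integer(metaphase_I),
                 metaphase_II = as.integer(metaphase_II),
                 fc_clamp_display = fc_clamp_display),
            class = "analysis_config")
}

#' Median fold change across replicate pairs with zero imputation
#'
#' Per-replicate ratios test/ref are computed pairwise (rep i of the test
#' group against rep i of the reference group) and summarized by their
#' median. When any paired value is zero, all zeros in the pair vectors
#' are first replaced by the minimum nonzero value of the whole filtered
#' dataset and the ratios recomputed; the `imputed` flag records that
#' substitution happened.
#'
#' @param ref,test Numeric vectors of replicate-matched intensities.
#' @param dataset_min Smallest nonzero intensity of the filtered dataset.
#' @return A list: `median_fc`, `imputed`, and `raw_median_fc` (the
#'   median of the unimputed ratios, possibly `Inf`/`NaN`).
#' @export
replicate_fold_change <- function(ref, test, dataset_min) {
  if (!length(ref) || length(ref) != length(test))
    stop2("ref and test must be nonempty and replicate-matched")
  if (!is.finite(dataset_min) || dataset_min <= 0)
    stop2("dataset_min must be a positive number")
  raw <- stats::median(test / ref)
  imputed <- any(ref == 0) || any(test == 0)
  if (imputed) {
    ref2 <- ifelse(ref == 0, dataset_min, ref)
    test2 <- ifelse(test == 0, dataset_min, test)
    fc <- stats::median(test2 / ref2)
  } else {
    fc <- raw
  }
  list(median_fc = fc, imputed = imputed, raw_median_fc = raw)
}

#' Welch's two-sample t-test
#'
#' The unequal-variance t statistic with Satterthwaite degrees of freedom
#' and a two-sided p-value, as run by `t.test()` with default parameters.
#' Degenerate inputs follow a deterministic convention: when both groups
#' have zero variance, equal means give `p = 1` and unequal means give
#' `p = 0` (the limit of vanishing standard error).
#'
#' @param a,b Numeric vectors, at least two values each.
#' @return A list with `t`, `df` and `p`.
#' @export
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop2("each group needs at least two values")
  va <- stats::var(a); vb <- stats::var(b)
  delta <- mean(a) - mean(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (delta == 0) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(delta) * Inf, df = NA_real_, p = 0))
  }
  t <- delta / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

categorize_fc <- function(fc, p, rescue, config) {
  sig <- !is.na(p) & p < config$alpha
  up <- (!is.na(fc) & fc > config$fc_threshold) | rescue == "up"
  dn <- (!is.na(fc) & fc < 1 / config$fc_threshold) | rescue == "down"
  ifelse(sig & up, "increased", ifelse(sig & dn, "decreased", "no_change"))
}

call_one_comparison <- function(m, ref_cols, test_cols, label, config,
                                dataset_min) {
  n <- nrow(m)
  fc <- numeric(n); imputed <- logical(n); rescue <- character(n)
  pv <- numeric(n)
  refm <- m[, ref_cols, drop = FALSE]
  testm <- m[, test_cols, drop = FALSE]
  for (i in seq_len(n)) {
    r <- refm[i, ]; t_ <- testm[i, ]
    rfc <- replicate_fold_change(r, t_, dataset_min)
    fc[i] <- rfc$median_fc
    imputed[i] <- rfc$imputed
    ## 0-vs->0 rescue: one side entirely missing, the other entirely
    ## observed; the fold-change criterion is then satisfied by rule
    rescue[i] <- if (all(r == 0) && all(t_ > 0)) "up"
      else if (all(t_ == 0) && all(r > 0)) "down"
      else ""
    ## t test on the literal intensity values, zeros included
    pv[i] <- welch_t(t_, r)$p
  }
  cat_ <- categorize_fc(fc, pv, rescue, config)
  data.frame(feature = rownames(m) %||% as.character(seq_len(n)),
             comparison = label,
             median_fc = fc,
             p_value = pv,
             category = cat_,
             zero_rescue = rescue != "" & cat_ != "no_change",
             imputed = imputed,
             stringsAsFactors = FALSE)
}

#' Differential calling across a set of pairwise comparisons
#'
#' Implements the fold-change plus Welch t-test calling rule: per feature
#' and comparison, the median replicate-paired fold change must exceed
#' `fc_threshold` (or fall below its reciprocal) and the Welch t-test on
#' all replicate values of each side must give `p < alpha`. Comparisons
#' where one side is entirely zero and the other entirely nonzero may
#' satisfy the fold-change criterion by rule (zero rescue); their fold
#' changes are imputed with the dataset minimum. A Benjamini-Hochberg
#' column is appended for information only and never used for category
#' assignment (the original analysis applies none).
#'
#' @param m Intensity matrix (features x channels), zeros = missing.
#' @param comparisons A list of comparisons, each a list with `label`,
#'   `ref` (channel names of the reference group, replicate-ordered) and
#'   `test` (channel names of the test group, replicate-ordered).
#' @param config An [analysis_config()].
#' @param dataset_min Smallest nonzero value of the filtered dataset;
#'   computed from `m` when `NULL`.
#' @return A data.frame of per-feature, per-comparison results with
#'   columns `feature`, `comparison`, `median_fc`, `p_value`, `category`,
#'   `zero_rescue`, `imputed`, `q_value`.
#' @export
call_differential <- function(m, comparisons, config = analysis_config(),
                              dataset_min = NULL) {
  if (is.null(dataset_min)) {
    vals <- m[m > 0 & !is.na(m)]
    if (!length(vals)) stop2("matrix has no nonzero values")
    dataset_min <- min(vals)
  }
  for (cmp in comparisons) {
    bad <- setdiff(c(cmp$ref, cmp$test), colnames(m))
    if (length(bad))
      stop2("comparison '", cmp$label, "' references unknown channel(s): ",
            paste(bad, collapse = ", "))
  }
  out <- do.call(rbind, lapply(comparisons, function(cmp)
    call_one_comparison(m, cmp$ref, cmp$test, cmp$label, config,
                        dataset_min)))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Build the reference-timepoint comparisons of a time-course design
#'
#' One comparison per post-reference timepoint: reference channels are
#' the strain's replicates at `ref_timepoint`, test channels the same
#' replicates at the later timepoint.
#'
#' @param design A [sample_design()].
#' @param strain Strain to compare within.
#' @param enrichment `"N"` or `"PE"`.
#' @param ref_timepoint Reference timepoint (default 0).
#' @return A list of comparisons for [call_differential()].
#' @export
timecourse_comparisons <- function(design, strain, enrichment = "PE",
                                   ref_timepoint = 0L) {
  d <- design[design$enrichment == enrichment & design$strain == strain, ,
              drop = FALSE]
  d <- d[order(d$replicate, d$timepoint_min), , drop = FALSE]
  tps <- sort(unique(d$timepoint_min))
  if (!ref_timepoint %in% tps)
    stop2("reference timepoint ", ref_timepoint, " not in design")
  chan <- function(tp) {
    dd <- d[d$timepoint_min == tp, , drop = FALSE]
    dd$channel_label[order(dd$replicate)]
  }
  lapply(setdiff(tps, ref_timepoint), function(tp)
    list(label = paste0(strain, ":t", ref_timepoint, "-vs-t", tp),
         ref = chan(ref_timepoint), test = chan(tp)))
}

#' Build strain-versus-strain comparisons at matched timepoints
#'
#' @param design A [sample_design()].
#' @param strain_ref,strain_test The two strains; fold changes are
#'   test/ref.
#' @param enrichment `"N"` or `"PE"`.
#' @param timepoints Timepoints to compare; default all shared.
#' @return A list of comparisons for [call_differential()].
#' @export
strain_comparisons <- function(design, strain_ref, strain_test,
                               enrichment = "PE", timepoints = NULL) {
  d <- design[design$enrichment == enrichment, , drop = FALSE]
  tps <- timepoints %||% sort(unique(d$timepoint_min))
  chan <- function(s, tp) {
    dd <- d[d$strain == s & d$timepoint_min == tp, , drop = FALSE]
    dd$channel_label[order(dd$replicate)]
  }
  lapply(tps, function(tp)
    list(label = paste0(strain_test, "-vs-", strain_ref, "@t", tp),
         ref = chan(strain_ref, tp), test = chan(strain_test, tp)))
}

#' Summarize per-comparison calls into per-feature dynamic flags
#'
#' A feature is dynamic when at least one comparison is called
#' `increased` or `decreased`.
#'
#' @param calls Result of [call_differential()].
#' @return A data.frame with `feature`, `dynamic`, `n_increased`,
#'   `n_decreased`, `direction` (`increased`/`decreased`/`variable`/
#'   `no_change`).
#' @export
summarize_calls <- function(calls) {
  sp <- split(calls$category, calls$feature)
  feats <- names(sp)
  ninc <- vapply(sp, function(x) sum(x == "increased"), integer(1))
  ndec <- vapply(sp, function(x) sum(x == "decreased"), integer(1))
  data.frame(feature = feats,
             dynamic = ninc + ndec > 0L,
             n_increased = ninc,
             n_decreased = ndec,
             direction = ifelse(ninc > 0 & ndec > 0, "variable",
                         ifelse(ninc > 0, "increased",
                         ifelse(ndec > 0, "decreased", "no_change"))),
             stringsAsFactors = FALSE)
}

#' Classify the metaphase-to-anaphase transition of a feature set
#'
#' Compares the metaphase anchor timepoint against each later timepoint
#' with the same fold-change plus t-test rule; a feature is classified by
#' its earliest significant post-metaphase change.
#'
#' @param m Intensity matrix.
#' @param design A [sample_design()].
#' @param strain Strain to analyze.
#' @param enrichment `"N"` or `"PE"`.
#' @param metaphase `"I"` or `"II"`, selecting the configured anchor
#'   (75 or 120 min).
#' @param config An [analysis_config()].
#' @param dataset_min See [call_differential()].
#' @return A data.frame with `feature` and `category`
#'   (`increased`/`decreased`/`no_change` after the chosen metaphase).
#' @export
classify_transition <- function(m, design, strain, enrichment = "PE",
                                metaphase = c("I", "II"),
                                config = analysis_config(),
                                dataset_min = NULL) {
  metaphase <- match.arg(metaphase)
  anchor <- if (metaphase == "I") config$metaphase_I else config$metaphase_II
  d <- design[design$enrichment == enrichment & design$strain == strain, ,
              drop = FALSE]
  tps <- sort(unique(d$timepoint_min))
  if (!anchor %in% tps) stop2("metaphase anchor not in design timepoints")
  later <- tps[tps > anchor]
  chan <- function(tp) {
    dd <- d[d$timepoint_min == tp, , drop = FALSE]
    dd$channel_label[order(dd$replicate)]
  }
  cmps <- lapply(later, function(tp)
    list(label = paste0("t", tp), ref = chan(anchor), test = chan(tp)))
  calls <- call_differential(m, cmps, config, dataset_min)
  ## earliest significant change decides the class
  cat_ <- vapply(split(calls, calls$feature), function(df) {
    df <- df[match(paste0("t", later), df$comparison), ]
    hit <- which(df$category != "no_change")
    if (!length(hit)) "no_change" else df$category[hit[1L]]
  }, character(1))
  data.frame(feature = names(cat_), category = unname(cat_),
             stringsAsFactors = FALSE)
}

#' Scale temporal profiles
#'
#' `mode = "mean"`: each feature is divided by its own mean over the
#' scoped values, zeros included (so scaled values average 1; zeros stay
#' zero). For a combined two-strain profile the mean is taken over all
#' scoped timepoints jointly, preserving inter-strain differences.
#' `mode = "reference_tp"`: each feature is divided by its value at the
#' reference column, putting the reference timepoint at 1.
#'
#' @param m Matrix of averaged profiles (features x timepoints, possibly
#'   strain-concatenated).
#' @param mode `"mean"` or `"reference_tp"`.
#' @param reference_col Column name or index of the reference timepoint
#'   (required for `mode = "reference_tp"`).
#' @return The scaled matrix; features with zero mean (or zero reference
#'   value) are dropped, with a message, and recorded in the `dropped`
#'   attribute.
#' @export
scale_profile <- function(m, mode = c("mean", "reference_tp"),
                          reference_col = NULL) {
  mode <- match.arg(mode)
  denom <- if (mode == "mean") rowMeans(m) else {
    if (is.null(reference_col)) stop2("reference_col required")
    m[, reference_col]
  }
  bad <- !is.finite(denom) | denom <= 0
  if (any(bad))
    message(sum(bad), " feature(s) with zero ",
            if (mode == "mean") "mean" else "reference value",
            " excluded from scaling")
  out <- m[!bad, , drop = FALSE] / denom[!bad]
  attr(out, "dropped") <- rownames(m)[bad] %||% which(bad)
  out
}

#' Average replicate time courses
#'
#' Arithmetic mean of the replicate matrices, zeros included — a feature
#' missing at a timepoint in one of two replicates is thereby reduced by
#' half.
#'
#' @param ... Two or more matrices of identical dimensions (features x
#'   timepoints), or a single list of such matrices.
#' @return The element-wise mean matrix.
#' @export
average_replicates <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]]))
    mats <- mats[[1L]]
  if (length(mats) < 2L) stop2("at least two replicates required")
  dims <- unique(lapply(mats, dim))
  if (length(dims) > 1L) stop2("replicate matrices differ in dimension")
  Reduce(`+`, mats) / length(mats)
}

#' Assemble per-replicate profile matrices from a channel matrix
#'
#' @param m Intensity matrix (features x channels).
#' @param design A [sample_design()].
#' @param strain Strain to extract.
#' @param enrichment `"N"` or `"PE"`.
#' @return A named list of matrices, one per replicate, columns ordered
#'   by timepoint and named `t<minutes>`.
#' @export
replicate_profiles <- function(m, design, strain, enrichment = "PE") {
  d <- design[design$enrichment == enrichment & design$strain == strain, ,
              drop = FALSE]
  reps <- sort(unique(d$replicate))
  stats::setNames(lapply(reps, function(r) {
    dd <- d[d$replicate == r, , drop = FALSE]
    dd <- dd[order(dd$timepoint_min), , drop = FALSE]
    prof <- m[, dd$channel_label, drop = FALSE]
    colnames(prof) <- paste0("t", dd$timepoint_min)
    prof
  }), paste0("rep", reps))
}
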
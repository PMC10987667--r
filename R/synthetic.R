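## Synthetic MaxQuant-dialect datasets with planted kinase-activity
## waves. The generator emulates the statistical structure of a TMT
## phosphoproteome study of the budding-yeast meiotic divisions: a
## 10-timepoint prophase block-release time course in two strains with
## two replicate TMT plexes each (plus a replicate-only metaphase-I
## arrest design), multiplicative log-normal measurement noise,
## per-channel scaling, per-replicate batch effects, intensity-dependent
## dropout and phospho-site localization scores.

#' Default planted kinase-activity waves
#'
#' Three kinase classes over the 10-timepoint design:
#' * `cdk` — strict Cdk consensus `[ST]*Px[KR]`, a biphasic wave peaking
#'   at metaphase I (75 min) and metaphase II (120 min) in both strains;
#' * `polo_spo13` — Polo consensus with a +1 aromatic preference,
#'   `[DEN]x[ST]*F`: a meiosis-I peak (x`mi_peak` at 75 min) present in
#'   the wild type and abolished in the mutant, plus a shared smaller
#'   meiosis-II component;
#' * `ck1` — casein-kinase-1-like acidophilic consensus `[ST]xx[ST]*`,
#'   rising in late meiosis II in both strains.
#'
#' @param timepoints Timepoint vector (minutes).
#' @param mi_peak Wild-type meiosis-I activity ratio of the
#'   `polo_spo13` class at 75 min (default 3).
#' @return Named list of kinase specifications (`pattern`, `fraction`,
#'   `activity`: strain x timepoint matrix).
#' @export
default_kinases <- function(timepoints = c(0L, seq(45L, 165L, by = 15L)),
                            mi_peak = 3) {
  if (length(timepoints) != 10L)
    stop2("default kinase waves are defined for the 10-timepoint design")
  act <- function(wt, mut) {
    m <- rbind(wild_type = wt, mutant = mut)
    colnames(m) <- paste0("t", timepoints)
    m
  }
  cdk <- c(1, 1, 1.6, 3, 1.6, 1.3, 3, 1.6, 1, 1)
  polo_wt <- c(1, 1, 2, mi_peak, 2, 1.2, 1.8, 1.8, 1, 1)
  polo_mut <- c(1, 1, 1, 1, 1, 1, 1.8, 1.8, 1, 1)
  ck1 <- c(1, 1, 1, 1, 1, 1, 1.3, 2, 3, 3)
  list(
    cdk = list(pattern = "[ST]*Px[KR]", fraction = 0.15,
               activity = act(cdk, cdk)),
    polo_spo13 = list(pattern = "[DEN]x[ST]*F", fraction = 0.10,
                      activity = act(polo_wt, polo_mut)),
    ck1 = list(pattern = "[ST]xx[ST]*", fraction = 0.10,
               activity = act(ck1, ck1)))
}

#' Simulation configuration
#'
#' @param n_proteins,n_sites Dataset size (defaults 1000 proteins, 2000
#'   phospho-sites; sites are assigned to proteins uniformly at random,
#'   giving a Poisson-like sites-per-protein distribution).
#' @param timepoints Time-course design (minutes).
#' @param n_replicates Replicate TMT plexes per strain (default 2).
#' @param n_replicates_arrest Replicates per strain in the arrest design
#'   (default 4).
#' @param strains Strain names; the first is the wild type.
#' @param kinases Kinase specification list, see [default_kinases()].
#' @param metaphase_tp Timepoint sampled by the arrest design (75 min).
#' @param baseline_log2_mean,baseline_log2_sd Protein baseline log2
#'   intensity distribution (site baselines sit 2 log2 units lower).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (default 0.2).
#' @param channel_sd_log2 SD of per-channel log2 scaling effects.
#' @param batch_sd_log2 SD of per-feature, per-replicate (batch) log2
#'   offsets in the time-course design (arrest plexes are single runs and
#'   carry none).
#' @param dropout_rate Target marginal zero rate (default 0.10).
#' @param dropout_slope Slope of the logistic dropout model in log2
#'   intensity units (default 0.35; small values give a sharp detection
#'   limit, concentrating missingness in low-abundance features).
#' @param loc_high_shape1,loc_high_shape2,loc_high_frac Localization
#'   probability model: a `loc_high_frac` fraction of sites draw from
#'   `Beta(shape1, shape2)` (well-localized), the rest from Uniform(0,1).
#' @param frac_contaminant,frac_reverse Fractions of appended decoy rows.
#' @param protein_dynamic_frac,protein_dynamic_amp Fraction of proteins
#'   given a temporal abundance wave, and its amplitude.
#' @param seed Integer seed; every draw derives from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 1000L, n_sites = 2000L,
                       timepoints = c(0L, seq(45L, 165L, by = 15L)),
                       n_replicates = 2L, n_replicates_arrest = 4L,
                       strains = c("wild_type", "mutant"),
                       kinases = default_kinases(timepoints),
                       metaphase_tp = 75L,
                       baseline_log2_mean = 20, baseline_log2_sd = 2,
                       noise_cv = 0.2,
                       channel_sd_log2 = 0.4,
                       batch_sd_log2 = 0.4,
                       dropout_rate = 0.10, dropout_slope = 0.35,
                       loc_high_shape1 = 40, loc_high_shape2 = 2,
                       loc_high_frac = 0.85,
                       frac_contaminant = 0.01, frac_reverse = 0.01,
                       protein_dynamic_frac = 0.10,
                       protein_dynamic_amp = 2,
                       seed = 1L) {
  cfg <- mget(names(formals()))
  if (any(vapply(kinases, function(k) any(k$activity <= 0), logical(1))))
    stop2("kinase activity profiles must be positive")
  if (sum(vapply(kinases, `[[`, numeric(1), "fraction")) > 1)
    stop2("kinase fractions sum to more than 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop2("dropout_rate must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

## draw a window matching (or not constrained by) a motif pattern
draw_windows <- function(n, center_res, pattern = NULL, half = 15L) {
  if (n == 0L) return(character(0))
  wl <- 2L * half + 1L
  mat <- matrix(sample(AA, n * wl, replace = TRUE), nrow = n)
  mat[, half + 1L] <- center_res
  if (!is.null(pattern)) {
    offs <- as.integer(names(pattern$constraints))
    for (i in seq_along(offs)) {
      set <- pattern$constraints[[i]]
      if (offs[i] == 0L) next   # center already drawn from the star set
      mat[, half + 1L + offs[i]] <-
        sample(set, n, replace = TRUE)
    }
  }
  apply(mat, 1, paste, collapse = "")
}

calibrate_dropout_midpoint <- function(log2_values, rate, slope) {
  if (rate <= 0) return(-Inf)
  f <- function(m) mean(stats::plogis((m - log2_values) / slope)) - rate
  lo <- min(log2_values) - 10; hi <- max(log2_values) + 10
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

sim_design <- function(config, kind) {
  if (kind == "timecourse") {
    g <- expand.grid(enrichment = c("N", "PE"),
                     timepoint_min = config$timepoints,
                     replicate = seq_len(config$n_replicates),
                     strain = config$strains,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    g <- expand.grid(enrichment = c("N", "PE"),
                     replicate = seq_len(config$n_replicates_arrest),
                     strain = config$strains,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$timepoint_min <- config$metaphase_tp
  }
  g$channel_label <- sprintf("%s_r%d_t%d_%s", g$strain, g$replicate,
                             g$timepoint_min, g$enrichment)
  sample_design(g[, c("channel_label", "strain", "replicate",
                      "timepoint_min", "enrichment")])
}

#' Generate a synthetic dataset with known ground truth
#'
#' Emits MaxQuant-dialect proteinGroups and Phospho (STY)Sites tables,
#' the matching sample design, and a truth object recording every
#' planted feature. Protein channel intensity =
#' baseline x temporal profile x channel factor x batch factor x
#' log-normal noise; phospho-site PE intensity additionally carries the
#' assigned kinase's activity(strain, timepoint). Sequence windows are
#' drawn i.i.d. uniform over residues and then overwritten at the
#' assigned kinase's constrained offsets, so unassigned sites match
#' motifs only at the combinatorial background rate. Zeros are injected
#' by a logistic intensity-dependent dropout model whose midpoint is
#' calibrated to the configured marginal rate; contaminant/reverse decoy
#' rows are appended. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param design_kind `"timecourse"` (default) or `"arrest"` (replicated
#'   metaphase-I samples, single TMT run, no batch structure).
#' @return A list: `protein_table`, `phospho_table` (data.frames in the
#'   dialect read by [read_protein_table()] / [read_phospho_table()]),
#'   `design` (a [sample_design()]), and `truth` (list with `sites`,
#'   `proteins`, `kinases`, `config`).
#' @export
generate_dataset <- function(config = sim_config(),
                             design_kind = c("timecourse", "arrest")) {
  design_kind <- match.arg(design_kind)
  set.seed(config$seed)
  np <- config$n_proteins; ns <- config$n_sites
  tps <- config$timepoints
  ntp <- length(tps)
  kin <- lapply(config$kinases, function(k) {
    k$motif <- parse_motif(k$pattern)
    star <- k$motif$constraints[["0"]]
    if (!length(intersect(star, c("S", "T"))))
      stop2("kinase motif unsatisfiable: no S/T phospho-acceptor in '",
            k$pattern, "'")
    k
  })

  ## --- proteins -----------------------------------------------------
  protein_id <- sprintf("P%04d", seq_len(np))
  baseline_p <- 2^stats::rnorm(np, config$baseline_log2_mean,
                               config$baseline_log2_sd)
  dyn_p <- stats::runif(np) < config$protein_dynamic_frac
  ## smooth abundance wave: Gaussian bump at a random timepoint
  prof_p <- matrix(1, np, ntp, dimnames = list(protein_id,
                                               paste0("t", tps)))
  peak_tp <- sample(seq_len(ntp), np, replace = TRUE)
  for (i in which(dyn_p)) {
    prof_p[i, ] <- 1 + (config$protein_dynamic_amp - 1) *
      exp(-((seq_len(ntp) - peak_tp[i])^2) / 4)
  }

  ## --- sites --------------------------------------------------------
  site_protein <- protein_id[sample.int(np, ns, replace = TRUE)]
  nk <- vapply(kin, function(k) as.integer(floor(k$fraction * ns)),
               integer(1))
  kinase_of <- rep("none", ns)
  idx <- sample.int(ns)   # shuffle so planted classes are interspersed
  at <- 1L
  for (kn in names(kin)) {
    kinase_of[idx[at:(at + nk[[kn]] - 1L)]] <- kn
    at <- at + nk[[kn]]
  }
  center <- character(ns)
  windows <- character(ns)
  bg <- kinase_of == "none"
  center[bg] <- sample(c("S", "T", "Y"), sum(bg), replace = TRUE,
                       prob = c(0.75, 0.2, 0.05))
  windows[bg] <- draw_windows(sum(bg), center[bg])
  for (kn in names(kin)) {
    sel <- kinase_of == kn
    star <- intersect(kin[[kn]]$motif$constraints[["0"]], c("S", "T"))
    center[sel] <- sample(star, sum(sel), replace = TRUE)
    windows[sel] <- draw_windows(sum(sel), center[sel], kin[[kn]]$motif)
  }
  position <- sample.int(600L, ns, replace = TRUE)
  site_id <- make.unique(paste0(site_protein, "_", center, position))
  hi <- stats::runif(ns) < config$loc_high_frac
  localization <- ifelse(hi,
                         stats::rbeta(ns, config$loc_high_shape1,
                                      config$loc_high_shape2),
                         stats::runif(ns))
  baseline_s <- 2^stats::rnorm(ns, config$baseline_log2_mean - 2,
                               config$baseline_log2_sd)

  ## --- channel values ----------------------------------------------
  design <- sim_design(config, design_kind)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  ch_factor <- 2^stats::rnorm(nrow(design), 0, config$channel_sd_log2)
  names(ch_factor) <- design$channel_label
  use_batch <- design_kind == "timecourse" && config$batch_sd_log2 > 0
  nreps <- if (design_kind == "timecourse") config$n_replicates else
    config$n_replicates_arrest
  batch_p <- matrix(0, np, nreps)
  batch_s <- matrix(0, ns, nreps)
  if (use_batch) {
    batch_p <- matrix(stats::rnorm(np * nreps, 0, config$batch_sd_log2),
                      np, nreps)
    batch_s <- matrix(stats::rnorm(ns * nreps, 0, config$batch_sd_log2),
                      ns, nreps)
  }
  tp_index <- match(design$timepoint_min, tps)
  prot_of_site <- match(site_protein, protein_id)

  activity_at <- function(kn, strain, tpi) {
    if (kn == "none") return(rep(1, length(tpi)))
    kin[[kn]]$activity[strain, tpi]
  }

  n_mat <- matrix(0, np, nrow(design[design$enrichment == "N", ]))
  pe_mat <- matrix(0, ns, nrow(design[design$enrichment == "PE", ]))
  dn <- design[design$enrichment == "N", , drop = FALSE]
  dpe <- design[design$enrichment == "PE", , drop = FALSE]
  colnames(n_mat) <- dn$channel_label
  colnames(pe_mat) <- dpe$channel_label
  rownames(n_mat) <- protein_id
  rownames(pe_mat) <- site_id
  for (j in seq_len(nrow(dn))) {
    tpi <- match(dn$timepoint_min[j], tps)
    n_mat[, j] <- baseline_p * prof_p[, tpi] *
      ch_factor[dn$channel_label[j]] * 2^batch_p[, dn$replicate[j]] *
      exp(stats::rnorm(np, 0, sdlog))
  }
  site_act <- matrix(1, ns, nrow(dpe))
  for (j in seq_len(nrow(dpe))) {
    tpi <- match(dpe$timepoint_min[j], tps)
    act <- rep(1, ns)
    for (kn in names(kin)) {
      sel <- kinase_of == kn
      act[sel] <- kin[[kn]]$activity[dpe$strain[j], tpi]
    }
    site_act[, j] <- act
    pe_mat[, j] <- baseline_s * prof_p[prot_of_site, tpi] * act *
      ch_factor[dpe$channel_label[j]] * 2^batch_s[, dpe$replicate[j]] *
      exp(stats::rnorm(ns, 0, sdlog))
  }

  ## --- dropout ------------------------------------------------------
  if (config$dropout_rate > 0) {
    all_log2 <- log2(c(n_mat, pe_mat))
    mid <- calibrate_dropout_midpoint(all_log2, config$dropout_rate,
                                      config$dropout_slope)
    p_n <- stats::plogis((mid - log2(n_mat)) / config$dropout_slope)
    p_pe <- stats::plogis((mid - log2(pe_mat)) / config$dropout_slope)
    n_mat[stats::runif(length(n_mat)) < p_n] <- 0
    pe_mat[stats::runif(length(pe_mat)) < p_pe] <- 0
  } else {
    mid <- -Inf
  }

  ## --- truth --------------------------------------------------------
  fc_thr <- 1.5
  dyn_flag <- function(kn, strain) {
    if (kn == "none") return(FALSE)
    a <- kin[[kn]]$activity[strain, ]
    any(a / a[1L] > fc_thr | a / a[1L] < 1 / fc_thr)
  }
  strain_wt <- config$strains[1L]
  strain_mut <- config$strains[2L]
  diff_flag <- vapply(kinase_of, function(kn) {
    if (kn == "none") return(FALSE)
    r <- kin[[kn]]$activity[strain_wt, ] / kin[[kn]]$activity[strain_mut, ]
    any(r > fc_thr | r < 1 / fc_thr)
  }, logical(1))
  truth_sites <- data.frame(
    site_id = site_id,
    protein_id = site_protein,
    kinase = kinase_of,
    class = match(kinase_of, c("none", names(kin))) - 1L,
    window = windows,
    localization_prob = localization,
    true_dynamic_wt = vapply(kinase_of, dyn_flag, logical(1),
                             strain = strain_wt),
    true_dynamic_mut = vapply(kinase_of, dyn_flag, logical(1),
                              strain = strain_mut),
    true_strain_diff = diff_flag,
    stringsAsFactors = FALSE)
  truth_proteins <- data.frame(protein_id = protein_id,
                               dynamic = dyn_p,
                               stringsAsFactors = FALSE)

  ## --- decoys and tables -------------------------------------------
  n_cont <- ceiling(config$frac_contaminant * np)
  n_rev <- ceiling(config$frac_reverse * np)
  decoy_ids <- c(sprintf("CON_%03d", seq_len(n_cont)),
                 sprintf("REV_%03d", seq_len(n_rev)))
  decoy_m <- matrix(2^stats::rnorm(length(decoy_ids) * ncol(n_mat),
                                   config$baseline_log2_mean,
                                   config$baseline_log2_sd),
                    nrow = length(decoy_ids), ncol = ncol(n_mat))
  protein_table <- data.frame(
    `Majority protein IDs` = c(protein_id, decoy_ids),
    `Gene names` = c(sprintf("GEN%04d", seq_len(np)),
                     rep("", length(decoy_ids))),
    `Potential contaminant` = c(rep("", np), rep("+", n_cont),
                                rep("", n_rev)),
    Reverse = c(rep("", np + n_cont), rep("+", n_rev)),
    check.names = FALSE, stringsAsFactors = FALSE)
  pm <- rbind(n_mat, decoy_m)
  colnames(pm) <- colnames(n_mat)
  for (ch in colnames(pm))
    protein_table[[paste0("Reporter intensity corrected ", ch)]] <- pm[, ch]

  n_cont_s <- ceiling(config$frac_contaminant * ns / 10)
  decoy_site <- sprintf("CON_SITE_%03d", seq_len(n_cont_s))
  decoy_sm <- matrix(2^stats::rnorm(n_cont_s * ncol(pe_mat),
                                    config$baseline_log2_mean - 2,
                                    config$baseline_log2_sd),
                     nrow = n_cont_s, ncol = ncol(pe_mat))
  phospho_table <- data.frame(
    Protein = c(site_protein, decoy_site),
    Position = c(position, sample.int(600L, n_cont_s, replace = TRUE)),
    `Amino acid` = c(center, rep("S", n_cont_s)),
    `Localization prob` = c(localization,
                            stats::runif(n_cont_s)),
    `Sequence window` = c(windows, draw_windows(n_cont_s, "S")),
    `Potential contaminant` = c(rep("", ns), rep("+", n_cont_s)),
    Reverse = rep("", ns + n_cont_s),
    check.names = FALSE, stringsAsFactors = FALSE)
  sm <- rbind(pe_mat, decoy_sm)
  for (ch in colnames(pe_mat))
    phospho_table[[paste0("Reporter intensity corrected ", ch, "___1")]] <-
      sm[, match(ch, colnames(pe_mat))]

  list(protein_table = protein_table,
       phospho_table = phospho_table,
       design = design,
       truth = list(sites = truth_sites, proteins = truth_proteins,
                    kinases = kin, dropout_midpoint = mid,
                    config = config, design_kind = design_kind))
}

#' Write a synthetic dataset to tab-delimited files
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(protein = file.path(dir, "proteinGroups.txt"),
             phospho = file.path(dir, "phospho_sites.txt"),
             design = file.path(dir, "sample_design.tsv"),
             truth = file.path(dir, "truth_sites.tsv"))
  write_tsv(dataset$protein_table, paths["protein"])
  write_tsv(dataset$phospho_table, paths["phospho"])
  write_tsv(as.data.frame(dataset$design), paths["design"])
  write_tsv(dataset$truth$sites, paths["truth"])
  invisible(paths)
}

#' Score pipeline calls against the planted truth
#'
#' Metrics are computed over the features present in `calls` (the
#' analyzed set): features removed upstream by detection or localization
#' filters are not counted against the calling procedure. Every call id
#' must exist in the truth table.
#'
#' @param calls A data.frame with columns `feature` and `called`
#'   (logical), e.g. derived from [summarize_calls()].
#' @param truth The `truth$sites` data.frame of [generate_dataset()].
#' @param truth_col Name of the logical truth column to score against
#'   (default `"true_strain_diff"`).
#' @param clusters Optional `ward_cluster` object or named assignment
#'   vector; scored by adjusted Rand index against the planted `class`
#'   column over the clustered features.
#' @param profiles Optional averaged profile matrix (features x
#'   timepoints) for per-kinase profile correlations: Pearson correlation
#'   between each planted class's median profile and its activity wave.
#' @param strain Strain whose activity waves are correlated (default
#'   wild type).
#' @return A list: `sensitivity`, `fdr`, `n_called`, `n_true`, and when
#'   inputs are given `ari` and `kinase_cor`.
#' @export
evaluate_against_truth <- function(calls, truth,
                                   truth_col = "true_strain_diff",
                                   clusters = NULL, profiles = NULL,
                                   strain = NULL) {
  if (!all(c("feature", "called") %in% names(calls)))
    stop2("calls needs columns 'feature' and 'called'")
  full <- NULL
  if (!is.data.frame(truth)) { full <- truth; truth <- truth$sites }
  bad <- setdiff(calls$feature, truth$site_id)
  if (length(bad))
    stop2("call id(s) absent from truth: ",
          paste(utils::head(bad, 5), collapse = ", "))
  tr <- truth[[truth_col]][match(calls$feature, truth$site_id)]
  tp <- sum(calls$called & tr)
  fp <- sum(calls$called & !tr)
  fn <- sum(!calls$called & tr)
  out <- list(sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
              fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
              n_called = tp + fp, n_true = tp + fn)
  if (!is.null(clusters)) {
    cl <- if (inherits(clusters, "ward_cluster")) clusters$assignment else
      clusters
    common <- intersect(names(cl), truth$site_id)
    if (!length(common)) stop2("no clustered features found in truth")
    out$ari <- mclust::adjustedRandIndex(
      cl[common], truth$class[match(common, truth$site_id)])
  }
  if (!is.null(profiles)) {
    if (is.null(full))
      stop2("profile correlations need the full truth list")
    out$kinase_cor <- kinase_profile_cor(profiles, full, strain)
  }
  out
}

#' Correlation of planted-class median profiles with activity waves
#'
#' @param profiles Averaged (optionally scaled) profile matrix, columns
#'   `t<minutes>`.
#' @param truth The full `truth` list of [generate_dataset()] (needs
#'   `sites` and `kinases`).
#' @param strain Strain row of the activity matrices; default the first.
#' @return Named numeric vector of Pearson correlations per kinase class.
#' @export
kinase_profile_cor <- function(profiles, truth, strain = NULL) {
  sites <- if (is.data.frame(truth)) stop2("pass the full truth list") else
    truth$sites
  kin <- truth$kinases
  strain <- strain %||% rownames(kin[[1L]]$activity)[1L]
  vapply(names(kin), function(kn) {
    ids <- intersect(sites$site_id[sites$kinase == kn], rownames(profiles))
    if (length(ids) < 2L) return(NA_real_)
    med <- apply(profiles[ids, , drop = FALSE], 2, stats::median)
    act <- kin[[kn]]$activity[strain, colnames(profiles)]
    stats::cor(med, act)
  }, numeric(1))
}
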
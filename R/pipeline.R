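## End-to-end orchestration of the three analysis designs: prophase
## block-release time course, metaphase-I arrest, and analogue-sensitive
## kinase inhibition. Each run executes the stages in a fixed order —
## read, flag-drop, median-scale, phospho-to-protein normalize,
## batch-correct, detection-filter, differential calls, replicate
## averaging, mean scaling, clustering, motif enrichment — and records a
## manifest of per-stage feature counts.

as_protein_data <- function(x, design, template = NULL) {
  if (inherits(x, "protein_data")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(read_protein_table(x, design, template))
  stop2("protein input must be a path or a protein_data object")
}

as_phospho_data <- function(x, design, template = NULL) {
  if (inherits(x, "phospho_data")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(read_phospho_table(x, design, template))
  stop2("phospho input must be a path or a phospho_data object")
}

#' Convert in-memory MaxQuant-dialect tables to data objects
#'
#' Convenience wrappers for running the pipeline on tables produced by
#' [generate_dataset()] without a round trip through disk. They apply
#' the same parsing rules as the file readers.
#'
#' @param tab A data.frame in the dialect of the corresponding reader.
#' @param design A [sample_design()].
#' @param template Optional reporter-column template.
#' @return A `protein_data` / `phospho_data` object.
#' @export
protein_data_from_table <- function(tab, design, template = NULL) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  write_tsv(tab, tmp)
  read_protein_table(tmp, design, template)
}

#' @rdname protein_data_from_table
#' @export
phospho_data_from_table <- function(tab, design, template = NULL) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  write_tsv(tab, tmp)
  read_phospho_table(tmp, design, template)
}

normalize_stage <- function(prot, phos, design, batch_correct = TRUE) {
  ## channels are median-scaled separately per enrichment type
  ns <- median_scale_channels(prot$intensities)
  ps <- median_scale_channels(phos$intensities)
  prot$intensities <- ns$intensities
  norm <- phospho_to_protein(ps$intensities, ns$intensities,
                             phos$features$protein_id, design)
  if (batch_correct) {
    dn <- design[design$enrichment == "N", , drop = FALSE]
    dpe <- design[design$enrichment == "PE", , drop = FALSE]
    prot$intensities <- correct_batch(
      prot$intensities,
      dn$replicate[match(colnames(prot$intensities), dn$channel_label)])
    norm <- correct_batch(
      norm, dpe$replicate[match(colnames(norm), dpe$channel_label)])
  }
  phos$intensities <- norm
  list(prot = prot, phos = phos,
       reports = list(protein = ns$report, phospho = ps$report))
}

#' Run the time-course analysis design
#'
#' @param protein,phospho Paths to MaxQuant-dialect tables or
#'   `protein_data` / `phospho_data` objects.
#' @param design A [sample_design()] or path to one.
#' @param config An [analysis_config()].
#' @param fconfig A [filter_config()].
#' @param k Cluster count; `NULL` for elbow selection.
#' @param kmax Largest candidate k for the WSS curve.
#' @param cluster_features `"dynamic"` (cluster the wild-type dynamic
#'   features, as in the published analysis) or `"all"`.
#' @param motifs Named list of `motif_pattern`s for enrichment (default
#'   the packaged 12-kinase table); `NULL` to skip.
#' @param term_map Optional [term_map()] for per-cluster
#'   over-representation analysis of protein ids.
#' @param output_dir Optional directory; when given, all result tables
#'   and the manifest are written there as TSV.
#' @param batch_correct Apply two-batch correction with replicate as the
#'   batch (default `TRUE`).
#' @return A list with `normalized` (protein/phospho data), `filters`,
#'   `dynamic_calls`, `dynamic_summary`, `strain_calls` (when two or more
#'   strains), `profiles` (per-strain averaged), `scaled` (mean-scaled,
#'   strain-concatenated when combined), `clusters`, `cluster_summary`,
#'   `motif_enrichment`, `ora`, `manifest`.
#' @export
run_timecourse <- function(protein, phospho, design,
                           config = analysis_config(),
                           fconfig = filter_config(),
                           k = NULL, kmax = 15L,
                           cluster_features = c("dynamic", "all"),
                           motifs = kinase_motifs(),
                           term_map = NULL,
                           output_dir = NULL,
                           batch_correct = TRUE) {
  cluster_features <- match.arg(cluster_features)
  if (is.character(design)) design <- read_sample_design(design)
  if (length(unique(design$timepoint_min)) < 2L)
    stop2("time-course design requires multiple timepoints; ",
          "use run_arrest() for replicate-only designs")
  manifest <- list()
  prot <- as_protein_data(protein, design)
  phos <- as_phospho_data(phospho, design)
  manifest$n_proteins_read <- nrow(prot$features)
  manifest$n_sites_read <- nrow(phos$features)

  prot <- drop_flagged_features(prot)
  phos <- drop_flagged_features(phos)
  manifest$n_proteins_after_flags <- nrow(prot$features)
  manifest$n_sites_after_flags <- nrow(phos$features)

  nz <- normalize_stage(prot, phos, design, batch_correct)
  prot <- nz$prot; phos <- nz$phos

  strains <- unique(design$strain)
  prot_f <- detection_filter(prot, design, fconfig, "protein")
  phos_f <- detection_filter(phos, design, fconfig, "phospho")
  ## any remaining not-normalizable entries revert to true zeros
  phos_f$intensities[is.na(phos_f$intensities)] <- 0
  manifest$n_proteins_final <- nrow(prot_f$features)
  manifest$n_sites_final <- nrow(phos_f$features)

  dataset_min <- {
    v <- phos_f$intensities[phos_f$intensities > 0 &
                              !is.na(phos_f$intensities)]
    if (length(v)) min(v) else NA_real_
  }

  dyn_calls <- list(); dyn_sum <- list()
  for (s in strains) {
    cmp <- timecourse_comparisons(design, s, "PE")
    cl <- call_differential(phos_f$intensities, cmp, config, dataset_min)
    dyn_calls[[s]] <- cl
    dyn_sum[[s]] <- summarize_calls(cl)
    manifest[[paste0("n_dynamic_sites_", s)]] <- sum(dyn_sum[[s]]$dynamic)
  }
  strain_calls <- NULL; strain_sum <- NULL
  if (length(strains) >= 2L) {
    cmp <- strain_comparisons(design, strains[1L], strains[2L], "PE")
    strain_calls <- call_differential(phos_f$intensities, cmp, config,
                                      dataset_min)
    strain_sum <- summarize_calls(strain_calls)
    manifest$n_strain_different_sites <- sum(strain_sum$dynamic)
  }

  profiles <- lapply(strains, function(s)
    average_replicates(replicate_profiles(phos_f$intensities, design, s,
                                          "PE")))
  names(profiles) <- strains
  combined <- do.call(cbind, lapply(strains, function(s) {
    p <- profiles[[s]]
    colnames(p) <- paste0(s, ".", colnames(p))
    p
  }))
  scaled <- scale_profile(combined, "mean")

  wt <- strains[1L]
  cluster_ids <- if (cluster_features == "dynamic") {
    dyn_sum[[wt]]$feature[dyn_sum[[wt]]$dynamic]
  } else rownames(scaled)
  cluster_ids <- intersect(cluster_ids, rownames(scaled))
  clusters <- NULL; csum <- NULL; enrich <- NULL
  if (length(cluster_ids) >= 2L) {
    wt_cols <- grep(paste0("^", wt, "\\."), colnames(scaled))
    clusters <- ward_cluster(scaled[cluster_ids, wt_cols, drop = FALSE],
                             k = k, kmax = kmax)
    csum <- cluster_summary(scaled[cluster_ids, wt_cols, drop = FALSE],
                            clusters)
    manifest$k_clusters <- clusters$k
    if (!is.null(motifs)) {
      windows <- stats::setNames(phos_f$features$window,
                                 phos_f$features$site_id)
      mt <- motif_match_table(windows[cluster_ids], motifs)
      groups <- split(cluster_ids, clusters$assignment)
      names(groups) <- paste0("cluster", names(groups))
      enrich <- motif_enrichment(groups, cluster_ids, mt)
    }
  }

  ora_res <- NULL
  if (!is.null(term_map) && !is.null(clusters)) {
    ora_res <- lapply(split(cluster_ids, clusters$assignment), function(ids) {
      genes <- unique(phos_f$features$protein_id[
        match(ids, phos_f$features$site_id)])
      ora(genes, term_map)
    })
  }

  out <- list(normalized = list(protein = prot, phospho = phos,
                                reports = nz$reports),
              filters = list(protein_audit = attr(prot_f, "audit"),
                             phospho_audit = attr(phos_f, "audit")),
              protein_data = prot_f, phospho_data = phos_f,
              dynamic_calls = dyn_calls, dynamic_summary = dyn_sum,
              strain_calls = strain_calls, strain_summary = strain_sum,
              profiles = profiles, scaled = scaled,
              clusters = clusters, cluster_summary = csum,
              motif_enrichment = enrich, ora = ora_res,
              manifest = manifest, config = config)
  if (!is.null(output_dir)) write_run(out, output_dir)
  out
}

#' Run the replicated-arrest analysis design
#'
#' Median scaling, phospho-to-protein normalization, the
#' at-least-`min_reps`-replicates detection rule, and strain-versus-
#' strain differential calling over replicates. No batch correction is
#' applied (an arrest experiment is a single multiplexed run).
#'
#' @inheritParams run_timecourse
#' @param min_reps Minimum detected replicates per strain (default 3).
#' @param strain_ref,strain_test Strains compared (default the first two
#'   in the design); fold changes are test/ref.
#' @return A list with the filtered data, `calls`, `summary` and
#'   `manifest`.
#' @export
run_arrest <- function(protein, phospho, design,
                       config = analysis_config(),
                       fconfig = filter_config(),
                       min_reps = 3L,
                       strain_ref = NULL, strain_test = NULL,
                       output_dir = NULL) {
  if (is.character(design)) design <- read_sample_design(design)
  manifest <- list()
  prot <- as_protein_data(protein, design)
  phos <- as_phospho_data(phospho, design)
  manifest$n_proteins_read <- nrow(prot$features)
  manifest$n_sites_read <- nrow(phos$features)
  prot <- drop_flagged_features(prot)
  phos <- drop_flagged_features(phos)

  nz <- normalize_stage(prot, phos, design, batch_correct = FALSE)
  prot <- nz$prot; phos <- nz$phos

  prot_f <- arrest_detection_filter(prot, design, min_reps,
                                    config = fconfig)
  phos_f <- arrest_detection_filter(phos, design, min_reps,
                                    config = fconfig)
  phos_f$intensities[is.na(phos_f$intensities)] <- 0
  manifest$n_proteins_final <- nrow(prot_f$features)
  manifest$n_sites_final <- nrow(phos_f$features)

  strains <- unique(design$strain)
  strain_ref <- strain_ref %||% strains[1L]
  strain_test <- strain_test %||% strains[2L]
  d <- design[design$enrichment == "PE", , drop = FALSE]
  chan <- function(s) {
    dd <- d[d$strain == s, , drop = FALSE]
    dd$channel_label[order(dd$replicate)]
  }
  cmp <- list(list(label = paste0(strain_test, "-vs-", strain_ref),
                   ref = chan(strain_ref), test = chan(strain_test)))
  calls <- call_differential(phos_f$intensities, cmp, config)
  summary <- summarize_calls(calls)
  manifest$n_different_sites <- sum(summary$dynamic)

  out <- list(protein_data = prot_f, phospho_data = phos_f,
              calls = calls, summary = summary,
              reports = nz$reports, manifest = manifest, config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(calls, file.path(output_dir, "strain_calls.tsv"))
    write_tsv(manifest_frame(manifest),
              file.path(output_dir, "manifest.tsv"))
  }
  out
}

manifest_frame <- function(manifest) {
  data.frame(key = names(manifest),
             value = vapply(manifest, function(x) as.character(x[1L]),
                            character(1)),
             stringsAsFactors = FALSE)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(run$dynamic_calls))
    write_tsv(run$dynamic_calls[[s]],
              file.path(dir, paste0("dynamic_calls_", s, ".tsv")))
  if (!is.null(run$strain_calls))
    write_tsv(run$strain_calls, file.path(dir, "strain_calls.tsv"))
  if (!is.null(run$clusters)) {
    write_tsv(data.frame(feature = names(run$clusters$assignment),
                         cluster = unname(run$clusters$assignment)),
              file.path(dir, "cluster_assignment.tsv"))
    write_tsv(run$clusters$wss_curve, file.path(dir, "wss_curve.tsv"))
    write_tsv(run$cluster_summary, file.path(dir, "cluster_summary.tsv"))
  }
  if (!is.null(run$motif_enrichment))
    write_tsv(run$motif_enrichment, file.path(dir, "motif_enrichment.tsv"))
  write_tsv(run$normalized$reports$protein,
            file.path(dir, "normalization_protein.tsv"))
  write_tsv(run$normalized$reports$phospho,
            file.path(dir, "normalization_phospho.tsv"))
  write_tsv(run$filters$phospho_audit, file.path(dir, "filter_audit.tsv"))
  write_tsv(manifest_frame(run$manifest), file.path(dir, "manifest.tsv"))
  invisible(dir)
}
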
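## Small in-code fixtures shared across test files.

tiny_timepoints <- c(0L, 45L, 60L, 75L)

## a minimal two-replicate, one- or two-strain time-course design
make_design <- function(strains = "wild_type", reps = 2L,
                        timepoints = tiny_timepoints) {
  g <- expand.grid(enrichment = c("N", "PE"), timepoint_min = timepoints,
                   replicate = seq_len(reps), strain = strains,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$channel_label <- sprintf("%s_r%d_t%d_%s", g$strain, g$replicate,
                             g$timepoint_min, g$enrichment)
  sample_design(g[, c("channel_label", "strain", "replicate",
                      "timepoint_min", "enrichment")])
}

## channels of one enrichment in design order
chans <- function(design, enr) {
  design$channel_label[design$enrichment == enr]
}

## a window with given residues at given offsets, "A" elsewhere
make_window <- function(center = "S", at = list(), wl = 31L) {
  half <- (wl - 1L) %/% 2L
  w <- rep("A", wl)
  w[half + 1L] <- center
  for (off in names(at)) w[half + 1L + as.integer(off)] <- at[[off]]
  paste(w, collapse = "")
}

## write a minimal MaxQuant-style protein table
write_protein_fixture <- function(design, intensities, ids = NULL,
                                  contaminant = NULL, reverse = NULL,
                                  path = tempfile(fileext = ".txt"),
                                  col_prefix = "Reporter intensity corrected ") {
  n <- nrow(intensities)
  ids <- ids %||% sprintf("P%03d", seq_len(n))
  tab <- data.frame(`Majority protein IDs` = ids,
                    `Gene names` = paste0("GEN", seq_len(n)),
                    `Potential contaminant` = contaminant %||% rep("", n),
                    Reverse = reverse %||% rep("", n),
                    check.names = FALSE, stringsAsFactors = FALSE)
  cl <- chans(design, "N")
  for (i in seq_along(cl)) tab[[paste0(col_prefix, cl[i])]] <- intensities[, i]
  write_tsv(tab, path)
  path
}

write_phospho_fixture <- function(design, intensities, proteins,
                                  windows = NULL, positions = NULL,
                                  loc = NULL,
                                  path = tempfile(fileext = ".txt"),
                                  extra_multiplicity = FALSE) {
  n <- nrow(intensities)
  windows <- windows %||% replicate(n, make_window())
  tab <- data.frame(Protein = proteins,
                    Position = positions %||% (seq_len(n) * 7L),
                    `Amino acid` = substr(windows, 16, 16),
                    `Localization prob` = loc %||% rep(0.99, n),
                    `Sequence window` = windows,
                    `Potential contaminant` = rep("", n),
                    Reverse = rep("", n),
                    check.names = FALSE, stringsAsFactors = FALSE)
  cl <- chans(design, "PE")
  for (i in seq_along(cl)) {
    tab[[paste0("Reporter intensity corrected ", cl[i], "___1")]] <-
      intensities[, i]
    if (extra_multiplicity) {
      tab[[paste0("Reporter intensity corrected ", cl[i], "___2")]] <-
        intensities[, i] * 10
      tab[[paste0("Reporter intensity corrected ", cl[i], "___3")]] <-
        intensities[, i] * 100
    }
  }
  write_tsv(tab, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
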
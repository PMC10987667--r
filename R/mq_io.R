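## Readers and writers for MaxQuant-dialect tables, sample designs, motif
## tables and FASTA files. All intensity data are returned as a numeric
## matrix (features x channels) with 0 meaning "not detected", columns
## ordered as in the sample design.

#' Construct and validate a sample design
#'
#' A sample design maps TMT reporter channels to experimental metadata:
#' strain, biological replicate (which doubles as the batch identifier),
#' timepoint in minutes after prophase release, and enrichment type
#' (`"N"` for non-enriched total-protein samples, `"PE"` for
#' phospho-enriched samples).
#'
#' @param x A data.frame with columns `channel_label`, `strain`,
#'   `replicate`, `timepoint_min`, `enrichment`.
#' @return The validated design, classed `"sample_design"`.
#' @export
sample_design <- function(x) {
  need <- c("channel_label", "strain", "replicate", "timepoint_min",
            "enrichment")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop2("sample design is missing column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$replicate <- as.integer(x$replicate)
  x$timepoint_min <- as.integer(x$timepoint_min)
  if (any(is.na(x$replicate)) || any(x$replicate < 1))
    stop2("replicate must be a positive integer")
  if (any(is.na(x$timepoint_min)) || any(x$timepoint_min < 0))
    stop2("timepoint_min must be a nonnegative integer")
  if (!all(x$enrichment %in% c("N", "PE")))
    stop2("enrichment must be one of 'N', 'PE'")
  for (e in unique(x$enrichment)) {
    lab <- x$channel_label[x$enrichment == e]
    if (anyDuplicated(lab))
      stop2("duplicate channel labels within enrichment ", e)
  }
  ## every (strain, replicate) must cover the same timepoint set
  pe <- x[x$enrichment == x$enrichment[1L], ]
  tps <- split(pe$timepoint_min, paste(pe$strain, pe$replicate))
  tps <- lapply(tps, sort)
  if (length(unique(tps)) > 1L)
    stop2("every (strain, replicate) must cover the same timepoint set")
  class(x) <- c("sample_design", "data.frame")
  x
}

#' Read a sample design from a TSV file
#' @param path Path to a tab-delimited design table.
#' @return A `sample_design` data.frame.
#' @export
read_sample_design <- function(path) sample_design(read_tsv(path))

design_channels <- function(design, enrichment) {
  design[design$enrichment == enrichment, , drop = FALSE]
}

#' Resolve reporter-intensity column names for a design
#'
#' MaxQuant emits reporter columns named with spaces
#' (`"Reporter intensity corrected <label>"`); tables that have passed
#' through R often carry the dotted dialect
#' (`"Reporter.intensity.corrected.<label>"`). The template contains
#' `{label}` which is substituted with each channel label; both dialects
#' are tried when `template` is `NULL`.
#'
#' @param header Character vector of column names present in the file.
#' @param labels Channel labels from the design.
#' @param template Column-name template containing `{label}`, or `NULL` to
#'   auto-detect the dialect.
#' @param suffix Suffix appended after the label (used for the
#'   singly-phosphorylated `"___1"` columns).
#' @return Character vector of resolved column names, aligned to `labels`.
#' @export
reporter_columns <- function(header, labels, template = NULL, suffix = "") {
  templates <- if (is.null(template)) {
    c("Reporter intensity corrected {label}",
      "Reporter.intensity.corrected.{label}")
  } else template
  for (tpl in templates) {
    cols <- paste0(sub("{label}", "", tpl, fixed = TRUE), "")
    cols <- vapply(labels, function(l) sub("{label}", l, tpl, fixed = TRUE),
                   character(1))
    cols <- paste0(cols, suffix)
    if (all(cols %in% header)) return(cols)
  }
  ## report which designed channels are missing under the best template
  tpl <- templates[[1L]]
  cols <- paste0(vapply(labels, function(l) sub("{label}", l, tpl, fixed = TRUE),
                        character(1)), suffix)
  missing <- labels[!(cols %in% header)]
  stop2("reporter column(s) not found for channel(s): ",
        paste(missing, collapse = ", "))
}

extract_intensities <- function(tab, cols, path) {
  m <- as.matrix(tab[, cols, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(m, 1, function(r) any(is.na(suppressWarnings(as.numeric(r))) & !is.na(r))))
    stop2("non-numeric intensity value(s) in ", path,
          " at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  m[is.na(m)] <- 0
  if (any(m < 0)) stop2("negative intensity values in ", path)
  m
}

#' Read a MaxQuant proteinGroups table
#'
#' Extracts one record per protein group: the leading (majority) protein
#' accession, optional gene name, contaminant/reverse flags and the
#' reporter intensities of the design's non-enriched (`"N"`) channels,
#' re-ordered to the design's channel order.
#'
#' @param path Path to a tab-delimited proteinGroups table.
#' @param design A [sample_design()]; only its `enrichment == "N"` rows
#'   are used.
#' @param template Optional reporter-column template, see
#'   [reporter_columns()].
#' @return A list of class `"protein_data"` with elements `features`
#'   (data.frame: `protein_id`, `gene_name`, `is_contaminant`,
#'   `is_reverse`) and `intensities` (matrix, rownames = protein ids).
#' @export
read_protein_table <- function(path, design, template = NULL) {
  tab <- read_tsv(path)
  dn <- design_channels(design, "N")
  id_col <- intersect(c("Majority protein IDs", "Majority.protein.IDs",
                        "Protein IDs", "Protein.IDs"), names(tab))
  if (!length(id_col)) stop2("missing mandatory column: 'Majority protein IDs'")
  ids_raw <- tab[[id_col[1L]]]
  protein_id <- vapply(strsplit(as.character(ids_raw), ";", fixed = TRUE),
                       `[`, character(1), 1L)
  n_multi <- sum(grepl(";", ids_raw, fixed = TRUE))
  if (n_multi > 0)
    message(n_multi, " protein group(s) list multiple majority ids; ",
            "matched on the leading id")
  gene_col <- intersect(c("Gene names", "Gene.names"), names(tab))
  gene_name <- if (length(gene_col)) as.character(tab[[gene_col[1L]]]) else
    rep(NA_character_, nrow(tab))
  cont_col <- intersect(c("Potential contaminant", "Potential.contaminant",
                          "Contaminant"), names(tab))
  rev_col <- intersect(c("Reverse"), names(tab))
  cols <- reporter_columns(names(tab), dn$channel_label, template)
  m <- extract_intensities(tab, cols, path)
  colnames(m) <- dn$channel_label
  feats <- data.frame(
    protein_id = protein_id,
    gene_name = gene_name,
    is_contaminant = if (length(cont_col)) is_flag(tab[[cont_col[1L]]]) else
      rep(FALSE, nrow(tab)),
    is_reverse = if (length(rev_col)) is_flag(tab[[rev_col[1L]]]) else
      rep(FALSE, nrow(tab)),
    stringsAsFactors = FALSE)
  rownames(m) <- make.unique(protein_id)
  rownames(feats) <- rownames(m)
  structure(list(features = feats, intensities = m),
            class = "protein_data")
}

#' Read a MaxQuant Phospho (STY)Sites table
#'
#' Retains only the singly-phosphorylated reporter intensities (the
#' `"___1"` columns) of the design's phospho-enriched (`"PE"`) channels.
#' The phospho-acceptor residue is taken from the center of the sequence
#' window; windows must have odd length, with `"_"` padding beyond the
#' protein termini.
#'
#' @inheritParams read_protein_table
#' @return A list of class `"phospho_data"` with elements `features`
#'   (data.frame: `site_id`, `protein_id`, `position`, `residue`,
#'   `localization_prob`, `window`, `is_contaminant`, `is_reverse`) and
#'   `intensities` (matrix, rownames = site ids).
#' @export
read_phospho_table <- function(path, design, template = NULL) {
  tab <- read_tsv(path)
  dp <- design_channels(design, "PE")
  prot_col <- intersect(c("Protein", "Proteins", "Leading proteins"),
                        names(tab))
  if (!length(prot_col)) stop2("missing mandatory column: 'Protein'")
  pos_col <- intersect(c("Position", "Positions within proteins",
                         "Positions.within.proteins"), names(tab))
  if (!length(pos_col)) stop2("missing mandatory column: 'Position'")
  win_col <- intersect(c("Sequence window", "Sequence.window"), names(tab))
  if (!length(win_col)) stop2("missing mandatory column: 'Sequence window'")
  loc_col <- intersect(c("Localization prob", "Localization.prob"),
                       names(tab))
  if (!length(loc_col)) stop2("missing mandatory column: 'Localization prob'")

  protein_id <- vapply(strsplit(as.character(tab[[prot_col[1L]]]), ";",
                                fixed = TRUE), `[`, character(1), 1L)
  position <- as.integer(vapply(strsplit(as.character(tab[[pos_col[1L]]]),
                                         ";", fixed = TRUE),
                                `[`, character(1), 1L))
  window <- toupper(vapply(strsplit(as.character(tab[[win_col[1L]]]), ";",
                                    fixed = TRUE), `[`, character(1), 1L))
  wl <- nchar(window)
  if (any(wl %% 2L == 0L))
    stop2("sequence window(s) of even length at row(s): ",
          paste(utils::head(which(wl %% 2L == 0L), 5), collapse = ", "))
  loc <- as.numeric(tab[[loc_col[1L]]])
  if (any(!is.na(loc) & (loc < 0 | loc > 1)))
    stop2("localization probability outside [0, 1]")
  residue <- substr(window, (wl + 1L) %/% 2L, (wl + 1L) %/% 2L)
  aa_col <- intersect(c("Amino acid", "Amino.acid"), names(tab))
  if (length(aa_col)) {
    stated <- as.character(tab[[aa_col[1L]]])
    bad <- which(residue != PAD & stated != residue)
    if (length(bad))
      stop2("window center disagrees with 'Amino acid' at row(s): ",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  cols <- reporter_columns(names(tab), dp$channel_label, template,
                           suffix = "___1")
  m <- extract_intensities(tab, cols, path)
  colnames(m) <- dp$channel_label
  site_id <- make.unique(paste0(protein_id, "_", residue, position))
  cont_col <- intersect(c("Potential contaminant", "Potential.contaminant",
                          "Contaminant"), names(tab))
  rev_col <- intersect(c("Reverse"), names(tab))
  feats <- data.frame(
    site_id = site_id,
    protein_id = protein_id,
    position = position,
    residue = residue,
    localization_prob = loc,
    window = window,
    is_contaminant = if (length(cont_col)) is_flag(tab[[cont_col[1L]]]) else
      rep(FALSE, nrow(tab)),
    is_reverse = if (length(rev_col)) is_flag(tab[[rev_col[1L]]]) else
      rep(FALSE, nrow(tab)),
    stringsAsFactors = FALSE)
  rownames(m) <- site_id
  rownames(feats) <- site_id
  structure(list(features = feats, intensities = m),
            class = "phospho_data")
}

#' Read a kinase consensus-motif table
#'
#' Expects a two-column tab-delimited table (pattern, kinase name) in the
#' motif grammar of [parse_motif()]. The 12-kinase table shipped with the
#' package is at `system.file("extdata", "kinase_motifs.tsv",
#' package = "phoswave")`.
#'
#' @param path Path to the motif table.
#' @return A named list of `motif_pattern` objects.
#' @export
read_motif_table <- function(path) {
  tab <- read_tsv(path)
  if (ncol(tab) < 2L) stop2("motif table must have two columns")
  pats <- as.character(tab[[1L]])
  names_ <- as.character(tab[[2L]])
  if (anyDuplicated(names_))
    stop2("duplicate kinase name(s) in motif table: ",
          paste(unique(names_[duplicated(names_)]), collapse = ", "))
  out <- lapply(seq_along(pats),
                function(i) parse_motif(pats[i], name = names_[i]))
  names(out) <- names_
  out
}

#' Load the packaged 12-kinase consensus-motif table
#' @return A named list of `motif_pattern` objects.
#' @export
kinase_motifs <- function() {
  read_motif_table(system.file("extdata", "kinase_motifs.tsv",
                               package = "phoswave", mustWork = TRUE))
}

#' Read a FASTA file of protein sequences
#'
#' Uses `Biostrings::readAAStringSet()` when available, otherwise a plain
#' text reader. Identifiers are the first whitespace-delimited token of
#' each header; sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, protein id to sequence.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    seqs <- toupper(as.character(ss))
    ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop2("not a FASTA file: ", path)
    grp <- cumsum(hdr)
    ids <- sub("^>", "", lines[hdr])
    ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) toupper(paste(x, collapse = "")), character(1))
  }
  if (anyDuplicated(ids))
    stop2("duplicate FASTA id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop2("empty sequence(s) for id(s): ",
          paste(ids[nchar(seqs) == 0L], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Read a term-to-gene mapping for over-representation analysis
#'
#' Accepts a tab-delimited table with columns `term`, `gene` and
#' optionally `name` (term description).
#'
#' @param path Path to the mapping table.
#' @return A `term_map` list: `terms` (named list of gene-id vectors),
#'   `names` (term descriptions), `universe` (union of all genes).
#' @export
read_term_map <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("term", "gene") %in% names(tab)))
    stop2("term map needs columns 'term' and 'gene'")
  terms <- lapply(split(as.character(tab$gene), tab$term), unique)
  nm <- if ("name" %in% names(tab)) {
    vapply(split(as.character(tab$name), tab$term), `[`, character(1), 1L)
  } else stats::setNames(names(terms), names(terms))
  term_map(terms, names = nm)
}

#' Construct a term map
#' @param terms Named list of gene-id vectors.
#' @param names Optional named character vector of term descriptions.
#' @param universe Optional gene universe; defaults to the union of all
#'   term gene sets.
#' @return A `term_map` list.
#' @export
term_map <- function(terms, names = NULL, universe = NULL) {
  universe <- universe %||% unique(unlist(terms, use.names = FALSE))
  bad <- vapply(terms, function(g) !all(g %in% universe), logical(1))
  if (any(bad))
    stop2("term(s) with genes outside the universe: ",
          paste(utils::head(base::names(terms)[bad], 5), collapse = ", "))
  structure(list(terms = terms,
                 names = names %||%
                   stats::setNames(base::names(terms), base::names(terms)),
                 universe = universe),
            class = "term_map")
}
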
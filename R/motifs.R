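## Kinase consensus-motif grammar, site matching, enrichment statistics,
## residue-difference logos, sub-motif discovery and protein-sequence
## scanning.
##
## The grammar describes positional residue constraints anchored at the
## phospho-acceptor: tokens are a literal residue ("P"), a bracketed
## residue set ("[DEN]") or the wildcard "x"; exactly one token carries a
## trailing "*" marking the phospho-acceptor (offset 0). Example:
## "[ST]*Px[KR]" constrains offset 0 to {S,T}, +1 to {P}, +3 to {K,R}.

motif_tokens <- function(pattern_text) {
  chars <- strsplit(pattern_text, "")[[1]]
  toks <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars))
        stop2("motif grammar error in '", pattern_text, "': unclosed '['")
      set <- chars[(i + 1L):(j - 1L)]
      if (length(set) == 0L || chars[i + 1L] == "]")
        stop2("motif grammar error in '", pattern_text, "': empty bracket")
      if (!all(set %in% AA))
        stop2("motif grammar error in '", pattern_text, "': illegal residue '",
              paste(setdiff(set, AA), collapse = ""), "'")
      toks[[length(toks) + 1L]] <- list(set = set, star = FALSE)
      i <- j + 1L
    } else if (ch == "x") {
      toks[[length(toks) + 1L]] <- list(set = NULL, star = FALSE)
      i <- i + 1L
    } else if (ch == "*") {
      if (length(toks) == 0L)
        stop2("motif grammar error in '", pattern_text, "': leading '*'")
      if (toks[[length(toks)]]$star)
        stop2("motif grammar error in '", pattern_text, "': repeated '*'")
      if (is.null(toks[[length(toks)]]$set))
        stop2("motif grammar error in '", pattern_text,
              "': '*' cannot adorn the wildcard")
      toks[[length(toks)]]$star <- TRUE
      i <- i + 1L
    } else if (ch %in% AA) {
      toks[[length(toks) + 1L]] <- list(set = ch, star = FALSE)
      i <- i + 1L
    } else {
      stop2("motif grammar error in '", pattern_text,
            "': illegal character '", ch, "'")
    }
  }
  toks
}

#' Parse a kinase consensus-motif pattern
#'
#' @param pattern_text Pattern in the motif grammar, e.g. `"[DEN]x[ST]*"`.
#' @param name Optional kinase label attached to the pattern.
#' @return A `motif_pattern` object: list with `name`, `pattern_text` and
#'   `constraints`, a named list mapping offset (as character) to the
#'   allowed residue set. Offset 0 is the phospho-acceptor and is always
#'   present.
#' @examples
#' parse_motif("[ST]*Px[KR]", name = "Cdc28 strict")
#' @export
parse_motif <- function(pattern_text, name = pattern_text) {
  toks <- motif_tokens(pattern_text)
  stars <- which(vapply(toks, `[[`, logical(1), "star"))
  if (length(stars) != 1L)
    stop2("motif grammar error in '", pattern_text,
          "': exactly one '*' token required, found ", length(stars))
  center <- stars[1L]
  if (!all(toks[[center]]$set %in% c("S", "T", "Y")))
    stop2("motif grammar error in '", pattern_text,
          "': phospho-acceptor set must be within {S, T, Y}")
  constraints <- list()
  for (i in seq_along(toks)) {
    if (is.null(toks[[i]]$set)) next
    constraints[[as.character(i - center)]] <- toks[[i]]$set
  }
  structure(list(name = name, pattern_text = pattern_text,
                 constraints = constraints),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$name, ": ", x$pattern_text, "\n", sep = "")
  offs <- as.integer(names(x$constraints))
  for (i in order(offs)) {
    cat(sprintf("  %+d: {%s}\n", offs[i],
                paste(x$constraints[[i]], collapse = ",")))
  }
  invisible(x)
}

#' Match phospho-site sequence windows against a motif
#'
#' A window matches when the residue at every constrained offset (relative
#' to the window center, the phospho-acceptor) belongs to the motif's
#' allowed set. Padding (`"_"`) at a constrained offset never matches.
#'
#' @param windows Character vector of odd-length sequence windows.
#' @param pattern A `motif_pattern` from [parse_motif()], or a pattern
#'   string.
#' @return Logical vector, one element per window.
#' @export
match_site <- function(windows, pattern) {
  if (is.character(pattern)) pattern <- parse_motif(pattern)
  wl <- nchar(windows)
  if (length(unique(wl)) > 1L) stop2("windows must have equal length")
  wl <- wl[1L]
  if (wl %% 2L == 0L) stop2("windows must have odd length")
  center <- (wl + 1L) %/% 2L
  offs <- as.integer(names(pattern$constraints))
  if (any(abs(offs) > (wl - 1L) %/% 2L))
    stop2("motif offset(s) outside the window half-width")
  out <- rep(TRUE, length(windows))
  for (i in seq_along(offs)) {
    res <- substr(windows, center + offs[i], center + offs[i])
    out <- out & (res %in% pattern$constraints[[i]])
  }
  out
}

#' Tabulate motif matches for a set of sites
#'
#' @param windows Named character vector (names = site ids) of sequence
#'   windows.
#' @param patterns A list of `motif_pattern` objects (e.g.
#'   [kinase_motifs()]).
#' @return A logical matrix, sites x motifs.
#' @export
motif_match_table <- function(windows, patterns) {
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  m <- vapply(patterns, function(p) match_site(windows, p),
              logical(length(windows)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(windows))
  rownames(m) <- names(windows)
  colnames(m) <- vapply(patterns, function(p) p$name, character(1))
  m
}

#' Vectorized two-sided Fisher exact test for 2x2 tables
#'
#' Conditional exact test on tables `[a, b; c, d]` with fixed margins:
#' the two-sided p-value sums all hypergeometric point masses not
#' exceeding the observed one (with the customary `1 + 1e-7` relative
#' tolerance, as in `stats::fisher.test`).
#'
#' @param a,b,c,d Integer vectors of cell counts (recycled to a common
#'   length).
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0)) stop2("negative cell count")
  m <- a + b            # row-1 margin
  nn <- c + d           # row-2 margin
  k <- a + c            # column-1 margin
  lo <- pmax(0, k - nn)
  hi <- pmin(k, m)
  sup_len <- hi - lo + 1L
  idx <- rep.int(seq_len(n), sup_len)
  x <- sequence(sup_len) - 1L + rep.int(lo, sup_len)
  mass <- stats::dhyper(x, m[idx], nn[idx], k[idx])
  obs <- stats::dhyper(a, m, nn, k)
  keep <- mass <= obs[idx] * (1 + 1e-7)
  p <- rowsum(mass * keep, idx, reorder = TRUE)[, 1L]
  pmin(as.numeric(p), 1)
}

signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Motif enrichment of site groups against a background
#'
#' For each (group, motif) pair a 2x2 table of motif-matching counts is
#' tested with the two-sided Fisher exact test. The default table
#' construction (`mode = "total"`) compares each group against the full
#' background *including* the group itself — the construction used for
#' cluster-versus-total comparisons in the meiotic phosphoproteome
#' analysis this package reimplements. This overlapping construction is
#' statistically non-standard (the two samples are not independent);
#' `mode = "rest"` gives the disjoint group-versus-remainder test.
#'
#' @param groups Named list of character vectors of site ids.
#' @param background Character vector of site ids (must contain each group
#'   when `mode = "total"`).
#' @param match_table Logical matrix from [motif_match_table()], rows
#'   indexed by site id.
#' @param mode `"total"` (overlapping, default) or `"rest"` (disjoint).
#' @return A data.frame with one row per (group, motif): counts `a`
#'   (group match), `b` (group non-match), `c`, `d` (background or rest),
#'   percent matched, odds ratio, p-value, direction, significance stars.
#' @export
motif_enrichment <- function(groups, background, match_table,
                             mode = c("total", "rest")) {
  mode <- match.arg(mode)
  if (!length(groups) || any(!lengths(groups)))
    stop2("empty group(s)")
  res <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (!all(ids %in% rownames(match_table)))
      stop2("group '", g, "' contains site ids absent from the match table")
    if (!all(ids %in% background))
      stop2("group '", g, "' is not contained in the background")
    bg <- if (mode == "total") background else setdiff(background, ids)
    for (mo in colnames(match_table)) {
      a <- sum(match_table[ids, mo])
      b <- length(ids) - a
      c_ <- sum(match_table[bg, mo])
      d <- length(bg) - c_
      res[[length(res) + 1L]] <- data.frame(
        group = g, motif = mo, a = a, b = b, c = c_, d = d,
        pct_group = 100 * a / (a + b), pct_background = 100 * c_ / (c_ + d),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$odds_ratio <- (out$a * out$d) / (out$b * out$c)
  out$p_value <- fisher_exact_p(out$a, out$b, out$c, out$d)
  out$direction <- ifelse(out$pct_group >= out$pct_background,
                          "enriched", "depleted")
  out$stars <- signif_stars(out$p_value)
  rownames(out) <- NULL
  out
}

window_residue_counts <- function(windows, wl) {
  center <- (wl + 1L) %/% 2L
  half <- (wl - 1L) %/% 2L
  offs <- setdiff(seq.int(-half, half), 0L)
  counts <- matrix(0L, nrow = length(offs), ncol = length(AA),
                   dimnames = list(as.character(offs), AA))
  npad <- integer(length(offs)); names(npad) <- as.character(offs)
  for (i in seq_along(offs)) {
    res <- substr(windows, center + offs[i], center + offs[i])
    res <- res[res != PAD]
    npad[i] <- length(res)
    tb <- table(factor(res, levels = AA))
    counts[i, ] <- as.integer(tb)
  }
  list(counts = counts, n = npad, offsets = offs)
}

#' Position-specific residue-difference logo
#'
#' For every offset (excluding the phospho-acceptor at 0) and residue, the
#' percentage among foreground windows minus the percentage among
#' background windows, with a per-cell two-sided Fisher exact test.
#' Padding positions are excluded from the denominators. This is the
#' percent-difference statistic popularized by iceLogo-style displays.
#'
#' @param fg,bg Character vectors of equal-length sequence windows.
#' @param alpha Significance cutoff for flagging cells (default 0.05).
#' @return A data.frame with columns `offset`, `residue`, `fg_pct`,
#'   `bg_pct`, `diff_pct`, `p_value`, `significant`.
#' @export
residue_logo <- function(fg, bg, alpha = 0.05) {
  if (!length(fg) || !length(bg)) stop2("foreground and background required")
  wl <- unique(nchar(c(fg, bg)))
  if (length(wl) > 1L) stop2("foreground/background window length mismatch")
  f <- window_residue_counts(fg, wl)
  b <- window_residue_counts(bg, wl)
  grid <- expand.grid(offset = f$offsets, residue = AA,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  oi <- match(as.character(grid$offset), rownames(f$counts))
  ri <- match(grid$residue, AA)
  af <- f$counts[cbind(oi, ri)]
  ab <- b$counts[cbind(oi, ri)]
  nf <- f$n[oi]
  nb <- b$n[oi]
  grid$fg_pct <- 100 * af / nf
  grid$bg_pct <- 100 * ab / nb
  grid$diff_pct <- grid$fg_pct - grid$bg_pct
  grid$p_value <- fisher_exact_p(af, nf - af, ab, nb - ab)
  grid$significant <- grid$p_value < alpha
  grid[order(grid$offset, grid$residue), ]
}

#' Discover a single-offset sub-motif refinement
#'
#' Given a base motif matched by both site sets, asks which residues at
#' one additional (unconstrained) offset are over-represented among
#' foreground sites relative to background sites, by per-residue Fisher
#' exact tests. This is the procedure that revealed the +1 F/G preference
#' among Polo-motif sites whose phosphorylation depends on Spo13.
#'
#' @param base A `motif_pattern`; `fg` and `bg` are restricted to windows
#'   matching it.
#' @param offset Integer offset to interrogate; must not already be
#'   constrained in `base`.
#' @param fg,bg Character vectors of sequence windows.
#' @param alpha Significance cutoff (default 0.05).
#' @return A data.frame of residues with `p_value < alpha` and positive
#'   enrichment, ranked by p-value; columns `residue`, `fg_count`,
#'   `fg_pct`, `bg_count`, `bg_pct`, `p_value`.
#' @export
discover_submotif <- function(base, offset, fg, bg, alpha = 0.05) {
  if (is.character(base)) base <- parse_motif(base)
  if (as.character(offset) %in% names(base$constraints))
    stop2("offset ", offset, " is already constrained in '",
          base$pattern_text, "'")
  fg <- fg[match_site(fg, base)]
  bg <- bg[match_site(bg, base)]
  if (!length(fg) || !length(bg))
    stop2("no base-motif-matching windows in foreground or background")
  wl <- unique(nchar(c(fg, bg)))
  if (length(wl) > 1L) stop2("foreground/background window length mismatch")
  center <- (wl + 1L) %/% 2L
  rf <- substr(fg, center + offset, center + offset)
  rb <- substr(bg, center + offset, center + offset)
  rf <- rf[rf != PAD]; rb <- rb[rb != PAD]
  cf <- table(factor(rf, levels = AA))
  cb <- table(factor(rb, levels = AA))
  out <- data.frame(residue = AA,
                    fg_count = as.integer(cf),
                    fg_pct = 100 * as.integer(cf) / length(rf),
                    bg_count = as.integer(cb),
                    bg_pct = 100 * as.integer(cb) / length(rb),
                    stringsAsFactors = FALSE)
  out$p_value <- fisher_exact_p(out$fg_count, length(rf) - out$fg_count,
                                out$bg_count, length(rb) - out$bg_count)
  out <- out[out$p_value < alpha & out$fg_pct > out$bg_pct, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a protein sequence for a plain (unanchored) motif
#'
#' The pattern uses the same residue-set grammar but without a starred
#' phospho-acceptor — it describes consecutive positions, e.g.
#' `"S[ST]P"`. All (overlapping) 1-based match start positions are
#' returned.
#'
#' @param sequence A single protein sequence string.
#' @param pattern_text Pattern, default `"S[ST]P"` (the polo-box-domain
#'   binding motif).
#' @return Integer vector of 1-based match start positions.
#' @export
scan_protein_sequence <- function(sequence, pattern_text = "S[ST]P") {
  if (grepl("*", pattern_text, fixed = TRUE))
    stop2("starred patterns are anchored site motifs; ",
          "scan_protein_sequence takes the plain position grammar")
  toks <- motif_tokens(pattern_text)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  L <- length(toks)
  if (L == 0L || n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  starts <- seq_len(n - L + 1L)
  for (j in seq_len(L)) {
    if (is.null(toks[[j]]$set)) next
    res <- substr(rep(sequence, length(starts)), starts + j - 1L,
                  starts + j - 1L)
    ok <- ok & (res %in% toks[[j]]$set)
  }
  starts[ok]
}
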
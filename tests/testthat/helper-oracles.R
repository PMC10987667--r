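## Independent oracle implementations used to validate the package's own
## code paths. These deliberately take different routes: regular
## expressions for motif matching, log-choose enumeration for exact
## tests, a naive O(n^3) Lance-Williams agglomeration for Ward
## clustering, and closed forms where available.

## --- motif matching via the R regex engine -------------------------

## Translate a motif pattern to (regex string, 1-based star token index)
## without using the package parser: a token-by-token scan building a
## plain ERE character-class expression.
oracle_motif_regex <- function(pattern_text) {
  chars <- strsplit(pattern_text, "")[[1]]
  pieces <- character(0)
  star_at <- NA_integer_
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      pieces <- c(pieces, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (chars[i] == "x") {
      pieces <- c(pieces, ".")
      i <- i + 1L
    } else if (chars[i] == "*") {
      star_at <- length(pieces)
      i <- i + 1L
    } else {
      pieces <- c(pieces, chars[i])
      i <- i + 1L
    }
  }
  list(regex = paste0("^", paste(pieces, collapse = "")),
       star_at = star_at, n_tokens = length(pieces))
}

## Match windows against a pattern by anchoring the regex so that its
## starred token lands on the window center. Padding "_" fails any
## character class automatically (not a residue letter) and "." at a
## pad position must be made to fail explicitly, so pads are mapped to a
## character the classes cannot contain and "." is replaced by a
## residue-only class.
oracle_match_site <- function(windows, pattern_text) {
  tr <- oracle_motif_regex(pattern_text)
  regex <- gsub(".", "[ACDEFGHIKLMNPQRSTVWY]", tr$regex, fixed = TRUE)
  wl <- nchar(windows[1])
  center <- (wl + 1L) %/% 2L
  from <- center - (tr$star_at - 1L)
  to <- from + tr$n_tokens - 1L
  if (from < 1L || to > wl) stop("pattern exceeds window")
  grepl(regex, substr(windows, from, to))
}

## --- exact tests by log-choose enumeration -------------------------

oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  jj <- max(0, k - n):min(k, m)
  lp <- lchoose(m, jj) + lchoose(n, k - jj) - lchoose(m + n, k)
  pr <- exp(lp)
  obs <- exp(lchoose(m, a) + lchoose(n, c) - lchoose(m + n, k))
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

oracle_hyper_upper <- function(k, K, n, N) {
  ## P(X >= k) by direct summation of point masses
  jj <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, jj) + lchoose(N - K, n - jj) - lchoose(N, n)))
}

## --- Ward (ward.D2) agglomeration, naive O(n^3) --------------------

oracle_ward <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  active <- seq_len(n)
  sizes <- rep(1, n)
  id <- -seq_len(n)              # hclust convention: negatives = leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  labels <- seq_len(n)
  assign_env <- lapply(seq_len(n), function(i) i)
  for (s in seq_len(n - 1L)) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
      dij <- d[active[i], active[j]]
      if (dij < bestd - 1e-12) { bestd <- dij; best <- c(j, i) }
    }
    aj <- active[best[1]]; ai <- active[best[2]]
    height[s] <- bestd
    merge[s, ] <- sort(c(id[aj], id[ai]))
    ## Lance-Williams update, ward.D2 coefficients on squared distances
    ni <- sizes[ai]; nj <- sizes[aj]
    for (k in active) {
      if (k == ai || k == aj) next
      nk <- sizes[k]
      dn <- sqrt(((ni + nk) * d[ai, k]^2 + (nj + nk) * d[aj, k]^2 -
                    nk * d[ai, aj]^2) / (ni + nj + nk))
      d[aj, k] <- d[k, aj] <- dn
    }
    sizes[aj] <- ni + nj
    assign_env[[aj]] <- c(assign_env[[aj]], assign_env[[ai]])
    id[aj] <- s
    active <- setdiff(active, ai)
  }
  list(merge = merge, height = height)
}

## partition induced by the first n-k oracle merges (union-find replay)
oracle_cut <- function(ward, n, k) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  merges <- ward$merge
  leaf_of <- integer(n - 1L)   # representative leaf of each merge node
  for (s in seq_len(n - k)) {
    pick <- function(e) if (e < 0) -e else leaf_of[e]
    i <- find(pick(merges[s, 1])); j <- find(pick(merges[s, 2]))
    parent[j] <- i
    leaf_of[s] <- i
  }
  ## label components 1..k in order of first appearance
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

## partition agreement up to label permutation
same_partition <- function(a, b) {
  ta <- as.integer(factor(a, levels = unique(a)))
  tb <- as.integer(factor(b, levels = unique(b)))
  all(ta == tb)
}

## --- Welch closed form at df = 2 ------------------------------------

## two-sided p for a t statistic with 2 degrees of freedom:
## F(t) = 1/2 + t / (2*sqrt(2)*sqrt(1 + t^2/2))
oracle_p_t_df2 <- function(t) {
  cdf <- 0.5 + t / (2 * sqrt(2) * sqrt(1 + t^2 / 2))
  2 * min(cdf, 1 - cdf)
}

## --- misc ----------------------------------------------------------

oracle_scan <- function(sequence, allowed_sets) {
  ## brute-force scan over every start position
  n <- nchar(sequence); L <- length(allowed_sets)
  hits <- integer(0)
  for (s in seq_len(max(0, n - L + 1L))) {
    ok <- TRUE
    for (j in seq_len(L)) {
      ch <- substr(sequence, s + j - 1L, s + j - 1L)
      if (!is.null(allowed_sets[[j]]) && !(ch %in% allowed_sets[[j]])) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_windows <- function(n, wl = 31L, centers = c("S", "T", "Y")) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m <- matrix(sample(aa, n * wl, replace = TRUE), nrow = n)
  m[, (wl + 1L) %/% 2L] <- sample(centers, n, replace = TRUE)
  apply(m, 1, paste, collapse = "")
}
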
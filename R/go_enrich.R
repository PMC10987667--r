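## Hypergeometric over-representation analysis against a user-supplied
## term-to-gene mapping.

#' Over-representation analysis
#'
#' For each term, the upper-tail (cumulative) hypergeometric probability
#' of drawing at least `k` term genes when sampling `n` foreground genes
#' from a universe of `N` genes containing `K` term genes:
#' `P(X >= k)`. Benjamini-Hochberg q-values are reported across the
#' tested terms; the significance flag follows the raw p-value cutoff
#' `alpha`, mirroring the original analysis's `P < 0.05` reporting rule.
#'
#' @param foreground Character vector of gene ids; ids outside the
#'   universe are dropped with a message.
#' @param map A [term_map()].
#' @param alpha Raw p-value cutoff for the `significant` flag (default
#'   0.05).
#' @param signed_direction Optional `"increased"`/`"decreased"` label; when
#'   given, a `signed_log10_p` column carries `+log10(p)` for increased
#'   and `-log10(p)` for decreased groups.
#' @return A data.frame with one row per term: `term`, `name`, `k`, `K`,
#'   `n`, `N`, `p_value`, `q_value`, `significant` (and optionally
#'   `signed_log10_p`).
#' @export
ora <- function(foreground, map, alpha = 0.05, signed_direction = NULL) {
  if (!inherits(map, "term_map")) stop2("map must be a term_map")
  if (!length(map$universe)) stop2("empty universe")
  foreground <- unique(foreground)
  if (!length(foreground)) stop2("empty foreground")
  outside <- setdiff(foreground, map$universe)
  if (length(outside)) {
    message(length(outside), " foreground gene(s) outside the universe ",
            "dropped")
    foreground <- intersect(foreground, map$universe)
    if (!length(foreground)) stop2("no foreground genes in the universe")
  }
  N <- length(map$universe)
  n <- length(foreground)
  K <- lengths(map$terms)
  k <- vapply(map$terms, function(g) length(intersect(g, foreground)),
              integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(map$terms),
                    name = unname(map$names[names(map$terms)]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p_value = unname(p),
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_value < alpha
  if (!is.null(signed_direction)) {
    sgn <- if (identical(signed_direction, "decreased")) -1 else 1
    out$signed_log10_p <- sgn * -log10(out$p_value)
  }
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}
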
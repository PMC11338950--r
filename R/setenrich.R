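# Generic over-representation analysis (hypergeometric upper tail +
# Benjamini-Hochberg adjustment) against user-supplied GMT gene sets.

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values: `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at
#' 1, returned in input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values in the same order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the hit list overlaps the set more
#' than expected under uniform sampling from the background:
#' `p = P(X >= k)` with `X ~ Hypergeom(N, K, n)` where `N` is the
#' background size, `K` the set size within the background, `n` the hit
#' count and `k` the hits in the set. Set members are intersected with
#' the background before counting; sets empty after intersection are
#' omitted. Hits are protein-level identifiers, deduplicated.
#'
#' @param hits id set of interest (must be a subset of `background`).
#' @param background the sampling universe (e.g. all quantified proteins).
#' @param sets list of gene sets as from [read_gmt()].
#' @return `data.frame(set_name, k, K, n, N, p_value, q_value)` ordered
#'   by p-value.
#' @export
ora_test <- function(hits, background, sets) {
  hits <- unique(hits)
  background <- unique(background)
  if (!all(hits %in% background))
    stop("hits must be a subset of the background")
  N <- length(background)
  n <- length(hits)
  rows <- lapply(sets, function(s) {
    members <- intersect(unique(s$members), background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(hits, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = s$name, k = k, K = K, n = n, N = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(set_name = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}
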
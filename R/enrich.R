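#' One-sided Fisher exact test (upper tail)
#'
#' The probability of observing `k` or more query genes in a target set
#' under the hypergeometric null: `P(X >= k)` for `X ~ Hyper(U, t, q)`.
#' Vectorised over its arguments.
#'
#' @param k overlap count.
#' @param q query size.
#' @param t target-set size.
#' @param U universe size.
#' @return upper-tail p-value(s) in (0, 1].
#' @export
fisher_one_sided <- function(k, q, t, U) {
  if (any(k > pmin(q, t) | q > U | t > U | k < 0))
    stop("inconsistent contingency margins")
  phyper(k - 1, t, U - t, q, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin, validating wrapper
#' over the standard implementation, returned in input order.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Motif target-set enrichment of a query gene set
#'
#' One one-sided Fisher exact test per target set, with
#' Benjamini-Hochberg correction applied jointly across the whole
#' battery and a significance call at adjusted-P < `alpha` (6e-4 by
#' default). Query and target genes outside the universe are dropped and
#' counted.
#'
#' @param query character vector of query gene ids.
#' @param target_sets named list of gene-id vectors (see
#'   [build_target_sets()]).
#' @param universe character vector of all scored gene ids.
#' @param alpha adjusted-P significance threshold.
#' @param manifest optional manifest data.frame to join set metadata.
#' @return data.frame sorted by adjusted p, one row per target set, with
#'   overlap k, sizes, odds ratio (Haldane-corrected for zero cells),
#'   p_raw, p_adjusted and the significance flag.
#' @export
run_enrichment <- function(query, target_sets, universe, alpha = 6e-4,
                           manifest = NULL) {
  universe <- unique(universe)
  U <- length(universe)
  q_in <- unique(query[query %in% universe])
  dropped_query <- length(unique(query)) - length(q_in)
  if (!length(q_in)) warning("empty query; all p-values are 1")
  q <- length(q_in)
  res <- lapply(names(target_sets), function(id) {
    tg <- unique(target_sets[[id]])
    tg <- tg[tg %in% universe]
    t_n <- length(tg)
    k <- length(intersect(q_in, tg))
    p <- if (q == 0 || t_n == 0) 1.0 else fisher_one_sided(k, q, t_n, U)
    a <- k; b <- t_n - k; cc <- q - k; d <- U - t_n - q + k
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5
      cc <- cc + 0.5; d <- d + 0.5 }
    data.frame(set_id = id, k = k, q = q, t = t_n, U = U,
               odds_ratio = (a * d) / (b * cc), p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$significant <- out$p_adjusted < alpha
  attr(out, "dropped_query") <- dropped_query
  if (!is.null(manifest))
    out <- merge(manifest, out, by = "set_id", sort = FALSE)
  out <- out[order(out$p_adjusted, out$p_raw, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
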
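#' Map gene models to windows
#'
#' A window maps to a gene iff the two half-open intervals overlap by at
#' least 1 bp. Genes on scaffolds absent from the window table, or with
#' zero overlapping windows, are excluded with a warning.
#'
#' @param genes gene model data.frame (gene_id, scaffold, start, end).
#' @param windows window data.frame (scaffold, start, end), e.g. from
#'   [windowed_diversity()].
#' @return data.frame(gene_id, window) where `window` is the row index
#'   into `windows`.
#' @export
intersect_genes_windows <- function(genes, windows) {
  g_gr <- GenomicRanges::GRanges(genes$scaffold,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  w_gr <- GenomicRanges::GRanges(windows$scaffold,
                                 IRanges::IRanges(windows$start + 1L,
                                                  windows$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(g_gr, w_gr, minoverlap = 1L))
  unmapped <- setdiff(seq_len(nrow(genes)),
                      unique(S4Vectors::queryHits(hits)))
  if (length(unmapped))
    warning(length(unmapped), " gene(s) overlap no window and are excluded: ",
            paste(utils::head(genes$gene_id[unmapped], 5), collapse = ", "))
  data.frame(gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
             window = S4Vectors::subjectHits(hits),
             stringsAsFactors = FALSE)
}

#' Aggregate window statistics per gene
#'
#' Unweighted arithmetic mean of pi and Tajima's D over a gene's
#' overlapping windows. Windows with an undefined statistic are dropped
#' from that statistic's mean only; genes whose windows are all undefined
#' for D (or pi) are excluded from the scan and counted.
#'
#' @param map gene-to-window map from [intersect_genes_windows()].
#' @param windows the window table the map indexes, with columns `pi`
#'   (or `pi_corrected`, preferred when present) and `tajimas_d`.
#' @return data.frame(gene_id, mean_pi, mean_d, n_windows).
#' @export
aggregate_gene_stats <- function(map, windows) {
  pi_col <- if ("pi_corrected" %in% names(windows)) "pi_corrected" else "pi"
  ids <- unique(map$gene_id)
  rows <- split(map$window, map$gene_id)[ids]
  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- data.frame(
    gene_id = ids,
    mean_pi = vapply(rows, function(r) mean_def(windows[[pi_col]][r]),
                     numeric(1)),
    mean_d = vapply(rows, function(r) mean_def(windows$tajimas_d[r]),
                    numeric(1)),
    n_windows = lengths(rows),
    stringsAsFactors = FALSE)
  drop <- is.na(out$mean_pi) | is.na(out$mean_d)
  if (any(drop))
    warning(sum(drop), " gene(s) with no defined window statistic excluded")
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical cumulative percentile
#'
#' The fraction of observed values less than or equal to `x` (the
#' right-continuous empirical CDF), ranging over (0, 1] on observed
#' values.
#'
#' @param values non-empty numeric vector.
#' @param x query value(s).
#' @return percentile(s) in (0, 1].
#' @export
ecdf_percentile <- function(values, x) {
  if (!length(values)) stop("empty value list")
  stats::ecdf(values)(x)
}

#' Joint ECDF-percentile selection scan
#'
#' Computes each gene's cumulative percentile for mean pi and mean
#' Tajima's D from their own ECDFs, multiplies them, re-percentiles the
#' product over genes, and calls genes whose joint percentile falls in
#' the lowest `tail` (default 5%) as candidates under positive
#' directional selection. Ties at the boundary are all-in (the call uses
#' the `<= tail` rule); reporting order is joint percentile, then gene
#' id.
#'
#' @param gene_stats data.frame from [aggregate_gene_stats()].
#' @param tail selection tail (fraction).
#' @return data.frame(gene_id, mean_pi, mean_d, pct_pi, pct_d, joint,
#'   joint_pct, selected).
#' @export
joint_percentile_scan <- function(gene_stats, tail = 0.05) {
  n <- nrow(gene_stats)
  out <- gene_stats[, c("gene_id", "mean_pi", "mean_d")]
  out$pct_pi <- ecdf_percentile(out$mean_pi, out$mean_pi)
  out$pct_d <- ecdf_percentile(out$mean_d, out$mean_d)
  out$joint <- out$pct_pi * out$pct_d
  out$joint_pct <- ecdf_percentile(out$joint, out$joint)
  if (n < 20) {
    warning("fewer than 20 genes; selection tail is empty")
    out$selected <- FALSE
  } else {
    out$selected <- out$joint_pct <= tail
  }
  out <- out[order(out$joint_pct, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene scores as TSV
#' @param scores data.frame from [joint_percentile_scan()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_gene_scores_tsv <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
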
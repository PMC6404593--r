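#' Simulate a reference genome
#'
#' Draws i.i.d. bases with the configured GC content, split into the
#' scaffold lengths of [scaffold_lengths()]. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [Biostrings::DNAStringSet] with one record per scaffold.
#' @export
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  len <- scaffold_lengths(cfg)
  set.seed(op_seed(cfg$seed, 1L))
  p <- c(A = (1 - cfg$gc_mean) / 2, C = cfg$gc_mean / 2,
         G = cfg$gc_mean / 2, T = (1 - cfg$gc_mean) / 2)
  seqs <- vapply(len, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(len)))
}

# Deterministic gene placement grid: genes are distributed over scaffolds
# proportionally to length and centred in equal slots, so positions are
# known before any RNG is consumed (sweep layouts can be derived from the
# grid alone). The last 6 kb of every sufficiently long scaffold is kept
# gene-free so each scaffold retains a >= 5 kb non-genic region for
# background-composition training.
gene_grid <- function(cfg) {
  len <- scaffold_lengths(cfg)
  n <- cfg$n_genes
  share <- len / sum(len) * n
  per <- floor(share)
  rem <- n - sum(per)
  if (rem > 0) {
    o <- order(share - per, decreasing = TRUE)
    per[o[seq_len(rem)]] <- per[o[seq_len(rem)]] + 1L
  }
  out <- vector("list", length(len))
  for (i in seq_along(len)) {
    g <- per[i]
    if (g == 0) next
    usable <- if (len[i] >= 24000) len[i] - 6000L else len[i]
    slot <- floor(usable / g)
    if (slot < cfg$gene_length + 2400)
      stop("genome too short for requested gene count/spacing")
    start <- (seq_len(g) - 1) * slot + floor((slot - cfg$gene_length) / 2)
    out[[i]] <- data.frame(scaffold = names(len)[i],
                           start = as.integer(start),
                           end = as.integer(start + cfg$gene_length),
                           stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, out)
  grid$gene_id <- sprintf("g%04d", seq_len(nrow(grid)))
  rownames(grid) <- NULL
  grid[, c("gene_id", "scaffold", "start", "end")]
}

#' Simulate gene models
#'
#' Places `cfg$n_genes` non-overlapping genes on the deterministic grid of
#' `gene_grid()` and assigns random strands. Coordinates are 0-based
#' half-open; the TSS is the feature start for plus-strand genes and the
#' feature (half-open) end for minus-strand genes, so the 1 kb upstream
#' region is always `[tss-1000, tss)` in strand-oriented terms.
#'
#' @param cfg a [sim_config()].
#' @param genome the genome from [simulate_genome()] (used only for bounds
#'   checking).
#' @return data.frame with columns gene_id, scaffold, start, end, strand,
#'   tss.
#' @export
simulate_gene_models <- function(cfg, genome) {
  genes <- gene_grid(cfg)
  sl <- setNames(Biostrings::width(genome), names(genome))
  if (any(genes$end > sl[genes$scaffold]))
    stop("genome too short for requested gene count/spacing")
  set.seed(op_seed(cfg$seed, 2L))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes
}

genes_to_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$source <- "divscan"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$Name <- genes$gene_id
  gr
}

granges_to_genes <- function(gr) {
  id <- S4Vectors::mcols(gr)$ID
  if (is.null(id)) id <- S4Vectors::mcols(gr)$name
  genes <- data.frame(
    gene_id = as.character(id),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes
}

#' Write / read gene models as GFF3 or BED
#'
#' Internal coordinates are 0-based half-open; GFF3 is written 1-based
#' inclusive and BED 0-based half-open, both via rtracklayer.
#' @param genes gene model data.frame.
#' @param path output file.
#' @return `read_genes()` returns the gene model data.frame.
#' @export
write_genes_gff3 <- function(genes, path) {
  rtracklayer::export(genes_to_granges(genes), path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
write_genes_bed <- function(genes, path) {
  gr <- genes_to_granges(genes)
  names(gr) <- genes$gene_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @param format "gff3" or "bed" (guessed from the extension by default).
#' @export
read_genes <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path)) "bed" else "gff3"
  granges_to_genes(rtracklayer::import(path, format = format))
}

#' Simulate a per-window coverage track
#'
#' Draws a Poisson depth for every base (mean `coverage_mean`, or
#' `coverage_dip_mean` inside dip regions) and records, per tiling window,
#' the fraction of sites with depth >= `min_depth` -- the quantity used as
#' the coverage-corrected denominator of windowed pi.
#'
#' @param cfg a [sim_config()].
#' @param genome genome from [simulate_genome()].
#' @param window window size in bp.
#' @param min_depth depth threshold defining a "covered" site.
#' @return data.frame(scaffold, start, end, fraction), 0-based half-open.
#' @export
simulate_coverage <- function(cfg, genome, window = 1000L, min_depth = 5L) {
  set.seed(op_seed(cfg$seed, 3L))
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    scaf <- names(genome)[i]
    L <- Biostrings::width(genome)[i]
    if (L == 0) next
    lambda <- rep(cfg$coverage_mean, L)
    dips <- cfg$coverage_dip_regions
    if (!is.null(dips)) {
      for (j in which(dips$scaffold == scaf)) {
        idx <- seq.int(max(1, dips$start[j] + 1), min(L, dips$end[j]))
        lambda[idx] <- cfg$coverage_dip_mean
      }
    }
    covered <- rpois(L, lambda) >= min_depth
    starts <- seq.int(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    frac <- vapply(seq_along(starts), function(k) {
      mean(covered[(starts[k] + 1):ends[k]])
    }, numeric(1))
    out[[i]] <- data.frame(scaffold = scaf, start = starts, end = ends,
                           fraction = frac, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), fraction = numeric()))
  do.call(rbind, out)
}

#' Write / read a coverage track as 4-column BED (bedGraph)
#' @param coverage data.frame from [simulate_coverage()].
#' @param path file path.
#' @return `read_coverage_bed()` returns the coverage data.frame.
#' @export
write_coverage_bed <- function(coverage, path) {
  gr <- GenomicRanges::GRanges(
    coverage$scaffold,
    IRanges::IRanges(coverage$start + 1L, coverage$end),
    score = coverage$fraction)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_coverage_bed
#' @export
read_coverage_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             fraction = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

#' Write a genome FASTA (with a .fai-style index)
#' @param genome a DNAStringSet.
#' @param path FASTA path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  idx <- data.frame(names(genome), Biostrings::width(genome))
  write.table(idx, paste0(path, ".fai"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
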
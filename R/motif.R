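#' Partition a genome into sliding scoring windows
#'
#' Tiles each scaffold into 500 bp windows advancing by 250 bp, so
#' consecutive windows overlap by half. Masked intervals (e.g. tandem
#' repeats, supplied as input) are hard-masked before GC computation and
#' scoring; windows with more than `max_masked` of their length masked
#' are flagged unscored. A scaffold shorter than the window yields a
#' single truncated window, flagged partial.
#'
#' @param genome a DNAStringSet.
#' @param window,step window length and step in bp.
#' @param mask optional data.frame(scaffold, start, end), 0-based
#'   half-open, of intervals to mask.
#' @param max_masked maximum tolerated masked fraction for scoring.
#' @return list with `windows` (data.frame scaffold, start, end, gc,
#'   masked_fraction, partial, scored) and `genome` (the hard-masked
#'   DNAStringSet used for scoring).
#' @export
partition_windows <- function(genome, window = 500L, step = 250L,
                              mask = NULL, max_masked = 0.5) {
  masked <- genome
  if (!is.null(mask) && nrow(mask)) {
    for (i in seq_len(nrow(mask))) {
      scaf <- mask$scaffold[i]
      if (!scaf %in% names(masked)) next
      L <- Biostrings::width(masked[names(masked) == scaf])
      s <- max(0L, mask$start[i])
      e <- min(L, mask$end[i])
      if (e <= s) next
      masked[[scaf]] <- Biostrings::replaceAt(
        masked[[scaf]], IRanges::IRanges(s + 1L, e),
        paste(rep("N", e - s), collapse = ""))
    }
  }
  out <- vector("list", length(genome))
  for (i in seq_along(masked)) {
    scaf <- names(masked)[i]
    L <- Biostrings::width(masked)[i]
    if (L == 0) next
    starts <- if (L < window) 0L else seq.int(0L, L - window, by = step)
    ends <- pmin(starts + window, L)
    v <- Biostrings::Views(masked[[scaf]], start = starts + 1L, end = ends)
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
    unmasked <- rowSums(f[, 1:4, drop = FALSE])
    out[[i]] <- data.frame(
      scaffold = scaf, start = starts, end = ends,
      gc = ifelse(unmasked > 0,
                  (f[, "C"] + f[, "G"]) / unmasked, NA_real_),
      masked_fraction = f[, "N"] / (ends - starts),
      partial = (ends - starts) < window,
      stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(win) <- NULL
  win$scored <- win$masked_fraction <= max_masked & !is.na(win$gc)
  list(windows = win, genome = masked)
}

#' Background nucleotide distribution from non-genic sequence
#'
#' Mononucleotide frequencies over non-genic regions of at least
#' `min_region` bp drawn from scaffolds of at least `min_scaffold` bp,
#' with a floor of `floor_freq` per base (renormalised). When no region
#' qualifies, falls back to whole-genome frequencies with a warning.
#'
#' @param genome a DNAStringSet.
#' @param genes gene model data.frame (coding features to exclude).
#' @param min_region minimum non-genic interval length retained (bp).
#' @param min_scaffold minimum scaffold length considered (bp).
#' @param floor_freq per-base frequency floor.
#' @return named frequency vector (A, C, G, T) summing to 1.
#' @export
estimate_background <- function(genome, genes, min_region = 5000L,
                                min_scaffold = 22000L,
                                floor_freq = 0.001) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_along(genome)) {
    scaf <- names(genome)[i]
    L <- Biostrings::width(genome)[i]
    if (L < min_scaffold) next
    gr <- genes[genes$scaffold == scaf, , drop = FALSE]
    genic <- IRanges::reduce(IRanges::IRanges(gr$start + 1L, gr$end))
    nong <- IRanges::setdiff(IRanges::IRanges(1L, L), genic)
    nong <- nong[IRanges::width(nong) >= min_region]
    if (!length(nong)) next
    v <- Biostrings::Views(genome[[i]], nong)
    counts <- counts +
      colSums(Biostrings::letterFrequency(v, c("A", "C", "G", "T")))
  }
  if (sum(counts) == 0) {
    warning("no qualifying non-genic region; using whole-genome frequencies")
    counts <- colSums(Biostrings::letterFrequency(genome,
                                                  c("A", "C", "G", "T")))
  }
  f <- counts / sum(counts)
  f <- pmax(f, floor_freq)
  f / sum(f)
}

#' HMM partition-function motif score of one window
#'
#' Scores a window with a two-state (background / motif) hidden Markov
#' model: at each position the chain either emits one background base or
#' enters the motif state with fixed probability `t` (split evenly over
#' the two strands) and emits a full PWM instance. The score is the log
#' ratio of the full partition function to the background-only
#' likelihood; it tends to 0 as `t -> 0` and grows with the number and
#' strength of PWM matches in the window.
#'
#' @param seq character string (one window) or character vector of
#'   windows.
#' @param pwm a PWM list (see [read_pwms_meme()]) or a bare 4 x w
#'   probability matrix with rows A, C, G, T.
#' @param background named background frequencies (A, C, G, T).
#' @param t motif-entry transition probability.
#' @return numeric score(s), NA for windows shorter than the motif.
#' @export
stubb_score_window <- function(seq, pwm, background, t = 0.0025) {
  mat <- if (is.list(pwm)) pwm$mat else pwm
  stopifnot(nrow(mat) == 4)
  .stubb_score_cpp(as.character(seq), mat,
                   as.numeric(background[c("A", "C", "G", "T")]), t)
}

#' Score all windows for a motif collection
#'
#' @param part result of [partition_windows()].
#' @param pwms list of PWMs.
#' @param background background frequencies from [estimate_background()].
#' @param t motif-entry transition probability.
#' @return numeric matrix of raw log scores, scored windows x motifs;
#'   rownames are "scaffold:start" keys aligned with the scored subset of
#'   `part$windows`.
#' @export
score_motif_windows <- function(part, pwms, background, t = 0.0025) {
  win <- part$windows[part$windows$scored, , drop = FALSE]
  seqs <- character(nrow(win))
  for (scaf in unique(win$scaffold)) {
    rows <- which(win$scaffold == scaf)
    v <- Biostrings::Views(part$genome[[scaf]],
                           start = win$start[rows] + 1L,
                           end = win$end[rows])
    seqs[rows] <- as.character(v)
  }
  raw <- vapply(pwms, function(p)
    stubb_score_window(seqs, p, background, t),
    numeric(nrow(win)))
  if (nrow(win) == 1) raw <- matrix(raw, nrow = 1)
  dimnames(raw) <- list(paste0(win$scaffold, ":", win$start),
                        vapply(pwms, `[[`, character(1), "id"))
  raw
}

#' Rank normalization of motif scores
#'
#' Maps raw scores to `[0, 1]` by descending rank: the best score gets
#' 0, the worst 1, ties receive their mean rank. NA scores stay NA and
#' do not consume ranks.
#'
#' @param scores numeric vector of raw scores for one motif.
#' @return normalized scores in `[0, 1]`.
#' @export
rank_normalize <- function(scores) {
  ok <- !is.na(scores)
  N <- sum(ok)
  if (N < 2) stop("need at least 2 scored windows")
  out <- rep(NA_real_, length(scores))
  if (length(unique(scores[ok])) == 1) {
    warning("all scores identical; normalized to 0.5")
    out[ok] <- 0.5
    return(out)
  }
  r <- rank(-scores[ok], ties.method = "average")
  out[ok] <- (r - 1) / (N - 1)
  out
}

#' GC-binned rank normalization
#'
#' Sorts windows by GC content, splits them into `bins` equal-count bins
#' (any remainder spread one-per-bin over the first bins), and applies
#' [rank_normalize()] within each bin independently. This removes the
#' base-composition confound: a motif whose score tracks GC ranks
#' near-uniformly within every bin. With fewer than `2 * bins` windows
#' the bin count is reduced to `floor(N / 2)` with a warning.
#'
#' @param scores raw scores for one motif.
#' @param gc per-window GC fractions, same length.
#' @param bins number of GC bins.
#' @return normalized scores in `[0, 1]`, aligned with the input order.
#' @export
gc_rank_normalize <- function(scores, gc, bins = 20L) {
  stopifnot(length(scores) == length(gc))
  N <- length(scores)
  if (N < 2 * bins) {
    bins <- max(1L, N %/% 2L)
    warning("fewer than 40 windows; using ", bins, " GC bins")
  }
  ord <- order(gc)
  base <- N %/% bins
  rem <- N %% bins
  sizes <- rep(base, bins)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  out <- rep(NA_real_, N)
  at <- 0L
  for (b in seq_len(bins)) {
    idx <- ord[(at + 1):(at + sizes[b])]
    at <- at + sizes[b]
    out[idx] <- suppressWarnings(rank_normalize(scores[idx]))
  }
  out
}

#' Normalize a raw score matrix both ways
#'
#' @param raw raw score matrix from [score_motif_windows()].
#' @param windows the scored window table (for GC).
#' @return list(rank_norm, gc_norm) of matrices shaped like `raw`.
#' @export
normalize_scores <- function(raw, windows) {
  gc <- windows$gc[windows$scored]
  rank_norm <- apply(raw, 2, rank_normalize)
  gc_norm <- apply(raw, 2, gc_rank_normalize, gc = gc)
  dimnames(rank_norm) <- dimnames(gc_norm) <- dimnames(raw)
  list(rank_norm = rank_norm, gc_norm = gc_norm)
}

#' Regulatory-region definitions
#'
#' Builds, for every gene, one of the five strand-oriented regulatory
#' region definitions (0-based half-open, clipped to scaffold bounds):
#' \describe{
#'   \item{5Kup2Kdown}{5000 bp upstream of the TSS to 2000 bp downstream.}
#'   \item{5Kup}{5000 bp upstream of the TSS.}
#'   \item{1Kup}{1000 bp upstream of the TSS.}
#'   \item{NearStartSite}{all scoring windows whose midpoint is nearer
#'     this gene's TSS than any other TSS (ties assigned to both
#'     genes).}
#'   \item{GeneTerr}{the span between the boundaries of the nearest
#'     non-overlapping gene neighbours, extended to at least 5000 bp
#'     upstream of the TSS.}
#' }
#'
#' @param genes gene model data.frame.
#' @param definition one of the five names above.
#' @param lengths named scaffold lengths.
#' @param windows scoring window table (required for NearStartSite).
#' @return data.frame(gene_id, scaffold, start, end); possibly several
#'   rows per gene for NearStartSite.
#' @export
regulatory_regions <- function(genes,
                               definition = c("1Kup", "5Kup", "5Kup2Kdown",
                                              "NearStartSite", "GeneTerr"),
                               lengths, windows = NULL) {
  definition <- match.arg(definition)
  clip <- function(df) {
    df$start <- pmax(0L, df$start)
    df$end <- pmin(as.integer(lengths[df$scaffold]), df$end)
    df[df$end > df$start, , drop = FALSE]
  }
  plus <- genes$strand == "+"
  up_down <- function(up, down) {
    start <- ifelse(plus, genes$tss - up, genes$tss - down)
    end <- ifelse(plus, genes$tss + down, genes$tss + up)
    clip(data.frame(gene_id = genes$gene_id, scaffold = genes$scaffold,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE))
  }
  if (definition == "5Kup2Kdown") return(up_down(5000L, 2000L))
  if (definition == "5Kup") return(up_down(5000L, 0L))
  if (definition == "1Kup") return(up_down(1000L, 0L))
  if (definition == "NearStartSite") {
    if (is.null(windows)) stop("NearStartSite requires the window table")
    out <- vector("list", 0)
    for (scaf in unique(genes$scaffold)) {
      g <- genes[genes$scaffold == scaf, , drop = FALSE]
      w <- windows[windows$scaffold == scaf, , drop = FALSE]
      if (!nrow(w)) next
      mid <- (w$start + w$end) / 2
      d <- abs(outer(mid, g$tss, "-"))
      dmin <- apply(d, 1, min)
      near <- d <= dmin + 1e-9   # ties go to every nearest gene
      hit <- which(near, arr.ind = TRUE)
      out[[length(out) + 1]] <- data.frame(
        gene_id = g$gene_id[hit[, 2]], scaffold = scaf,
        start = w$start[hit[, 1]], end = w$end[hit[, 1]],
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    return(res[order(res$gene_id, res$start), , drop = FALSE])
  }
  # GeneTerr
  out <- genes[, c("gene_id", "scaffold")]
  out$start <- out$end <- NA_integer_
  for (i in seq_len(nrow(genes))) {
    scaf <- genes$scaffold[i]
    same <- genes[genes$scaffold == scaf & genes$gene_id != genes$gene_id[i],
                  , drop = FALSE]
    left <- same$end[same$end <= genes$start[i]]
    right <- same$start[same$start >= genes$end[i]]
    s <- if (length(left)) max(left) else 0L
    e <- if (length(right)) min(right) else as.integer(lengths[[scaf]])
    if (genes$strand[i] == "+") s <- min(s, genes$tss[i] - 5000L)
    else e <- max(e, genes$tss[i] + 5000L)
    out$start[i] <- s
    out$end[i] <- e
  }
  clip(out)
}

#' Gene-level motif scores (Pgm)
#'
#' For every gene with at least one scoring window overlapping its
#' regulatory region (>= 1 bp): `Wg` is the number of overlapping scored
#' windows, `Ngm` the best (minimum) normalized score for motif m among
#' them, and `Pgm = 1 - (1 - Ngm)^Wg` -- a Sidak-style correction of the
#' minimum across windows. Genes with no overlapping scored window are
#' unscored (dropped, counted in an attribute).
#'
#' @param regions regulatory regions from [regulatory_regions()].
#' @param windows full window table from [partition_windows()].
#' @param norm a normalized score matrix (scored windows x motifs).
#' @return list(gene_id, Wg, ngm, pgm) where `ngm` and `pgm` are genes x
#'   motifs matrices.
#' @export
gene_motif_scores <- function(regions, windows, norm) {
  sw <- windows[windows$scored, , drop = FALSE]
  r_gr <- GenomicRanges::GRanges(regions$scaffold,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
  w_gr <- GenomicRanges::GRanges(sw$scaffold,
                                 IRanges::IRanges(sw$start + 1L, sw$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(r_gr, w_gr, minoverlap = 1L))
  gene_of_hit <- regions$gene_id[S4Vectors::queryHits(hits)]
  win_of_hit <- S4Vectors::subjectHits(hits)
  by_gene <- lapply(split(win_of_hit, gene_of_hit), unique)
  ids <- sort(unique(regions$gene_id))
  scored_ids <- intersect(ids, names(by_gene))
  wg <- vapply(by_gene[scored_ids], length, integer(1))
  ngm <- t(vapply(scored_ids, function(g) {
    apply(norm[by_gene[[g]], , drop = FALSE], 2, min)
  }, numeric(ncol(norm))))
  if (ncol(norm) == 1) ngm <- matrix(ngm, ncol = 1,
                                     dimnames = list(scored_ids,
                                                     colnames(norm)))
  pgm <- 1 - (1 - ngm)^wg
  structure(list(gene_id = scored_ids, Wg = wg, ngm = ngm, pgm = pgm),
            n_unscored = length(ids) - length(scored_ids))
}

#' Build motif target sets
#'
#' For each combination of motif, normalization, region and size, the
#' target set is the `size` genes with the best (smallest) Pgm, ties
#' broken by gene id; when fewer genes are scored the full list is taken
#' and flagged. With 223 motifs, two normalizations, two regions and two
#' sizes this yields 1784 sets.
#'
#' @param scores named list of [gene_motif_scores()] results, indexed
#'   "normalization.region" (e.g. `rank.1Kup`).
#' @param sizes named target-set sizes.
#' @return list with `sets` (named list of ordered gene-id vectors) and
#'   `manifest` (data.frame motif, normalization, region, size_label,
#'   size, n_genes, truncated).
#' @export
build_target_sets <- function(scores,
                              sizes = c(conservative = 100L,
                                        liberal = 800L)) {
  sets <- list()
  man <- list()
  for (key in names(scores)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    norm_name <- parts[1]
    region <- parts[2]
    sc <- scores[[key]]
    for (m in colnames(sc$pgm)) {
      ord <- order(sc$pgm[, m], sc$gene_id)
      ranked <- sc$gene_id[ord]
      for (sz in names(sizes)) {
        take <- min(sizes[[sz]], length(ranked))
        set_id <- paste(m, norm_name, region, sz, sep = ".")
        sets[[set_id]] <- ranked[seq_len(take)]
        man[[set_id]] <- data.frame(
          set_id = set_id, motif = m, normalization = norm_name,
          region = region, size_label = sz, size = sizes[[sz]],
          n_genes = take, truncated = take < sizes[[sz]],
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, man)
  rownames(manifest) <- NULL
  list(sets = sets, manifest = manifest)
}

#' Run the whole motif-scoring pipeline
#'
#' Partition windows, estimate the background, score every motif,
#' normalize both ways, build gene-level Pgm scores for the requested
#' regulatory regions and assemble the target sets.
#'
#' @param genome a DNAStringSet.
#' @param genes gene model data.frame.
#' @param pwms motif collection.
#' @param mask optional mask intervals.
#' @param t motif-entry transition probability.
#' @param regions regulatory-region definitions to score.
#' @param sizes target-set sizes.
#' @return list(windows, background, raw, rank_norm, gc_norm, scores,
#'   target_sets, manifest).
#' @export
motif_scan_pipeline <- function(genome, genes, pwms, mask = NULL,
                                t = 0.0025,
                                regions = c("1Kup", "GeneTerr"),
                                sizes = c(conservative = 100L,
                                          liberal = 800L)) {
  part <- partition_windows(genome, mask = mask)
  bg <- estimate_background(genome, genes)
  raw <- score_motif_windows(part, pwms, bg, t = t)
  norms <- normalize_scores(raw, part$windows)
  lengths <- setNames(Biostrings::width(genome), names(genome))
  scores <- list()
  for (reg in regions) {
    rr <- regulatory_regions(genes, reg, lengths,
                             windows = part$windows[part$windows$scored, ])
    scores[[paste0("rank.", reg)]] <-
      gene_motif_scores(rr, part$windows, norms$rank_norm)
    scores[[paste0("gc.", reg)]] <-
      gene_motif_scores(rr, part$windows, norms$gc_norm)
  }
  ts <- build_target_sets(scores, sizes)
  list(windows = part$windows, background = bg, raw = raw,
       rank_norm = norms$rank_norm, gc_norm = norms$gc_norm,
       scores = scores, target_sets = ts$sets, manifest = ts$manifest)
}
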
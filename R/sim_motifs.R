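#' Construct a PWM from a consensus and a dominance level
#'
#' Each column gives probability `dominance` to the consensus base and
#' `(1 - dominance)/3` to the others; `dominance = 1` yields a
#' degenerate 2-bit-per-column PWM whose samples always equal the
#' consensus. A pseudocount is added and columns renormalised so no cell
#' is exactly zero.
#'
#' @param id motif identifier.
#' @param consensus consensus string (ACGT).
#' @param dominance consensus-base probability per column.
#' @param pseudocount per-cell pseudocount applied before normalisation.
#' @return a PWM: list(id, width, mat, consensus, pseudocount).
#' @export
make_pwm <- function(id, consensus, dominance = 0.97, pseudocount = 0.01) {
  bases <- c("A", "C", "G", "T")
  cols <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(cols %in% bases))
  w <- length(cols)
  mat <- matrix((1 - dominance) / 3, nrow = 4, ncol = w,
                dimnames = list(bases, NULL))
  for (k in seq_len(w)) mat[cols[k], k] <- dominance
  site_probs <- mat                      # planting distribution
  mat <- mat + pseudocount               # scoring matrix, no zero cells
  mat <- sweep(mat, 2, colSums(mat), "/")
  list(id = id, width = w, mat = mat, site_probs = site_probs,
       consensus = paste(cols, collapse = ""), pseudocount = pseudocount)
}

#' Simulate a motif collection and plant sites in promoters
#'
#' Generates `cfg$n_motifs` PWMs with random consensus sequences and, for
#' a fraction `cfg$planted_gene_fraction` of genes, writes one
#' high-probability sample of the *first* motif into the gene's 1 kb
#' upstream region (random offset and strand; reverse-complemented for
#' minus-strand placements). Planted positions are recorded in a truth
#' table; a site whose upstream region would run off the scaffold edge is
#' skipped with a warning.
#'
#' @param cfg a [sim_config()].
#' @param genome genome from [simulate_genome()].
#' @param genes gene models from [simulate_gene_models()].
#' @return list(pwms, genome = modified genome, planted_sites =
#'   data.frame(motif_id, scaffold, position, strand, gene_id),
#'   planted_gene_ids).
#' @export
simulate_pwms_and_plant_sites <- function(cfg, genome, genes) {
  validate_sim_config(cfg)
  if (cfg$motif_length < 6) stop("motif_length must be >= 6")
  set.seed(op_seed(cfg$seed, 5L))
  bases <- c("A", "C", "G", "T")
  pwms <- lapply(seq_len(cfg$n_motifs), function(i) {
    make_pwm(sprintf("motif%03d", i),
             paste(sample(bases, cfg$motif_length, replace = TRUE),
                   collapse = ""),
             dominance = cfg$pwm_dominance)
  })

  n_plant <- round(cfg$planted_gene_fraction * cfg$n_genes)
  planted <- data.frame(motif_id = character(), scaffold = character(),
                        position = integer(), strand = character(),
                        gene_id = character(), stringsAsFactors = FALSE)
  if (n_plant >= 1) {
    pwm <- pwms[[1]]
    w <- pwm$width
    sl <- setNames(Biostrings::width(genome), names(genome))
    targets <- sample(genes$gene_id, n_plant)
    for (gid in targets) {
      g <- genes[genes$gene_id == gid, ]
      # 1 kb upstream in oriented coordinates
      if (g$strand == "+") {
        lo <- g$tss - 1000L
        hi <- g$tss - w
      } else {
        lo <- g$tss
        hi <- g$tss + 1000L - w
      }
      if (lo < 0 || hi + w > sl[[g$scaffold]] || hi < lo) {
        warning("upstream region off scaffold edge; site skipped for ", gid)
        next
      }
      pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      probs <- if (!is.null(pwm$site_probs)) pwm$site_probs else pwm$mat
      site <- paste(apply(probs, 2, function(p) sample(bases, 1, prob = p)),
                    collapse = "")
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") site else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
      genome[[g$scaffold]] <- Biostrings::replaceAt(
        genome[[g$scaffold]], IRanges::IRanges(pos + 1L, pos + w), ins)
      planted <- rbind(planted, data.frame(
        motif_id = pwm$id, scaffold = g$scaffold, position = pos,
        strand = strand, gene_id = gid, stringsAsFactors = FALSE))
    }
  }
  list(pwms = pwms, genome = genome, planted_sites = planted,
       planted_gene_ids = unique(planted$gene_id))
}

#' Write / read motif collections
#'
#' `write_pwms_meme()` emits MEME minimal format;
#' `read_pwms_meme()` parses it back. `write_pwm_tsv()` /
#' `read_pwm_tsv()` handle a single motif as a plain 4 x w TSV with rows
#' A, C, G, T.
#'
#' @param pwms list of PWMs (from [make_pwm()] or a reader).
#' @param path file path.
#' @return readers return PWM lists; writers the path, invisibly.
#' @export
write_pwms_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      p$width), con)
    for (k in seq_len(p$width))
      writeLines(paste(sprintf("%.6f", p$mat[, k]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_pwms_meme
#' @export
read_pwms_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  lapply(starts, function(s) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + grep("letter-probability matrix",
                    lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4))
    dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
    cons <- paste(rownames(mat)[apply(mat, 2, which.max)], collapse = "")
    list(id = id, width = w, mat = mat, consensus = cons,
         pseudocount = NA_real_)
  })
}

#' @rdname write_pwms_meme
#' @param pwm a single PWM.
#' @export
write_pwm_tsv <- function(pwm, path) {
  write.table(pwm$mat, path, sep = "\t", quote = FALSE,
              row.names = c("A", "C", "G", "T"), col.names = FALSE)
  invisible(path)
}

#' @rdname write_pwms_meme
#' @param id motif id to assign on read.
#' @export
read_pwm_tsv <- function(path, id = basename(path)) {
  x <- read.table(path, sep = "\t", row.names = 1)
  mat <- as.matrix(x)
  rownames(mat) <- c("A", "C", "G", "T")
  colnames(mat) <- NULL
  list(id = id, width = ncol(mat), mat = mat,
       consensus = paste(rownames(mat)[apply(mat, 2, which.max)],
                         collapse = ""),
       pseudocount = NA_real_)
}
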
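#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# Emulates the study design this pipeline was built for: 18 resequenced
# diploid females plus one haploid male from a single panmictic
# population, ~0.0015/bp diversity, 30x coverage, with selective sweeps
# planted over 5% of the genes (diversity reduced to 0.2x and the site
# frequency spectrum skewed toward rare alleles) and a few low-coverage
# regions. All downstream steps read the files written here.

suppressMessages(library(divscan))

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
cfg <- sweep_recovery_config(cfg)     # sweeps over 5% of the gene grid
cfg$coverage_dip_regions <- data.frame(
  scaffold = "scaf01", start = c(100000L, 300000L),
  end = c(110000L, 305000L))

genome <- simulate_genome(cfg)
genes <- simulate_gene_models(cfg, genome)
sim <- simulate_variants(cfg, genome, genes)
coverage <- simulate_coverage(cfg, genome)

write_genome_fasta(genome, file.path(outdir, "genome.fa"))
write_genes_gff3(genes, file.path(outdir, "genes.gff3"))
write_genes_bed(genes, file.path(outdir, "genes.bed"))
write_vcf(sim$snps, file.path(outdir, "cohort.vcf"))
write_coverage_bed(coverage, file.path(outdir, "coverage.bed"))
write_truth_tsv(sim$truth, file.path(outdir, "truth_sites.tsv"))
writeLines(sim$truth$sweep_gene_ids, file.path(outdir, "truth_sweep_genes.txt"))

cat("genome:      ", sum(Biostrings::width(genome)), "bp on",
    length(genome), "scaffolds\n")
cat("gene models: ", nrow(genes), "\n")
cat("variants:    ", n_sites(sim$snps), "biallelic SNPs;",
    length(sim$truth$sweep_gene_ids), "genes under planted sweeps\n")
cat("outputs in", outdir, "\n")
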
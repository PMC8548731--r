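# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the lncm6a package: run them in order from the repository
# root, e.g.
#
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_expression.R
#   ...
#
# All outputs land under results/.

suppressMessages(library(lncm6a))

RESULTS_DIR <- "results"
SIM_DIR <- file.path(RESULTS_DIR, "simulated")
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Study-scale synthetic dataset: two conditions (GM myoblasts, D4 myotubes),
# two replicate libraries per condition and fraction, 120 lncRNAs and 120
# protein-coding genes, 60% of lncRNAs carrying an m6A peak, 30% of genes
# differentially expressed, and two forced lncRNA/mRNA neighbor pairs of
# each regulatory sign as positive controls.
study_config <- function() {
  sim_config(seed = 20101L,
             n_chromosomes = 2L,
             chrom_length = 1200000L,
             n_lnc = 120L,
             n_coding = 120L,
             frac_lnc_with_peak = 0.6,
             frac_de = 0.3,
             planted_neighbor_pairs = 2L,
             motif_planting = TRUE)
}

load_simulation <- function() {
  ann <- read_gtf(file.path(SIM_DIR, "annotation.gtf"))
  genome <- Biostrings::readDNAStringSet(file.path(SIM_DIR, "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))
  wcm <- read_window_counts(file.path(SIM_DIR, "window_counts.tsv"), ann)
  gtab <- utils::read.delim(file.path(SIM_DIR, "gene_counts.tsv"))
  counts <- as.matrix(gtab[, -1]); rownames(counts) <- gtab$gene_id
  cond <- ifelse(grepl("^GM", colnames(counts)), "GM", "D4")
  truth_genes <- utils::read.delim(file.path(SIM_DIR, "truth_genes.tsv"))
  truth_peaks <- utils::read.delim(file.path(SIM_DIR, "truth_peaks.tsv"))
  truth_pairs <- utils::read.delim(file.path(SIM_DIR, "truth_pairs.tsv"))
  list(annotation = ann, genome = genome, wcm = wcm,
       gene_counts = counts, gene_condition = cond,
       truth = list(genes = truth_genes, peaks = truth_peaks,
                    pairs = truth_pairs))
}

save_table <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
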
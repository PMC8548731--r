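# Where do the peaks sit on lncRNAs? Exon-element proportions and relative
# enrichment, the transcript-scaled metagene profile, peaks per lncRNA, and
# DRACH motif enrichment of summit sequences against non-peak background.

source("analysis/00_config.R")

sim <- load_simulation()
peaks <- rbind(call_peaks(sim$wcm, "GM"), call_peaks(sim$wcm, "D4"))

es <- element_summary(peaks, sim$annotation)
print(es)
save_table(data.frame(element = names(es$counts), count = es$counts,
                      proportion = es$proportions,
                      length_share = es$length_share,
                      relative_enrichment = es$relative_enrichment),
           "element_summary.tsv")

mg <- metagene(peaks, sim$annotation)
save_table(mg, "metagene.tsv")

for (cond in c("GM", "D4")) {
  ppg <- peaks_per_gene(call_peaks(sim$wcm, cond))
  message(sprintf("%s: median m6A peaks per methylated lncRNA %.1f over %d genes",
                  cond, ppg$median, ppg$n_genes))
}

fg <- peak_sequences(peaks, sim$annotation, sim$genome)
bg <- nonpeak_background(peaks, sim$annotation, sim$genome, n = 500,
                         seed = 20104)
mot <- motif_enrichment(fg, bg)
save_table(mot, "motif_drach.tsv")
message(sprintf("DRACH: fold %.2f, p %.2g over %d peak sequences",
                mot$fold, mot$pvalue, length(fg)))

denovo <- motif_enrichment(fg, bg, pattern = NULL, kmer_lengths = 5:6)
save_table(denovo, "motif_denovo.tsv")
message("top de-novo k-mer: ", denovo$pattern[1])
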
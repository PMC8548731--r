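# Joint view of methylation change and expression change: four-quadrant
# classification, Pearson correlation among dual-significant lncRNAs, and
# the KS comparison of expression shifts for methylated vs unmethylated
# lncRNAs.

source("analysis/00_config.R")

sim <- load_simulation()
gc <- gene_counts(sim$gene_counts, sim$gene_condition)
de <- differential_expression(gc, sim$annotation)
sp <- split_by_biotype(de, sim$annotation)
peaks_gm <- call_peaks(sim$wcm, "GM")
peaks_d4 <- call_peaks(sim$wcm, "D4")
dp <- differential_peaks(peaks_gm, peaks_d4, sim$wcm)

rec <- integrate_meth_expr(sp$lnc, dp)
quad <- classify_quadrants(rec)
save_table(quad$records, "quadrants.tsv")
message(paste(sprintf("%s: %d", names(quad$counts), quad$counts),
              collapse = ", "))

corr <- meth_expr_correlation(rec, "significant")
message(sprintf("Pearson r = %.2f (p = %.2g, n = %d) among dual-significant lncRNAs",
                corr$r, corr$p, corr$n))

meth_ids <- unique(c(peaks_gm$gene_id, peaks_d4$gene_id))
ks <- ks_by_methylation(sp$lnc$log2FoldChange, sp$lnc$gene_id %in% meth_ids)
message(sprintf("KS: D = %.3f, p = %.2g (%d methylated vs %d unmethylated)",
                ks$D, ks$p, ks$n_methylated, ks$n_unmethylated))

jsonlite::write_json(list(quadrants = as.list(quad$counts),
                          correlation = corr, ks = ks),
                     file.path(RESULTS_DIR, "integration.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote results/integration.json")
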
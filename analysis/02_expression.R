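# Differential expression between growth-medium myoblasts (GM) and day-4
# myotubes (D4): RPKM normalization, moderated NB Wald test, and the
# lncRNA / mRNA partition by gene biotype.

source("analysis/00_config.R")

sim <- load_simulation()
gc <- gene_counts(sim$gene_counts, sim$gene_condition)

expressed <- expressed_genes(gc)
message(sprintf("%d of %d genes expressed in at least one condition",
                sum(expressed), length(expressed)))

de <- differential_expression(gc, sim$annotation)
sp <- split_by_biotype(de, sim$annotation)
write_de_table(sp$lnc, sim$annotation, file.path(RESULTS_DIR, "de_lncRNA.tsv"))
write_de_table(sp$mrna, sim$annotation, file.path(RESULTS_DIR, "de_mRNA.tsv"))

for (nm in c("lnc", "mrna")) {
  d <- sp[[nm]]
  message(sprintf("%-5s: %d tested, %d up in D4, %d down", nm, nrow(d),
                  sum(d$direction == "Up"), sum(d$direction == "Down")))
}

# agreement with the planted truth
m <- merge(de, sim$truth$genes[, c("gene_id", "true_de_flag", "true_de_log2fc")])
sens <- mean(m$padj[m$true_de_flag] <= 0.05)
fpr <- mean(m$padj[!m$true_de_flag] <= 0.05)
message(sprintf("truth check: sensitivity %.2f, false-positive fraction %.3f",
                sens, fpr))
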
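# Build the synthetic two-condition m6A/expression dataset the rest of the
# analysis runs on: genome, annotation, windowed IP/input counts, gene-level
# RNA-seq counts, and the truth tables recording what was planted.

source("analysis/00_config.R")

cfg <- study_config()
sim <- simulate_dataset(cfg)
write_simulation(sim, SIM_DIR)

tg <- sim$truth$genes
tp <- sim$truth$peaks
message(sprintf("genes: %d (%d lncRNA); windows: %d across %d libraries",
                nrow(tg), sum(tg$gene_type != "protein_coding"),
                nrow(sim$wcm$windows), ncol(sim$wcm$counts)))
message(sprintf("planted: %d DE genes, %d m6A peaks (%d differential), %d neighbor pairs",
                sum(tg$true_de_flag), nrow(tp), sum(tp$true_diff_flag),
                nrow(sim$truth$pairs)))
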
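# m6A peak detection per condition from windowed IP/input counts, and the
# Fisher-exact differential comparison over the union peak set.

source("analysis/00_config.R")

sim <- load_simulation()
peaks_gm <- call_peaks(sim$wcm, "GM")
peaks_d4 <- call_peaks(sim$wcm, "D4")
write_peaks_bed(peaks_gm, file.path(RESULTS_DIR, "peaks_GM.bed"))
write_peaks_bed(peaks_d4, file.path(RESULTS_DIR, "peaks_D4.bed"))
message(sprintf("peaks: %d in GM, %d in D4 (planted: %d)",
                nrow(peaks_gm), nrow(peaks_d4), nrow(sim$truth$peaks)))

dp <- differential_peaks(peaks_gm, peaks_d4, sim$wcm)
save_table(dp, "diff_peaks.tsv")
message(sprintf("differential: %d hyper, %d hypo of %d union peaks (planted %d)",
                sum(dp$status == "hyper"), sum(dp$status == "hypo"), nrow(dp),
                sum(sim$truth$peaks$true_diff_flag)))

hit <- vapply(seq_len(nrow(sim$truth$peaks)), function(i) {
  tp <- sim$truth$peaks[i, ]
  any(peaks_gm$gene_id == tp$gene_id & peaks_gm$start < tp$end & peaks_gm$end > tp$start) ||
  any(peaks_d4$gene_id == tp$gene_id & peaks_d4$start < tp$end & peaks_d4$end > tp$start)
}, logical(1))
message(sprintf("planted-peak recovery: %.2f", mean(hit)))
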
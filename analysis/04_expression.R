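#!/usr/bin/env Rscript

# Step 4 - developmental expression.
#
# Computes RPKM from the simulated read-count tables, summarises
# log2(RPKM + 1) per stage (mean and SD over replicates), verifies the
# per-library conservation identity, and draws per-gene stage profiles
# for a selection of transcripts.  Writes the expression table and a
# figure under results/expression/.

suppressPackageStartupMessages(library(gstmine))

sim <- "results/simulation"
out <- "results/expression"
stopifnot(dir.exists(sim))  # run analysis/01_simulate.R first
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts_df <- utils::read.delim(file.path(sim, "read_counts.tsv"),
                               check.names = FALSE)
libs <- utils::read.delim(file.path(sim, "library_sizes.tsv"))
assembly <- read_fasta(file.path(sim, "assembly_pop_a.fasta"),
                       type = "dna")
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$transcript_id
ct <- count_table(counts, stage = libs$stage, replicate = libs$replicate,
                  total_mapped = libs$total_mapped,
                  length_bp = stats::setNames(assembly$length_bp,
                                              assembly$id))

summ <- summarize_stages(ct, pseudocount = 1)
write_tsv(summ, file.path(out, "stage_summary.tsv"))

# conservation identity: catalog RPKM mass equals the catalog's share of
# the library, library by library
rp <- rpkm_matrix(ct)
rel <- vapply(seq_len(ncol(rp)), function(j) {
  lhs <- sum(rp[, j] * ct$length_bp / 1000)
  rhs <- 1e6 * sum(ct$counts[, j]) / ct$total_mapped[j]
  abs(lhs - rhs) / rhs
}, numeric(1))
cat(sprintf("libraries: %d; max relative conservation error: %.2e\n",
            ncol(rp), max(rel)))

# bar plot of log2 RPKM per stage for the six most expressed transcripts
top <- names(sort(tapply(summ$mean_log2_rpkm, summ$transcript_id, max),
                  decreasing = TRUE))[1:6]
grDevices::pdf(file.path(out, "stage_profiles.pdf"), width = 9, height = 6)
graphics::par(mfrow = c(2, 3), mar = c(6, 4, 2, 1))
for (tx in top) {
  sub <- summ[summ$transcript_id == tx, ]
  bp <- graphics::barplot(sub$mean_log2_rpkm, names.arg = sub$stage,
                          las = 2, ylab = "log2(RPKM + 1)", main = tx,
                          ylim = c(0, max(sub$mean_log2_rpkm +
                                            sub$sd_log2_rpkm) * 1.1))
  graphics::arrows(bp, sub$mean_log2_rpkm - sub$sd_log2_rpkm,
                   bp, sub$mean_log2_rpkm + sub$sd_log2_rpkm,
                   angle = 90, code = 3, length = 0.03)
}
grDevices::dev.off()
cat(sprintf("wrote stage summaries for %d transcripts and %s\n",
            length(unique(summ$transcript_id)),
            file.path(out, "stage_profiles.pdf")))
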
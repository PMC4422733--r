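#!/usr/bin/env Rscript

# Step 1 - simulate the study inputs.
#
# Generates the default two-population synthetic study: nine GST
# subclasses planted at the family sizes recovered from the first
# assembly (39 genes: Delta 11, Theta 1, Mu 5, Omega 3, Sigma 10, Zeta 2,
# Kappa 1, mGST-1 2, mGST-3 4) plus one population-private Delta and one
# private Omega gene in the second population, embedded among decoy
# contigs, together with stage-structured read counts.  Writes the two
# assemblies, the labeled query/reference panel, the ground truth and the
# count tables under results/simulation/.

suppressPackageStartupMessages(library(gstmine))

seed <- 1
out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- generate_scenario(seed = seed)
write_fasta(sc$assembly_a, file.path(out, "assembly_pop_a.fasta"))
write_fasta(sc$assembly_b, file.path(out, "assembly_pop_b.fasta"))
panel_out <- sc$panel
panel_out$description <- panel_out$label
write_fasta(panel_out, file.path(out, "reference_panel.fasta"))
write_tsv(sc$truth, file.path(out, "truth_genes.tsv"))
write_tsv(sc$plants_a, file.path(out, "truth_transcripts_pop_a.tsv"))
write_tsv(sc$plants_b, file.path(out, "truth_transcripts_pop_b.tsv"))

lens <- stats::setNames(sc$assembly_a$length_bp, sc$assembly_a$id)
sim <- simulate_counts(sc$plants_a, lens, seed = seed + 20000L)
counts_df <- data.frame(transcript_id = rownames(sim$counts$counts),
                        sim$counts$counts, check.names = FALSE)
write_tsv(counts_df, file.path(out, "read_counts.tsv"))
write_tsv(data.frame(library = colnames(sim$counts$counts),
                     stage = sim$counts$stage,
                     replicate = sim$counts$replicate,
                     total_mapped = sim$counts$total_mapped),
          file.path(out, "library_sizes.tsv"))
write_tsv(data.frame(transcript_id = rownames(sim$levels), sim$levels,
                     check.names = FALSE),
          file.path(out, "truth_expression_levels.tsv"))

cat(sprintf(paste0(
  "Simulated %d genes across 9 subclasses (two populations, seed %d):\n",
  "  population A: %d contigs (%d planted + decoys)\n",
  "  population B: %d contigs (%d planted + decoys)\n",
  "  read counts: %d transcripts x %d libraries\n"),
  nrow(sc$truth), seed,
  nrow(sc$assembly_a), nrow(sc$plants_a),
  nrow(sc$assembly_b), nrow(sc$plants_b),
  nrow(sim$counts$counts), ncol(sim$counts$counts)))
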
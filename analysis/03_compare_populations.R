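#!/usr/bin/env Rscript

# Step 3 - cross-population correspondence and the merged catalog.
#
# Re-runs the two single-assembly workflows, pairs the deduced proteins
# between populations by bidirectional best hit within subclass, applies
# the >= 90% (same gene) / < 50% (distinct gene) overlap-identity
# thresholds, triggers targeted re-searches for additional-gene
# candidates, and merges everything into one gene catalog.  Writes the
# correspondence table, the variation/additional-gene table and the
# merged catalog with per-subclass totals under results/compare/.

suppressPackageStartupMessages(library(gstmine))

sim <- "results/simulation"
out <- "results/compare"
stopifnot(dir.exists(sim))  # run analysis/01_simulate.R first
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- read_fasta(file.path(sim, "reference_panel.fasta"),
                    type = "protein")
profiles <- load_domain_profiles()
cfg <- pipeline_config()
assembly_a <- read_fasta(file.path(sim, "assembly_pop_a.fasta"),
                         type = "dna", assembly = "pop_a")
assembly_b <- read_fasta(file.path(sim, "assembly_pop_b.fasta"),
                         type = "dna", assembly = "pop_b")
res_a <- run_single(assembly_a, panel, profiles, cfg)
res_b <- run_single(assembly_b, panel, profiles, cfg)
cmp <- run_compare(res_a, res_b, assembly_a, assembly_b, cfg)

# correspondence report layout:
# protein, accession A, type (F/P), accession B, type, % identity, verdict
prot_tx <- function(res) stats::setNames(res$proteins$transcript_id,
                                         res$proteins$name)
pairs <- cmp$pairs
pairs$accession_a <- unname(prot_tx(res_a)[pairs$protein_a_id])
pairs$accession_b <- unname(prot_tx(res_b)[pairs$protein_b_id])
pairs$identity_rounded <- round(pairs$overlap_identity_pct)
write_tsv(pairs[, c("protein_a_id", "accession_a", "completeness_a",
                    "protein_b_id", "accession_b", "completeness_b",
                    "identity_rounded", "verdict", "note")],
          file.path(out, "correspondence.tsv"))
write_tsv(pairs[pairs$verdict != "same_gene", ],
          file.path(out, "variation.tsv"))
write_tsv(cmp$additional, file.path(out, "additional_genes.tsv"))
write_tsv(cmp$catalog, file.path(out, "merged_catalog.tsv"))
write_tsv(cmp$counts, file.path(out, "merged_gene_counts.tsv"))

cat(sprintf(paste0(
  "correspondence: %d pairs (%d same gene, %d divergent, %d distinct,",
  " %d unmatched)\nadditional genes: %d\nmerged catalog: %d genes\n"),
  nrow(pairs), sum(pairs$verdict == "same_gene"),
  sum(pairs$verdict == "divergent_ortholog"),
  sum(pairs$verdict == "distinct_gene"),
  sum(pairs$verdict == "unmatched"),
  nrow(cmp$additional), cmp$total_genes))
print(cmp$counts, row.names = FALSE)
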
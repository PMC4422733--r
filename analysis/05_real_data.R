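#!/usr/bin/env Rscript

# Step 5 (optional, real data) - the same workflow on downloaded
# assemblies.
#
# The study's real inputs are two public transcriptome shotgun
# assemblies (NCBI TSA; transcript accessions GAXK01xxxxxx for the Gulf
# of Maine assembly and GBFB01xxxxxx for the Norwegian Sea assembly) and
# a labeled query panel of arthropod GST proteins.  None of that is
# fetched here: place the files below by hand (e.g. with NCBI datasets /
# efetch) and re-run.  The script then runs exactly the synthetic-data
# workflow of steps 2-3 on the real inputs: mine, deduce, annotate,
# compare, merge.
#
#   data/real/assembly_gulf_of_maine.fasta
#   data/real/assembly_norwegian_sea.fasta
#   data/real/panel.fasta    (headers: ">ACC class|subclass")

suppressPackageStartupMessages(library(gstmine))

paths <- c(a = "data/real/assembly_gulf_of_maine.fasta",
           b = "data/real/assembly_norwegian_sea.fasta",
           panel = "data/real/panel.fasta")
if (!all(file.exists(paths))) {
  cat("real-data inputs not present; nothing to do.\n",
      "Expected files:\n", paste(" ", paths, collapse = "\n"), "\n")
  quit(status = 0)
}

out <- "results/real"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
panel <- read_fasta(paths["panel"], type = "protein")
cfg <- pipeline_config(prefix = "Calfi")
assembly_a <- read_fasta(paths["a"], type = "dna",
                         assembly = "gulf_of_maine")
assembly_b <- read_fasta(paths["b"], type = "dna",
                         assembly = "norwegian_sea")
res_a <- run_single(assembly_a, panel, profiles = NULL, cfg)
res_b <- run_single(assembly_b, panel, profiles = NULL, cfg)
cmp <- run_compare(res_a, res_b, assembly_a, assembly_b, cfg)
write_tsv(res_a$annotations, file.path(out, "annotations_gulf.tsv"))
write_tsv(res_b$annotations, file.path(out, "annotations_norwegian.tsv"))
write_tsv(cmp$pairs, file.path(out, "correspondence.tsv"))
write_tsv(cmp$catalog, file.path(out, "merged_catalog.tsv"))
cat(sprintf("merged catalog: %d genes\n", cmp$total_genes))
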
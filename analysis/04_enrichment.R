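#!/usr/bin/env Rscript
# Stage 4: gene-set over-representation of stability-altered transcripts.
#
# Universe = genes passing the expression/length filters and evaluable
# for stability; hypergeometric upper tail per set, BH across sets.

suppressPackageStartupMessages(library(brustab))
data_dir <- "results/data"

counts <- read_counts(file.path(data_dir, "counts.tsv"))
sheet <- read_sample_sheet(file.path(data_dir, "samples.csv"))
gm <- read_gene_models(file.path(data_dir, "gene_models.tsv"))
sets <- read_gmt(file.path(data_dir, "gene_sets.gmt"))
stab <- read_tsv("results/stability.tsv")

rpkm <- compute_rpkm(counts, gm)
pulse_libs <- sheet$library_id[sheet$assay == "pulse"]
universe <- intersect(apply_filters(rpkm, gm, pulse_libs),
                      stab$gene_id[stab$class != "not_evaluable"])

for (cls in c("destabilized", "stabilized")) {
  query <- intersect(stab$gene_id[stab$class == cls], universe)
  ora <- ora_analysis(query, sets, universe, enrichment_fdr = 0.05)
  write_tsv(ora, sprintf("results/ora_%s.tsv", cls))
  hits <- ora[ora$significant, ]
  cat(sprintf("%s (%d genes): %d set(s) at FDR < 0.05%s\n", cls,
              length(query), nrow(hits),
              if (nrow(hits)) paste0(": ", paste(
                sprintf("%s (q=%.2g, %.1fx)", hits$set_name, hits$q,
                        hits$fold_enrichment), collapse = ", "))
              else ""))
}
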
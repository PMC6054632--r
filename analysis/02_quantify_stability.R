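#!/usr/bin/env Rscript
# Stage 2: RPKM quantification and differential RNA stability.
#
# Stability index per transcript = chase RPKM / pulse RPKM per replicate
# pair; condition index = median across replicates; case/control ratio
# classified at the 1.5-fold rule.

suppressPackageStartupMessages(library(brustab))
data_dir <- "results/data"

counts <- read_counts(file.path(data_dir, "counts.tsv"))
sheet <- read_sample_sheet(file.path(data_dir, "samples.csv"))
gm <- read_gene_models(file.path(data_dir, "gene_models.tsv"))

rpkm <- compute_rpkm(counts, gm)
write_tsv(data.frame(gene_id = rownames(rpkm), rpkm, check.names = FALSE),
          "results/rpkm.tsv")

sa <- stability_analysis(counts, gm, sheet, case = "case",
                         control = "control", fold_change_min = 1.5)
write_tsv(sa$records, "results/stability.tsv")

sm <- sa$summary
cat(sprintf("%d of %d transcripts altered >= 1.5-fold (%d stabilized, %d destabilized)\n",
            sm$n_altered, sm$n_genes, sm$stabilized, sm$destabilized))
cat(sprintf("%.0f%% of altered transcripts were destabilized\n",
            100 * sm$fraction_destabilized))

# how well do calls recover the planted truth?
truth <- read_tsv(file.path(data_dir, "truth.tsv"))
ctl <- truth[truth$group == "control", ]
cas <- truth[truth$group == "case", ]
true_dest <- cas$gene_id[cas$k > ctl$k[match(cas$gene_id, ctl$gene_id)]]
called <- sa$records$gene_id[sa$records$class == "destabilized"]
cat(sprintf("planted destabilized genes recovered: %d/%d; false calls: %d\n",
            length(intersect(called, true_dest)), length(true_dest),
            length(setdiff(called, true_dest))))
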
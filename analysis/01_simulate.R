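#!/usr/bin/env Rscript
# Stage 1: generate the demonstration pulse-chase experiment.
#
# A 4 vs 4 contrast (control vs case) over 2000 genes in which the
# "ribosome" (2-fold) and "oxphos" (2.5-fold) gene sets are destabilized,
# a UGUGUG motif is spiked into the 3'UTRs of the destabilized sets at 3x
# density, and protein abundances track log2 stability with slope 0.8
# except for the decoupled ribosome set. All artifacts are written as
# plain-text files under results/data/ so later stages exercise the
# package's readers.

suppressPackageStartupMessages(library(brustab))
seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 2000L, dispersion = 0.01,
                  n_sets = 20L, set_size = 60L,
                  planted_motif = "UGUGUG", planted_motif_fold = 3,
                  groups = list(
                    sim_group("control", 4L),
                    sim_group("case", 4L,
                              k_mult = c(ribosome = 2, oxphos = 2.5))))
ds <- simulate_experiment(cfg, seed)
prot <- simulate_protein_table(ds$truth, coupling_slope = 0.8,
                               noise_sd = 0.2,
                               decoupled_sets = "ribosome",
                               gene_sets = ds$gene_sets,
                               n_replicates = 3L, seed = seed + 1L)

write_counts(ds$counts, file.path(out, "counts.tsv"))
write_sample_sheet(ds$sample_sheet, file.path(out, "samples.csv"))
write_gene_models(ds$gene_models, file.path(out, "gene_models.tsv"))
write_gmt(ds$gene_sets, file.path(out, "gene_sets.gmt"))
write_fasta(ds$utr3, file.path(out, "utr3.fasta"))
write_tsv(ds$truth, file.path(out, "truth.tsv"))
write_protein_table(prot, file.path(out, "protein.tsv"))
write_tsv(default_motif_table(), file.path(out, "motifs.tsv"))

cat(sprintf("simulated %d genes x %d libraries (seed %d)\n",
            nrow(ds$counts), ncol(ds$counts), seed))
cat(sprintf("planted: ribosome k x2, oxphos k x2.5; motif UGUGUG x3 density\n"))
cat(sprintf("wrote %d files under %s\n", length(list.files(out)), out))
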
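#!/usr/bin/env Rscript
# Stage 5: transcript characteristics and 3'UTR motif enrichment.
#
# Spearman association of the case-condition stability index with
# transcript length, 3'UTR length and intron count, plus IUPAC motif
# scanning of destabilized vs unchanged 3'UTRs.

suppressPackageStartupMessages(library(brustab))
data_dir <- "results/data"

gm <- read_gene_models(file.path(data_dir, "gene_models.tsv"))
stab <- read_tsv("results/stability.tsv")
utr3 <- read_fasta(file.path(data_dir, "utr3.fasta"))
motifs <- read_motif_table(file.path(data_dir, "motifs.tsv"))

idx <- match(stab$gene_id, gm$gene_id)
altered <- stab$class %in% c("stabilized", "destabilized")
feats <- rbind(
  feature_association(stab$s_case, gm$length_bp[idx], seed = 1L,
                      altered = altered, feature_name = "length_bp"),
  feature_association(stab$s_case, gm$utr3_len_bp[idx], seed = 1L,
                      altered = altered, feature_name = "utr3_len_bp"),
  feature_association(stab$s_case, gm$intron_count[idx], seed = 1L,
                      altered = altered, feature_name = "intron_count"))
write_tsv(feats, "results/feature_association.tsv")
for (i in seq_len(nrow(feats))) {
  cat(sprintf("%s: rho = %+.3f (perm p = %.3g)\n", feats$feature_name[i],
              feats$spearman_rho[i], feats$p_perm[i]))
}

me <- motif_enrichment(stab$gene_id[stab$class == "destabilized"],
                       stab$gene_id[stab$class == "unchanged"],
                       utr3, motifs)
me <- me[order(me$q, me$fisher_p), ]
write_tsv(me, "results/motif_enrichment.tsv")
cat(sprintf("top motif among destabilized 3'UTRs: %s (%s), OR = %.2f, q = %.2g\n",
            me$motif_name[1], me$pattern[1], me$presence_odds_ratio[1],
            me$q[1]))
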
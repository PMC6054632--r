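#!/usr/bin/env Rscript
# Stage 6: RNA stability vs protein abundance.
#
# Log2-log2 regression of case protein abundance on the stability index
# (overall and for the decoupled ribosome set), the concordant-change
# set at the 10% protein rule, and pathway-level aggregate ANOVA.

suppressPackageStartupMessages(library(brustab))
data_dir <- "results/data"

stab <- read_tsv("results/stability.tsv")
prot <- read_protein_table(file.path(data_dir, "protein.tsv"))
sets <- read_gmt(file.path(data_dir, "gene_sets.gmt"))

prot_case <- prot[prot$group == "case", ]
mean_ab <- tapply(prot_case$abundance, prot_case$gene_id, mean)
s_case <- stab$s_case[match(names(mean_ab), stab$gene_id)]

fit_all <- fit_stability_protein_regression(s_case, as.numeric(mean_ab))
in_rib <- names(mean_ab) %in% sets$ribosome
fit_rib <- fit_stability_protein_regression(s_case[in_rib],
                                            as.numeric(mean_ab)[in_rib])
cat(sprintf("all transcripts: slope = %.3f (F = %.1f, p = %.2g, n = %d)\n",
            fit_all$slope, fit_all$F, fit_all$p, fit_all$n))
cat(sprintf("ribosome set (decoupled in truth): slope = %.3f (p = %.2g)\n",
            fit_rib$slope, fit_rib$p))
write_tsv(rbind(cbind(set = "all", fit_all), cbind(set = "ribosome", fit_rib)),
          "results/regression.tsv")

pchg <- protein_changes(prot, case = "case", control = "control")
cs <- concordant_set(stab, pchg, protein_min_change = 0.10)
write_tsv(cs$records, "results/concordance.tsv")
sm <- cs$summary
cat(sprintf("%d concordant genes: %.0f%% of stability changes, %.0f%% of protein changes\n",
            sm$n_concordant, 100 * sm$fraction_of_stability_changes,
            100 * sm$fraction_of_protein_changes))

agg <- aggregate_pathway_compare(prot, sets, control = "control",
                                 groups = c("case", "control"))
agg <- agg[order(agg$q), ]
write_tsv(agg, "results/aggregate_pathways.tsv")
top <- agg[1, ]
cat(sprintf("strongest aggregate protein shift: %s (case mean %.2f of control, q = %.2g)\n",
            top$pathway_name, top$mean_case, top$q))
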
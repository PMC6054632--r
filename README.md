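# brustab

Genome-wide RNA stability analysis for bromouridine pulse-chase
sequencing (Bru-seq / BruChase-seq), for researchers studying RNA
turnover — e.g. transcriptome-wide destabilization phenotypes in
disease models — from gene-level count matrices.

In a pulse-chase design, nascent RNA is metabolically labeled for a
short pulse (0.5 h) and sequenced either immediately (synthesis) or
after a chase (here 6 h), so surviving labeled RNA reflects stability.
Under first-order decay at rate *k*, the labeled mass surviving the
chase is a fraction e^(−k·t_chase) of the pulse mass, and the
per-transcript **stability index**

    S = RPKM_chase / RPKM_pulse        (per replicate pair)

estimates that fraction up to a shared normalization constant.
Condition-level indices are medians across replicates, and transcripts
with a case/control ratio R = S_case/S_control ≥ 1.5 (or ≤ 1/1.5) are
called stabilized (destabilized). Around this core the package
provides:

* RPKM quantification with the standard mean-RPKM ≥ 0.5 and
  length ≥ 300 bp gene filters,
* differential synthesis on pulse counts: a negative-binomial Wald test
  with median-of-ratios size factors and a bias-corrected, trend-shrunk
  method-of-moments dispersion estimator (selection at FDR ≤ 0.1 and
  ≥ 1.5-fold),
* gene-set over-representation (hypergeometric upper tail,
  Benjamini–Hochberg across sets),
* transcript-feature association (Spearman, permutation p) and 3'UTR
  motif enrichment (exact IUPAC scanning, Fisher presence test),
* RNA-stability-to-protein-abundance concordance: log2–log2 regression
  with the extra-sum-of-squares F test, concordant-set extraction at a
  10% protein-change rule, and pathway-level aggregate ANOVA,
* a kinetic synthetic-data generator (first-order decay, compositional
  read sampling, NB replicate noise, planted pathway effects, coupled
  proteins) that gives every analysis a ground truth to be validated
  against.

## Worked example

The `analysis/` scripts run a complete in-silico experiment: 2000
genes, 4 control vs 4 case replicate pairs, with the "ribosome" and
"oxphos" gene sets destabilized (k ×2 and ×2.5), a UGUGUG motif spiked
into destabilized 3'UTRs, and proteins coupled to stability except for
the ribosome set.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify_stability.R
Rscript analysis/03_synthesis.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_features_motifs.R
Rscript analysis/06_concordance.R
```

which prints, stage by stage:

```
124 of 2000 transcripts altered >= 1.5-fold (8 stabilized, 116 destabilized)
94% of altered transcripts were destabilized
planted destabilized genes recovered: 110/120; false calls: 6

1999 genes tested after filters; 1 pass FDR <= 0.1 and FC >= 1.5

destabilized (116 genes): 2 set(s) at FDR < 0.05: oxphos (q=3.4e-68, 16.0x),
  ribosome (q=2e-67, 15.8x)
stabilized (8 genes): 0 set(s) at FDR < 0.05

top motif among destabilized 3'UTRs: UG_repeat (UGUGUG), OR = 3.06, q = 1e-07

all transcripts: slope = 0.739 (F = 19383.4, p = 0, n = 1993)
ribosome set (decoupled in truth): slope = 0.005 (p = 0.58)
72 concordant genes: 58% of stability changes, 9% of protein changes
strongest aggregate protein shift: oxphos (case mean 0.35 of control, q = 5.4e-05)
```

Reading the output: the stability stage recovers 110 of the 120
planted destabilized genes with 6 false calls; the synthesis stage is
null-like because decay, not synthesis, was perturbed; ORA ranks
exactly the two planted pathways first; the spiked motif tops the
10-motif panel; the regression slope on measured indices (0.739) is
the attenuated version of the generative coupling (0.8) — regression
on noisy predictors shrinks slopes — while the decoupled ribosome set
shows no relationship, and the oxphos proteins drop to 35% of control
in aggregate. Tables land under `results/`.

The same pipeline runs as one orchestrated call with a config (list or
YAML):

```r
library(brustab)
summary <- run_pipeline(demo_run_config(seed = 1), "pipeline_out")
```

## Layout

```
R/                 implementation (simulator, io, quantify, stability,
                   synthesis, enrichment, features/motifs, concordance,
                   pipeline orchestration)
analysis/          numbered narrative drivers for the demo experiment
scripts/           acceptance.R (see above)
tests/testthat/    unit, property and end-to-end acceptance tests
vignettes/         methods vignette (model, estimators, design choices)
inst/extdata/      column schema and a demo pipeline config
```
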
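---
title: "Methods: RNA stability analysis from pulse-chase sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA stability analysis from pulse-chase sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brustab)
```

## The measurement and its model

Bromouridine pulse-chase sequencing measures RNA turnover directly:
nascent transcripts are metabolically labeled during a short pulse
(0.5 h of BrU), and the labeled population is sequenced either
immediately (the pulse library, reflecting synthesis) or after a 6 h
uridine chase (the chase library, in which only RNA that survived
degradation remains). brustab implements the genome-wide analysis of
such experiments: stability indices, differential stability between
conditions, differential synthesis, gene-set over-representation,
transcript-feature and 3'UTR-motif association, and the relation of RNA
stability to protein abundance.

Under constant synthesis at rate $\alpha$ (copies/h) and first-order
decay at rate $k$ (/h), the labeled mass accumulated over a pulse of
length $t_p$ is $m_p = (\alpha/k)(1 - e^{-k t_p})$, and after a chase
of length $t_c$, $m_c = m_p e^{-k t_c}$. The per-transcript **stability
index** $S$ — the chase/pulse ratio of RPKM — therefore estimates
$e^{-k t_c}$ up to a library-normalization constant shared by all genes
of a condition. The chase clock starts at pulse end, and labeling is
taken as uniform in time during the pulse (the protocol does not
constrain incorporation kinetics; uniformity is the minimal assumption).
Ratios *between* genes or *between* conditions cancel the shared
constant, which is why the pipeline's inferential quantities are ratios:
the condition index (median of $S$ across replicate pairs) and the
differential ratio $R = S_{case}/S_{control}$, classified as
stabilized when $R \ge 1.5$, destabilized when $R \le 1/1.5$ (both
bounds inclusive).

An auxiliary half-life column, $t_{1/2} = -t_c \ln 2 / \ln S$, is
emitted as model-derived: it assumes first-order decay and perfect
normalization, and is not used by any classification.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `t_pulse`, `t_chase` | 0.5, 6 | h | labeling design being emulated |
| `min_mean_rpkm` | 0.5 | RPKM | expression filter (inclusive) |
| `min_length_bp` | 300 | bp | length filter (inclusive) |
| `fold_change_min` | 1.5 | — | stability/synthesis selection |
| `synthesis_fdr_max` | 0.1 | — | BH threshold for synthesis calls |
| `enrichment_fdr` | 0.05 | — | BH threshold for ORA significance |
| `pulse_min_rpkm` | 0.5 | RPKM | guard against ratio blow-up |
| `protein_min_change` | 0.10 | — | protein up/down threshold |

The expression and length filters are applied to the pulse libraries of
the two groups being compared (they condition the synthesis comparison;
a flag applies them to chase libraries instead). `pulse_min_rpkm` is an
artifact decision of this package: source experiments do not state how
zero-denominator transcripts were handled, and the guard simply marks a
pair not-evaluable rather than producing unstable ratios. Stability
selection is fold-change-only by design; no FDR is attached to the
1.5-fold rule.

## What the simulator emulates — and what it does not

The generator (`sim_config()` / `simulate_experiment()`) draws a gene
population once per configuration (`population_seed`): lengths
lognormal (median 2 kb), synthesis rates lognormal, decay rates
lognormal with **median half-life 4 h and log-sd 0.7**, NB dispersion
0.05, ~5 million reads per library, 4 replicate pairs per condition.
Condition effects multiply $k$ and/or $\alpha$ for named gene sets, so
pathway-structured destabilization can be planted and later recovered.
Reads are sampled compositionally in proportion to transcript mass
$\times$ length, which makes RPKM recover copy number; replicate counts
are NB with variance $\mu + \phi\mu^2$. The run seed redraws only
sequencing noise (and 3'UTR/protein noise), never the truth table, so
Monte-Carlo runs share ground truth unless `population_seed` is varied
too. With `dispersion = 0` counts equal their real-valued expectations
exactly — a noiseless diagnostic mode (the one case where the count
matrix is not integer).

Protein abundances are linear in log2 of the true stability index
(default slope 0.8, noise sd 0.2 on log2), with a designated decoupled
set (slope 0) emulating feedback-buffered pathways such as the
cytoplasmic ribosome.

Deliberately not simulated: read-level data (no FASTQ), isoforms and
splicing, NMD/cryptic-exon events, batch effects, GC or length bias in
library prep, and correlated gene-gene noise. Passing tests on this
generator therefore demonstrate correctness of the estimators under the
stated kinetic model and NB noise — not robustness to real-data
artifacts such as mappability or 3' bias.

## The differential-synthesis test

Counts are normalized by median-of-ratios size factors (reference genes
= nonzero in every library; factors rescaled to geometric mean 1; a
pseudo-reference fallback exists for sparse matrices). The two-group
test is a Wald test on the log ratio of normalized group means with the
NB delta-method variance $(1/n^2)\sum_j (\mu/s_j + \phi\mu^2)$ per
group. Its calibration at few replicates depends entirely on the
dispersion estimator, which is where the design effort went:

* per-gene method-of-moments $\hat\phi$ from the pooled within-group
  variance of normalized counts;
* a lowess trend of $\log\hat\phi$ on $\log\mu$ across genes, fitted
  with `iter = 0` (plain local least squares) and **bias-corrected** by
  $\psi(d/2) + \log 2 - \log d$ (with $d$ the residual df): in the
  overdispersion-dominated regime $\hat\phi \sim \phi\,\chi^2_d/d$, so
  the *mean of the log* is biased low by exactly that amount, and an
  uncorrected trend underestimates $\phi$ and inflates every statistic.
  Non-robust fitting matters here because robustness iterations track
  the median of $\log\chi^2$, which has a different offset than the
  mean;
* geometric shrinkage of the corrected per-gene value toward the trend
  with weight 0.65 on the trend, floored at $10^{-8}$;
* a $t$ reference whose degrees of freedom reflect the shrunk
  estimator's precision, $df = 2/\mathrm{Var}((1-w)\log\hat\phi)$ with
  $\mathrm{Var}(\log(\chi^2_d/d)) = \psi'(d/2)$ — with known dispersion
  the Wald $z$ is very nearly standard normal, and finite df accounts
  for the remaining dispersion noise.

The shrink weight 0.65 was fixed by null-simulation calibration studies
during development (4 vs 4, 2000 genes): it balances the liberal bias
of a pure trend (trend misfit at low counts) against the conservative
averaging of the per-gene component, holding the empirical
$P(p \le 0.05)$ at 0.050 across independent simulation batches. The
fold change reported alongside uses a 0.5 pseudocount on both
normalized means (display robustness); the test statistic does not.
Genes failing the expression/length filters are excluded *before*
testing, so the BH family is the filtered gene set.

## Enrichment, features, motifs

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ via the log-space survival function, with the universe
defined as genes that passed the filters *and* were evaluable for
stability — conditioning on testability rather than the whole
annotation, whose composition would dilute $N$ arbitrarily. BH is
applied across sets within a call.

Motif scanning is a position-by-position IUPAC scan with exact,
documented semantics: overlapping matches all count, T and U are
equivalent, N in a *pattern* matches any concrete base, N in a
*sequence* matches nothing (an unknown base should never create a
hit). This scanner is implemented in the package (vectorized over a
concatenated sequence with non-matching separators) because those
semantics — particularly the N asymmetry — are part of the method's
contract. Enrichment per motif combines a pooled hits-per-kb density
(pooling total hits over total kb avoids the instability of per-gene
densities on very short UTRs) with a presence/absence Fisher exact test
and BH across the panel; a per-gene Mann-Whitney on densities is
emitted as a secondary statistic. Altered transcripts default to
stabilized ∪ destabilized, restrictable to one class; only the
sense-strand 3'UTR is scanned.

## Stability-protein concordance

The regression of protein abundance on stability index is ordinary
least squares on log2-log2 scales (both quantities are ratio-scaled;
the transform is a flag), with the slope tested against the
intercept-only model by the extra-sum-of-squares F test on
$F(1, n-2)$ — identical to the squared slope $t$-test. Note that
regressing on *measured* stability indices attenuates the slope toward
zero relative to the generative coupling (errors-in-variables); slope
recovery is therefore validated against true expected indices, while
pipeline runs on noisy indices report the attenuated estimate.

A gene is concordant when RNA and protein move together past
thresholds: destabilized with protein down, or stabilized with protein
up, where "up/down" requires a relative change of at least 10% vs
control (optionally also a significance flag; the flag is off by
default because the source analyses do not state whether significance
was required on both sides). Pathway-level aggregate comparisons
normalize each protein to its control mean, pool within pathway per
sample, and apply standard one-way ANOVA with BH across pathways;
degenerate inputs (zero within-group variance with unequal means) are
flagged rather than silently producing p-values.

## Numerical and degenerate-input decisions

* `expected_label_mass` evaluates $(1-e^{-x})/x$ by series below
  $10^{-8}$ so $k \to 0$ degrades gracefully to $m_p = \alpha t_p$.
* Zero pulse RPKM (or below the guard) → not-evaluable, never an
  exception; zero control index likewise.
* Condition medians use the standard even-count convention (mean of the
  two central values) and ignore non-evaluable replicates.
* Both-zero genes in the synthesis test are flagged untested with
  $p = 1$; a single zero group mean is floored at half a normalized
  count for the statistic only.
* A zero presence or absence margin in the motif Fisher table reports
  odds ratio 1 (no signal) rather than the degenerate conditional MLE.
* BH inputs are validated to lie in $(0, 1]$; adjusted values are
  order-stable under permutation.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at 2000 genes, 4 vs 4
replicate pairs and 5 million reads per library — the design being
emulated — with 20–60 Monte-Carlo repetitions per property and smaller
populations (100–500 genes) where the property is per-gene rather than
population-level. These sizes were chosen so each property is measured
with enough repetitions for its tolerance while the whole suite stays
interactive.

## Known limitations

* Sensitivity of the 1.5-fold rule is bounded by kinetics, not by the
  estimator: a 2-fold decay increase moves $e^{-6k}$ by less than
  1.5-fold whenever the half-life exceeds ~10 h, which is ~10% of a
  population with median half-life 4 h and log-sd 0.7. On such genes no
  ratio-based classifier at this threshold can call the change; the
  pipeline recovers ~99% of what an oracle classifying on true expected
  indices recovers under identical conditions.
* A single chase time point cannot distinguish deviations from
  first-order decay; the half-life column inherits the model.
* The compositional library correction ($M_{pulse}/M_{chase}$) is
  shared by all genes of a condition and cancels in differential
  ratios, but absolute stability indices are normalization-dependent
  and should not be compared across experiments.
* Motif enrichment is consensus-based (no PWMs, no de-novo discovery)
  and scans only the provided 3'UTR sequences.
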
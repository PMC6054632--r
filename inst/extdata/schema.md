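# On-disk artifact schemas

All tables are plain text; TSV unless noted. Readers reject malformed
files with errors naming the file and offending record; writers
round-trip through the matching reader to identical content. Row order
is preserved.

## counts.tsv
| column | type | notes |
|---|---|---|
| gene_id | string | unique; first column |
| `<library_id>` ... | number >= 0 | one column per library |

Library sizes default to column sums; user-supplied totals may be
larger (reads mapped outside the gene models).

## samples.csv (CSV)
| column | type | notes |
|---|---|---|
| library_id | string | unique |
| subject_id | string | pairs pulse/chase with replicate |
| group | string | condition label |
| assay | enum | `pulse` or `chase` |
| replicate | integer >= 1 | (subject_id, replicate, assay) unique |

Every chase library requires a pulse partner with the same
(subject_id, replicate) unless unpaired mode is requested on the
pairing check.

## gene_models.tsv
| column | type | notes |
|---|---|---|
| gene_id | string | unique |
| length_bp | integer >= 1 | transcript length |
| utr3_len_bp | integer | <= length_bp |
| intron_count | integer >= 0 | |
| strand | `+`/`-`/`.` | optional |
| chrom, start, end | optional | 0-based half-open (BED convention) |

Only lengths are used by computations.

## gene_sets.gmt (GMT)
One set per line: `name<TAB>description<TAB>member1<TAB>member2...`
Members deduplicated within a set; lines with < 3 fields rejected with
their line number.

## utr3.fasta (FASTA)
Record key = header token before the first whitespace. U is read as T;
sequences upper-cased.

## motifs.tsv
| column | type | notes |
|---|---|---|
| motif_name | string | |
| pattern | IUPAC string | RNA or DNA alphabet; validated |
| rbp | string | associated RNA-binding protein |

## protein.tsv
| column | type | notes |
|---|---|---|
| gene_id | string | |
| group | string | |
| abundance | number > 0 | arbitrary MS units |
| replicate | integer | optional |
| significant | logical | optional |
| fold_change | number | optional |

Unknown extra columns are preserved.

## truth.tsv (simulator output)
| column | type | notes |
|---|---|---|
| gene_id, group | string | one row per gene per group |
| alpha | copies/h | effective synthesis rate |
| k | /h | effective decay rate |
| expected_index | number | e^(-k t_chase) x mass correction |

## Pipeline result tables
`stability.tsv` (gene_id, s_case, s_control, ratio, class,
half_life_case, half_life_control), `synthesis.tsv` (gene_id,
base_mean, log2fc, stat, p, q, tested, passes), `ora_*.tsv`
(set_name, k, n, K, N, fold_enrichment, p, q, significant),
`feature_association.tsv`, `motif_enrichment.tsv`,
`concordance.tsv`, `aggregate_pathways.tsv`, `run_summary.json`,
`manifest.tsv` (file, md5).
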
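# Validated readers and writers for every on-disk artifact the pipeline
# touches. Column schemas are documented in inst/extdata/schema.md.
#
# Contracts shared by all readers: a valid file round-trips through its
# writer to identical content; malformed input raises an error naming the
# file and offending record; row order in equals row order out.

#' Read a gene x library count matrix (TSV)
#'
#' First column `gene_id`, remaining columns one per library. Counts must
#' be non-negative; duplicated gene ids are rejected naming the duplicate.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames and library colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "gene_id") {
    stop_brustab("%s: expected a 'gene_id' column followed by library columns",
                 path)
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    stop_brustab("%s: duplicated gene_id '%s'", path, dup[1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_brustab("%s: non-numeric count values", path)
  bad <- which(m < 0 | !is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_brustab("%s: negative or non-finite count for gene '%s', library '%s'",
                 path, df$gene_id[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_counts
#' @param counts matrix as returned by [read_counts()].
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (CSV)
#'
#' Required columns: `library_id`, `subject_id`, `group`, `assay`
#' (`pulse` or `chase`), `replicate` (integer >= 1). The combination
#' (subject_id, replicate, assay) must be unique.
#'
#' @param path CSV file path.
#' @return Data frame with the columns above.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df, source = path)
}

#' @noRd
validate_sample_sheet <- function(df, source = "sample sheet") {
  need <- c("library_id", "subject_id", "group", "assay", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_brustab("%s: missing column(s) %s", source,
                 paste(missing, collapse = ", "))
  }
  if (!all(df$assay %in% c("pulse", "chase"))) {
    stop_brustab("%s: assay must be 'pulse' or 'chase' (got '%s')",
                 source, setdiff(df$assay, c("pulse", "chase"))[1])
  }
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    stop_brustab("%s: replicate must be an integer >= 1", source)
  }
  if (anyDuplicated(df$library_id)) {
    stop_brustab("%s: duplicated library_id '%s'", source,
                 df$library_id[duplicated(df$library_id)][1])
  }
  key <- paste(df$subject_id, df$replicate, df$assay)
  if (anyDuplicated(key)) {
    stop_brustab("%s: duplicated (subject_id, replicate, assay): %s",
                 source, key[duplicated(key)][1])
  }
  df
}

#' Check pulse/chase pairing of a sample sheet
#'
#' In paired mode (the default) every chase library must have a pulse
#' partner with the same (subject_id, replicate); orphans are listed in the
#' error.
#'
#' @param sheet sample sheet data frame.
#' @param paired require pairing (set FALSE for pulse-only designs).
#' @return The sheet, invisibly, if valid.
#' @export
check_pairing <- function(sheet, paired = TRUE) {
  if (paired) {
    key <- function(d) paste(d$subject_id, d$replicate)
    chase <- sheet[sheet$assay == "chase", ]
    pulse <- sheet[sheet$assay == "pulse", ]
    orphan <- chase$library_id[!key(chase) %in% key(pulse)]
    if (length(orphan)) {
      stop_brustab("chase libraries without a pulse partner: %s",
                   paste(orphan, collapse = ", "))
    }
  }
  invisible(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-model table (TSV)
#'
#' Required columns: `gene_id`, `length_bp` (>= 1), `utr3_len_bp`,
#' `intron_count` (>= 0); optional `strand`, `chrom`, `start`, `end`
#' (0-based half-open when present; only lengths are used by any
#' computation).
#'
#' @param path TSV file path.
#' @return Data frame.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_bp", "utr3_len_bp", "intron_count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_brustab("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", "))
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stop_brustab("%s: duplicated gene_id '%s'", path, dup[1])
  if (any(df$length_bp < 1)) {
    stop_brustab("%s: length_bp must be >= 1 (gene '%s')", path,
                 df$gene_id[df$length_bp < 1][1])
  }
  if (any(df$intron_count < 0)) {
    stop_brustab("%s: intron_count must be >= 0 (gene '%s')", path,
                 df$gene_id[df$intron_count < 0][1])
  }
  df
}

#' @rdname read_gene_models
#' @param gene_models data frame.
#' @export
write_gene_models <- function(gene_models, path) {
  utils::write.table(gene_models, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member gene ids, tab
#' separated. Members are deduplicated within a set; lines with fewer than
#' three fields are rejected with their line number.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions kept as the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_brustab("%s: line %d has %d tab-separated field(s); need >= 3",
                   path, i, length(f))
    }
    if (f[1] %in% names(out)) {
      stop_brustab("%s: line %d: duplicated set name '%s'", path, i, f[1])
    }
    out[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  attr(out, "descriptions") <- desc
  out
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, d, unique(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read 3'UTR sequences from FASTA
#'
#' Records are keyed by the header token before the first whitespace. U is
#' converted to T on read (RNA and DNA alphabets are equivalent here);
#' sequences are upper-cased.
#'
#' @param path FASTA file path.
#' @return Named character vector of DNA-alphabet sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    stop_brustab("%s: duplicated sequence id '%s'", path,
                 names(seqs)[duplicated(names(seqs))][1])
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a motif table (TSV)
#'
#' Columns: `motif_name`, `pattern` (IUPAC, RNA or DNA alphabet), `rbp`.
#'
#' @param path TSV file path.
#' @return Data frame.
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("motif_name", "pattern")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_brustab("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", "))
  }
  for (p in df$pattern) iupac_allowed(p)  # validates symbols
  df
}

#' Read a protein-abundance table (TSV)
#'
#' Columns: `gene_id`, `group`, `abundance` (> 0); optional `replicate`,
#' `significant`, `fold_change`. Unknown columns are preserved.
#'
#' @param path TSV file path.
#' @return Data frame.
#' @export
read_protein_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "group", "abundance")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_brustab("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", "))
  }
  bad <- which(!is.na(df$abundance) & df$abundance <= 0)
  if (length(bad)) {
    stop_brustab("%s: abundance must be > 0 (gene '%s', group '%s')",
                 path, df$gene_id[bad[1]], df$group[bad[1]])
  }
  df
}

#' @rdname read_protein_table
#' @param protein data frame.
#' @export
write_protein_table <- function(protein, path) {
  utils::write.table(protein, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a generic TSV result table
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
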
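# RPKM quantification and expression/length gene filters.

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM_ij = count_ij / ((L_i / 1e3) * (N_j / 1e6))` with `L_i` the
#' transcript length and `N_j` the library size (total mapped reads;
#' defaults to the column sum when not supplied — supplied values may
#' exceed the column sum when they count reads mapped outside the gene
#' models).
#'
#' @param counts gene x library count matrix (gene ids as rownames).
#' @param gene_models data frame with `gene_id` and `length_bp`.
#' @param library_size optional named vector of per-library totals.
#' @return Matrix of RPKM values, same dimnames as `counts`.
#' @export
compute_rpkm <- function(counts, gene_models, library_size = NULL) {
  genes <- rownames(counts)
  idx <- match(genes, gene_models$gene_id)
  if (anyNA(idx)) {
    stop_brustab("no gene-model length for gene '%s'", genes[is.na(idx)][1])
  }
  len_kb <- gene_models$length_bp[idx] / 1e3
  if (is.null(library_size)) {
    library_size <- colSums(counts)
  } else {
    library_size <- library_size[colnames(counts)]
    if (anyNA(library_size)) {
      stop_brustab("library_size missing for library '%s'",
                   colnames(counts)[is.na(library_size)][1])
    }
  }
  if (any(library_size <= 0)) {
    stop_brustab("library size must be > 0 (library '%s')",
                 colnames(counts)[library_size <= 0][1])
  }
  sweep(counts / len_kb, 2, library_size / 1e6, "/")
}

#' Expression and length gene filters
#'
#' Retains genes whose mean RPKM over the named libraries is at least
#' `min_mean_rpkm` and whose transcript length is at least
#' `min_length_bp`; both thresholds are inclusive. FDR and fold-change
#' criteria are applied downstream by the synthesis test, not here.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param gene_models data frame with `gene_id` and `length_bp`.
#' @param libraries library ids over which the mean is taken (typically the
#'   pulse libraries of the two groups being compared).
#' @param min_mean_rpkm default 0.5.
#' @param min_length_bp default 300.
#' @return Character vector of retained gene ids (row order preserved).
#' @export
apply_filters <- function(rpkm, gene_models, libraries,
                          min_mean_rpkm = 0.5, min_length_bp = 300) {
  if (!length(libraries)) stop_brustab("'libraries' must be non-empty")
  missing <- setdiff(libraries, colnames(rpkm))
  if (length(missing)) {
    stop_brustab("library '%s' not found in expression matrix", missing[1])
  }
  genes <- rownames(rpkm)
  len <- gene_models$length_bp[match(genes, gene_models$gene_id)]
  if (anyNA(len)) {
    stop_brustab("no gene-model length for gene '%s'", genes[is.na(len)][1])
  }
  mean_rpkm <- rowMeans(rpkm[, libraries, drop = FALSE])
  genes[mean_rpkm >= min_mean_rpkm & len >= min_length_bp]
}
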
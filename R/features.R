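# Transcript-feature association and 3'UTR motif enrichment.

# IUPAC nucleotide codes -> allowed DNA letters. N in a *pattern* matches
# any concrete base; N in a *sequence* is an unknown base and never
# matches any pattern position.
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' @noRd
iupac_allowed <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    stop_brustab("motif pattern must be a non-empty string")
  }
  chars <- strsplit(chartr("U", "T", toupper(pattern)), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_DNA))
  if (length(bad)) {
    stop_brustab("invalid IUPAC symbol '%s' in pattern '%s'", bad[1], pattern)
  }
  IUPAC_DNA[chars]
}

# Map sequence letters to integer codes 1..4 (ACGT); N -> 5 (matches
# nothing); anything else is an error. U is accepted as T.
#' @noRd
encode_seq <- function(sequence) {
  chars <- strsplit(chartr("U", "T", toupper(sequence)), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) {
    stop_brustab("invalid sequence symbol '%s'", chars[is.na(code)][1])
  }
  code
}

#' Count motif occurrences in a nucleotide sequence
#'
#' Counts matching start positions of an IUPAC pattern; overlapping
#' matches are all counted. T and U are equivalent in both sequence and
#' pattern. An N in the sequence never matches any pattern position
#' (unknown base), while an N in the pattern matches any concrete base.
#'
#' @param sequence string over A/C/G/T/U/N.
#' @param iupac_pattern IUPAC motif (RNA or DNA alphabet).
#' @return Integer hit count.
#' @examples
#' scan_motif("UGUGUGU", "UGUG")  # 2: positions 1 and 3 overlap
#' @export
scan_motif <- function(sequence, iupac_pattern) {
  allowed <- iupac_allowed(iupac_pattern)
  code <- encode_seq(sequence)
  scan_codes(code, allowed)
}

# Core scanner on integer codes; `allowed` is iupac_allowed() output.
#' @noRd
scan_codes <- function(code, allowed) {
  m <- length(allowed)
  L <- length(code)
  if (L < m) return(0L)
  # per pattern position, logical over the 5 codes (N never allowed)
  ok <- vapply(allowed, function(a) {
    c("A", "C", "G", "T", "N") %in% a
  }, logical(5))
  hit <- ok[code[seq_len(L - m + 1L)], 1L]
  if (m > 1L) {
    for (j in 2:m) {
      hit <- hit & ok[code[j:(L - m + j)], j]
    }
  }
  sum(hit)
}

#' Motif hit counts across many sequences
#'
#' Same semantics as [scan_motif()], vectorized by scanning the
#' concatenation of all sequences with a non-matching separator.
#'
#' @param seqs named character vector of sequences.
#' @param iupac_pattern IUPAC motif.
#' @return Named integer vector of per-sequence hit counts.
#' @export
scan_motif_set <- function(seqs, iupac_pattern) {
  allowed <- iupac_allowed(iupac_pattern)
  if (!length(seqs)) return(integer())
  m <- length(allowed)
  codes <- lapply(seqs, encode_seq)
  lens <- lengths(codes)
  # separator long enough that no match spans two sequences; code 5 = N
  sep <- rep(5L, m)
  cat_code <- unlist(lapply(codes, function(x) c(x, sep)), use.names = FALSE)
  offsets <- cumsum(c(0, (lens + m)[-length(lens)]))
  L <- length(cat_code)
  ok <- vapply(allowed, function(a) c("A", "C", "G", "T", "N") %in% a,
               logical(5))
  hit <- ok[cat_code[seq_len(L - m + 1L)], 1L]
  if (m > 1L) {
    for (j in 2:m) hit <- hit & ok[cat_code[j:(L - m + j)], j]
  }
  starts <- which(hit)
  # assign each hit start to its source sequence
  idx <- findInterval(starts - 1L, offsets)
  out <- integer(length(seqs))
  tb <- tabulate(idx, nbins = length(seqs))
  out <- tb
  names(out) <- names(seqs)
  out
}

#' Association between stability and a transcript feature
#'
#' Spearman rank correlation (average ranks for ties) between stability
#' indices and a feature (length, 3'UTR length, intron count, ...), with
#' a permutation p-value `(1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_perm)`.
#' When an `altered` flag is supplied, a Wilcoxon rank-sum comparison of
#' the feature between altered and unchanged genes is added.
#'
#' @param stability numeric vector of stability indices.
#' @param feature numeric vector, same length.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @param altered optional logical vector (altered vs background genes).
#' @param feature_name label carried into the output.
#' @return One-row data frame: `feature_name`, `n`, `spearman_rho`,
#'   `p_perm`, `group_stat`, `group_p`.
#' @export
feature_association <- function(stability, feature, n_perm = 1000L,
                                seed = 1L, altered = NULL,
                                feature_name = "feature") {
  if (length(stability) != length(feature)) {
    stop_brustab("'stability' and 'feature' must have equal length")
  }
  keep <- !is.na(stability) & !is.na(feature)
  s <- stability[keep]
  f <- feature[keep]
  if (length(s) < 3L) stop_brustab("need >= 3 complete pairs")
  rho <- NA_real_
  p_perm <- NA_real_
  if (length(unique(s)) > 1L && length(unique(f)) > 1L) {
    rho <- stats::cor(s, f, method = "spearman")
    rf <- rank(f)
    rs <- rank(s)
    p_perm <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        r <- stats::cor(rs, sample(rf))
        if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_perm)
    })
  }
  group_stat <- NA_real_
  group_p <- NA_real_
  if (!is.null(altered)) {
    a <- altered[keep]
    if (sum(a) >= 1L && sum(!a) >= 1L) {
      wt <- suppressWarnings(stats::wilcox.test(f[a], f[!a]))
      group_stat <- unname(wt$statistic)
      group_p <- wt$p.value
    }
  }
  data.frame(feature_name = feature_name, n = length(s),
             spearman_rho = rho, p_perm = p_perm,
             group_stat = group_stat, group_p = group_p,
             stringsAsFactors = FALSE)
}

#' 3'UTR motif enrichment in altered vs background transcripts
#'
#' For each motif: hit densities (total hits per total kb of 3'UTR,
#' pooled across each gene list), a presence/absence 2x2 Fisher exact
#' test (gene has >= 1 hit, altered vs background), and BH adjustment
#' across motifs. A secondary per-gene Mann-Whitney test on hit densities
#' is also reported.
#'
#' @param altered_genes,background_genes gene-id vectors.
#' @param utr3_seqs named character vector of 3'UTR sequences.
#' @param motif_table data frame with `motif_name` and `pattern`.
#' @param min_seq_fraction minimum fraction of each list with an available
#'   sequence (default 0.8); below it the call errors.
#' @return Data frame per motif: densities, `presence_odds_ratio`,
#'   `fisher_p`, `q`, `mw_p`.
#' @export
motif_enrichment <- function(altered_genes, background_genes, utr3_seqs,
                             motif_table, min_seq_fraction = 0.8) {
  if (!length(background_genes)) stop_brustab("background gene list is empty")
  if (!length(altered_genes)) stop_brustab("altered gene list is empty")
  get_seqs <- function(genes, label) {
    found <- intersect(unique(genes), names(utr3_seqs))
    frac <- length(found) / length(unique(genes))
    if (frac < min_seq_fraction) {
      stop_brustab("only %.0f%% of %s genes have a 3'UTR sequence (need >= %.0f%%)",
                   100 * frac, label, 100 * min_seq_fraction)
    }
    utr3_seqs[found]
  }
  alt <- get_seqs(altered_genes, "altered")
  bg <- get_seqs(background_genes, "background")
  kb_alt <- sum(nchar(alt)) / 1000
  kb_bg <- sum(nchar(bg)) / 1000
  res <- lapply(seq_len(nrow(motif_table)), function(i) {
    hits_alt <- scan_motif_set(alt, motif_table$pattern[i])
    hits_bg <- scan_motif_set(bg, motif_table$pattern[i])
    tab <- matrix(c(sum(hits_alt > 0), sum(hits_alt == 0),
                    sum(hits_bg > 0), sum(hits_bg == 0)), nrow = 2)
    ft <- stats::fisher.test(tab)
    # a zero presence or absence margin carries no enrichment signal; the
    # conditional-MLE estimate degenerates there, so report OR = 1
    or <- if (any(rowSums(tab) == 0)) 1 else unname(ft$estimate)
    dens_alt <- hits_alt / (nchar(alt) / 1000)
    dens_bg <- hits_bg / (nchar(bg) / 1000)
    mw <- suppressWarnings(stats::wilcox.test(dens_alt, dens_bg))
    data.frame(motif_name = motif_table$motif_name[i],
               pattern = motif_table$pattern[i],
               density_altered = sum(hits_alt) / kb_alt,
               density_background = sum(hits_bg) / kb_bg,
               presence_altered = sum(hits_alt > 0),
               presence_background = sum(hits_bg > 0),
               presence_odds_ratio = or,
               fisher_p = ft$p.value,
               mw_p = mw$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out$q <- bh_adjust(out$fisher_p)
  out
}
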
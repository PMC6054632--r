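# Shared fixture builders; everything is generated in code at test time.

# tiny paired pulse/chase sample sheet: n replicates per group
tiny_sheet <- function(groups = c("control", "case"), n = 2L) {
  rows <- list()
  for (g in groups) {
    for (r in seq_len(n)) {
      for (a in c("pulse", "chase")) {
        rows[[length(rows) + 1L]] <- data.frame(
          library_id = sprintf("%s_rep%d_%s", g, r, a),
          subject_id = sprintf("%s_line%d", g, r),
          group = g, assay = a, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

tiny_gene_models <- function(gene_ids, length_bp = 1000L) {
  data.frame(gene_id = gene_ids,
             length_bp = rep_len(length_bp, length(gene_ids)),
             utr3_len_bp = pmin(rep_len(length_bp, length(gene_ids)), 300L),
             intron_count = seq_along(gene_ids) %% 5L,
             strand = "+", stringsAsFactors = FALSE)
}

# small configured simulation used by several modules
small_sim <- function(seed = 1L, n_genes = 300L, ...) {
  cfg <- sim_config(n_genes = n_genes, depth_pulse = 1e6, depth_chase = 1e6,
                    n_sets = 4L, set_size = max(5L, min(25L, n_genes %/% 5L)),
                    ...)
  simulate_experiment(cfg, seed)
}

# groups with no planted effects (usable with n_sets = 0)
null_groups <- function(n = 4L) {
  list(sim_group("control", n), sim_group("case", n))
}

# literal step-up BH re-implementation (oracle, kept independent of the
# package's bh_adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force hypergeometric upper tail by enumeration of draw outcomes
hyper_oracle <- function(k, K, n, N) {
  sum(vapply(k:min(n, K), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, 0))
}

# position-by-position motif scan oracle (no shared code with scan_motif)
scan_oracle <- function(sequence, pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  s <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1]]
  p <- strsplit(chartr("U", "T", toupper(pattern)), "")[[1]]
  if (length(s) < length(p)) return(0L)
  hits <- 0L
  for (i in 1:(length(s) - length(p) + 1L)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (s[i + j - 1L] == "N" || !(s[i + j - 1L] %in% iupac[[p[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}
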
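# RNA stability vs protein abundance: regression, concordant sets, and
# pathway-level aggregate protein comparisons.

#' Linear regression of protein abundance on RNA stability
#'
#' Ordinary least squares of transformed protein abundance on transformed
#' stability index (default log2-log2: both quantities are ratio-scaled).
#' The slope is tested against the intercept-only model by the extra
#' sum-of-squares F test, `F = (SS_null - SS_slope) / (SS_slope / (n-2))`
#' with p from the upper tail of F(1, n-2) — identical to the squared-t
#' test of the slope.
#'
#' @param stability numeric vector of stability indices.
#' @param protein numeric vector of protein abundances, same gene order.
#' @param transform "log2" (default) or "identity".
#' @return One-row data frame: `slope`, `intercept`, `r_squared`, `F`,
#'   `p`, `n`.
#' @export
fit_stability_protein_regression <- function(stability, protein,
                                             transform = c("log2",
                                                           "identity")) {
  transform <- match.arg(transform)
  if (length(stability) != length(protein)) {
    stop_brustab("'stability' and 'protein' must have equal length")
  }
  keep <- !is.na(stability) & !is.na(protein)
  if (transform == "log2") keep <- keep & stability > 0 & protein > 0
  x <- stability[keep]
  y <- protein[keep]
  if (transform == "log2") {
    x <- log2(x)
    y <- log2(y)
  }
  n <- length(x)
  if (n < 3L) stop_brustab("need >= 3 complete pairs")
  if (stats::var(x) == 0) stop_brustab("zero variance in the predictor")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_null <- sum((y - mean(y))^2)
  if (ss_res == 0 && ss_null == 0) {
    # constant response: slope 0, no evidence against the null
    return(data.frame(slope = 0, intercept = mean(y), r_squared = 1,
                      F = 0, p = 1, n = n))
  }
  F <- if (ss_res == 0) Inf else (ss_null - ss_res) / (ss_res / (n - 2))
  p <- stats::pf(F, 1, n - 2, lower.tail = FALSE)
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = if (ss_null == 0) 1 else 1 - ss_res / ss_null,
             F = F, p = p, n = n)
}

#' Concordant changes in RNA stability and protein abundance
#'
#' A gene is concordant when its RNA is destabilized and its protein is
#' down, or stabilized and up. Protein direction is `up`/`down` when the
#' relative change vs control meets `protein_min_change` (default 10%),
#' `unchanged` otherwise; optionally a significance flag must also be set.
#'
#' @param stability_records data frame from [differential_stability()]
#'   (`gene_id`, `class`).
#' @param protein_changes data frame `gene_id`, `rel_change` (signed
#'   fractional change vs control, e.g. -0.2 for a 20% reduction),
#'   optional logical `significant`.
#' @param protein_min_change magnitude threshold on `rel_change`.
#' @param require_significant also require `significant == TRUE` for a
#'   protein to count as changed.
#' @return List: `records` (`gene_id`, `stability_class`,
#'   `protein_direction`, `concordant`) and `summary` (set size and its
#'   fractions of all stability changes and of all protein changes).
#' @export
concordant_set <- function(stability_records, protein_changes,
                           protein_min_change = 0.10,
                           require_significant = FALSE) {
  shared <- intersect(stability_records$gene_id, protein_changes$gene_id)
  n_skipped <- length(union(
    setdiff(stability_records$gene_id, shared),
    setdiff(protein_changes$gene_id, shared)))
  sc <- stability_records$class[match(shared, stability_records$gene_id)]
  pc <- protein_changes[match(shared, protein_changes$gene_id), ]
  changed <- abs(pc$rel_change) >= protein_min_change & !is.na(pc$rel_change)
  if (require_significant) {
    if (!"significant" %in% names(pc)) {
      stop_brustab("require_significant = TRUE but no 'significant' column")
    }
    changed <- changed & pc$significant %in% TRUE
  }
  dir <- ifelse(!changed, "unchanged",
                ifelse(pc$rel_change > 0, "up", "down"))
  concordant <- (sc == "destabilized" & dir == "down") |
    (sc == "stabilized" & dir == "up")
  records <- data.frame(gene_id = shared, stability_class = sc,
                        protein_direction = dir, concordant = concordant,
                        stringsAsFactors = FALSE)
  n_stab_changed <- sum(sc %in% c("stabilized", "destabilized"))
  n_prot_changed <- sum(dir != "unchanged")
  list(records = records,
       summary = list(
         n_concordant = sum(concordant),
         n_stability_changes = n_stab_changed,
         n_protein_changes = n_prot_changed,
         fraction_of_stability_changes =
           if (n_stab_changed > 0) sum(concordant) / n_stab_changed else NA_real_,
         fraction_of_protein_changes =
           if (n_prot_changed > 0) sum(concordant) / n_prot_changed else NA_real_,
         n_skipped = n_skipped))
}

#' Pathway-level aggregate protein comparison
#'
#' For each pathway: per-protein abundances are normalized to the control
#' group mean (control = 1), pooled within the pathway per sample
#' (group x replicate mean across member proteins), and compared across
#' groups by standard one-way ANOVA; BH adjustment across the pathways
#' tested in the same call. Degenerate inputs: all values identical gives
#' F = 0, p = 1; zero within-group variance with unequal means gives
#' p = 0 with `degenerate = TRUE`.
#'
#' @param protein_table data frame `gene_id`, `group`, `replicate`,
#'   `abundance`.
#' @param pathways named list of gene-id vectors.
#' @param control control group name (normalization reference).
#' @param groups groups to compare (default: all in the table).
#' @return Data frame per pathway: group means, `F_anova`, `p`, `q`,
#'   `degenerate`.
#' @export
aggregate_pathway_compare <- function(protein_table, pathways, control,
                                      groups = NULL) {
  need <- c("gene_id", "group", "replicate", "abundance")
  missing <- setdiff(need, names(protein_table))
  if (length(missing)) {
    stop_brustab("protein table missing column(s) %s",
                 paste(missing, collapse = ", "))
  }
  if (is.null(groups)) groups <- unique(protein_table$group)
  if (length(groups) < 2L) stop_brustab("need >= 2 groups to compare")
  if (!control %in% groups) stop_brustab("control group '%s' not present",
                                         control)
  pt <- protein_table[protein_table$group %in% groups, ]
  res <- lapply(names(pathways), function(nm) {
    sub <- pt[pt$gene_id %in% pathways[[nm]], ]
    if (!nrow(sub)) {
      return(data.frame(pathway_name = nm, F_anova = NA_real_, p = NA_real_,
                        degenerate = FALSE, stringsAsFactors = FALSE))
    }
    ctrl_mean <- tapply(sub$abundance[sub$group == control],
                        sub$gene_id[sub$group == control], mean)
    sub <- sub[sub$gene_id %in% names(ctrl_mean), ]
    sub$norm <- sub$abundance / ctrl_mean[sub$gene_id]
    # one pooled value per sample (group x replicate)
    samp <- stats::aggregate(norm ~ group + replicate, data = sub, FUN = mean)
    if (any(table(samp$group) < 2L)) {
      stop_brustab("pathway '%s': need >= 2 observations per group", nm)
    }
    gm <- tapply(samp$norm, samp$group, mean)
    within_var <- tapply(samp$norm, samp$group, stats::var)
    row <- as.list(stats::setNames(gm[groups],
                                   paste0("mean_", groups)))
    if (all(within_var == 0)) {
      if (max(gm) - min(gm) == 0) {
        f <- 0; p <- 1; degen <- FALSE
      } else {
        f <- Inf; p <- 0; degen <- TRUE
      }
    } else {
      ow <- stats::oneway.test(norm ~ group, data = samp, var.equal = TRUE)
      f <- unname(ow$statistic)
      p <- ow$p.value
      degen <- FALSE
    }
    cbind(data.frame(pathway_name = nm, stringsAsFactors = FALSE),
          as.data.frame(row),
          data.frame(F_anova = f, p = p, degenerate = degen))
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  tested <- !is.na(out$p)
  out$q <- NA_real_
  out$q[tested] <- bh_adjust(pmax(out$p[tested], .Machine$double.xmin))
  out
}

#' Protein relative changes (case vs control) from a replicate-level table
#'
#' Convenience: mean abundance per gene per group, relative change
#' `(case - control) / control`, and a Welch-t significance flag when both
#' groups have >= 2 replicates.
#'
#' @inheritParams aggregate_pathway_compare
#' @param case case group name.
#' @param alpha significance level for the per-gene flag.
#' @return Data frame `gene_id`, `rel_change`, `p`, `significant`.
#' @export
protein_changes <- function(protein_table, case, control, alpha = 0.05) {
  pt <- protein_table[protein_table$group %in% c(case, control), ]
  genes <- unique(pt$gene_id)
  res <- lapply(genes, function(g) {
    a <- pt$abundance[pt$gene_id == g & pt$group == case]
    b <- pt$abundance[pt$gene_id == g & pt$group == control]
    if (!length(a) || !length(b)) return(NULL)
    rel <- (mean(a) - mean(b)) / mean(b)
    p <- if (length(a) >= 2L && length(b) >= 2L &&
             (stats::var(a) > 0 || stats::var(b) > 0)) {
      stats::t.test(a, b)$p.value
    } else NA_real_
    data.frame(gene_id = g, rel_change = rel, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out$significant <- !is.na(out$p) & out$p <= alpha
  out
}
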
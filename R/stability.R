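# Per-transcript stability indices and differential-stability calls.
#
# The stability index of a transcript is the ratio of its abundance after
# the chase to its abundance after the pulse (RPKM_chase / RPKM_pulse, per
# pulse/chase library pair). Condition-level indices are medians across
# replicate pairs; a case/control ratio of condition indices >= 1.5 (or
# <= 1/1.5) calls a transcript stabilized (destabilized).

#' Per-replicate stability index
#'
#' Computes `S = RPKM_chase / RPKM_pulse` for every (subject, replicate)
#' pulse/chase pair. Pairs whose pulse RPKM falls below `pulse_min_rpkm`
#' yield NA (not evaluable) rather than an unstable ratio; a pulse RPKM of
#' exactly 0 is likewise guarded, never an exception.
#'
#' @param rpkm RPKM matrix (genes x libraries).
#' @param sample_sheet sample sheet covering the libraries.
#' @param pulse_min_rpkm minimum pulse RPKM for a ratio to be evaluable.
#' @return Long data frame: `gene_id`, `subject_id`, `replicate`, `group`,
#'   `s` (NA when not evaluable).
#' @export
replicate_stability_index <- function(rpkm, sample_sheet,
                                      pulse_min_rpkm = 0.5) {
  sheet <- validate_sample_sheet(sample_sheet)
  sheet <- sheet[sheet$library_id %in% colnames(rpkm), ]
  check_pairing(sheet, paired = TRUE)
  pulse <- sheet[sheet$assay == "pulse", ]
  chase <- sheet[sheet$assay == "chase", ]
  key <- function(d) paste(d$subject_id, d$replicate)
  chase <- chase[key(chase) %in% key(pulse), ]
  m <- match(key(chase), key(pulse))
  res <- lapply(seq_len(nrow(chase)), function(i) {
    p <- rpkm[, pulse$library_id[m[i]]]
    cc <- rpkm[, chase$library_id[i]]
    s <- ifelse(p >= pulse_min_rpkm & p > 0, cc / p, NA_real_)
    data.frame(gene_id = rownames(rpkm),
               subject_id = chase$subject_id[i],
               replicate = chase$replicate[i],
               group = chase$group[i],
               s = unname(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Condition-level stability index
#'
#' Median of evaluable per-replicate indices within each (gene, group);
#' for an even number of values, the arithmetic mean of the two central
#' ones (the standard sample median). Zero evaluable replicates yield NA.
#'
#' @param stab long data frame from [replicate_stability_index()].
#' @return Data frame `gene_id`, `group`, `s_cond`, `n_evaluable`.
#' @export
condition_stability <- function(stab) {
  stopifnot(all(c("gene_id", "group", "s") %in% names(stab)))
  agg <- stats::aggregate(stab$s, by = list(gene_id = stab$gene_id,
                                            group = stab$group),
                          FUN = function(v) {
                            c(med = stats::median(v, na.rm = TRUE),
                              n = sum(!is.na(v)))
                          })
  out <- data.frame(gene_id = agg$gene_id, group = agg$group,
                    s_cond = ifelse(agg$x[, "n"] > 0, agg$x[, "med"], NA_real_),
                    n_evaluable = as.integer(agg$x[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(match(out$group, unique(stab$group)),
            match(out$gene_id, unique(stab$gene_id))), , drop = FALSE]
}

#' Differential stability between two conditions
#'
#' `R = S_case / S_control`; transcripts are classified `stabilized` when
#' `R >= fold_change_min`, `destabilized` when `R <= 1/fold_change_min`
#' (both boundaries inclusive, matching the >= 1.5-fold selection rule),
#' `unchanged` otherwise, and `not_evaluable` when either condition index
#' is missing or the control index is 0. A model-derived half-life column
#' (`t1/2 = -t_chase * log(2) / log(S)`, valid only under first-order decay
#' and perfect normalization) is emitted as an auxiliary.
#'
#' @param cond data frame from [condition_stability()].
#' @param case,control group names.
#' @param fold_change_min classification threshold (> 1); default 1.5.
#' @param t_chase chase duration (hours) for the auxiliary half-life.
#' @return Data frame `gene_id`, `s_case`, `s_control`, `ratio`, `class`,
#'   `half_life_case`, `half_life_control` (model-derived).
#' @export
differential_stability <- function(cond, case, control,
                                   fold_change_min = 1.5, t_chase = 6) {
  if (fold_change_min <= 1) stop_brustab("'fold_change_min' must be > 1")
  for (g in c(case, control)) {
    if (!g %in% cond$group) stop_brustab("group '%s' not in condition table", g)
  }
  a <- cond[cond$group == case, ]
  b <- cond[cond$group == control, ]
  genes <- union(a$gene_id, b$gene_id)
  s_case <- a$s_cond[match(genes, a$gene_id)]
  s_control <- b$s_cond[match(genes, b$gene_id)]
  ratio <- ifelse(!is.na(s_case) & !is.na(s_control) & s_control > 0,
                  s_case / s_control, NA_real_)
  cls <- rep("not_evaluable", length(genes))
  ok <- !is.na(ratio)
  cls[ok] <- ifelse(ratio[ok] >= fold_change_min, "stabilized",
                    ifelse(ratio[ok] <= 1 / fold_change_min, "destabilized",
                           "unchanged"))
  data.frame(gene_id = genes, s_case = s_case, s_control = s_control,
             ratio = ratio, class = cls,
             half_life_case = half_life_from_index(s_case, t_chase),
             half_life_control = half_life_from_index(s_control, t_chase),
             stringsAsFactors = FALSE)
}

#' End-to-end stability analysis for one case/control contrast
#'
#' Convenience wrapper: RPKM, per-replicate indices, condition medians,
#' differential classification, and a summary in the style used to report
#' such screens (counts per class, fraction of altered transcripts that
#' are destabilized).
#'
#' @inheritParams compute_rpkm
#' @inheritParams replicate_stability_index
#' @inheritParams differential_stability
#' @param t_chase chase duration in hours (for auxiliary half-life).
#' @return List with `records` (per-gene data frame) and `summary`.
#' @export
stability_analysis <- function(counts, gene_models, sample_sheet,
                               case, control, fold_change_min = 1.5,
                               pulse_min_rpkm = 0.5, library_size = NULL,
                               t_chase = 6) {
  keep <- sample_sheet$group %in% c(case, control)
  sheet <- sample_sheet[keep, , drop = FALSE]
  if (!all(c(case, control) %in% sheet$group)) {
    stop_brustab("case/control group missing from sample sheet")
  }
  rpkm <- compute_rpkm(counts[, sheet$library_id, drop = FALSE], gene_models,
                       library_size)
  stab <- replicate_stability_index(rpkm, sheet, pulse_min_rpkm)
  cond <- condition_stability(stab)
  rec <- differential_stability(cond, case, control, fold_change_min, t_chase)
  list(records = rec, summary = stability_summary(rec))
}

#' Summarize a differential-stability table
#' @param records data frame from [differential_stability()].
#' @return Named list of class counts and the destabilized fraction among
#'   altered transcripts.
#' @export
stability_summary <- function(records) {
  counts <- table(factor(records$class,
                         levels = c("stabilized", "destabilized",
                                    "unchanged", "not_evaluable")))
  altered <- counts[["stabilized"]] + counts[["destabilized"]]
  list(n_genes = nrow(records),
       stabilized = counts[["stabilized"]],
       destabilized = counts[["destabilized"]],
       unchanged = counts[["unchanged"]],
       not_evaluable = counts[["not_evaluable"]],
       n_altered = altered,
       fraction_destabilized = if (altered > 0) {
         counts[["destabilized"]] / altered
       } else NA_real_)
}
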
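# Orchestration: simulate/load -> quantify -> stability + synthesis ->
# enrichment, features/motifs, concordance; writes every stage artifact,
# a manifest with checksums, and a machine-readable run summary.

#' Default demonstration run configuration
#'
#' A complete in-silico experiment: 4 control vs 4 case replicate pairs,
#' 2000 genes, the "ribosome" and "oxphos" sets destabilized in the case
#' group, a planted 3'UTR motif, and a coupled protein table with the
#' ribosome set decoupled.
#'
#' @param seed integer seed driving every random draw.
#' @return Config list for [run_pipeline()].
#' @export
demo_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    case = "case", control = "control",
    fold_change_min = 1.5,
    synthesis_fdr_max = 0.1,
    enrichment_fdr = 0.05,
    protein_min_change = 0.10,
    min_mean_rpkm = 0.5, min_length_bp = 300, pulse_min_rpkm = 0.5,
    simulation = list(
      n_genes = 2000L,
      planted_motif = "UGUGUG",
      protein = list(coupling_slope = 0.8, noise_sd = 0.2,
                     decoupled_sets = "ribosome", n_replicates = 3L)))
}

#' Run the full pulse-chase stability pipeline
#'
#' Stages: (1) simulate a dataset (when `config$simulation` is present)
#' or read the configured input files; (2) RPKM quantification;
#' (3) per-replicate and condition stability indices and differential
#' classification; (4) NB differential synthesis on pulse counts;
#' (5) over-representation analysis of destabilized and stabilized lists
#' against the testable-gene universe; (6) transcript-feature association
#' and 3'UTR motif enrichment; (7) stability-protein regression,
#' concordant set, and pathway-level aggregate protein comparison.
#' Every stage output is written under `out_dir`; a manifest with md5
#' checksums and a JSON run summary make reruns comparable byte-for-byte
#' given identical (config, seed).
#'
#' @param config list as produced by [demo_run_config()], or a path to a
#'   YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return The run summary, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = demo_run_config(), out_dir = "pipeline_out") {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  cat("", file = log_path)  # truncate
  fail <- function(stage, err) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(err)),
               file.path(out_dir, "FAILED"))
    stop_brustab("stage '%s' failed: %s", stage, conditionMessage(err))
  }

  seed <- config$seed %||% 1L
  fc_min <- config$fold_change_min %||% 1.5
  logf("run_pipeline: seed=%d fold_change_min=%g synthesis_fdr_max=%g enrichment_fdr=%g",
       seed, fc_min, config$synthesis_fdr_max %||% 0.1,
       config$enrichment_fdr %||% 0.05)

  # ---- stage: inputs -------------------------------------------------
  ds <- tryCatch({
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      prot_cfg <- sim_args$protein
      sim_args$protein <- NULL
      sc <- do.call(sim_config, sim_args)
      d <- simulate_experiment(sc, seed)
      if (!is.null(prot_cfg)) {
        d$protein <- do.call(simulate_protein_table, c(
          list(truth = d$truth, gene_sets = d$gene_sets,
               seed = seed + 1L), prot_cfg))
      }
      d
    } else {
      inp <- config$inputs
      d <- list(counts = read_counts(inp$counts),
                sample_sheet = read_sample_sheet(inp$sample_sheet),
                gene_models = read_gene_models(inp$gene_models))
      if (!is.null(inp$gmt)) d$gene_sets <- read_gmt(inp$gmt)
      if (!is.null(inp$utr_fasta)) d$utr3 <- read_fasta(inp$utr_fasta)
      if (!is.null(inp$motifs)) d$motif_table <- read_motif_table(inp$motifs)
      if (!is.null(inp$proteins)) d$protein <- read_protein_table(inp$proteins)
      d
    }
  }, error = function(e) fail("inputs", e))
  for (g in c(config$case, config$control)) {
    if (!g %in% ds$sample_sheet$group) {
      stop_brustab("configured group '%s' not present in the sample sheet", g)
    }
  }
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)
  write_counts(ds$counts, file.path(in_dir, "counts.tsv"))
  write_sample_sheet(ds$sample_sheet, file.path(in_dir, "samples.csv"))
  write_gene_models(ds$gene_models, file.path(in_dir, "gene_models.tsv"))
  if (!is.null(ds$gene_sets)) {
    write_gmt(ds$gene_sets, file.path(in_dir, "gene_sets.gmt"))
  }
  if (!is.null(ds$utr3)) write_fasta(ds$utr3, file.path(in_dir, "utr3.fasta"))
  if (!is.null(ds$truth)) write_tsv(ds$truth, file.path(in_dir, "truth.tsv"))
  if (!is.null(ds$protein)) {
    write_protein_table(ds$protein, file.path(in_dir, "protein.tsv"))
  }
  logf("inputs: %d genes, %d libraries", nrow(ds$counts), ncol(ds$counts))

  case <- config$case
  control <- config$control

  # ---- stage: quantify ----------------------------------------------
  rpkm <- tryCatch(compute_rpkm(ds$counts, ds$gene_models),
                   error = function(e) fail("quantify", e))
  write_tsv(data.frame(gene_id = rownames(rpkm), rpkm, check.names = FALSE),
            file.path(out_dir, "rpkm.tsv"))

  # ---- stage: stability ----------------------------------------------
  stab <- tryCatch(
    stability_analysis(ds$counts, ds$gene_models, ds$sample_sheet,
                       case, control, fold_change_min = fc_min,
                       pulse_min_rpkm = config$pulse_min_rpkm %||% 0.5),
    error = function(e) fail("stability", e))
  write_tsv(stab$records, file.path(out_dir, "stability.tsv"))
  logf("stability: %d stabilized, %d destabilized (%.0f%% of altered destabilized)",
       stab$summary$stabilized, stab$summary$destabilized,
       100 * (stab$summary$fraction_destabilized %||% NA))

  # ---- stage: synthesis ----------------------------------------------
  synth <- tryCatch(
    synthesis_analysis(ds$counts, ds$gene_models, ds$sample_sheet,
                       case, control,
                       fdr_max = config$synthesis_fdr_max %||% 0.1,
                       fc_min = fc_min,
                       min_mean_rpkm = config$min_mean_rpkm %||% 0.5,
                       min_length_bp = config$min_length_bp %||% 300),
    error = function(e) fail("synthesis", e))
  write_tsv(synth, file.path(out_dir, "synthesis.tsv"))
  volcano <- data.frame(gene_id = synth$gene_id, log2fc = synth$log2fc,
                        neg_log10_q = -log10(pmax(synth$q, 1e-300)))
  write_tsv(volcano, file.path(out_dir, "synthesis_volcano.tsv"))
  logf("synthesis: %d genes tested, %d pass FDR+FC", sum(synth$tested),
       sum(synth$passes))

  # ---- stage: enrichment ---------------------------------------------
  enr <- NULL
  if (!is.null(ds$gene_sets)) {
    universe <- tryCatch({
      pulse_libs <- ds$sample_sheet$library_id[
        ds$sample_sheet$assay == "pulse" &
          ds$sample_sheet$group %in% c(case, control)]
      filtered <- apply_filters(rpkm, ds$gene_models, pulse_libs,
                                config$min_mean_rpkm %||% 0.5,
                                config$min_length_bp %||% 300)
      evaluable <- stab$records$gene_id[stab$records$class != "not_evaluable"]
      intersect(filtered, evaluable)
    }, error = function(e) fail("enrichment", e))
    enr <- tryCatch({
      lapply(c(destabilized = "destabilized", stabilized = "stabilized"),
             function(cls) {
               q <- intersect(
                 stab$records$gene_id[stab$records$class == cls], universe)
               if (!length(q)) return(NULL)
               ora_analysis(q, ds$gene_sets, universe,
                            config$enrichment_fdr %||% 0.05)
             })
    }, error = function(e) fail("enrichment", e))
    for (nm in names(enr)) {
      if (!is.null(enr[[nm]])) {
        write_tsv(enr[[nm]], file.path(out_dir, sprintf("ora_%s.tsv", nm)))
      }
    }
    logf("enrichment: universe %d genes", length(universe))
  }

  # ---- stage: features / motifs --------------------------------------
  feats <- NULL
  motifs <- NULL
  alt_classes <- c("stabilized", "destabilized")
  altered_ids <- stab$records$gene_id[stab$records$class %in% alt_classes]
  tryCatch({
    gm <- ds$gene_models
    idx <- match(stab$records$gene_id, gm$gene_id)
    s_case <- stab$records$s_case
    feats <- do.call(rbind, list(
      feature_association(s_case, gm$length_bp[idx], seed = seed,
                          altered = stab$records$class %in% alt_classes,
                          feature_name = "length_bp"),
      feature_association(s_case, gm$utr3_len_bp[idx], seed = seed,
                          altered = stab$records$class %in% alt_classes,
                          feature_name = "utr3_len_bp"),
      feature_association(s_case, gm$intron_count[idx], seed = seed,
                          altered = stab$records$class %in% alt_classes,
                          feature_name = "intron_count")))
    write_tsv(feats, file.path(out_dir, "feature_association.tsv"))
    mt <- ds$motif_table
    if (is.null(mt)) mt <- default_motif_table()
    if (!is.null(ds$utr3) && length(altered_ids)) {
      background <- setdiff(
        stab$records$gene_id[stab$records$class == "unchanged"], altered_ids)
      motifs <- motif_enrichment(altered_ids, background, ds$utr3, mt)
      write_tsv(motifs, file.path(out_dir, "motif_enrichment.tsv"))
    }
  }, error = function(e) fail("features", e))

  # ---- stage: concordance --------------------------------------------
  conc <- NULL
  if (!is.null(ds$protein)) {
    conc <- tryCatch({
      prot_case <- ds$protein[ds$protein$group == case, ]
      prot_mean <- tapply(prot_case$abundance, prot_case$gene_id, mean)
      s_case <- stab$records$s_case[match(names(prot_mean),
                                          stab$records$gene_id)]
      reg_all <- fit_stability_protein_regression(s_case, as.numeric(prot_mean))
      reg_sets <- list()
      if (!is.null(ds$gene_sets)) {
        for (nm in names(ds$gene_sets)) {
          in_set <- names(prot_mean) %in% ds$gene_sets[[nm]]
          if (sum(in_set & !is.na(s_case)) >= 3L) {
            reg_sets[[nm]] <- fit_stability_protein_regression(
              s_case[in_set], as.numeric(prot_mean)[in_set])
          }
        }
      }
      pchg <- protein_changes(ds$protein, case, control)
      cs <- concordant_set(stab$records, pchg,
                           config$protein_min_change %||% 0.10)
      agg <- if (!is.null(ds$gene_sets)) {
        aggregate_pathway_compare(ds$protein, ds$gene_sets, control,
                                  groups = c(case, control))
      }
      write_tsv(cs$records, file.path(out_dir, "concordance.tsv"))
      if (!is.null(agg)) {
        write_tsv(agg, file.path(out_dir, "aggregate_pathways.tsv"))
      }
      list(regression_all = reg_all, regression_sets = reg_sets,
           concordant = cs, aggregate = agg)
    }, error = function(e) fail("concordance", e))
    logf("concordance: %d concordant genes",
         conc$concordant$summary$n_concordant)
  }

  # ---- summary + manifest --------------------------------------------
  summary <- list(
    package_version = as.character(utils::packageVersion("brustab")),
    seed = seed, case = case, control = control,
    thresholds = list(fold_change_min = fc_min,
                      synthesis_fdr_max = config$synthesis_fdr_max %||% 0.1,
                      enrichment_fdr = config$enrichment_fdr %||% 0.05,
                      protein_min_change = config$protein_min_change %||% 0.10),
    n_genes = nrow(ds$counts), n_libraries = ncol(ds$counts),
    stability = stab$summary,
    synthesis = list(n_tested = sum(synth$tested),
                     n_passing = sum(synth$passes)),
    top_enriched = if (!is.null(enr$destabilized)) {
      utils::head(enr$destabilized$set_name, 3)
    },
    regression_slope_all = if (!is.null(conc)) conc$regression_all$slope,
    n_concordant = if (!is.null(conc)) conc$concordant$summary$n_concordant)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  logf("done: %d output files", nrow(manifest))
  invisible(summary)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
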
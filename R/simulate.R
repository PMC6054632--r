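# Synthetic pulse-chase dataset generator.
#
# Emulates the statistical structure of a bromouridine pulse-chase
# experiment: per-gene synthesis and first-order decay set the labeled mass
# present at the end of the pulse and of the chase; libraries sample reads
# compositionally in proportion to transcript mass x length (so RPKM
# recovers copy number); replicate counts are negative binomial; condition
# effects act multiplicatively on decay and/or synthesis rates of named
# gene sets ("planted pathways"); protein abundances are coupled linearly
# to log stability with a configurable decoupled set.

#' Group specification for the simulator
#'
#' @param name group label (e.g. "control", "C9ALS").
#' @param n_replicates number of paired pulse/chase library pairs (>= 1).
#' @param k_mult named numeric vector of multipliers applied to the decay
#'   rate of every gene in the named gene sets (values > 1 destabilize).
#' @param alpha_mult named numeric vector of multipliers on synthesis rate.
#' @return A list of class `bru_group`.
#' @export
sim_group <- function(name, n_replicates = 4L, k_mult = numeric(),
                      alpha_mult = numeric()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L) {
    stop_brustab("group '%s': n_replicates must be >= 1", name)
  }
  for (m in list(k_mult, alpha_mult)) {
    if (length(m) && (is.null(names(m)) || any(!is.finite(m)) || any(m <= 0))) {
      stop_brustab("group '%s': effect multipliers must be named and > 0", name)
    }
  }
  structure(list(name = name, n_replicates = n_replicates,
                 k_mult = k_mult, alpha_mult = alpha_mult),
            class = "bru_group")
}

#' Simulation configuration
#'
#' Defaults encode the experimental design being emulated: a 0.5 h
#' bromouridine pulse followed by a 6 h uridine chase, sequenced to ~5
#' million reads per library, with decay rates drawn lognormal around a
#' median half-life of 4 h (log-sd 0.7) and negative-binomial dispersion
#' 0.05. The default group layout is a 4-replicate control against a
#' 4-replicate case in which the "ribosome" and "oxphos" gene sets are
#' destabilized, mirroring the pathway-level destabilization pattern the
#' pipeline is designed to detect.
#'
#' @param n_genes number of genes.
#' @param groups list of [sim_group()] specs; first group is the reference.
#' @param t_pulse,t_chase pulse and chase durations, hours.
#' @param depth_pulse,depth_chase expected reads per pulse / chase library.
#' @param half_life_median median half-life in hours for the lognormal decay
#'   rate draw.
#' @param half_life_log_sd lognormal sd (natural-log scale) of half-life.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); scalar or
#'   per-gene vector. `0` switches to a noiseless diagnostic mode in which
#'   counts equal their (real-valued) expectations exactly.
#' @param n_sets,set_size number and size of disjoint gene sets; the first
#'   two are named "ribosome" and "oxphos" so default group effects and
#'   planted-pathway tests can refer to them.
#' @param length_log_mean,length_log_sd lognormal parameters for transcript
#'   length (bp).
#' @param alpha_log_mean,alpha_log_sd lognormal parameters for synthesis
#'   rate (copies/hour).
#' @param utr_base_density expected motif-independent background density used
#'   when 3'UTR sequences are generated, in planted-motif occurrences per kb.
#' @param planted_motif optional IUPAC motif planted into the 3'UTRs of
#'   genes destabilized in any non-reference group.
#' @param planted_motif_fold density multiplier for planted genes.
#' @param assays which assays to simulate; pulse-only runs are cheaper when
#'   only synthesis is being studied.
#' @param population_seed seed for the gene population (lengths, kinetic
#'   rates, set membership). Held in the config — not the run seed — so the
#'   ground truth is a property of the configured experiment: running
#'   [simulate_experiment()] with different run seeds redraws sequencing
#'   noise over the *same* truth table.
#' @param fixed_kinetics optional data frame `gene` (integer index into the
#'   population), `alpha`, `k`: kinetic parameters pinned to exact values
#'   after the random draw, for experiments that need genes with known
#'   half-lives.
#' @return A list of class `bru_sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       groups = list(
                         sim_group("control"),
                         sim_group("case",
                                   k_mult = c(ribosome = 2, oxphos = 2.5))),
                       t_pulse = 0.5, t_chase = 6,
                       depth_pulse = 5e6, depth_chase = 5e6,
                       half_life_median = 4, half_life_log_sd = 0.7,
                       dispersion = 0.05,
                       n_sets = 20L, set_size = 60L,
                       length_log_mean = log(2000), length_log_sd = 0.6,
                       alpha_log_mean = log(50), alpha_log_sd = 1,
                       utr_base_density = 1, planted_motif = NULL,
                       planted_motif_fold = 3,
                       assays = c("pulse", "chase"),
                       population_seed = 2016L,
                       fixed_kinetics = NULL) {
  assert_scalar_number(t_pulse, "t_pulse", lower = 0, strict_lower = TRUE)
  assert_scalar_number(t_chase, "t_chase", lower = 0, strict_lower = TRUE)
  assert_scalar_number(depth_pulse, "depth_pulse", lower = 0, strict_lower = TRUE)
  assert_scalar_number(depth_chase, "depth_chase", lower = 0, strict_lower = TRUE)
  assert_scalar_number(half_life_median, "half_life_median", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(half_life_log_sd, "half_life_log_sd", lower = 0)
  if (any(!is.finite(dispersion)) || any(dispersion < 0)) {
    stop_brustab("'dispersion' must be >= 0")
  }
  n_genes <- as.integer(n_genes)
  n_sets <- as.integer(n_sets)
  set_size <- as.integer(set_size)
  if (n_genes < 1L) stop_brustab("'n_genes' must be >= 1")
  if (n_sets * set_size > n_genes) {
    stop_brustab("n_sets * set_size (%d) exceeds n_genes (%d)",
                 n_sets * set_size, n_genes)
  }
  if (!length(groups) || !all(vapply(groups, inherits, TRUE, "bru_group"))) {
    stop_brustab("'groups' must be a non-empty list of sim_group() specs")
  }
  nm <- vapply(groups, `[[`, "", "name")
  if (anyDuplicated(nm)) stop_brustab("duplicate group names in 'groups'")
  assays <- match.arg(assays, c("pulse", "chase"), several.ok = TRUE)
  structure(list(
    n_genes = n_genes, groups = groups, t_pulse = t_pulse, t_chase = t_chase,
    depth_pulse = depth_pulse, depth_chase = depth_chase,
    half_life_median = half_life_median, half_life_log_sd = half_life_log_sd,
    dispersion = dispersion, n_sets = n_sets, set_size = set_size,
    length_log_mean = length_log_mean, length_log_sd = length_log_sd,
    alpha_log_mean = alpha_log_mean, alpha_log_sd = alpha_log_sd,
    utr_base_density = utr_base_density, planted_motif = planted_motif,
    planted_motif_fold = planted_motif_fold, assays = assays,
    population_seed = as.integer(population_seed),
    fixed_kinetics = fixed_kinetics),
    class = "bru_sim_config")
}

#' @noRd
sim_gene_population <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  length_bp <- pmax(150L, as.integer(round(
    rlnorm(n, config$length_log_mean, config$length_log_sd))))
  utr3_len_bp <- pmin(length_bp,
                      pmax(30L, as.integer(round(rlnorm(n, log(300), 0.5)))))
  intron_count <- rpois(n, pmax(0.5, length_bp / 1500))
  alpha <- rlnorm(n, config$alpha_log_mean, config$alpha_log_sd)
  half_life <- rlnorm(n, log(config$half_life_median), config$half_life_log_sd)
  k <- log(2) / half_life
  fk <- config$fixed_kinetics
  if (!is.null(fk)) {
    if (any(fk$gene < 1L | fk$gene > n)) {
      stop_brustab("fixed_kinetics gene index out of range")
    }
    alpha[fk$gene] <- fk$alpha
    k[fk$gene] <- fk$k
  }

  sets <- list()
  if (config$n_sets > 0L) {
    set_names <- c("ribosome", "oxphos",
                   sprintf("set%02d", seq_len(max(0L, config$n_sets - 2L)) + 2L))
    set_names <- set_names[seq_len(config$n_sets)]
    member <- sample(gene_id, config$n_sets * config$set_size)
    sets <- split(member, rep(set_names, each = config$set_size))
    sets <- sets[set_names]  # keep declared order
  }
  list(gene_models = data.frame(
         gene_id = gene_id, length_bp = length_bp, utr3_len_bp = utr3_len_bp,
         intron_count = intron_count, strand = "+",
         stringsAsFactors = FALSE),
       alpha = stats::setNames(alpha, gene_id),
       k = stats::setNames(k, gene_id),
       gene_sets = sets)
}

#' @noRd
apply_group_effects <- function(base, gene_sets, mult) {
  out <- base
  for (set in names(mult)) {
    if (!set %in% names(gene_sets)) {
      stop_brustab("effect refers to unknown gene set '%s'", set)
    }
    idx <- gene_sets[[set]]
    out[idx] <- out[idx] * mult[[set]]
  }
  out
}

#' Simulate a full pulse-chase dataset
#'
#' Produces a count matrix over paired pulse/chase libraries, a sample
#' sheet, gene models, gene sets, ground-truth kinetics per group, 3'UTR
#' sequences, and (optionally via [simulate_protein_table()]) coupled
#' protein abundances.
#'
#' For library j with expected depth D and assay-appropriate labeled masses
#' m (group effect multipliers applied), the expected count of gene i is
#' `D * m_i * L_i / sum_g(m_g * L_g)`: read sampling is proportional to
#' transcript mass times length, so RPKM recovers copy number. Realized
#' counts are negative binomial with mean mu and variance mu + phi mu^2;
#' with `dispersion = 0` counts equal mu exactly (noiseless diagnostic
#' mode, the one case where counts are not integers). Identical
#' (config, seed) pairs reproduce the dataset bit-for-bit; the gene
#' population and truth table depend only on the config (via
#' `population_seed`), so two runs with different run seeds draw
#' independent counts over identical ground truth.
#'
#' The truth table records, per gene and group, the effective alpha and k
#' and the expected stability index
#' `exp(-k * t_chase) * M_pulse / M_chase`, where `M` is the total
#' mass-times-length in the corresponding assay — the compositional
#' correction shared by all genes of the group.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; same seed, same dataset.
#' @return A list of class `bru_dataset` with elements `counts`,
#'   `sample_sheet`, `gene_models`, `truth`, `gene_sets`, `utr3`, `config`.
#' @export
simulate_experiment <- function(config, seed) {
  stopifnot(inherits(config, "bru_sim_config"))
  pop <- with_seed(config$population_seed, sim_gene_population(config))
  with_seed(seed, {
    genes <- pop$gene_models$gene_id
    n <- length(genes)
    phi <- rep_len(config$dispersion, n)

    sheet_rows <- list()
    count_cols <- list()
    truth_rows <- list()
    for (grp in config$groups) {
      a_eff <- apply_group_effects(pop$alpha, pop$gene_sets, grp$alpha_mult)
      k_eff <- apply_group_effects(pop$k, pop$gene_sets, grp$k_mult)
      mass <- expected_label_mass(a_eff, k_eff, config$t_pulse, config$t_chase)
      w_pulse <- mass$mass_pulse * pop$gene_models$length_bp
      w_chase <- mass$mass_chase * pop$gene_models$length_bp
      if (sum(w_pulse) <= 0 || sum(w_chase) <= 0) {
        stop_brustab("total labeled mass is zero in group '%s'", grp$name)
      }
      truth_rows[[grp$name]] <- data.frame(
        gene_id = genes, group = grp$name,
        alpha = unname(a_eff), k = unname(k_eff),
        expected_index = unname(exp(-k_eff * config$t_chase) *
                                  sum(w_pulse) / sum(w_chase)),
        stringsAsFactors = FALSE)
      for (r in seq_len(grp$n_replicates)) {
        subject <- sprintf("%s_line%d", grp$name, r)
        for (assay in config$assays) {
          depth <- if (assay == "pulse") config$depth_pulse else config$depth_chase
          w <- if (assay == "pulse") w_pulse else w_chase
          mu <- depth * w / sum(w)
          cnt <- if (all(phi == 0)) mu else {
            ifelse(phi == 0, rpois(n, mu), rnbinom(n, mu = mu, size = 1 / phi))
          }
          lib <- sprintf("%s_rep%d_%s", grp$name, r, assay)
          count_cols[[lib]] <- cnt
          sheet_rows[[lib]] <- data.frame(
            library_id = lib, subject_id = subject, group = grp$name,
            assay = assay, replicate = r, stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(cbind, count_cols)
    rownames(counts) <- genes
    truth <- do.call(rbind, c(truth_rows, make.row.names = FALSE))

    destabilized_sets <- unique(unlist(lapply(config$groups, function(g) {
      names(g$k_mult)[g$k_mult > 1]
    })))
    planted_genes <- unique(unlist(pop$gene_sets[destabilized_sets]))
    utr3 <- simulate_utr_sequences(
      pop$gene_models,
      base_density = config$utr_base_density,
      planted_motif = config$planted_motif,
      planted_genes = planted_genes,
      planted_fold = config$planted_motif_fold,
      seed = sample.int(.Machine$integer.max, 1))

    structure(list(counts = counts,
                   sample_sheet = do.call(rbind, c(unname(sheet_rows),
                                                   make.row.names = FALSE)),
                   gene_models = pop$gene_models,
                   truth = truth,
                   gene_sets = pop$gene_sets,
                   utr3 = utr3,
                   config = config),
              class = "bru_dataset")
  })
}

#' Simulate 3'UTR sequences with optional planted motif
#'
#' Generates uniform-random ACGT sequences of each gene's 3'UTR length,
#' then overwrites non-overlapping positions with instances of
#' `planted_motif` (degenerate IUPAC positions resolved uniformly at
#' random) at a Poisson-distributed count with expectation
#' `base_density * kb` for background genes and `planted_fold` times that
#' for `planted_genes`. With `planted_motif = NULL` every gene gets
#' motif-free random sequence.
#'
#' @param gene_models data frame with `gene_id` and `utr3_len_bp`.
#' @param base_density expected motif occurrences per kb in background genes.
#' @param planted_motif IUPAC string (RNA or DNA alphabet) or NULL.
#' @param planted_genes gene ids receiving the elevated density.
#' @param planted_fold density multiplier for planted genes (> 0).
#' @param seed integer seed.
#' @return Named character vector of DNA-alphabet sequences.
#' @export
simulate_utr_sequences <- function(gene_models, base_density = 1,
                                   planted_motif = NULL,
                                   planted_genes = character(),
                                   planted_fold = 3, seed = 1L) {
  stopifnot(all(c("gene_id", "utr3_len_bp") %in% names(gene_models)))
  assert_scalar_number(base_density, "base_density", lower = 0)
  assert_scalar_number(planted_fold, "planted_fold", lower = 0,
                       strict_lower = TRUE)
  with_seed(seed, {
    lens <- gene_models$utr3_len_bp
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    names(seqs) <- gene_models$gene_id
    if (!is.null(planted_motif)) {
      allowed <- iupac_allowed(planted_motif)  # list of letter sets
      m <- length(allowed)
      rate <- base_density * lens / 1000
      rate[gene_models$gene_id %in% planted_genes] <-
        rate[gene_models$gene_id %in% planted_genes] * planted_fold
      n_ins <- rpois(length(lens), rate)
      for (i in which(n_ins > 0 & lens >= m)) {
        chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
        slots <- max(1L, lens[i] %/% m)
        starts <- (sample(slots, min(n_ins[i], slots)) - 1L) * m + 1L
        for (s in starts) {
          inst <- vapply(allowed, function(a) a[sample.int(length(a), 1L)], "")
          chars[s:(s + m - 1L)] <- inst
        }
        seqs[[i]] <- paste(chars, collapse = "")
      }
    }
    seqs
  })
}

#' Simulate protein abundances coupled to RNA stability
#'
#' Log2 protein abundance is linear in log2 of the ground-truth stability
#' index with slope `coupling_slope`, plus Gaussian noise per measurement,
#' except for genes in `decoupled_sets`, whose slope is 0 — emulating a
#' pathway (e.g. a "ribosome-like" set) buffered by feedback so that
#' protein levels do not track RNA stability.
#'
#' @param truth truth table from [simulate_experiment()] (`gene_id`,
#'   `group`, `expected_index`).
#' @param coupling_slope slope of log2 abundance on log2 stability.
#' @param noise_sd Gaussian sd on log2 abundance per replicate (>= 0).
#' @param decoupled_sets names of gene sets whose slope is forced to 0.
#' @param gene_sets named list of gene-id vectors (needed when
#'   `decoupled_sets` is non-empty).
#' @param n_replicates protein replicates per group.
#' @param intercept log2 abundance at stability index 1.
#' @param seed integer seed.
#' @return Data frame `gene_id`, `group`, `replicate`, `abundance`, with
#'   attributes `coupling_slope` and `decoupled_sets` recording the truth.
#' @export
simulate_protein_table <- function(truth, coupling_slope = 0.8,
                                   noise_sd = 0.2,
                                   decoupled_sets = character(),
                                   gene_sets = list(),
                                   n_replicates = 3L, intercept = 10,
                                   seed = 1L) {
  stopifnot(all(c("gene_id", "group", "expected_index") %in% names(truth)))
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (length(decoupled_sets) && !all(decoupled_sets %in% names(gene_sets))) {
    stop_brustab("decoupled_sets not found in gene_sets")
  }
  decoupled_genes <- unique(unlist(gene_sets[decoupled_sets]))
  with_seed(seed, {
    rows <- truth[rep(seq_len(nrow(truth)), each = n_replicates), ]
    rows$replicate <- rep(seq_len(n_replicates), nrow(truth))
    slope <- ifelse(rows$gene_id %in% decoupled_genes, 0, coupling_slope)
    log2a <- intercept + slope * log2(rows$expected_index) +
      rnorm(nrow(rows), 0, noise_sd)
    out <- data.frame(gene_id = rows$gene_id, group = rows$group,
                      replicate = rows$replicate, abundance = 2^log2a,
                      stringsAsFactors = FALSE)
    attr(out, "coupling_slope") <- coupling_slope
    attr(out, "decoupled_sets") <- decoupled_sets
    out
  })
}

#' A small RNA-binding-protein motif panel
#'
#' Consensus IUPAC motifs for RNA-binding proteins commonly implicated in
#' 3'UTR-mediated stability control, used as the default panel for motif
#' enrichment tests and simulations.
#'
#' @return Data frame with `motif_name`, `pattern` (RNA alphabet), `rbp`.
#' @export
default_motif_table <- function() {
  data.frame(
    motif_name = c("UG_repeat", "ARE_core", "GU_rich", "PUM_like",
                   "CU_rich", "GCAUG", "AU_rich", "CA_repeat",
                   "U_rich", "GAAGAA"),
    pattern = c("UGUGUG", "AUUUA", "GUUUG", "UGUANAUA",
                "CUCUCU", "GCAUG", "AUAUAU", "CACACA",
                "UUUUUU", "GAAGAA"),
    rbp = c("TDP-43", "ELAVL1", "TIA1", "PUM1",
            "PCBP2", "RBFOX1", "HNRNPC-like", "hnRNP-L",
            "HNRNPC", "SRSF1-like"),
    stringsAsFactors = FALSE)
}
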
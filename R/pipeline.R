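#' Build the observed alignments for ABC from a phased study
#'
#' Per locus: computes the diploid consensus, assigns each tetraploid
#' sample's MIN and MAX haplotypes by distance to that consensus (the two
#' intermediate haplotypes are discarded), and takes one random haplotype
#' from each diploid sample. The result is one nucleotide matrix per locus
#' with population labels (`A` = diploid, `B` = pooled tetraploid MIN+MAX),
#' the layout on which the summary statistics for ABC are computed —
#' subgenome assignment is used to pick the haplotypes but the statistics
#' are blind to it.
#'
#' @param loci List of [locus_alignment()] objects (tetraploids phased as
#'   4 haplotypes; see [phase_as_four()] if needed).
#' @param diploids,tetraploids Character vectors of sample ids.
#' @param seed Seed for the random diploid haplotype choice.
#' @return List with one element per locus: `mat` (character matrix), `pop`.
#' @export
build_observed_data <- function(loci, diploids, tetraploids, seed = 1L) {
  set.seed(seed)
  lapply(loci, function(aln) {
    ref <- consensus_sequence(aln, diploids)
    rows <- list(); pops <- character(0)
    for (s in diploids) {
      idx <- which(aln$sample_id == s)
      pick <- if (length(idx) == 1L) idx else sample(idx, 1L)
      rows[[length(rows) + 1L]] <- aln$mat[pick, ]
      pops <- c(pops, "A")
    }
    for (s in tetraploids) {
      asg <- assign_subgenomes(aln, s, ref)
      idx <- which(aln$sample_id == s)
      rows[[length(rows) + 1L]] <-
        aln$mat[idx[aln$hap_index[idx] == asg$min_hap], ]
      rows[[length(rows) + 1L]] <-
        aln$mat[idx[aln$hap_index[idx] == asg$max_hap], ]
      pops <- c(pops, "B", "B")
    }
    list(mat = do.call(rbind, rows), pop = pops)
  })
}

#' Summary-statistic vector of observed alignments
#'
#' @param observed Output of [build_observed_data()].
#' @return A `stat_vector` (see [dataset_stat_vector()]).
#' @export
observed_stat_vector <- function(observed) {
  stats <- t(vapply(observed, function(l) locus_stats(l$mat, l$pop),
                    stats::setNames(numeric(length(LOCUS_STAT_NAMES)),
                                    LOCUS_STAT_NAMES)))
  dataset_stat_vector(stats)
}

#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings with a single master seed from which all
#' stage seeds are derived deterministically. The reference-table size is
#' the main cost knob: the published full-scale setting is 1e6 simulations
#' per model; hundreds to thousands per model is the desk scale.
#'
#' @param study A [study_config()] (the synthetic study stage).
#' @param models Named list of scenarios to compare (default the six-model
#'   set).
#' @param priors A [prior_set()].
#' @param n_sims_per_model Reference-table rows per model.
#' @param n_loci_sim Loci per simulated dataset (the observed data is also
#'   subsampled to this many loci).
#' @param tolerance,n_nets,n_hidden,n_keep ABC settings.
#' @param estimate_posterior Fit the parameter posterior for the top model?
#' @param master_seed Integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(),
                            models = default_model_set(),
                            priors = prior_set(),
                            n_sims_per_model = 500L,
                            n_loci_sim = 50L,
                            tolerance = 0.02, n_nets = 35L, n_hidden = 10L,
                            n_keep = 200L, estimate_posterior = TRUE,
                            master_seed = 1L) {
  structure(list(study = study, models = models, priors = priors,
                 n_sims_per_model = as.integer(n_sims_per_model),
                 n_loci_sim = as.integer(n_loci_sim),
                 tolerance = tolerance, n_nets = as.integer(n_nets),
                 n_hidden = as.integer(n_hidden),
                 n_keep = as.integer(n_keep),
                 estimate_posterior = estimate_posterior,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

derive_seed <- function(master, stage) {
  (master * 48271 + stage * 16807) %% 2147483399 + 1
}

#' Run the whole inference pipeline on a synthetic study
#'
#' Executes every stage: synthetic-study generation, MIN/MAX observed-data
#' construction, observed summary statistics on a random locus subsample,
#' reference-table simulation under the configured model set, ABC model
#' choice, and (optionally) the parameter posterior of the best model.
#' Every stochastic stage receives a seed derived from the master seed, so
#' identical configurations give identical reports.
#'
#' @param config A [pipeline_config()].
#' @param report_path Optional path to write the report as JSON.
#' @return An object of class `pipeline_report`: list with `model_posterior`,
#'   `parameter_posterior` (or NULL), `observed` (`stat_vector`), `study`,
#'   `table`, `seeds`.
#' @export
run_end_to_end <- function(config, report_path = NULL) {
  seeds <- list(study = derive_seed(config$master_seed, 1L),
                observed = derive_seed(config$master_seed, 2L),
                table = derive_seed(config$master_seed, 3L),
                abc = derive_seed(config$master_seed, 4L))
  sc <- config$study
  sc$seed <- seeds$study
  study <- generate_study(sc)
  dip <- study$true_labels$sample_id[study$true_labels$true_ploidy == "diploid"]
  tet <- study$true_labels$sample_id[study$true_labels$true_ploidy == "tetraploid"]
  n_loci_obs <- min(config$n_loci_sim, length(study$loci))
  set.seed(seeds$observed)
  pick <- sort(sample.int(length(study$loci), n_loci_obs))
  obs <- build_observed_data(study$loci[pick], dip, tet,
                             seed = seeds$observed)
  sv <- observed_stat_vector(obs)
  gen_t <- config$study$params$generation_time
  # simulations mirror the observed construction: two lineages per
  # subgenome per tetraploid individual, reduced to the MIN/MAX pair
  table <- build_reference_table(
    config$models, config$priors, n_sims = config$n_sims_per_model,
    n_loci = config$n_loci_sim,
    locus_length = round(config$study$locus_length_mean),
    sample_sizes = list(diploid = length(dip), tetA = length(tet),
                        tetB = length(tet)),
    clock_mean = config$study$clock_mean, clock_sd = config$study$clock_sd,
    generation_time = gen_t, minmax_sampling = TRUE, seed = seeds$table)
  mp <- abc_model_choice(sv$row, table, tolerance = config$tolerance,
                         n_nets = config$n_nets, n_hidden = config$n_hidden,
                         seed = seeds$abc)
  pp <- NULL
  if (config$estimate_posterior) {
    best <- names(which.max(mp$prob))
    sub <- subset_reference_table(table, best)
    bounds <- prior_bounds_for_posterior(config$priors)
    pp <- abc_parameter_posterior(
      sv$row, sub, bounds,
      n_keep = min(config$n_keep, nrow(sub$params)),
      n_nets = config$n_nets, n_hidden = config$n_hidden, seed = seeds$abc)
  }
  report <- structure(
    list(model_posterior = mp, parameter_posterior = pp, observed = sv,
         study = study, table = table, seeds = seeds,
         config = config),
    class = "pipeline_report")
  if (!is.null(report_path)) {
    out <- list(
      model_probabilities = as.list(mp$prob),
      rejection_probabilities = as.list(mp$rejection_prob),
      best_model = names(which.max(mp$prob)),
      parameter_pdv = if (!is.null(pp)) as.list(pp$pdv),
      parameter_ci = if (!is.null(pp)) apply(pp$ci, 2L, as.list),
      seeds = seeds, master_seed = config$master_seed)
    jsonlite::write_json(out, report_path, auto_unbox = TRUE, digits = NA)
  }
  report
}

# logit bounds for the posterior: prior bounds, with migration fractions
# sharing the m bounds and times sharing their own
prior_bounds_for_posterior <- function(priors) {
  list(N_dip = priors$N_dip, N_ext = priors$N_ext, N_tet = priors$N_tet,
       N_anc = priors$N_anc, T_split = priors$T_split,
       T_WGD = c(min(priors$T_WGD[1L], priors$T_split[1L]),
                 max(priors$T_WGD[2L], priors$T_split[2L])),
       m_dip_to_A = priors$m, m_dip_to_B = priors$m,
       m_A_to_dip = priors$m, m_B_to_dip = priors$m)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== polyploid origin inference report ==\n")
  print(x$model_posterior)
  if (!is.null(x$parameter_posterior)) {
    cat("posterior for best model:\n")
    print(x$parameter_posterior)
  }
  invisible(x)
}
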
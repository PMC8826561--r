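#' Specification of the inheritance/formation/migration model grid
#'
#' The full diagnostic grid crosses three inheritance modes (tetrasomic,
#' disomic, heterosomic), three formation modes (autopolyploid from the
#' extinct lineage, autopolyploid from the extant diploid, allopolyploid)
#' and five migration patterns (none, diploid to A, diploid to B, diploid to
#' both, asymmetric bidirectional), giving 45 models. The enumeration is a
#' reconstruction of the published 45-model set, and is fully configurable.
#'
#' @param inheritance,formation,migration Character vectors of levels to
#'   cross.
#' @param n_sims Simulated datasets per model.
#' @param n_loci Loci per simulated dataset (default 50).
#' @param priors A [prior_set()].
#' @param seed Integer seed.
#' @return An object of class `model_grid_spec`.
#' @export
model_grid_spec <- function(inheritance = INHERITANCES,
                            formation = FORMATIONS,
                            migration = MIGRATIONS,
                            n_sims = 100L, n_loci = 50L,
                            priors = prior_set(), seed = 1L) {
  inheritance <- match.arg(inheritance, INHERITANCES, several.ok = TRUE)
  formation <- match.arg(formation, FORMATIONS, several.ok = TRUE)
  migration <- match.arg(migration, MIGRATIONS, several.ok = TRUE)
  if (n_sims < 1L) stop("n_sims must be >= 1")
  structure(list(inheritance = inheritance, formation = formation,
                 migration = migration, n_sims = n_sims, n_loci = n_loci,
                 priors = priors, seed = seed),
            class = "model_grid_spec")
}

#' @export
print.model_grid_spec <- function(x, ...) {
  cat("<model_grid_spec>",
      length(x$formation) * length(x$inheritance) * length(x$migration),
      "models,", x$n_sims, "sims x", x$n_loci, "loci each\n")
  invisible(x)
}

#' Simulate the model grid and pool tetraploid site frequency spectra
#'
#' For every model in the grid, draws parameters from the priors per
#' simulation, simulates a multilocus dataset, and pools the tetraploid
#' folded SFS counts across simulations (pooling SNPs, not averaging
#' histograms, mirrors a density histogram of allele frequencies).
#' Heterosomic models draw their number of disomic loci from a discrete
#' uniform on 0..n_loci per simulation, so a heterosomic pool reflects a
#' genome with about 50% disomic inheritance on average.
#'
#' @param spec A [model_grid_spec()].
#' @param locus_length,sample_sizes,clock_mean,clock_sd,generation_time
#'   Simulation settings (see [simulate_dataset()]).
#' @return An object of class `grid_sfs_result`: list with `spectra` (named
#'   list per model: `counts`, `mass`, `mass_at_half`, `n_snps`, `n`),
#'   `disomic_fraction` (mean drawn fraction, heterosomic models), `spec`.
#' @export
simulate_model_grid <- function(spec, locus_length = 1380L,
                                sample_sizes = list(diploid = 10L,
                                                    tetA = 5L, tetB = 5L),
                                clock_mean = 8.62e-10, clock_sd = 1e-10,
                                generation_time = 2) {
  set.seed(spec$seed)
  n_tet <- sample_sizes$tetA + sample_sizes$tetB
  half <- floor(n_tet / 2)
  spectra <- list()
  disomic_fraction <- list()
  for (f in spec$formation) for (inh in spec$inheritance)
    for (mig in spec$migration) {
      sc <- polyploid_scenario(f, inh, mig)
      key <- scenario_key(sc)
      counts <- numeric(half)
      dis <- numeric(0)
      for (i in seq_len(spec$n_sims)) {
        par <- sample_prior(spec$priors, sc, generation_time, spec$n_loci)
        if (inh == "heterosomic")
          dis <- c(dis, par$n_disomic_loci / spec$n_loci)
        ds <- simulate_dataset(sc, par, n_loci = spec$n_loci,
                               locus_length = locus_length,
                               sample_sizes = sample_sizes,
                               clock_mean = clock_mean, clock_sd = clock_sd,
                               seed = sample.int(.Machine$integer.max, 1L))
        counts <- counts + tetraploid_sfs(ds)$counts
      }
      n_snps <- sum(counts)
      spectra[[key]] <- list(
        counts = counts,
        mass = if (n_snps > 0) counts / n_snps else counts,
        bins = seq_len(half) / n_tet,
        mass_at_half = if (n_tet %% 2L == 0L && n_snps > 0)
          counts[half] / n_snps else 0,
        n_snps = n_snps, n = n_tet)
      if (inh == "heterosomic") disomic_fraction[[key]] <- mean(dis)
    }
  structure(list(spectra = spectra,
                 disomic_fraction = unlist(disomic_fraction),
                 spec = spec),
            class = "grid_sfs_result")
}

#' @export
print.grid_sfs_result <- function(x, ...) {
  cat("<grid_sfs_result>", length(x$spectra), "models,",
      x$spec$n_sims, "sims each\n")
  mh <- vapply(x$spectra, `[[`, 0, "mass_at_half")
  print(round(sort(mh, decreasing = TRUE), 4))
  invisible(x)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

#' Rank grid models by similarity of their SFS to the observed spectrum
#'
#' Distance is the total variation distance between the observed folded
#' spectrum and each model's pooled spectrum (compatible bins required);
#' models are ranked ascending. `excess_at_half` flags an observed
#' 50%-frequency mass exceeding the mean of the tetrasomic models' pooled
#' values by more than three of their SDs — the signature of disomic or
#' heterosomic inheritance.
#'
#' @param observed A [folded_sfs()] result.
#' @param grid A [simulate_model_grid()] result.
#' @return An object of class `sfs_ranking`: data.frame (`model`,
#'   `distance`, `mass_at_half`, `inheritance`) sorted by distance, with
#'   attribute `excess_at_half`.
#' @export
rank_models_by_sfs <- function(observed, grid) {
  if (observed$n_snps == 0L) stop("observed spectrum is empty")
  spectra <- grid$spectra
  n0 <- spectra[[1L]]$n
  if (observed$n != n0)
    stop("observed and simulated spectra have different sample sizes (",
         observed$n, " vs ", n0, ")")
  d <- vapply(spectra, function(s) total_variation(observed$mass, s$mass), 0)
  mh <- vapply(spectra, `[[`, 0, "mass_at_half")
  inh <- vapply(strsplit(names(spectra), ".", fixed = TRUE), `[[`, "", 2L)
  out <- data.frame(model = names(spectra), distance = unname(d),
                    mass_at_half = unname(mh), inheritance = unname(inh),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$distance), ]
  tet <- mh[inh == "tetrasomic"]
  excess <- if (length(tet) >= 2L) {
    observed$mass_at_half > mean(tet) + 3 * stats::sd(tet)
  } else NA
  attr(out, "excess_at_half") <- excess
  class(out) <- c("sfs_ranking", "data.frame")
  out
}
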
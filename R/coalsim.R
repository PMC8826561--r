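#' Simulate one locus under a polyploid speciation scenario
#'
#' Hudson-style structured coalescent with infinite-sites mutation, run
#' backward in time through three epochs. Between the present and the
#' whole-genome duplication (`T_WGD`), tetraploid lineages occupy one
#' panmictic deme of size `N_tet` under tetrasomic inheritance, or two
#' isolated demes of size `N_tet/2` under disomic inheritance, with migration
#' to and from the diploid deme at the configured per-generation fractions.
#' At `T_WGD` the tetraploid lineages re-join their progenitor(s):
#' autopolyploid formation sends them all into the extinct lineage's deme
#' (`N_ext`), formation from the extant diploid sends them into the diploid
#' deme, and allopolyploid formation sends subgenome A into the diploid and
#' subgenome B into the extinct lineage (with tetrasomic inheritance each
#' lineage picks a parent by an independent fair coin, since free segregation
#' erases subgenome identity). At `T_split` the extinct lineage and the
#' diploid merge into the ancestral deme (`N_anc`). Mutations fall on
#' branches as a Poisson process at `clock_rate * length` per year under the
#' infinite-sites model.
#'
#' @param scenario A [polyploid_scenario()] (heterosomic scenarios must pass
#'   an explicit per-locus `inheritance`).
#' @param params A [scenario_parameters()].
#' @param locus_length Locus length in sites.
#' @param clock_rate Substitutions per site per year.
#' @param sample_sizes Named list/vector: `diploid`, `tetA`, `tetB` numbers
#'   of sampled lineages.
#' @param inheritance Per-locus inheritance override (`"tetrasomic"` or
#'   `"disomic"`); defaults to the scenario's mode.
#' @param inter_subgenome_m Backward exchange rate between the two disomic
#'   subgenome demes; a consistency knob (at a very large value disomic
#'   demes behave as one panmictic deme), zero in all real scenarios.
#' @return A list with `mat` (0/1 haplotype matrix, rows = sampled lineages),
#'   `pop` (deme label per row: `"diploid"`, `"tetA"`, `"tetB"`),
#'   `positions` (relative positions in (0,1) of segregating sites),
#'   `length`, `clock_rate`, `inheritance`.
#' @export
simulate_locus <- function(scenario, params, locus_length, clock_rate,
                           sample_sizes = list(diploid = 10L, tetA = 5L,
                                               tetB = 5L),
                           inheritance = NULL,
                           inter_subgenome_m = 0) {
  check_scenario_params(scenario, params)
  if (is.null(inheritance)) inheritance <- scenario$inheritance
  if (inheritance == "heterosomic")
    stop("heterosomic is a dataset-level mode; pass per-locus inheritance")
  if (locus_length < 1L) stop("locus_length must be >= 1")
  if (clock_rate <= 0) stop("clock_rate must be positive")

  gen <- params$generation_time
  G_wgd <- params$T_WGD / gen
  G_split <- params$T_split / gen
  mu <- clock_rate * locus_length * gen   # per lineage per generation

  n_d <- sample_sizes$diploid; n_a <- sample_sizes$tetA; n_b <- sample_sizes$tetB
  n <- n_d + n_a + n_b
  if (n < 2L) stop("need at least two sampled lineages")
  pop <- c(rep("diploid", n_d), rep("tetA", n_a), rep("tetB", n_b))

  # global deme indices: 0 dip, 1 tet/tetA, 2 tetB, 3 ext, 4 anc
  tetrasomic <- inheritance == "tetrasomic"
  deme0 <- c(rep(0L, n_d), rep(1L, n_a), rep(if (tetrasomic) 1L else 2L, n_b))
  sizes <- matrix(NA_real_, 3L, 5L)
  sizes[1L, 1L] <- params$N_dip
  if (tetrasomic) sizes[1L, 2L] <- params$N_tet
  else sizes[1L, 2:3] <- params$N_tet / 2
  sizes[2L, 1L] <- params$N_dip
  sizes[2L, 4L] <- params$N_ext
  sizes[3L, 5L] <- params$N_anc
  if (tetrasomic) {
    flows <- rbind(c(1L, 0L), c(0L, 1L))
    rates <- c((params$m_dip_to_A + params$m_dip_to_B) / 2,
               params$m_A_to_dip + params$m_B_to_dip)
  } else {
    flows <- rbind(c(1L, 0L), c(2L, 0L), c(0L, 1L), c(0L, 2L),
                   c(1L, 2L), c(2L, 1L))
    rates <- c(params$m_dip_to_A, params$m_dip_to_B,
               params$m_A_to_dip, params$m_B_to_dip,
               inter_subgenome_m, inter_subgenome_m)
  }
  keep <- rates > 0
  flows <- flows[keep, , drop = FALSE]; rates <- rates[keep]
  formation_code <- match(scenario$formation, FORMATIONS) - 1L
  # FORMATIONS order: autopolyploid, allopolyploid, autopolyploid_extant
  formation_code <- c(0L, 2L, 1L)[formation_code + 1L]
  res <- .cpp_simulate_locus(deme0, sizes, flows[, 1L], flows[, 2L], rates,
                             G_wgd, G_split, mu, formation_code, tetrasomic)
  mat <- res$mat
  S <- ncol(mat)
  if (S > 0L) {
    pos <- stats::runif(S)
    ord <- order(pos)
    mat <- mat[, ord, drop = FALSE]
    pos <- pos[ord]
  } else pos <- numeric()
  list(mat = mat, pop = pop, positions = pos, length = locus_length,
       clock_rate = clock_rate, inheritance = inheritance)
}

#' Simulate a multilocus dataset
#'
#' Simulates `n_loci` independent loci under one scenario/parameter set.
#' Per-locus clock rates are drawn from a normal distribution truncated at
#' zero (defaults: mean 8.62e-10, SD 1e-10 substitutions/site/year, the
#' anchored-enrichment nuclear rate used throughout the package), unless
#' explicit `clock_rates` are supplied. Under heterosomic inheritance,
#' exactly `params$n_disomic_loci` randomly chosen loci are simulated
#' disomically and the rest tetrasomically; the assignment is recorded.
#'
#' @param scenario A [polyploid_scenario()].
#' @param params A [scenario_parameters()].
#' @param n_loci Number of loci (default 50, the subsampled locus count used
#'   for observed data).
#' @param locus_length Locus length in sites (single value or per-locus
#'   vector).
#' @param sample_sizes As in [simulate_locus()].
#' @param clock_mean,clock_sd Normal clock-rate distribution
#'   (substitutions/site/year).
#' @param clock_rates Optional explicit per-locus rates (overrides the draw).
#' @param seed Optional integer seed; per-locus seeds are derived from it.
#' @param inter_subgenome_m See [simulate_locus()].
#' @return An object of class `simulated_dataset`: list with `loci` (each as
#'   returned by [simulate_locus()]), `scenario`, `params`, `clock_rates`,
#'   `disomic_loci` (integer indices), `seed`.
#' @export
simulate_dataset <- function(scenario, params, n_loci = 50L,
                             locus_length = 1380L,
                             sample_sizes = list(diploid = 10L, tetA = 5L,
                                                 tetB = 5L),
                             clock_mean = 8.62e-10, clock_sd = 1e-10,
                             clock_rates = NULL, seed = NULL,
                             inter_subgenome_m = 0) {
  if (n_loci < 1L) stop("n_loci must be >= 1")
  check_scenario_params(scenario, params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(clock_rates)) {
    clock_rates <- stats::rnorm(n_loci, clock_mean, clock_sd)
    while (any(clock_rates <= 0)) {
      bad <- clock_rates <= 0
      clock_rates[bad] <- stats::rnorm(sum(bad), clock_mean, clock_sd)
    }
  } else clock_rates <- rep_len(clock_rates, n_loci)
  lens <- rep_len(locus_length, n_loci)
  inh <- rep(if (scenario$inheritance == "heterosomic") "tetrasomic"
             else scenario$inheritance, n_loci)
  disomic_loci <- integer()
  if (scenario$inheritance == "heterosomic" && params$n_disomic_loci > 0L) {
    if (params$n_disomic_loci > n_loci)
      stop("n_disomic_loci exceeds n_loci")
    disomic_loci <- sort(sample.int(n_loci, params$n_disomic_loci))
    inh[disomic_loci] <- "disomic"
  }
  loc_seeds <- sample.int(.Machine$integer.max, n_loci)
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    set.seed(loc_seeds[i])
    loci[[i]] <- simulate_locus(scenario, params, lens[i], clock_rates[i],
                                sample_sizes, inheritance = inh[i],
                                inter_subgenome_m = inter_subgenome_m)
  }
  structure(list(loci = loci, scenario = scenario, params = params,
                 clock_rates = clock_rates, disomic_loci = disomic_loci,
                 seed = seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  S <- vapply(x$loci, function(l) ncol(l$mat), 0L)
  cat("<simulated_dataset>", scenario_key(x$scenario), "-",
      length(x$loci), "loci,", nrow(x$loci[[1L]]$mat), "haplotypes,",
      "mean segregating sites", round(mean(S), 2), "\n")
  invisible(x)
}

#' Write a dataset as ms-style segregating-sites blocks
#'
#' One block per locus: `//`, `segsites:`, `positions:` and 0/1 haplotype
#' rows, for interoperability with ms-format consumers.
#'
#' @param dataset A `simulated_dataset`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_ms <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (l in dataset$loci) {
    writeLines("//", con)
    writeLines(paste("segsites:", ncol(l$mat)), con)
    if (ncol(l$mat) > 0L) {
      writeLines(paste("positions:",
                       paste(formatC(l$positions, format = "f", digits = 5),
                             collapse = " ")), con)
      writeLines(apply(l$mat, 1L, paste, collapse = ""), con)
    }
  }
  invisible(path)
}
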
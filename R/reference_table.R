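REFTABLE_PARAM_COLS <- c("N_dip", "N_ext", "N_tet", "N_anc", "T_split",
                         "T_WGD", "m_dip_to_A", "m_dip_to_B",
                         "m_A_to_dip", "m_B_to_dip")

#' Apply MIN/MAX haplotype selection to a simulated dataset
#'
#' Observed tetraploids contribute their MIN and MAX haplotypes — the
#' closest and farthest of their four phased alleles from the diploid
#' consensus — not a random allele per subgenome. Selecting extremes
#' inflates apparent tetraploid diversity, so reference-table simulations
#' must mirror the construction: this function takes a dataset simulated
#' with two lineages per subgenome per tetraploid individual, computes the
#' per-locus diploid majority consensus (binary; ties to the ancestral
#' allele), and keeps for each individual only its nearest (MIN) and
#' farthest (MAX) haplotype among the four, with the same tie rules as
#' [assign_subgenomes()].
#'
#' @param dataset A `simulated_dataset` whose `tetA` and `tetB` sample
#'   sizes are twice the number of tetraploid individuals.
#' @return The dataset with each locus reduced to diploid rows plus two
#'   rows per tetraploid individual (`pop` relabelled `tetA` for MIN,
#'   `tetB` for MAX).
#' @export
minmax_reduce_dataset <- function(dataset) {
  dataset$loci <- lapply(dataset$loci, function(l) {
    dip <- which(l$pop == "diploid")
    A <- which(l$pop == "tetA"); B <- which(l$pop == "tetB")
    if (length(A) %% 2L || length(A) != length(B))
      stop("min/max reduction needs two lineages per subgenome per individual")
    n_ind <- length(A) / 2L
    cons <- if (ncol(l$mat)) {
      as.integer(colMeans(l$mat[dip, , drop = FALSE]) > 0.5)
    } else integer()
    keep <- integer(0)
    for (k in seq_len(n_ind)) {
      rows <- c(A[2L * k - 1L], A[2L * k], B[2L * k - 1L], B[2L * k])
      d <- if (ncol(l$mat)) {
        rowSums(l$mat[rows, , drop = FALSE] !=
                  matrix(cons, 4L, ncol(l$mat), byrow = TRUE))
      } else rep(0, 4L)
      i_min <- which.min(d)
      i_max <- 5L - which.max(rev(d))
      if (i_min == i_max) { i_min <- 1L; i_max <- 4L }
      keep <- c(keep, rows[i_min], rows[i_max])
    }
    sel <- c(dip, keep)
    list(mat = l$mat[sel, , drop = FALSE],
         pop = c(rep("diploid", length(dip)),
                 rep(c("tetA", "tetB"), n_ind)),
         positions = l$positions, length = l$length,
         clock_rate = l$clock_rate, inheritance = l$inheritance)
  })
  dataset
}

#' Build an ABC reference table by simulation
#'
#' Draws parameters from the priors and simulates a multilocus dataset for
#' each row of each model, storing the model label, the parameter draw, and
#' the multilocus summary-statistic vector. The published analysis ran 1e6
#' simulations per model; the table size here is a knob, with 1e3-1e4 the
#' desk-scale setting.
#'
#' @param models Named list of [polyploid_scenario()] objects (e.g.
#'   [default_model_set()]).
#' @param priors A [prior_set()].
#' @param n_sims Simulations per model.
#' @param n_loci,locus_length,sample_sizes,clock_mean,clock_sd Simulation
#'   settings (see [simulate_dataset()]).
#' @param generation_time Years per generation for the prior draws.
#' @param minmax_sampling If `TRUE`, simulate two lineages per subgenome
#'   per tetraploid individual and reduce each to its MIN/MAX pair
#'   ([minmax_reduce_dataset()]), mirroring the observed-data construction;
#'   `sample_sizes$tetA`/`tetB` then count tetraploid individuals. The
#'   default `FALSE` keeps the one-lineage-per-subgenome layout.
#' @param seed Integer seed.
#' @return An object of class `reference_table`: list with `model`
#'   (character vector), `params` (matrix), `stats` (matrix), `manifest`
#'   (statistic column names), `seed`.
#' @export
build_reference_table <- function(models, priors, n_sims = 1000L,
                                  n_loci = 50L, locus_length = 1380L,
                                  sample_sizes = list(diploid = 10L,
                                                      tetA = 5L, tetB = 5L),
                                  clock_mean = 8.62e-10, clock_sd = 1e-10,
                                  generation_time = 2,
                                  minmax_sampling = FALSE, seed = 1L) {
  if (is.null(names(models))) stop("models must be a named list")
  sim_sizes <- if (minmax_sampling) {
    list(diploid = sample_sizes$diploid, tetA = 2L * sample_sizes$tetA,
         tetB = 2L * sample_sizes$tetB)
  } else sample_sizes
  set.seed(seed)
  total <- n_sims * length(models)
  model_lab <- character(total)
  params <- matrix(NA_real_, total, length(REFTABLE_PARAM_COLS),
                   dimnames = list(NULL, REFTABLE_PARAM_COLS))
  stats_rows <- vector("list", total)
  r <- 0L
  for (m in names(models)) {
    for (i in seq_len(n_sims)) {
      r <- r + 1L
      par <- sample_prior(priors, models[[m]], generation_time, n_loci)
      ds <- simulate_dataset(models[[m]], par, n_loci = n_loci,
                             locus_length = locus_length,
                             sample_sizes = sim_sizes,
                             clock_mean = clock_mean, clock_sd = clock_sd,
                             seed = sample.int(.Machine$integer.max, 1L))
      if (minmax_sampling) ds <- minmax_reduce_dataset(ds)
      model_lab[r] <- m
      params[r, ] <- unlist(par[REFTABLE_PARAM_COLS])
      stats_rows[[r]] <- dataset_stat_vector(dataset_locus_stats(ds))$row
    }
  }
  stats <- do.call(rbind, stats_rows)
  structure(list(model = model_lab, params = params, stats = stats,
                 manifest = colnames(stats), seed = seed),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("<reference_table>", nrow(x$stats), "rows,",
      length(unique(x$model)), "models,",
      ncol(x$stats), "statistics\n")
  print(table(x$model))
  invisible(x)
}

#' Restrict a reference table to one model
#' @param table A `reference_table`.
#' @param model Model label.
#' @return A `reference_table` with only that model's rows.
#' @export
subset_reference_table <- function(table, model) {
  keep <- table$model == model
  if (!any(keep)) stop("model not present in table: ", model)
  structure(list(model = table$model[keep],
                 params = table$params[keep, , drop = FALSE],
                 stats = table$stats[keep, , drop = FALSE],
                 manifest = table$manifest, seed = table$seed),
            class = "reference_table")
}

#' Write / read a reference table as TSV with a sidecar manifest
#'
#' @param table A `reference_table`.
#' @param path Base path; writes `<path>.tsv` and `<path>.manifest.json`.
#' @return The TSV path, invisibly.
#' @export
write_reference_table <- function(table, path) {
  df <- data.frame(model = table$model, table$params, table$stats,
                   check.names = FALSE)
  tsv <- paste0(path, ".tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(manifest = table$manifest, params = colnames(table$params),
         seed = table$seed),
    paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(tsv)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  df <- utils::read.delim(paste0(path, ".tsv"), check.names = FALSE)
  man <- jsonlite::read_json(paste0(path, ".manifest.json"),
                             simplifyVector = TRUE)
  structure(list(model = as.character(df$model),
                 params = as.matrix(df[, man$params, drop = FALSE]),
                 stats = as.matrix(df[, man$manifest, drop = FALSE]),
                 manifest = man$manifest, seed = man$seed),
            class = "reference_table")
}
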
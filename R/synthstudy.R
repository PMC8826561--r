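#' Configuration of a synthetic study
#'
#' Defaults emulate the anchored-enrichment study the package targets: 244
#' loci of mean length 1,380 bp, 71 diploid and 35 tetraploid samples, 2.7%
#' missing data. Locus lengths are drawn Normal(mean, sd) truncated at
#' `locus_length_min` and rounded. Phasing error is not quantified for real
#' data; the default rate is a fixture parameter, not an estimate.
#'
#' @param n_loci Number of loci (>= 1).
#' @param locus_length_mean,locus_length_sd,locus_length_min Locus length
#'   distribution in sites (`locus_length_min >= 12`, room for a SNP with
#'   5-site flanks).
#' @param n_diploid,n_tetraploid Sample counts.
#' @param scenario A [polyploid_scenario()].
#' @param params A [scenario_parameters()] (the true generating history).
#' @param missing_rate Fraction of (sample x site) cells masked, in \[0, 1).
#' @param phase_error_rate Per polymorphic site per sample probability that
#'   two haplotypes swap their base, in \[0, 0.5).
#' @param clock_mean,clock_sd Per-locus clock-rate distribution.
#' @param seed Integer seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_loci = 244L, locus_length_mean = 1380,
                         locus_length_sd = 150, locus_length_min = 300L,
                         n_diploid = 71L, n_tetraploid = 35L,
                         scenario = polyploid_scenario("autopolyploid",
                                                       "tetrasomic",
                                                       "unidirectional_dip_to_AB"),
                         params = scenario_parameters(m_dip_to_A = 1e-5,
                                                      m_dip_to_B = 1e-5),
                         missing_rate = 0.027, phase_error_rate = 0.02,
                         clock_mean = 8.62e-10, clock_sd = 1e-10,
                         seed = 1L) {
  if (n_loci < 1L) stop("n_loci must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (phase_error_rate < 0 || phase_error_rate >= 0.5)
    stop("phase_error_rate must be in [0, 0.5)")
  if (locus_length_min < 12L)
    stop("locus_length_min must be >= 12")
  check_scenario_params(scenario, params)
  structure(list(n_loci = as.integer(n_loci),
                 locus_length_mean = locus_length_mean,
                 locus_length_sd = locus_length_sd,
                 locus_length_min = as.integer(locus_length_min),
                 n_diploid = as.integer(n_diploid),
                 n_tetraploid = as.integer(n_tetraploid),
                 scenario = scenario, params = params,
                 missing_rate = missing_rate,
                 phase_error_rate = phase_error_rate,
                 clock_mean = clock_mean, clock_sd = clock_sd,
                 seed = as.integer(seed)),
            class = "study_config")
}

# map one simulated binary locus onto nucleotide sequences: monomorphic
# background, ancestral base uniform on ACGT per site, derived base uniform
# on the remaining three at each segregating position
binary_to_nucleotide <- function(mat, locus_length) {
  bases <- c("A", "C", "G", "T")
  S <- ncol(mat)
  if (S > locus_length)
    stop("more segregating sites than locus length; locus too short")
  anc <- sample(bases, locus_length, replace = TRUE)
  out <- matrix(rep(anc, each = nrow(mat)), nrow = nrow(mat))
  if (S > 0L) {
    sites <- sort(sample.int(locus_length, S))
    for (j in seq_len(S)) {
      der <- sample(setdiff(bases, anc[sites[j]]), 1L)
      out[mat[, j] == 1L, sites[j]] <- der
    }
  }
  out
}

#' Inject missing data and phasing errors into an alignment
#'
#' Masks (sample x site) cells independently at `missing_rate` (a masked
#' cell becomes `N` in all of that sample's haplotypes at that site,
#' emulating sample-level coverage gaps), and, for each polymorphic column
#' and each sample, with probability `phase_error_rate` exchanges the bases
#' of two randomly chosen haplotypes of that sample — what an imperfect
#' four-allele phaser does. Labels are untouched and rates (0, 0) return
#' the input unchanged.
#'
#' @param aln A [locus_alignment()].
#' @param missing_rate,phase_error_rate Rates in \[0, 1) and \[0, 0.5).
#' @param seed Optional seed.
#' @return A degraded `locus_alignment`.
#' @export
degrade_alignment <- function(aln, missing_rate, phase_error_rate,
                              seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (phase_error_rate < 0 || phase_error_rate >= 0.5)
    stop("phase_error_rate must be in [0, 0.5)")
  if (missing_rate == 0 && phase_error_rate == 0) return(aln)
  if (!is.null(seed)) set.seed(seed)
  m <- aln$mat
  L <- ncol(m)
  samples <- unique(aln$sample_id)
  if (phase_error_rate > 0) {
    poly <- which(apply(m, 2L, function(col) {
      col <- col[!is_missing_base(col)]
      length(unique(col)) > 1L
    }))
    for (j in poly) for (s in samples) {
      if (stats::runif(1L) < phase_error_rate) {
        rows <- which(aln$sample_id == s)
        if (length(rows) >= 2L) {
          ij <- sample(rows, 2L)
          tmp <- m[ij[1L], j]
          m[ij[1L], j] <- m[ij[2L], j]
          m[ij[2L], j] <- tmp
        }
      }
    }
  }
  if (missing_rate > 0) {
    for (s in samples) {
      rows <- which(aln$sample_id == s)
      mask <- stats::runif(L) < missing_rate
      if (any(mask)) m[rows, mask] <- "N"
    }
  }
  locus_alignment(aln$locus_id, m, aln$sample_id, aln$hap_index)
}

#' Generate a complete synthetic study
#'
#' Simulates a truth-labelled multilocus study under the configured
#' polyploid speciation history: haplotypes come from the structured
#' coalescent (two lineages per diploid sample; two per subgenome per
#' tetraploid sample), are mapped from binary infinite-sites output onto
#' nucleotide sequences, and are then degraded with missing data and
#' phasing errors. Tetraploid haplotype order is shuffled within each
#' sample so subgenome identity is hidden, as in real phased data. With a
#' directory, writes one FASTA per locus (`locus_0001.fasta`, headers
#' `sampleID|hap0..hap3`), `samples.tsv` and `truth.json`; output is
#' byte-identical for identical config.
#'
#' @param config A [study_config()].
#' @param dir Optional output directory (created if needed).
#' @return An object of class `synthetic_study`: list with `config`, `loci`
#'   (list of [locus_alignment()]), `true_labels` (data.frame), `dataset`
#'   (the underlying `simulated_dataset`), `manifest`.
#' @export
generate_study <- function(config, dir = NULL) {
  set.seed(config$seed)
  n_dip <- config$n_diploid; n_tet <- config$n_tetraploid
  dip_ids <- sprintf("D%03d", seq_len(n_dip))
  tet_ids <- sprintf("T%03d", seq_len(n_tet))
  lens <- pmax(config$locus_length_min,
               round(stats::rnorm(config$n_loci, config$locus_length_mean,
                                  config$locus_length_sd)))
  ds <- simulate_dataset(
    config$scenario, config$params, n_loci = config$n_loci,
    locus_length = lens,
    sample_sizes = list(diploid = 2L * n_dip, tetA = 2L * n_tet,
                        tetB = 2L * n_tet),
    clock_mean = config$clock_mean, clock_sd = config$clock_sd,
    seed = sample.int(.Machine$integer.max, 1L))
  loci <- vector("list", config$n_loci)
  for (k in seq_len(config$n_loci)) {
    l <- ds$loci[[k]]
    nuc <- binary_to_nucleotide(l$mat, l$length)
    # rows: diploids (2 each), then tetA (2 each), then tetB (2 each)
    sid <- character(0); hap <- integer(0); ord <- integer(0)
    for (i in seq_len(n_dip)) {
      rows <- c(2L * i - 1L, 2L * i)
      ord <- c(ord, rows); sid <- c(sid, rep(dip_ids[i], 2L))
      hap <- c(hap, 0:1)
    }
    offA <- 2L * n_dip; offB <- offA + 2L * n_tet
    for (i in seq_len(n_tet)) {
      rows <- c(offA + 2L * i - 1L, offA + 2L * i,
                offB + 2L * i - 1L, offB + 2L * i)
      rows <- sample(rows)   # hide subgenome identity in haplotype order
      ord <- c(ord, rows); sid <- c(sid, rep(tet_ids[i], 4L))
      hap <- c(hap, 0:3)
    }
    aln <- locus_alignment(sprintf("locus_%04d", k),
                           nuc[ord, , drop = FALSE], sid, hap)
    loci[[k]] <- degrade_alignment(aln, config$missing_rate,
                                   config$phase_error_rate)
  }
  true_labels <- data.frame(
    sample_id = c(dip_ids, tet_ids),
    species_label = c(rep("diploid_sp", n_dip), rep("tetraploid_sp", n_tet)),
    true_ploidy = c(rep("diploid", n_dip), rep("tetraploid", n_tet)),
    population = c(rep("dip", n_dip), rep("tet", n_tet)),
    stringsAsFactors = FALSE)
  manifest <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fasta_paths <- file.path(dir, sprintf("locus_%04d.fasta",
                                          seq_len(config$n_loci)))
    for (k in seq_len(config$n_loci))
      write_locus_fasta(loci[[k]], fasta_paths[k])
    utils::write.table(true_labels, file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- list(scenario = unclass(config$scenario),
                  params = unclass(config$params),
                  seed = config$seed, n_loci = config$n_loci)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(dir = dir, fasta = fasta_paths,
                     samples = file.path(dir, "samples.tsv"),
                     truth = file.path(dir, "truth.json"))
  }
  structure(list(config = config, loci = loci, true_labels = true_labels,
                 dataset = ds, manifest = manifest),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", x$config$n_loci, "loci;",
      x$config$n_diploid, "diploid +", x$config$n_tetraploid,
      "tetraploid samples; scenario", scenario_key(x$config$scenario), "\n")
  invisible(x)
}

#' Read a written synthetic study back from disk
#'
#' @param dir Directory written by [generate_study()].
#' @return List with `loci` (list of [locus_alignment()]), `samples`
#'   (data.frame), `truth` (list).
#' @export
read_study <- function(dir) {
  fa <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  loci <- lapply(fa, read_locus_fasta)
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(loci = loci, samples = samples, truth = truth)
}
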
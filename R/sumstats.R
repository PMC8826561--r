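LOCUS_STAT_NAMES <- c("S_A", "S_B", "pi_A", "pi_B", "thetaW_A", "thetaW_B",
                      "TajD_A", "TajD_B", "Dxy", "Da", "FST",
                      "sf", "ss", "sxA", "sxB", "bialsites")

# Tajima's D from segregating sites S, total (per-locus) pi, sample size n
tajimas_d <- function(S, pi_tot, n) {
  if (S == 0L || n < 4L) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# per-column mean pairwise difference from derived-allele counts
col_pi <- function(cnt, n) cnt * (n - cnt) / choose(n, 2)

#' Per-locus summary statistics for a two-population sample
#'
#' Computes the mscalc-style per-locus statistics for a diploid population A
#' against a (pooled-subgenome) tetraploid population B: segregating sites,
#' per-site nucleotide diversity, Watterson's theta, Tajima's D per
#' population; raw (`Dxy`) and net (`Da`) between-population divergence per
#' site; Hudson-style `FST = 1 - mean within-population pi / total pi`; and
#' the biallelic-site classification into fixed differences (`sf`), shared
#' polymorphisms (`ss`), and exclusive polymorphisms (`sxA`, `sxB`), which
#' always sum to `bialsites`.
#'
#' Input is either a 0/1 infinite-sites haplotype matrix (with `length` the
#' locus length in sites, for per-site scaling) or a nucleotide character
#' matrix; nucleotide columns containing any missing base (`N`/`-`) are
#' removed before calculation, matching how observed alignments are filtered
#' to parity with simulated data, and per-site statistics are scaled by the
#' retained length.
#'
#' @param mat Haplotype matrix, rows = haplotypes.
#' @param pop Vector assigning each row to `"A"` or `"B"`.
#' @param length Locus length in sites (required for binary input; ignored
#'   for nucleotide input).
#' @return Named numeric vector of the statistics listed above (undefined
#'   entries are `NA`).
#' @export
locus_stats <- function(mat, pop, length = NULL) {
  pop <- as.character(pop)
  if (!all(pop %in% c("A", "B"))) stop("pop labels must be 'A' or 'B'")
  nA <- sum(pop == "A"); nB <- sum(pop == "B")
  if (nA < 2L || nB < 2L) stop("each population needs at least 2 haplotypes")

  if (is.character(mat)) {
    keep <- !apply(mat, 2L, function(col) any(is_missing_base(col)))
    mat <- mat[, keep, drop = FALSE]
    L <- ncol(mat)
    if (L == 0L) stop("no complete columns in nucleotide alignment")
    return(locus_stats_nuc(mat, pop, nA, nB, L))
  }
  if (is.null(length)) stop("binary input requires the locus length")
  L <- length
  A <- mat[pop == "A", , drop = FALSE]
  B <- mat[pop == "B", , drop = FALSE]
  cA <- colSums(A); cB <- colSums(B); cT <- cA + cB
  n <- nA + nB

  segA <- cA > 0L & cA < nA
  segB <- cB > 0L & cB < nB
  segT <- cT > 0L & cT < n
  S_A <- sum(segA); S_B <- sum(segB)
  piA_tot <- sum(col_pi(cA, nA)); piB_tot <- sum(col_pi(cB, nB))
  piT_tot <- sum(col_pi(cT, n))
  a1 <- function(k) sum(1 / seq_len(k - 1L))
  dxy_tot <- sum(cA / nA * (1 - cB / nB) + cB / nB * (1 - cA / nA))

  fixed <- sum((cA == 0L | cA == nA) & (cB == 0L | cB == nB) &
                 (cA / nA != cB / nB))
  shared <- sum(segA & segB)
  sxA <- sum(segA & !segB)
  sxB <- sum(segB & !segA)
  bial <- sum(segT)

  pi_A <- piA_tot / L; pi_B <- piB_tot / L
  Dxy <- dxy_tot / L
  pi_within <- (pi_A + pi_B) / 2
  pi_total <- piT_tot / L
  FST <- if (pi_total > 0) 1 - pi_within / pi_total else NA_real_
  c(S_A = S_A, S_B = S_B, pi_A = pi_A, pi_B = pi_B,
    thetaW_A = S_A / a1(nA) / L, thetaW_B = S_B / a1(nB) / L,
    TajD_A = tajimas_d(S_A, piA_tot, nA),
    TajD_B = tajimas_d(S_B, piB_tot, nB),
    Dxy = Dxy, Da = Dxy - pi_within, FST = FST,
    sf = fixed, ss = shared, sxA = sxA, sxB = sxB, bialsites = bial)
}

# nucleotide path on complete columns; handles multiallelic columns for
# diversity, restricts sf/ss/sx/bialsites to biallelic columns
locus_stats_nuc <- function(mat, pop, nA, nB, L) {
  A <- mat[pop == "A", , drop = FALSE]
  B <- mat[pop == "B", , drop = FALSE]
  n <- nA + nB
  pi_col <- function(m) {
    k <- nrow(m)
    apply(m, 2L, function(col) {
      tab <- table(col)
      (choose(k, 2) - sum(choose(tab, 2))) / choose(k, 2)
    })
  }
  nal <- function(m) apply(m, 2L, function(col) length(unique(col)))
  piA_cols <- pi_col(A); piB_cols <- pi_col(B); piT_cols <- pi_col(mat)
  dxy_cols <- vapply(seq_len(L), function(j) {
    mean(outer(A[, j], B[, j], "!="))
  }, 0)
  segA <- nal(A) > 1L; segB <- nal(B) > 1L
  S_A <- sum(segA); S_B <- sum(segB)
  a1 <- function(k) sum(1 / seq_len(k - 1L))
  nal_T <- nal(mat)
  bial_cols <- nal_T == 2L
  fixed <- sum(bial_cols & !segA & !segB &
                 vapply(seq_len(L), function(j) A[1L, j] != B[1L, j], NA))
  shared <- sum(bial_cols & segA & segB)
  sxA <- sum(bial_cols & segA & !segB)
  sxB <- sum(bial_cols & segB & !segA)
  pi_A <- sum(piA_cols) / L; pi_B <- sum(piB_cols) / L
  Dxy <- sum(dxy_cols) / L
  pi_within <- (pi_A + pi_B) / 2
  pi_total <- sum(piT_cols) / L
  FST <- if (pi_total > 0) 1 - pi_within / pi_total else NA_real_
  c(S_A = S_A, S_B = S_B, pi_A = pi_A, pi_B = pi_B,
    thetaW_A = S_A / a1(nA) / L, thetaW_B = S_B / a1(nB) / L,
    TajD_A = tajimas_d(S_A, sum(piA_cols), nA),
    TajD_B = tajimas_d(S_B, sum(piB_cols), nB),
    Dxy = Dxy, Da = Dxy - pi_within, FST = FST,
    sf = fixed, ss = shared, sxA = sxA, sxB = sxB,
    bialsites = sum(bial_cols))
}

#' Per-locus statistics for a simulated dataset
#'
#' Applies [locus_stats()] to every locus of a [simulate_dataset()] result,
#' with the diploid deme as population A and the pooled tetraploid subgenomes
#' as population B (summary statistics are blind to subgenome assignment).
#'
#' @param dataset A `simulated_dataset`.
#' @return Matrix with one row per locus and the [locus_stats()] columns.
#' @export
dataset_locus_stats <- function(dataset) {
  t(vapply(dataset$loci, function(l) {
    locus_stats(l$mat, ifelse(l$pop == "diploid", "A", "B"),
                length = l$length)
  }, stats::setNames(numeric(length(LOCUS_STAT_NAMES)), LOCUS_STAT_NAMES)))
}

#' Multilocus summary-statistic vector
#'
#' Mean and (population) SD across loci of every per-locus statistic,
#' skipping undefined entries and recording how many were skipped. The flat
#' concatenation `mean_*`, `sd_*` is the row format of the ABC reference
#' table.
#'
#' @param stats_matrix Matrix of per-locus statistics (rows = loci), e.g.
#'   from [dataset_locus_stats()].
#' @return An object of class `stat_vector`: list with `mean`, `sd`,
#'   `n_loci`, `n_undefined`, and `row` (the flat named vector).
#' @export
dataset_stat_vector <- function(stats_matrix) {
  if (is.null(dim(stats_matrix))) stats_matrix <- t(as.matrix(stats_matrix))
  if (nrow(stats_matrix) < 1L) stop("need at least one locus")
  mu <- apply(stats_matrix, 2L, function(x) mean(x[!is.na(x)]))
  sdv <- apply(stats_matrix, 2L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    sqrt(mean((x - mean(x))^2))   # population SD
  })
  nun <- colSums(is.na(stats_matrix))
  row <- c(stats::setNames(mu, paste0("mean_", colnames(stats_matrix))),
           stats::setNames(sdv, paste0("sd_", colnames(stats_matrix))))
  structure(list(mean = mu, sd = sdv, n_loci = nrow(stats_matrix),
                 n_undefined = nun, row = row),
            class = "stat_vector")
}

#' @export
print.stat_vector <- function(x, ...) {
  cat("<stat_vector> over", x$n_loci, "loci\n")
  print(round(rbind(mean = x$mean, sd = x$sd), 5))
  invisible(x)
}

#' Folded site frequency spectrum
#'
#' Minor-allele-frequency histogram of the segregating columns of a
#' haplotype matrix, with the proportion of SNPs at exactly 50% frequency
#' (`mass_at_half`, defined for even sample sizes) — the diagnostic that is
#' elevated under disomic relative to tetrasomic inheritance once the
#' subgenomes have differentiated.
#'
#' @param mat 0/1 haplotype matrix (rows = haplotypes), or a nucleotide
#'   character matrix whose biallelic complete columns are used.
#' @return An object of class `frequency_spectrum`: list with `counts` (per
#'   minor-allele count 1..n/2), `mass` (normalized), `bins` (i/n),
#'   `mass_at_half`, `n_snps`, `n`.
#' @export
folded_sfs <- function(mat) {
  if (is.character(mat)) {
    keep <- !apply(mat, 2L, function(col) any(is_missing_base(col)))
    mat <- mat[, keep, drop = FALSE]
    cntlist <- apply(mat, 2L, function(col) {
      tab <- table(col)
      if (length(tab) == 2L) min(tab) else NA_integer_
    })
    minor <- cntlist[!is.na(cntlist)]
    n <- nrow(mat)
  } else {
    n <- nrow(mat)
    cnt <- colSums(mat)
    seg <- cnt > 0L & cnt < n
    minor <- pmin(cnt[seg], n - cnt[seg])
  }
  if (n < 1L) stop("no haplotypes")
  half <- floor(n / 2)
  counts <- tabulate(minor, nbins = half)
  n_snps <- length(minor)
  mass <- if (n_snps > 0L) counts / n_snps else rep(0, half)
  mass_at_half <- if (n %% 2L == 0L) {
    if (n_snps > 0L) mass[half] else 0
  } else NA_real_
  structure(list(counts = counts, mass = mass,
                 bins = seq_len(half) / n,
                 mass_at_half = mass_at_half, n_snps = n_snps, n = n),
            class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat("<frequency_spectrum> n =", x$n, "haplotypes,", x$n_snps, "SNPs;",
      "mass at 50% =", format(x$mass_at_half), "\n")
  invisible(x)
}

#' Folded SFS of the tetraploid population of a dataset
#'
#' Pools the segregating-column minor-allele counts of the tetraploid rows
#' (both subgenomes) across all loci of a dataset.
#'
#' @param dataset A `simulated_dataset`.
#' @return A `frequency_spectrum`.
#' @export
tetraploid_sfs <- function(dataset) {
  tet <- dataset$loci[[1L]]$pop != "diploid"
  mats <- lapply(dataset$loci, function(l) l$mat[tet, , drop = FALSE])
  folded_sfs(do.call(cbind, mats))
}

#' Randomization test of a k-locus subsample against its null
#'
#' Tests whether the summary-statistic vector of a designated `k`-locus
#' subset is typical of the full study, by building a null from `n_reps`
#' random `k`-subsets (drawn without replacement within a subset) and
#' flagging every statistic of the observed subset outside the 2.5%-97.5%
#' percentile envelope.
#'
#' @param stats_matrix Per-locus statistics for the full study.
#' @param observed_loci Integer indices of the designated subset (length k).
#' @param n_reps Number of null subsets (default 1000).
#' @param seed Optional seed.
#' @return An object of class `randomization_report`: data.frame with
#'   `statistic`, `observed`, `q025`, `q975`, `outside`, plus attributes
#'   `n_reps` and `seed`.
#' @export
randomization_test_loci <- function(stats_matrix, observed_loci,
                                    n_reps = 1000L, seed = NULL) {
  k <- length(observed_loci)
  if (k > nrow(stats_matrix)) stop("k exceeds the number of loci")
  if (!is.null(seed)) set.seed(seed)
  obs <- dataset_stat_vector(stats_matrix[observed_loci, , drop = FALSE])$row
  null <- t(vapply(seq_len(n_reps), function(i) {
    idx <- sample.int(nrow(stats_matrix), k)
    dataset_stat_vector(stats_matrix[idx, , drop = FALSE])$row
  }, obs))
  q <- apply(null, 2L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(statistic = names(obs), observed = unname(obs),
                    q025 = q[1L, ], q975 = q[2L, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$outside <- !is.na(out$observed) &
    (out$observed < out$q025 | out$observed > out$q975)
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("randomization_report", "data.frame")
  out
}
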
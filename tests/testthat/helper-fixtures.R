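# Fixture builders and independent brute-force oracles used across tests.

# alignment from plain strings; samples get 2 or 4 haplotypes by grouping
make_aln <- function(seqs, sample_id, hap_index = NULL, locus_id = "L1") {
  if (is.null(hap_index)) {
    hap_index <- unlist(lapply(table(factor(sample_id, levels = unique(sample_id))),
                               function(k) seq_len(k) - 1L))
  }
  locus_alignment(locus_id, seqs, sample_id, hap_index)
}

# random nucleotide toy alignment (no missing unless asked)
random_aln <- function(n_hap, len, n_samples = n_hap / 2, missing_p = 0,
                       locus_id = "L1") {
  stopifnot(n_hap %% n_samples == 0)
  per <- n_hap / n_samples
  m <- matrix(sample(c("A", "C", "G", "T"), n_hap * len, replace = TRUE),
              nrow = n_hap)
  if (missing_p > 0)
    m[matrix(runif(n_hap * len) < missing_p, nrow = n_hap)] <- "N"
  sid <- rep(sprintf("s%02d", seq_len(n_samples)), each = per)
  hap <- rep(seq_len(per) - 1L, n_samples)
  locus_alignment(locus_id, m, sid, hap)
}

# brute-force SNP scanner: per-column re-derivation of the flank filter
oracle_snps <- function(aln, flank) {
  m <- aln$mat
  miss <- function(col) any(col %in% c("N", "-"))
  alleles <- function(col) unique(col[!col %in% c("N", "-")])
  hits <- integer()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (miss(col) || length(alleles(col)) != 2L) next
    lo <- j - flank; hi <- j + flank
    if (lo < 1L || hi > ncol(m)) next
    ok <- TRUE
    for (w in setdiff(lo:hi, j)) {
      cw <- m[, w]
      if (miss(cw) || length(alleles(cw)) > 1L) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, j)
  }
  hits
}

# brute-force mean pairwise difference per site (binary matrix)
oracle_pi <- function(mat, L) {
  n <- nrow(mat)
  if (n < 2L) return(0)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + sum(mat[i, ] != mat[j, ]); np <- np + 1
  }
  tot / np / L
}

# brute-force weighted quantile by cumulative-weight interpolation is the
# package's own; use direct discrete check instead: smallest x with
# cumweight >= p (step-function quantile, tolerance-compared in tests)
oracle_wq_step <- function(x, w, p) {
  ord <- order(x)
  x <- x[ord]; cw <- cumsum(w[ord]) / sum(w)
  x[which(cw >= p)[1L]]
}

tiny_priors <- function() {
  prior_set(N_bounds = c(1e3, 1e5), T_split_bounds = c(1e3, 1e6),
            T_WGD_bounds = c(1e2, 1e6), m_bounds = c(0, 1e-4))
}

total_variation_test_helper <- function(p, q) 0.5 * sum(abs(p - q))
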
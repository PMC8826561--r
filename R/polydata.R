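#' Majority-rule consensus sequence of a sample group
#'
#' Per column, the most frequent non-missing base across the haplotypes of the
#' requested samples; ties are broken alphabetically so the consensus stays in
#' the A/C/G/T alphabet, and an all-missing column yields `N`.
#'
#' @param aln A [locus_alignment()].
#' @param group Character vector of sample ids to build the consensus from.
#' @return A character vector of single bases (one per alignment column).
#' @export
consensus_sequence <- function(aln, group) {
  if (length(group) == 0L) stop("consensus group is empty")
  sub <- subset_samples(aln, group)
  apply(sub$mat, 2L, function(col) {
    col <- col[!is_missing_base(col)]
    if (!length(col)) return("N")
    tab <- table(col)
    names(tab)[which.max(tab)]  # table() is alphabetical; which.max takes first
  })
}

#' Pairwise p-distance with pairwise deletion
#'
#' Proportion of differing columns among columns where both sequences carry a
#' non-missing base. Returns `NA` when no column is comparable.
#'
#' @param a,b Character vectors of bases of equal length (or strings).
#' @return Numeric p-distance in \[0, 1\], or `NA` if undefined.
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a[1L]) > 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (length(b) == 1L && nchar(b[1L]) > 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- !is_missing_base(a) & !is_missing_base(b)
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' MIN/MAX subgenome assignment for one tetraploid sample
#'
#' Assigns the haplotype with the smallest p-distance to the diploid reference
#' consensus to the MIN subgenome and the one with the greatest distance to
#' the MAX subgenome; the two intermediate haplotypes are reported as
#' discarded. Ties are broken toward the lowest haplotype index for MIN and
#' the highest for MAX, so a sample with four identical haplotypes yields
#' MIN = hap0 and MAX = hap3.
#'
#' @param aln A [locus_alignment()].
#' @param sample A tetraploid sample id present with four haplotypes.
#' @param reference Reference consensus (character vector of bases), usually
#'   from [consensus_sequence()] over the diploid samples.
#' @return A list with `min_hap`, `max_hap`, `d_min`, `d_max`, `discarded`.
#' @export
assign_subgenomes <- function(aln, sample, reference) {
  sub <- subset_samples(aln, sample)
  if (nrow(sub$mat) != 4L)
    stop("sample ", sample, " does not have 4 haplotypes at locus ",
         aln$locus_id)
  ord <- order(sub$hap_index)
  d <- vapply(ord, function(i) p_distance(sub$mat[i, ], reference), 0)
  hap <- sub$hap_index[ord]
  if (anyNA(d)) stop("undefined distance for sample ", sample,
                     " at locus ", aln$locus_id)
  i_min <- which.min(d)                      # first min -> lowest hap index
  i_max <- length(d) + 1L - which.max(rev(d))  # last max -> highest hap index
  if (i_min == i_max) { i_min <- 1L; i_max <- 4L }
  list(min_hap = hap[i_min], max_hap = hap[i_max],
       d_min = d[i_min], d_max = d[i_max],
       discarded = hap[-c(i_min, i_max)])
}

#' Extract flank-filtered biallelic SNPs
#'
#' Scans every locus for columns where exactly two bases segregate among the
#' included haplotypes, requiring no missing data at the column itself or at
#' the `flank` columns on either side, and requiring those flanking columns to
#' be monomorphic. This is the "flanked by five monomorphic sites with no
#' missing data" filter used to build clean SNP sets from enrichment loci.
#'
#' @param loci List of [locus_alignment()] objects.
#' @param samples Character vector of sample ids to include (default: all).
#' @param flank Number of clean monomorphic columns required on each side
#'   (default 5).
#' @return A data.frame with columns `locus_id`, `column` (1-based),
#'   `allele1`, `allele2` (alphabetical), `count1`, `count2`.
#' @export
extract_snps <- function(loci, samples = NULL, flank = 5L) {
  if (inherits(loci, "locus_alignment")) loci <- list(loci)
  flank <- as.integer(flank)
  if (flank < 0L) stop("flank must be >= 0")
  out <- list()
  for (aln in loci) {
    sub <- if (is.null(samples)) aln else subset_samples(aln, samples)
    m <- sub$mat
    L <- ncol(m)
    miss <- apply(m, 2L, function(col) any(is_missing_base(col)))
    nallele <- apply(m, 2L, function(col) {
      length(unique(col[!is_missing_base(col)]))
    })
    clean_mono <- !miss & nallele <= 1L
    for (j in seq_len(L)) {
      if (miss[j] || nallele[j] != 2L) next
      if (j - flank < 1L || j + flank > L) next
      win <- setdiff((j - flank):(j + flank), j)
      if (!all(clean_mono[win])) next
      tab <- sort(table(m[, j]))  # names alphabetical within table
      al <- sort(names(tab))
      out[[length(out) + 1L]] <- data.frame(
        locus_id = aln$locus_id, column = j,
        allele1 = al[1L], allele2 = al[2L],
        count1 = as.integer(sum(m[, j] == al[1L])),
        count2 = as.integer(sum(m[, j] == al[2L])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(locus_id = character(), column = integer(),
                      allele1 = character(), allele2 = character(),
                      count1 = integer(), count2 = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify SNPs as fixed, shared, or private polymorphisms
#'
#' For each SNP column, compares the allele sets of two disjoint sample
#' groups: a site is a fixed difference when each group is monomorphic for a
#' different base, shared when both groups are polymorphic, and private to a
#' group when only that group is polymorphic.
#'
#' @param loci List of [locus_alignment()] objects.
#' @param snps SNP table from [extract_snps()] (run on the union of both
#'   groups).
#' @param group_A,group_B Disjoint, non-empty character vectors of sample ids.
#' @return A list with counts `fixed`, `shared`, `private_A`, `private_B` and
#'   `n_snps`.
#' @export
classify_polymorphisms <- function(loci, snps, group_A, group_B) {
  if (!length(group_A) || !length(group_B)) stop("groups must be non-empty")
  if (length(intersect(group_A, group_B))) stop("groups must be disjoint")
  if (inherits(loci, "locus_alignment")) loci <- list(loci)
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  res <- c(fixed = 0L, shared = 0L, private_A = 0L, private_B = 0L)
  for (i in seq_len(nrow(snps))) {
    aln <- loci[[snps$locus_id[i]]]
    j <- snps$column[i]
    col_A <- aln$mat[aln$sample_id %in% group_A, j]
    col_B <- aln$mat[aln$sample_id %in% group_B, j]
    al_A <- unique(col_A[!is_missing_base(col_A)])
    al_B <- unique(col_B[!is_missing_base(col_B)])
    poly_A <- length(al_A) > 1L
    poly_B <- length(al_B) > 1L
    if (poly_A && poly_B) res["shared"] <- res["shared"] + 1L
    else if (poly_A) res["private_A"] <- res["private_A"] + 1L
    else if (poly_B) res["private_B"] <- res["private_B"] + 1L
    else if (length(al_A) == 1L && length(al_B) == 1L && al_A != al_B)
      res["fixed"] <- res["fixed"] + 1L
    # monomorphic-same columns are not SNPs of the pooled groups
  }
  c(as.list(res), n_snps = nrow(snps))
}

#' D3 distance-based introgression statistic
#'
#' `(d13 - d23) / (d13 + d23)` where `d13` and `d23` are mean pairwise
#' p-distances between the named populations. The statistic is antisymmetric
#' in its arguments and bounded in \[-1, 1\].
#'
#' @param d13,d23 Non-negative mean pairwise distances; not both zero.
#' @return The D3 value.
#' @export
d3_statistic <- function(d13, d23) {
  if (d13 < 0 || d23 < 0) stop("distances must be non-negative")
  if (d13 + d23 == 0) stop("D3 undefined when both distances are zero")
  (d13 - d23) / (d13 + d23)
}

#' Phaseability SNP-density threshold
#'
#' With paired-end 150-bp reads, two SNPs farther than 300 bp apart can never
#' share a read pair, so read-backed phasing needs at least two SNPs within a
#' 300-bp span: 2/300, conventionally rounded to four decimals.
#'
#' @return The threshold constant 0.0067 SNPs/site.
#' @export
phaseability_threshold <- function() round(2 / 300, 4L)

#' Per-sample heterozygous SNP density
#'
#' For each requested sample, the number of columns segregating among that
#' sample's own haplotypes divided by the number of columns with no missing
#' base in that sample, pooled across loci.
#'
#' @param loci List of [locus_alignment()] objects.
#' @param samples Sample ids to profile (default: all samples seen).
#' @return A data.frame with `sample_id`, `het_sites`, `sites`, `density`,
#'   plus the phaseability threshold as attribute `"threshold"`.
#' @export
snp_density_profile <- function(loci, samples = NULL) {
  if (inherits(loci, "locus_alignment")) loci <- list(loci)
  if (is.null(samples))
    samples <- unique(unlist(lapply(loci, `[[`, "sample_id")))
  het <- tot <- stats::setNames(numeric(length(samples)), samples)
  for (aln in loci) {
    for (s in intersect(samples, unique(aln$sample_id))) {
      m <- aln$mat[aln$sample_id == s, , drop = FALSE]
      ok <- !apply(m, 2L, function(col) any(is_missing_base(col)))
      nal <- apply(m[, ok, drop = FALSE], 2L,
                   function(col) length(unique(col)))
      het[s] <- het[s] + sum(nal > 1L)
      tot[s] <- tot[s] + sum(ok)
    }
  }
  if (any(tot == 0)) stop("sample(s) with no non-missing columns: ",
                          paste(samples[tot == 0], collapse = ", "))
  out <- data.frame(sample_id = samples, het_sites = as.integer(het),
                    sites = as.integer(tot), density = het / tot,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- phaseability_threshold()
  out
}
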
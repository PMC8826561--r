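#' Locus alignment of phased haplotypes
#'
#' A `locus_alignment` holds one locus's equal-length phased haplotypes, each
#' row tagged by sample and haplotype index (0-3). Diploid samples carry
#' exactly two haplotypes, tetraploids four. Internally the residues live in a
#' character matrix (rows = haplotypes, columns = alignment sites) over the
#' alphabet A, C, G, T, N, -; N and the gap are both treated as missing.
#'
#' @param locus_id Character scalar naming the locus.
#' @param seqs Character vector of equal-length sequences (one per haplotype),
#'   or a character matrix with one row per haplotype and one column per site.
#' @param sample_id Character vector, one entry per haplotype.
#' @param hap_index Integer vector of haplotype indices (0-based, unique
#'   within a sample).
#' @return An object of class `locus_alignment`: a list with elements
#'   `locus_id`, `mat` (character matrix), `sample_id`, `hap_index`.
#' @examples
#' aln <- locus_alignment("L1", c("ACGT", "ACGA"), c("s1", "s1"), c(0L, 1L))
#' aln
#' @export
locus_alignment <- function(locus_id, seqs, sample_id, hap_index) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    n <- nchar(seqs)
    if (length(unique(n)) != 1L)
      stop("all sequences in a locus alignment must have equal length")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  mat[] <- toupper(mat)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("unexpected residues in alignment: ", paste(bad, collapse = ", "))
  if (nrow(mat) != length(sample_id) || nrow(mat) != length(hap_index))
    stop("sample_id and hap_index must match the number of haplotype rows")
  hap_index <- as.integer(hap_index)
  for (s in unique(sample_id)) {
    idx <- hap_index[sample_id == s]
    if (anyDuplicated(idx))
      stop("duplicated haplotype index for sample ", s)
    if (!length(idx) %in% c(2L, 4L))
      stop("sample ", s, " must have 2 or 4 haplotypes, has ", length(idx))
  }
  structure(
    list(locus_id = as.character(locus_id), mat = mat,
         sample_id = as.character(sample_id), hap_index = hap_index),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_id, ": ", nrow(x$mat), " haplotypes (",
      length(unique(x$sample_id)), " samples) x ", ncol(x$mat), " sites\n",
      sep = "")
  invisible(x)
}

#' @export
dim.locus_alignment <- function(x) dim(x$mat)

#' Subset an alignment to a set of samples
#'
#' @param aln A `locus_alignment`.
#' @param samples Character vector of sample ids to keep.
#' @return A `locus_alignment` restricted to the requested samples.
#' @export
subset_samples <- function(aln, samples) {
  keep <- aln$sample_id %in% samples
  if (!any(keep)) stop("no requested sample present in locus ", aln$locus_id)
  structure(
    list(locus_id = aln$locus_id, mat = aln$mat[keep, , drop = FALSE],
         sample_id = aln$sample_id[keep], hap_index = aln$hap_index[keep]),
    class = "locus_alignment")
}

is_missing_base <- function(x) x == "N" | x == "-"

#' Read a per-locus phased FASTA file
#'
#' Reads the package's per-locus FASTA dialect: one file per locus, headers of
#' the form `sampleID|hap<k>` with `k` in 0-3.
#'
#' @param path Path to a FASTA file.
#' @param locus_id Locus name; defaults to the file name without extension.
#' @return A `locus_alignment`.
#' @export
read_locus_fasta <- function(path, locus_id = NULL) {
  if (is.null(locus_id))
    locus_id <- sub("\\.(fa|fasta)$", "", basename(path))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  headers <- names(recs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("FASTA headers must be 'sampleID|hapK': ", path)
  sample_id <- vapply(parts, `[[`, "", 1L)
  hap_index <- as.integer(sub("^hap", "", vapply(parts, `[[`, "", 2L)))
  locus_alignment(locus_id, unlist(recs, use.names = FALSE), sample_id, hap_index)
}

#' Write a per-locus phased FASTA file
#'
#' @param aln A `locus_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  nm <- paste0(aln$sample_id, "|hap", aln$hap_index)
  seqinr::write.fasta(as.list(seqs), names = nm, file.out = path,
                      nbchar = 80L)
  invisible(path)
}
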
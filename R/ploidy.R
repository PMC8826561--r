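#' Phase a sample's rows as four haplotypes
#'
#' A four-allele phaser presented with a true diploid returns each of its two
#' haplotypes twice. This helper reproduces that behaviour for alignments
#' whose diploids carry only two rows, so ploidy features can be computed
#' uniformly on four rows per sample.
#'
#' @param aln A [locus_alignment()].
#' @return A `locus_alignment` in which every sample has four haplotypes.
#' @export
phase_as_four <- function(aln) {
  mats <- list(); sid <- character(); hap <- integer()
  for (s in unique(aln$sample_id)) {
    rows <- which(aln$sample_id == s)
    m <- aln$mat[rows, , drop = FALSE][order(aln$hap_index[rows]), , drop = FALSE]
    if (nrow(m) == 2L) m <- m[c(1L, 2L, 1L, 2L), , drop = FALSE]
    mats[[length(mats) + 1L]] <- m
    sid <- c(sid, rep(s, 4L)); hap <- c(hap, 0:3)
  }
  locus_alignment(aln$locus_id, do.call(rbind, mats), sid, hap)
}

#' Ploidy features from four phased alleles
#'
#' For each sample, computes over loci the mean of each of the six sorted
#' pairwise p-distances among the four phased haplotypes, the mean number of
#' distinct haplotypes per locus, and the fraction of loci where more than two
#' haplotypes are distinct. A true diploid phased for four alleles duplicates
#' its two haplotypes, so its smallest sorted distances are (near) zero and
#' its distinct-haplotype count stays at two; a tetraploid's four alleles are
#' generally all distinct. Loci where a pairwise distance is undefined (no
#' comparable columns) are skipped and counted.
#'
#' @param loci List of [locus_alignment()] objects in which the sample has
#'   four haplotypes (see [phase_as_four()]).
#' @param samples Sample ids to featurize (default: all).
#' @return A data.frame with one row per sample: `sample_id`, `d1`..`d6`
#'   (sorted mean distances), `mean_distinct`, `frac_gt2`, `n_loci_used`.
#' @export
ploidy_features <- function(loci, samples = NULL) {
  if (inherits(loci, "locus_alignment")) loci <- list(loci)
  if (is.null(samples))
    samples <- unique(unlist(lapply(loci, `[[`, "sample_id")))
  rows <- lapply(samples, function(s) {
    dsum <- numeric(6L); distinct <- numeric(); gt2 <- logical(); used <- 0L
    for (aln in loci) {
      if (!s %in% aln$sample_id) next
      m <- aln$mat[aln$sample_id == s, , drop = FALSE]
      if (nrow(m) != 4L) stop("sample ", s, " is not phased as 4 haplotypes")
      pr <- utils::combn(4L, 2L)
      d <- apply(pr, 2L, function(ij) p_distance(m[ij[1L], ], m[ij[2L], ]))
      if (anyNA(d)) next
      dsum <- dsum + sort(d)
      # distinct haplotypes judged on comparable (pairwise) distances
      ndist <- n_distinct_rows(m)
      distinct <- c(distinct, ndist)
      gt2 <- c(gt2, ndist > 2L)
      used <- used + 1L
    }
    if (used == 0L) stop("no usable loci for sample ", s)
    data.frame(sample_id = s, t(dsum / used),
               mean_distinct = mean(distinct), frac_gt2 = mean(gt2),
               n_loci_used = used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:7] <- paste0("d", 1:6)
  out
}

# distinct rows by zero p-distance (missing-tolerant)
n_distinct_rows <- function(m) {
  n <- nrow(m); groups <- integer(n); g <- 0L
  for (i in seq_len(n)) {
    if (groups[i] > 0L) next
    g <- g + 1L; groups[i] <- g
    if (i < n) for (j in (i + 1L):n) {
      if (groups[j] > 0L) next
      d <- p_distance(m[i, ], m[j, ])
      if (!is.na(d) && d == 0) groups[j] <- g
    }
  }
  g
}

ploidy_feature_cols <- c(paste0("d", 1:6), "mean_distinct", "frac_gt2")

#' Train a nearest-centroid ploidy classifier
#'
#' Fits a transparent nearest-centroid discriminant on scale-standardized
#' ploidy features of known-ploidy training samples (diploids that are
#' allopatric, or otherwise confirmed). The original published classifier of
#' this design defers its exact algorithm to package documentation; this is a
#' documented reconstruction of the stated distance signal, not a port.
#'
#' @param features Feature table from [ploidy_features()].
#' @param labels Character vector (`"diploid"`/`"tetraploid"`) aligned with
#'   `features` rows; each class needs at least two samples.
#' @param margin_threshold Standardized-margin width below which a call is
#'   flagged ambiguous (default 0.1).
#' @return An object of class `ploidy_model` with centroids, scales, the
#'   threshold, and training accuracy.
#' @export
train_ploidy_classifier <- function(features, labels,
                                    margin_threshold = 0.1) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  if (!setequal(unique(labels), c("diploid", "tetraploid")))
    stop("training data must contain both classes: diploid and tetraploid")
  if (any(table(labels) < 2L))
    stop("each class needs at least two training samples")
  x <- as.matrix(features[, ploidy_feature_cols])
  # pooled within-class SD per feature, floored to avoid zero scales
  scales <- sqrt(colMeans(rbind(
    scale(x[labels == "diploid", , drop = FALSE], scale = FALSE)^2,
    scale(x[labels == "tetraploid", , drop = FALSE], scale = FALSE)^2)))
  floor_at <- 1e-8
  if (any(scales < floor_at)) {
    warning("zero-variance feature scale(s) floored")
    scales <- pmax(scales, floor_at)
  }
  centroids <- rbind(diploid = colMeans(x[labels == "diploid", , drop = FALSE]),
                     tetraploid = colMeans(x[labels == "tetraploid", , drop = FALSE]))
  model <- structure(
    list(centroids = centroids, scales = scales,
         margin_threshold = margin_threshold,
         n_train = table(labels)),
    class = "ploidy_model")
  pred <- predict(model, features)
  model$training_accuracy <- mean(pred$call == labels)
  model
}

#' @export
print.ploidy_model <- function(x, ...) {
  cat("<ploidy_model> nearest-centroid classifier\n")
  cat("  training n:", paste(names(x$n_train), as.integer(x$n_train),
                             collapse = ", "), "\n")
  if (!is.null(x$training_accuracy))
    cat("  training accuracy:", format(x$training_accuracy), "\n")
  cat("  ambiguity threshold:", x$margin_threshold,
      "standardized margin units\n")
  invisible(x)
}

#' Predict ploidy for unknown samples
#'
#' @param object A `ploidy_model`.
#' @param features Feature table from [ploidy_features()].
#' @param ... Unused.
#' @return A data.frame with `sample_id`, `call`, `margin` (standardized
#'   distance difference, positive = tetraploid-leaning), and `ambiguous`.
#' @export
predict.ploidy_model <- function(object, features, ...) {
  x <- as.matrix(features[, ploidy_feature_cols])
  if (ncol(x) != ncol(object$centroids)) stop("feature dimension mismatch")
  xs <- sweep(x, 2L, object$scales, "/")
  cs <- sweep(object$centroids, 2L, object$scales, "/")
  d_dip <- sqrt(rowSums(sweep(xs, 2L, cs["diploid", ])^2))
  d_tet <- sqrt(rowSums(sweep(xs, 2L, cs["tetraploid", ])^2))
  margin <- d_dip - d_tet
  data.frame(sample_id = features$sample_id,
             call = ifelse(margin > 0, "tetraploid", "diploid"),
             margin = margin,
             ambiguous = abs(margin) < object$margin_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
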
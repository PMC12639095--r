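# Count tables are tibbles with a gene_id column plus one integer column per
# sample; these helpers move between that shape and a plain matrix.
count_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  m
}

#' Remove low-expression genes
#'
#' Keeps genes having at least `min_count` counts in at least `min_samples`
#' samples; everything else is treated as noise and dropped before
#' normalization and testing.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param min_count Count threshold per sample. Default 5.
#' @param min_samples Number of samples that must reach it. Default 3.
#' @return The retained rows of `counts`, order preserved.
#' @export
filter_low_expression <- function(counts, min_count = 5L, min_samples = 3L) {
  m <- count_matrix(counts)
  if (min_samples > ncol(m)) {
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         ncol(m), ")", call. = FALSE)
  }
  keep <- rowSums(m >= min_count) >= min_samples
  counts[keep, ]
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors correcting for sequencing depth and library
#' composition: for each gene expressed in every sample (the reference set),
#' the ratio of its count to its geometric mean across samples is formed, and
#' the size factor of a sample is the median of those ratios.
#'
#' @param counts Count tibble.
#' @return Tibble with `sample_id` and `size_factor` (all positive).
#' @export
estimate_size_factors <- function(counts) {
  m <- count_matrix(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop("no gene has nonzero counts in all samples; relax the ",
         "low-expression filter or check the input", call. = FALSE)
  }
  lg <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  s <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  tibble::tibble(sample_id = colnames(m), size_factor = unname(s))
}

#' Log2 variance-flattening transform of normalized counts
#'
#' Divides each sample's counts by its size factor and applies
#' `log2(x + 1)`, yielding a log2-like matrix whose variance is roughly
#' mean-independent — suitable for PCA and correlation QC. This is a simple
#' pseudocount log transform, not a fitted mean-dispersion transform; its
#' name is recorded in the `"transform"` attribute of the result.
#'
#' @param counts Count tibble.
#' @param size_factors Output of [estimate_size_factors()] on the same
#'   counts.
#' @return Tibble of transformed values, same shape as `counts`, with
#'   attribute `transform = "log2_norm_plus1"`.
#' @export
vst_transform <- function(counts, size_factors) {
  m <- count_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m),
                                       size_factors$sample_id)]
  if (anyNA(sf)) {
    stop("size_factors do not cover all samples in the count table",
         call. = FALSE)
  }
  t_m <- log2(sweep(m, 2, sf, "/") + 1)
  out <- tibble::as_tibble(t_m)
  out <- dplyr::mutate(out, gene_id = counts$gene_id, .before = 1)
  attr(out, "transform") <- "log2_norm_plus1"
  out
}

#' Principal component analysis of samples
#'
#' Samples are the observations and genes the variables; genes with zero
#' variance across samples are dropped (their count is messaged) before
#' optional centering and unit-variance scaling. Explained-variance fractions
#' come from the squared singular values.
#'
#' @param transformed Transformed tibble from [vst_transform()].
#' @param samples Optional sample sheet joined onto the scores by
#'   `sample_id`.
#' @param center,scale Center / scale genes before the decomposition.
#'   Defaults `TRUE`.
#' @param k Number of components to keep; default all (at most
#'   `n_samples - 1`).
#' @return A `tag_pca` object with `scores` (tibble), `var_explained`
#'   (fractions, non-increasing) and the dropped-gene count.
#' @export
run_pca <- function(transformed, samples = NULL, center = TRUE, scale = TRUE,
                    k = NULL) {
  m <- count_matrix(transformed)
  if (ncol(m) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  x <- t(m)  # samples x genes
  v <- apply(x, 2, stats::var)
  n_dropped <- sum(v == 0)
  if (n_dropped > 0 && scale) {
    message(n_dropped, " zero-variance gene(s) dropped before scaling")
    x <- x[, v > 0, drop = FALSE]
  }
  if (!is.null(k) && k > nrow(x) - 1) {
    stop("k must be at most n_samples - 1", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = center, scale. = scale)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(k)) min(length(frac), nrow(x) - 1L) else k
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::mutate(scores, sample_id = rownames(x), .before = 1)
  if (!is.null(samples)) {
    scores <- dplyr::left_join(scores, samples, by = "sample_id")
  }
  structure(
    list(scores = scores, var_explained = frac[seq_len(k)],
         sdev = pc$sdev, n_dropped = n_dropped, center = center,
         scale = scale),
    class = "tag_pca"
  )
}

#' @export
print.tag_pca <- function(x, ...) {
  cat("<tag_pca> ", nrow(x$scores), " samples, ", length(x$var_explained),
      " components; PC1 ", sprintf("%.1f%%", 100 * x$var_explained[1]),
      if (length(x$var_explained) > 1) {
        sprintf(", PC2 %.1f%%", 100 * x$var_explained[2])
      } else "",
      " of variance\n", sep = "")
  invisible(x)
}

#' Pairwise sample Pearson correlation with clustering order
#'
#' Computes all pairwise Pearson correlations between samples on the
#' transformed matrix and orders samples by average-linkage hierarchical
#' clustering on the `1 - r` distance.
#'
#' @param transformed Transformed tibble from [vst_transform()].
#' @return A `tag_cor` object: the correlation matrix `r`, the leaf `order`
#'   (sample ids) and the `hclust` tree.
#' @export
sample_correlation <- function(transformed) {
  m <- count_matrix(transformed)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(m)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(
    list(r = r, order = colnames(m)[hc$order], hclust = hc),
    class = "tag_cor"
  )
}

#' @export
print.tag_cor <- function(x, ...) {
  cat("<tag_cor> ", ncol(x$r), " samples; mean off-diagonal r = ",
      sprintf("%.3f", mean(x$r[upper.tri(x$r)])), "\n", sep = "")
  invisible(x)
}
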
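#' Negative-binomial Wald test between two replicate groups
#'
#' A fully specified count-based test for 3' tag data: counts are normalized
#' by the size factors, the log2 fold change is
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`, the per-gene
#' dispersion `alpha` is estimated by method of moments from the pooled
#' within-group variance of the normalized counts
#' (`alpha = max(0, (var - mean) / mean^2)`) and then moderated towards the
#' experiment-wide mean dispersion with `prior_df` prior degrees of freedom
#' — an empirical-Bayes stabilisation in the spirit of limma/edgeR, without
#' which per-gene dispersions at 2-4 replicates are too noisy to test
#' against. The standard error of the log2 fold change follows from the
#' delta method under the NB variance `mean + alpha * mean^2`; two-sided
#' p-values come from the standard normal. No fold-change shrinkage is
#' applied.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param size_factors From [estimate_size_factors()].
#' @param group_a,group_b Disjoint character vectors of sample ids (each of
#'   size >= 2); the fold change is `group_b` over `group_a`.
#' @param pseudocount Added to both group means in the fold change. Default
#'   0.5.
#' @param prior_df Prior degrees of freedom of the dispersion moderation;
#'   0 disables it. Default 10.
#' @param label Optional contrast label (e.g. `"R1-D1"`), stored as an
#'   attribute.
#' @return Tibble: `gene_id`, `base_mean`, `log2fc`, `se`, `p_value`.
#' @export
nb_wald_test <- function(counts, size_factors, group_a, group_b,
                         pseudocount = 0.5, prior_df = 10, label = NULL) {
  m <- count_matrix(counts)
  if (!all(c(group_a, group_b) %in% colnames(m))) {
    stop("contrast groups name samples absent from the count table",
         call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("contrast groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each contrast group needs at least 2 samples", call. = FALSE)
  }
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  norm <- sweep(m, 2, sf, "/")
  xa <- norm[, group_a, drop = FALSE]
  xb <- norm[, group_b, drop = FALSE]
  if (all(xa == 0) || all(xb == 0)) {
    stop("a contrast group has all-zero counts for every gene", call. = FALSE)
  }
  na <- ncol(xa)
  nb <- ncol(xb)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  df_resid <- na + nb - 2
  ss <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  v <- ss / df_resid
  mean_all <- rowMeans(cbind(xa, xb))
  alpha <- pmax(0, (v - mean_all) / mean_all^2)
  alpha[!is.finite(alpha)] <- 0
  if (prior_df > 0 && length(alpha) > 1) {
    alpha_prior <- mean(alpha, trim = 0.05)
    alpha <- (df_resid * alpha + prior_df * alpha_prior) /
      (df_resid + prior_df)
  }
  log2fc <- log2((mb + pseudocount) / (ma + pseudocount))
  var_ma <- (ma + alpha * ma^2) / na
  var_mb <- (mb + alpha * mb^2) / nb
  se <- sqrt(var_ma / (ma + pseudocount)^2 +
               var_mb / (mb + pseudocount)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[se == 0] <- 1
  out <- tibble::tibble(
    gene_id = counts$gene_id,
    base_mean = unname(mean_all),
    log2fc = unname(log2fc),
    se = unname(se),
    p_value = unname(p)
  )
  attr(out, "contrast") <- label
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement; values
#' map back to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Classify significance of differential-expression results
#'
#' A gene is `up` when `log2fc > lfc_threshold` and `fdr < fdr_threshold`,
#' `down` when `log2fc < -lfc_threshold` and `fdr < fdr_threshold`, otherwise
#' `ns`. Comparisons are strict.
#'
#' @param results Tibble with `log2fc` and `fdr` columns.
#' @param lfc_threshold Absolute log2 fold-change threshold (exclusive).
#'   Default 0.5.
#' @param fdr_threshold FDR threshold (exclusive). Default 0.05.
#' @return `results` with a `sig_class` column (`up`/`down`/`ns`).
#' @export
classify_sig <- function(results, lfc_threshold = 0.5, fdr_threshold = 0.05) {
  stopifnot(all(c("log2fc", "fdr") %in% names(results)))
  dplyr::mutate(
    results,
    sig_class = dplyr::case_when(
      .data$log2fc > lfc_threshold & .data$fdr < fdr_threshold ~ "up",
      .data$log2fc < -lfc_threshold & .data$fdr < fdr_threshold ~ "down",
      TRUE ~ "ns"
    )
  )
}

#' Differential expression for one contrast
#'
#' Convenience wrapper chaining [nb_wald_test()], [bh_adjust()] and
#' [classify_sig()].
#'
#' @inheritParams nb_wald_test
#' @inheritParams classify_sig
#' @return A `tag_de` tibble: `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `p_value`, `fdr`, `sig_class`, with the contrast label as attribute.
#' @export
run_de <- function(counts, size_factors, group_a, group_b,
                   pseudocount = 0.5, prior_df = 10, lfc_threshold = 0.5,
                   fdr_threshold = 0.05, label = NULL) {
  res <- nb_wald_test(counts, size_factors, group_a, group_b,
                      pseudocount = pseudocount, prior_df = prior_df,
                      label = label)
  res$fdr <- bh_adjust(res$p_value)
  res <- classify_sig(res, lfc_threshold = lfc_threshold,
                      fdr_threshold = fdr_threshold)
  class(res) <- c("tag_de", class(res))
  attr(res, "contrast") <- label
  res
}
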
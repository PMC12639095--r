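counts_tbl <- function(m, gene_ids = sprintf("g%03d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  tibble::as_tibble(cbind(tibble::tibble(gene_id = gene_ids),
                          as.data.frame(m)))
}

test_that("filter_low_expression keeps genes with enough expressed samples", {
  m <- rbind(
    c(6, 7, 8, 0, 0, 0),   # exactly 3 samples >= 5 -> kept
    c(6, 7, 0, 0, 0, 0),   # only 2 -> removed
    c(0, 0, 0, 0, 0, 0),   # all zero -> removed
    c(5, 5, 5, 5, 5, 5)    # kept
  )
  res <- filter_low_expression(counts_tbl(m))
  expect_equal(res$gene_id, c("g001", "g004"))
  expect_error(filter_low_expression(counts_tbl(m), min_samples = 7),
               "min_samples")
})

test_that("filter_low_expression matches a brute-force row scan", {
  set.seed(3)
  m <- matrix(rpois(600, 4), nrow = 100)
  counts <- counts_tbl(m)
  res <- filter_low_expression(counts, min_count = 5, min_samples = 3)
  keep <- vapply(seq_len(nrow(m)),
                 function(i) sum(m[i, ] >= 5) >= 3, logical(1))
  expect_equal(res$gene_id, counts$gene_id[keep])
})

test_that("median-of-ratios size factors match the hand computation", {
  m <- rbind(c(10, 20), c(30, 60), c(50, 100))
  sf <- estimate_size_factors(counts_tbl(m))
  # geometric means (14.142, 42.426, 70.711); every ratio is (0.7071, 1.4142)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  # equal columns -> equal factors
  sf2 <- estimate_size_factors(counts_tbl(matrix(7, 5, 4)))
  expect_true(all(sf2$size_factor == sf2$size_factor[1]))
})

test_that("size factors are scale-equivariant and gene-order invariant", {
  set.seed(13)
  m <- matrix(rnbinom(300, mu = 50, size = 5) + 1, nrow = 50)
  counts <- counts_tbl(m)
  sf <- estimate_size_factors(counts)
  doubled <- m
  doubled[, 3] <- 2 * doubled[, 3]
  sf2 <- estimate_size_factors(counts_tbl(doubled))
  # median-of-ratios is equivariant up to a common rescaling (the geometric
  # means absorb 2^(1/n)); the factor vector scales as (1,...,2,...,1)
  ratio <- sf2$size_factor / sf$size_factor
  expect_equal(ratio / ratio[1], c(1, 1, 2, 1, 1, 1), tolerance = 1e-12)
  perm <- counts[sample(nrow(counts)), ]
  expect_equal(estimate_size_factors(perm), sf)
})

test_that("size factors agree with DESeq2's median-of-ratios", {
  skip_if_not_installed("DESeq2")
  set.seed(17)
  m <- matrix(rnbinom(400, mu = 100, size = 5), nrow = 50)
  sf <- estimate_size_factors(counts_tbl(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(sf$size_factor, unname(ref), tolerance = 1e-8)
})

test_that("a matrix with no all-positive gene is rejected with guidance", {
  m <- rbind(c(0, 5), c(5, 0))
  expect_error(estimate_size_factors(counts_tbl(m)), "relax")
})

test_that("the log2 transform is anchored, monotone and labelled", {
  m <- rbind(c(0, 7), c(7, 0), c(3, 3))
  counts <- counts_tbl(m)
  sf <- tibble::tibble(sample_id = c("s1", "s2"), size_factor = c(1, 1))
  v <- vst_transform(counts, sf)
  expect_equal(v$s1, log2(m[, 1] + 1))
  expect_equal(v$s1[1], 0)
  expect_equal(v$s2[1], 3)
  expect_equal(attr(v, "transform"), "log2_norm_plus1")
  # strictly increasing in the count for fixed size factor
  grid <- counts_tbl(matrix(0:20, ncol = 1), sprintf("g%03d", 1:21))
  vv <- vst_transform(grid, tibble::tibble(sample_id = "s1", size_factor = 1))
  expect_true(all(diff(vv$s1) > 0))
})

test_that("PCA fractions behave at the rank-1 limit and in general", {
  set.seed(29)
  pattern <- rnorm(40)
  scale_per_sample <- c(1, 2, 3, 4, 5, 6)
  m <- outer(pattern, scale_per_sample)  # rank-1 genes x samples
  v <- counts_tbl(m)
  p <- run_pca(v, scale = FALSE)
  expect_equal(p$var_explained[1], 1.0, tolerance = 1e-9)
  # random matrix: fractions non-increasing, sum <= 1
  m2 <- matrix(rnorm(40 * 12), nrow = 40)
  p2 <- run_pca(counts_tbl(m2))
  expect_true(all(diff(p2$var_explained) <= 1e-12))
  expect_lte(sum(p2$var_explained), 1 + 1e-12)
  expect_error(run_pca(counts_tbl(m2[, 1, drop = FALSE])), "2 samples")
})

test_that("PCA separates planted sample groups on PC1", {
  set.seed(37)
  n_genes <- 200
  base <- matrix(rnorm(n_genes * 12, sd = 0.5), nrow = n_genes)
  shift <- matrix(0, n_genes, 12)
  shift[1:100, 7:12] <- 2  # group B up on half the genes
  p <- run_pca(counts_tbl(base + shift))
  pc1 <- p$scores$PC1
  expect_true(all(sign(pc1[1:6]) != sign(pc1[7:12])))
  expect_gt(p$var_explained[1], max(p$var_explained[-1]))
})

test_that("zero-variance genes are dropped before scaling with a message", {
  set.seed(41)
  m <- rbind(matrix(rnorm(30), 5, 6), rep(1, 6))
  expect_message(p <- run_pca(counts_tbl(m)), "zero-variance")
  expect_equal(p$n_dropped, 1)
})

test_that("sample correlation has exact structure and clustering order", {
  set.seed(43)
  x <- rnorm(50)
  m <- cbind(x, x, -x) + 0  # duplicated and negated samples
  colnames(m) <- c("a", "b", "neg")
  v <- counts_tbl(m)
  co <- sample_correlation(v)
  expect_equal(unname(diag(co$r)), rep(1, 3))
  expect_equal(co$r["a", "b"], 1)
  expect_equal(co$r["a", "neg"], -1)
  expect_true(isSymmetric(co$r))
  # zero-variance sample is fatal with its name
  m2 <- cbind(rnorm(10), rep(3, 10))
  colnames(m2) <- c("ok", "flat")
  expect_error(sample_correlation(counts_tbl(m2)), "flat")
})

test_that("replicate triplets correlate more within than between", {
  set.seed(47)
  n_genes <- 300
  base <- rnorm(n_genes, sd = 2)
  group_effect <- replicate(3, rnorm(n_genes, sd = 2))
  m <- do.call(cbind, lapply(1:3, function(g) {
    replicate(3, base + group_effect[, g] + rnorm(n_genes, sd = 0.5))
  }))
  colnames(m) <- paste0("t", rep(1:3, each = 3), "_", rep(1:3, 3))
  co <- sample_correlation(counts_tbl(m))
  grp <- rep(1:3, each = 3)
  same <- outer(grp, grp, "==") & upper.tri(co$r)
  diff_ <- outer(grp, grp, "!=") & upper.tri(co$r)
  expect_gt(mean(co$r[same]), mean(co$r[diff_]))
})
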
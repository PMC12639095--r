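aln_span <- function(start, end, strand = "+", reference = "chr1",
                     has_polya = FALSE) {
  n <- length(start)
  tibble::tibble(
    query_id = paste0("q", seq_len(n)),
    reference = rep_len(reference, n),
    start = start, end = end,
    strand = rep_len(strand, n),
    has_polya = rep_len(has_polya, n)
  )
}

test_that("build_clusters merges transitively overlapping reads per strand", {
  a <- aln_span(c(100L, 150L, 300L), c(175L, 225L, 375L))
  cl <- build_clusters(a, "s1")
  expect_equal(cl$start, c(100L, 300L))
  expect_equal(cl$end, c(225L, 375L))
  expect_equal(cl$n_reads, c(2L, 1L))
  # the middle read on the other strand splits the first cluster
  a2 <- a
  a2$strand[2] <- "-"
  cl2 <- build_clusters(a2, "s1")
  expect_equal(nrow(cl2), 3)
  expect_equal(sort(cl2$n_reads), c(1L, 1L, 1L))
  # book-ended intervals do not overlap under gap = 0, but merge with gap > 0
  a3 <- aln_span(c(100L, 200L), c(200L, 300L))
  expect_equal(nrow(build_clusters(a3, "s1")), 2)
  expect_equal(nrow(build_clusters(a3, "s1", gap = 1L)), 1)
})

test_that("clustering equals brute-force connected components on random input", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    start <- sample(0:5000, n, replace = TRUE)
    end <- start + sample(10:150, n, replace = TRUE)
    ids <- tagseq3p:::overlap_components(start, end)
    oracle <- brute_components(start, end)
    expect_equal(component_summary(start, end, ids),
                 component_summary(start, end, oracle),
                 ignore_attr = TRUE)
    # membership partitions are identical, not just summaries
    expect_equal(length(unique(ids)), length(unique(oracle)))
    expect_true(all(tapply(oracle, ids, function(x) length(unique(x))) == 1))
  }
})

test_that("cluster output is invariant to record order", {
  set.seed(5)
  n <- 100
  start <- sample(0:2000, n, replace = TRUE)
  a <- aln_span(start, start + sample(30:80, n, replace = TRUE),
                strand = sample(c("+", "-"), n, replace = TRUE),
                has_polya = sample(c(TRUE, FALSE), n, replace = TRUE))
  cl1 <- build_clusters(a, "s1")
  cl2 <- build_clusters(a[sample(n), ], "s1")
  expect_equal(cl1, cl2)
})

test_that("detect_polya inspects the strand-appropriate soft clip", {
  body <- strrep("C", 69)
  a <- make_aln(
    list(start = 0L, cigar = "69M6S", sequence = paste0(body, "AAAAAA")),
    list(start = 0L, cigar = "69M6S", sequence = paste0(body, "AAGAAA")),
    list(start = 0L, cigar = "6S69M", strand = "-",
         sequence = paste0("TTTTTT", body)),
    list(start = 0L, cigar = "69M6S", strand = "-",
         sequence = paste0(body, "TTTTTT")),
    list(start = 0L, cigar = "75M")
  )
  res <- detect_polya(a)
  expect_equal(res$has_polya, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # clip length reported at the transcript-3' end, 0 when no clip there
  expect_equal(res$tail_length, c(6L, 6L, 6L, 0L, 0L))
})

test_that("polya thresholds are configurable", {
  a <- make_aln(
    list(start = 0L, cigar = "71M4S", sequence = paste0(strrep("C", 71), "AAAA")),
    list(start = 0L, cigar = "65M10S",
         sequence = paste0(strrep("C", 65), "AAAAAAAAAG"))  # 9/10 A
  )
  res <- detect_polya(a)
  expect_equal(res$has_polya, c(FALSE, TRUE))  # 4 < 5; 0.9 >= 0.9
  res2 <- detect_polya(a, polya_policy(min_tail = 4, min_purity = 0.95))
  expect_equal(res2$has_polya, c(TRUE, FALSE))
})

test_that("group_replicates merges clusters across samples by overlap", {
  mk <- function(sample_id, start, end) {
    tibble::tibble(sample_id = sample_id, reference = "chr1", strand = "+",
                   start = start, end = end, n_reads = 1L,
                   n_polya_reads = 0L)
  }
  clusters <- dplyr::bind_rows(
    mk("rep1", 100L, 200L), mk("rep2", 150L, 250L), mk("rep3", 400L, 500L)
  )
  sets <- tibble::tibble(sample_id = c("rep1", "rep2", "rep3"), group = "g")
  members <- group_replicates(clusters, sets)
  expect_equal(length(unique(members$meta_id)), 2)
  merged <- members[members$sample_id %in% c("rep1", "rep2"), ]
  expect_equal(unique(merged$meta_id), merged$meta_id[1])
  expect_equal(unique(merged$meta_start), 100L)
  expect_equal(unique(merged$meta_end), 250L)
  # identical clusters in 3 replicates collapse to one meta-cluster
  same <- dplyr::bind_rows(mk("rep1", 10L, 50L), mk("rep2", 10L, 50L),
                           mk("rep3", 10L, 50L))
  m2 <- group_replicates(same, sets)
  expect_equal(length(unique(m2$meta_id)), 1)
  # unknown sample is fatal
  expect_error(group_replicates(mk("repX", 1L, 2L), sets), "repX")
})

test_that("meta-grouping equals brute-force cross-sample overlap components", {
  set.seed(31)
  for (rep in 1:10) {
    clusters <- dplyr::bind_rows(lapply(1:3, function(r) {
      n <- sample(5:25, 1)
      start <- sort(sample(seq(0, 3000, by = 10), n))
      tibble::tibble(sample_id = paste0("rep", r), reference = "chr1",
                     strand = "+", start = start,
                     end = start + sample(20:200, n, replace = TRUE),
                     n_reads = 1L, n_polya_reads = 0L)
    }))
    sets <- tibble::tibble(sample_id = paste0("rep", 1:3), group = "g")
    members <- group_replicates(clusters, sets)
    ids <- as.integer(factor(members$meta_id))
    oracle <- brute_components(members$start, members$end)
    expect_true(all(tapply(oracle, ids, function(x) length(unique(x))) == 1))
    expect_equal(length(unique(ids)), length(unique(oracle)))
  }
})

test_that("the replicate validation rule follows the decided semantics", {
  expect_true(validate_metacluster(c(2, 0, 0)))
  expect_false(validate_metacluster(c(1, 1, 1)))
  expect_false(validate_metacluster(c(0, 0, 0)))
  expect_true(validate_metacluster(c(1, 1, 1), mode = "pooled"))
  expect_false(validate_metacluster(c(1, 0, 0), mode = "pooled"))
})

test_that("assign_and_count assigns by maximal overlap and sums member reads", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"),
    reference = "chr1",
    start = c(1000L, 2060L),
    end = c(2000L, 3000L),
    strand = "+"
  )
  member <- function(sample_id, n_reads) {
    tibble::tibble(
      sample_id = sample_id, reference = "chr1", strand = "+",
      start = 1700L, end = 2100L, n_reads = n_reads, n_polya_reads = 2L,
      group = "g", meta_id = "meta1", meta_start = 1700L, meta_end = 2100L,
      validated = TRUE
    )
  }
  members <- dplyr::bind_rows(member("rep1", 10L), member("rep2", 7L),
                              member("rep3", 12L))
  samples <- tibble::tibble(sample_id = c("rep1", "rep2", "rep3"))
  res <- assign_and_count(members, genes, samples)
  # meta [1700,2100) overlaps g1 by 300 and g2 by 40 -> all counts to g1
  g1 <- res$counts[res$counts$gene_id == "g1", ]
  expect_equal(unlist(g1[, -1]), c(rep1 = 10L, rep2 = 7L, rep3 = 12L))
  expect_equal(sum(unlist(res$counts[res$counts$gene_id == "g2", -1])), 0)
  expect_equal(nrow(res$intergenic), 0)
  # an intergenic meta-cluster is reported, not counted
  members_ig <- dplyr::mutate(members, start = 5000L, end = 5400L,
                              meta_start = 5000L, meta_end = 5400L)
  res2 <- assign_and_count(members_ig, genes, samples)
  expect_equal(sum(unlist(res2$counts[, -1])), 0)
  expect_equal(nrow(res2$intergenic), 1)
  expect_equal(res2$intergenic$score, 29L)
  # unknown reference in a meta-cluster is fatal
  members_bad <- dplyr::mutate(members, reference = "chrX")
  expect_error(assign_and_count(members_bad, genes, samples), "chrX")
})

test_that("quantify recovers ground truth exactly on a noise-free fixture", {
  fx <- make_read_fixture(withr::local_tempdir(), n_genes = 20, seed = 101)
  q <- quantify(fx$sheet, fx$genes)
  got <- q$counts
  truth <- fx$truth[match(got$gene_id, fx$truth$gene_id), ]
  for (sid in fx$samples$sample_id) {
    expect_equal(got[[sid]], truth[[sid]])
  }
  expect_equal(nrow(q$intergenic), 0)
  # conservation: assigned + intergenic + rejected reads = passing reads
  per_sample_members <- dplyr::summarise(
    dplyr::group_by(q$members, .data$sample_id),
    total = sum(.data$n_reads)
  )
  expect_equal(
    per_sample_members$total[match(q$log$sample_id,
                                   per_sample_members$sample_id)],
    q$log$n_pass
  )
})

test_that("genes without polyA evidence drop out of the matrix", {
  dir <- withr::local_tempdir()
  genes <- simulate_annotation(n_genes = 20, genome_length = 200000,
                               seed = 300)
  samples <- tibble::tibble(
    genotype = "G1", time_point = "R1", replicate = 1:3,
    sample_id = paste0("G1_R1_", 1:3)
  )
  truth <- simulate_truth_counts(genes, samples$sample_id, seed = 301)
  tailed <- truth[1:15, ]
  untailed <- truth[16:20, ]
  sim_a <- simulate_tag_reads(genes, tailed, file.path(dir, "a"),
                              polya_fraction = 1, seed = 302)
  sim_b <- simulate_tag_reads(genes, untailed, file.path(dir, "b"),
                              polya_fraction = 0, seed = 303)
  # splice the two read sets into one SAM per sample
  sheet <- dplyr::mutate(samples, path = NA_character_)
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    pa <- sim_a$files$path[sim_a$files$sample_id == sid]
    pb <- sim_b$files$path[sim_b$files$sample_id == sid]
    la <- readLines(pa)
    lb <- readLines(pb)
    merged <- file.path(dir, paste0(sid, ".sam"))
    writeLines(c(la, lb[!startsWith(lb, "@")]), merged)
    sheet$path[i] <- merged
  }
  q <- quantify(sheet, genes)
  got <- q$counts
  for (sid in samples$sample_id) {
    expect_equal(got[[sid]][match(tailed$gene_id, got$gene_id)],
                 tailed[[sid]])
    expect_equal(got[[sid]][match(untailed$gene_id, got$gene_id)],
                 rep(0L, 5))
  }
})

test_that("empty alignment files give an all-zero matrix with a warning", {
  dir <- withr::local_tempdir()
  genes <- simulate_annotation(n_genes = 5, genome_length = 60000, seed = 9)
  sheet <- tibble::tibble(
    sample_id = c("s1", "s2"), genotype = "G1", time_point = "R1",
    replicate = 1:2,
    path = vapply(c("s1", "s2"), function(s) {
      write_sam(file.path(dir, paste0(s, ".sam")), character())
    }, character(1))
  )
  w <- testthat::capture_warnings(q <- quantify(sheet, genes))
  expect_true(any(grepl("no reads", w)))
  expect_equal(sum(unlist(q$counts[, -1])), 0)
  expect_equal(nrow(q$counts), 5)
})
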
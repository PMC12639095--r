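#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` non-overlapping genes with random lengths and strands on
#' one reference sequence, separated by at least `min_spacing` nt so that tag
#' clusters can never bridge neighbouring genes. Deterministic for a given
#' seed.
#'
#' @param n_genes Number of genes. Default 20.
#' @param genome_length Reference length in nt. Default 200000.
#' @param gene_length_range Min/max gene length. Default `c(500, 2000)`.
#' @param min_spacing Minimum intergenic gap. Default 300.
#' @param reference Reference name. Default `"chr1"`.
#' @param seed Optional integer seed.
#' @return Gene-model tibble (as from [load_annotation()]) with attribute
#'   `"genome"` (tibble of reference name and length).
#' @export
simulate_annotation <- function(n_genes = 20, genome_length = 200000,
                                gene_length_range = c(500, 2000),
                                min_spacing = 300, reference = "chr1",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(gene_length_range[1]:gene_length_range[2], n_genes,
                 replace = TRUE)
  slack <- genome_length - sum(lens) - min_spacing * (n_genes + 1)
  if (slack < 0) {
    stop("genome_length too small to place ", n_genes,
         " genes with the requested spacing", call. = FALSE)
  }
  u <- stats::runif(n_genes + 1)
  extra <- floor(slack * u / sum(u))
  gaps <- min_spacing + extra
  # 0-based starts: gene i begins after i gaps and i-1 gene bodies
  starts <- cumsum(gaps[seq_len(n_genes)]) +
    c(0, cumsum(lens))[seq_len(n_genes)]
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    reference = reference,
    start = as.integer(starts),
    end = as.integer(starts + lens),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
  attr(genes, "genome") <- tibble::tibble(reference = reference,
                                          length = genome_length)
  genes
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble (0-based half-open coordinates).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  genome <- attr(genes, "genome")
  if (is.null(genome)) {
    genome <- dplyr::summarise(
      dplyr::group_by(genes, .data$reference),
      length = max(.data$end) + 1000L, .groups = "drop"
    )
  }
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", genome$reference, genome$length),
    sprintf("%s\ttagseq3p_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            genes$reference, genes$start + 1L, genes$end, genes$strand,
            genes$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Draw per-gene, per-sample ground-truth read counts
#'
#' Log-normal counts emulating detectably expressed genes; counts are floored
#' at `min_count` so every simulated 3'-end site carries enough reads for the
#' polyA validation rule to act on.
#'
#' @param genes Gene-model tibble.
#' @param sample_ids Character vector of sample ids.
#' @param meanlog,sdlog Log-normal parameters of reads per gene. Defaults
#'   `log(30)` and 0.6.
#' @param min_count Floor applied to every cell. Default 2.
#' @param seed Optional integer seed.
#' @return Count tibble (`gene_id` + one column per sample).
#' @export
simulate_truth_counts <- function(genes, sample_ids, meanlog = log(30),
                                  sdlog = 0.6, min_count = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genes)
  cols <- stats::setNames(lapply(sample_ids, function(s) {
    pmax(as.integer(round(stats::rlnorm(n, meanlog, sdlog))),
         as.integer(min_count))
  }), sample_ids)
  tibble::as_tibble(c(list(gene_id = genes$gene_id), cols))
}

# one decoy per filter criterion, placed inside a host gene
decoy_records <- function(sample_id, host, read_length) {
  pos <- host$start + 10L  # 1-based POS = start + 11
  body <- function(n) paste(sample(c("C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  half <- floor(read_length / 2)          # matched == half fails strict 50%
  specs <- list(
    low_match = list(cigar = sprintf("%dM%dS", half, read_length - half),
                     nm = 0L, as = 60L, nh = 1L),
    many_mismatch = list(cigar = sprintf("%dM", read_length), nm = 5L,
                         as = 70L, nh = 1L),
    low_score = list(cigar = sprintf("%dM", read_length), nm = 0L,
                     as = as.integer(floor(0.5 * read_length)), nh = 1L),
    multi_mapper = list(cigar = sprintf("%dM", read_length), nm = 0L,
                        as = read_length - 1L, nh = 2L)
  )
  recs <- vapply(names(specs), function(type) {
    sp <- specs[[type]]
    paste(
      sprintf("decoy_%s_%s", type, sample_id), "0", host$reference,
      pos + 1L, "255", sp$cigar, "*", "0", "0", body(read_length), "*",
      sprintf("NM:i:%d", sp$nm), sprintf("AS:i:%d", sp$as),
      sprintf("NH:i:%d", sp$nh),
      sep = "\t"
    )
  }, character(1))
  tibble::tibble(
    sample_id = sample_id,
    query_id = sprintf("decoy_%s_%s", names(specs), sample_id),
    type = names(specs),
    line = unname(recs)
  )
}

#' Simulate aligned 3' tag reads as per-sample SAM files
#'
#' For every gene and sample, emits `truth_counts[gene, sample]` single-end
#' tag alignments whose 3' ends fall within `end_window` nt of the gene's 3'
#' terminus (inside the gene body). A fraction `polya_fraction` of reads
#' carries a soft-clipped polyA tail: trailing A's on `+` genes, leading T's
#' on `-` genes (matching the reverse-complement storage convention). All
#' non-decoy records carry NM/AS/NH tags that pass the default
#' [filter_policy()]. With `decoys = TRUE`, four labelled decoy reads per
#' sample are spiked in, one violating each filter criterion.
#'
#' @param genes Gene models from [simulate_annotation()].
#' @param truth_counts Count tibble from [simulate_truth_counts()] (or any
#'   `gene_id` + sample-column tibble).
#' @param out_dir Directory for the SAM files (created if needed).
#' @param read_length Read length in nt. Default 75.
#' @param polya_fraction Fraction of reads given a polyA clip. Default 1.
#' @param tail_range Min/max clip length. Default `c(6, 12)`.
#' @param end_window Placement window for read 3' ends, nt inside the gene
#'   terminus. Default 50 (smaller than the aligned length, so one gene's
#'   reads always form a single overlap cluster).
#' @param decoys Spike in filter-violating decoy reads? Default `FALSE`.
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   files.
#' @return List: `files` (tibble `sample_id`, `path`), `truth`
#'   (`truth_counts` passed through), `decoys` (tibble of decoy read ids and
#'   the criterion each violates).
#' @export
simulate_tag_reads <- function(genes, truth_counts, out_dir,
                               read_length = 75L, polya_fraction = 1,
                               tail_range = c(6L, 12L), end_window = 50L,
                               decoys = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(truth_counts$gene_id %in% genes$gene_id))
  if (read_length - max(tail_range) <= end_window) {
    stop("end_window must be smaller than the minimum aligned length so ",
         "per-gene reads overlap", call. = FALSE)
  }
  if (any(genes$end - genes$start < end_window + read_length)) {
    stop("genes too short for the placement window", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- attr(genes, "genome")
  if (is.null(genome)) {
    genome <- dplyr::summarise(
      dplyr::group_by(genes, .data$reference),
      length = max(.data$end) + 1000L, .groups = "drop"
    )
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$reference, genome$length)
  )
  sample_ids <- setdiff(names(truth_counts), "gene_id")
  gm <- genes[match(truth_counts$gene_id, genes$gene_id), ]
  rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

  all_decoys <- list()
  files <- purrr::map(sample_ids, function(sid) {
    lines <- character(0)
    counts <- truth_counts[[sid]]
    for (i in seq_along(counts)) {
      c_i <- counts[i]
      if (c_i == 0) next
      g <- gm[i, ]
      tailed <- stats::runif(c_i) < polya_fraction
      tail_len <- ifelse(
        tailed,
        sample(tail_range[1]:tail_range[2], c_i, replace = TRUE),
        0L
      )
      aligned_len <- read_length - tail_len
      offset <- sample(0:(end_window - 1L), c_i, replace = TRUE)
      recs <- vapply(seq_len(c_i), function(j) {
        al <- aligned_len[j]
        tl <- tail_len[j]
        if (g$strand == "+") {
          aln_end <- g$end - offset[j]          # half-open end
          aln_start <- aln_end - al             # 0-based start
          cigar <- if (tl > 0) sprintf("%dM%dS", al, tl) else sprintf("%dM", al)
          seq <- paste0(paste(rand_base(al), collapse = ""), strrep("A", tl))
          flag <- 0L
        } else {
          aln_start <- g$start + offset[j]
          cigar <- if (tl > 0) sprintf("%dS%dM", tl, al) else sprintf("%dM", al)
          seq <- paste0(strrep("T", tl), paste(rand_base(al), collapse = ""))
          flag <- 16L
        }
        paste(
          sprintf("%s_%s_r%04d", sid, g$gene_id, j), flag, g$reference,
          aln_start + 1L, 255L, cigar, "*", 0L, 0L, seq, "*",
          "NM:i:0", sprintf("AS:i:%d", al), "NH:i:1",
          sep = "\t"
        )
      }, character(1))
      lines <- c(lines, recs)
    }
    if (decoys) {
      d <- decoy_records(sid, gm[1, ], read_length)
      all_decoys[[sid]] <<- dplyr::select(d, -"line")
      lines <- c(lines, d$line)
    }
    path <- file.path(out_dir, paste0(sid, ".sam"))
    writeLines(c(header, lines), path)
    tibble::tibble(sample_id = sid, path = path)
  })
  list(
    files = dplyr::bind_rows(files),
    truth = truth_counts,
    decoys = dplyr::bind_rows(all_decoys)
  )
}

#' Simulate a negative-binomial count experiment with planted effects
#'
#' Generates a gene x sample count table over time points `R1 -> D1 -> R2`
#' (rainy, dry, rainy) with three biological replicates per genotype by
#' default, planted log2 fold changes on the two transitions, and a planted
#' subset of re-regulated genes (strong response in `R1 -> D1` that is absent
#' or reversed in `D1 -> R2`). Counts are drawn from
#' `NB(mean * depth, size = 1/dispersion)`.
#'
#' @param n_genes Number of genes. Default 2000.
#' @param genotypes Character vector of genotype labels. Default `"G1"`.
#' @param time_points Ordered time points. Default `c("R1", "D1", "R2")`.
#' @param n_replicates Biological replicates per genotype x time point.
#'   Default 3.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of baseline
#'   gene means. Defaults `log(100)` and 1.
#' @param dispersion NB dispersion `alpha`. Default 0.1.
#' @param frac_de Fraction of non-re-regulated genes given a (persistent,
#'   same-direction) planted effect. Default 0.1.
#' @param lfc_values Planted log2 fold changes sampled for DE genes. Default
#'   `c(-2, -1, 1, 2)`.
#' @param n_reregulated Number of planted re-regulated genes. Default 26.
#' @param rereg_lfc Magnitude of their transition-1 log2 fold change.
#'   Default 2.
#' @param rereg_base_mean Their baseline mean. Default 200.
#' @param depth_factors Optional per-sample depth multipliers (named by
#'   sample id, or a single vector recycled over samples). Default all 1.
#' @param seed Optional integer seed.
#' @return List: `counts` (tibble), `samples` (sample sheet tibble without
#'   paths), `truth` (per-gene `base_mean`, `lfc_t1`, `lfc_t2`,
#'   `reregulated`, `rereg_type`).
#' @export
simulate_count_experiment <- function(n_genes = 2000, genotypes = "G1",
                                      time_points = c("R1", "D1", "R2"),
                                      n_replicates = 3,
                                      base_mean_meanlog = log(100),
                                      base_mean_sdlog = 1,
                                      dispersion = 0.1, frac_de = 0.1,
                                      lfc_values = c(-2, -1, 1, 2),
                                      n_reregulated = 26, rereg_lfc = 2,
                                      rereg_base_mean = 200,
                                      depth_factors = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(time_points) >= 2, n_reregulated <= n_genes)
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  base_mean <- stats::rlnorm(n_genes, base_mean_meanlog, base_mean_sdlog)
  lfc_t1 <- rep(0, n_genes)
  lfc_t2 <- rep(0, n_genes)
  rereg_type <- rep("none", n_genes)

  idx_rereg <- if (n_reregulated > 0) seq_len(n_reregulated) else integer()
  if (length(idx_rereg)) {
    sign1 <- sample(c(-1, 1), n_reregulated, replace = TRUE)
    lfc_t1[idx_rereg] <- sign1 * rereg_lfc
    reversed <- rep(c(TRUE, FALSE), length.out = n_reregulated)
    lfc_t2[idx_rereg] <- ifelse(reversed, -lfc_t1[idx_rereg], 0)
    rereg_type[idx_rereg] <- ifelse(reversed, "reversed", "sig_in_one")
    base_mean[idx_rereg] <- rereg_base_mean
  }
  rest <- setdiff(seq_len(n_genes), idx_rereg)
  n_de <- round(frac_de * length(rest))
  idx_de <- rest[seq_len(n_de)]
  if (n_de > 0) {
    eff <- sample(lfc_values, n_de, replace = TRUE)
    lfc_t1[idx_de] <- eff
    lfc_t2[idx_de] <- eff  # persistent response in the same direction
  }

  samples <- tidyr::expand_grid(
    genotype = genotypes,
    time_point = time_points,
    replicate = seq_len(n_replicates)
  )
  samples <- dplyr::mutate(
    samples,
    sample_id = paste(.data$genotype, .data$time_point, .data$replicate,
                      sep = "_"),
    .before = 1
  )
  depth <- if (is.null(depth_factors)) {
    rep(1, nrow(samples))
  } else if (!is.null(names(depth_factors))) {
    unname(depth_factors[samples$sample_id])
  } else {
    rep_len(depth_factors, nrow(samples))
  }
  # cumulative planted effects along the time course
  lfc_cum <- cbind(0, lfc_t1, lfc_t1 + lfc_t2)
  if (length(time_points) > 3) {
    lfc_cum <- cbind(lfc_cum, matrix(lfc_t1 + lfc_t2,
                                     n_genes, length(time_points) - 3))
  }
  cols <- lapply(seq_len(nrow(samples)), function(j) {
    t_idx <- match(samples$time_point[j], time_points)
    mu <- base_mean * 2^lfc_cum[, min(t_idx, ncol(lfc_cum))] * depth[j]
    stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  })
  counts <- tibble::as_tibble(
    c(list(gene_id = gene_id), stats::setNames(cols, samples$sample_id))
  )
  list(
    counts = counts,
    samples = samples,
    truth = tibble::tibble(
      gene_id = gene_id, base_mean = base_mean, lfc_t1 = lfc_t1,
      lfc_t2 = lfc_t2, reregulated = rereg_type != "none",
      rereg_type = rereg_type
    )
  )
}
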
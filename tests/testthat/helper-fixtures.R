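# In-code fixtures and independent oracles shared across the suite.

# Build an alignment tibble row-by-row without touching any file.
make_aln <- function(..., strand = "+", reference = "chr1") {
  rows <- list(...)
  dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    cg <- tagseq3p:::cigar_summary(r$cigar)
    tibble::tibble(
      query_id = r$query_id %||% paste0("q", i),
      reference = r$reference %||% reference,
      start = r$start,
      end = r$start + cg$ref_width,
      strand = r$strand %||% strand,
      cigar = r$cigar,
      read_length = cg$read_length,
      matched_length = cg$matched_length,
      n_mismatches = r$nm %||% 0L,
      align_score = r$as %||% cg$read_length,
      n_hits = r$nh %||% 1L,
      sequence = r$sequence %||% strrep("C", cg$read_length)
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a SAM file from raw record lines (tags optional per record).
write_sam <- function(path, records, refs = c(chr1 = 200000L)) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs)
  )
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos1, cigar, seq,
                       tags = c("NM:i:0", "AS:i:74", "NH:i:1")) {
  paste(c(qname, flag, rname, pos1, "255", cigar, "*", "0", "0", seq, "*",
          tags), collapse = "\t")
}

# Independent oracle: connected components of the interval-overlap graph by
# explicit union-find over all pairs (0-based half-open intervals).
brute_components <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (start[i] < end[j] && start[j] < end[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Canonical fingerprint of a clustering: sorted (span, size) summaries.
component_summary <- function(start, end, ids) {
  d <- data.frame(start = start, end = end, id = ids)
  agg <- do.call(rbind, lapply(split(d, d$id), function(g) {
    data.frame(start = min(g$start), end = max(g$end), n = nrow(g))
  }))
  agg[order(agg$start, agg$end, agg$n), , drop = FALSE]
}

# Textbook BH step-up, computed from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# A small quantification fixture: annotation + per-sample SAM files.
make_read_fixture <- function(dir, n_genes = 20, n_replicates = 3,
                              polya_fraction = 1, decoys = FALSE,
                              seed = 42, genotype = "G1", time_point = "R1") {
  genes <- simulate_annotation(n_genes = n_genes,
                               genome_length = n_genes * 10000,
                               seed = seed)
  samples <- tibble::tibble(
    genotype = genotype, time_point = time_point,
    replicate = seq_len(n_replicates),
    sample_id = paste(genotype, time_point, seq_len(n_replicates), sep = "_")
  )
  truth <- simulate_truth_counts(genes, samples$sample_id, seed = seed + 1)
  sim <- simulate_tag_reads(genes, truth, dir,
                            polya_fraction = polya_fraction,
                            decoys = decoys, seed = seed + 2)
  list(
    genes = genes,
    samples = samples,
    truth = truth,
    sheet = dplyr::inner_join(samples, sim$files, by = "sample_id"),
    decoys = sim$decoys
  )
}
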
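#' PolyA-tail detection policy
#'
#' A soft clip at the transcript-3' end of an alignment counts as polyA
#' evidence when it is at least `min_tail` bases long and its A content (T on
#' the minus strand, where the stored read is reverse-complemented) is at
#' least `min_purity`.
#'
#' @param min_tail Minimum clip length in nt. Default 5.
#' @param min_purity Minimum A (or T) fraction of the clip. Default 0.9.
#' @return A `polya_policy` object.
#' @export
polya_policy <- function(min_tail = 5L, min_purity = 0.9) {
  stopifnot(min_tail >= 1, min_purity > 0, min_purity <= 1)
  structure(
    list(min_tail = as.integer(min_tail), min_purity = min_purity),
    class = "polya_policy"
  )
}

#' Detect soft-clipped polyA tails at the transcript 3' end
#'
#' For a `+`-strand alignment the transcript 3' end is the right end, so the
#' trailing soft clip is examined for A content; for a `-`-strand alignment
#' the 3' end is the left end and the leading clip is examined for T content
#' (the file stores the reverse complement of the read). A clip at the wrong
#' end is never polyA evidence.
#'
#' @param alignments Alignment tibble with `cigar`, `strand` and `sequence`
#'   columns (see [read_alignments()]).
#' @param policy A [polya_policy()].
#' @return The input with added columns `tail_length` (length of the 3'-end
#'   soft clip, 0 if absent) and `has_polya`.
#' @export
detect_polya <- function(alignments, policy = polya_policy()) {
  stopifnot(inherits(policy, "polya_policy"))
  a <- alignments
  if (!nrow(a)) {
    return(dplyr::mutate(a, tail_length = integer(), has_polya = logical()))
  }
  cg <- cigar_summary(a$cigar)
  plus <- a$strand == "+"
  tail_length <- ifelse(plus, cg$clip_right, cg$clip_left)
  clip_seq <- ifelse(
    plus,
    substr(a$sequence, nchar(a$sequence) - tail_length + 1L,
           nchar(a$sequence)),
    substr(a$sequence, 1L, tail_length)
  )
  base <- ifelse(plus, "A", "T")
  n_base <- mapply(function(s, b) {
    if (!nchar(s)) return(0L)
    sum(strsplit(s, "", fixed = TRUE)[[1]] == b)
  }, clip_seq, base, USE.NAMES = FALSE)
  purity <- ifelse(tail_length > 0, n_base / tail_length, 0)
  dplyr::mutate(
    a,
    tail_length = as.integer(tail_length),
    has_polya = tail_length >= policy$min_tail & purity >= policy$min_purity
  )
}

# Sweep-line connected components of overlapping intervals within one
# (reference, strand) group. Intervals are 0-based half-open; two intervals
# belong to the same cluster when they are linked by a chain of pairs with
# start < running_max_end + gap. gap = 0 requires strict overlap.
overlap_components <- function(start, end, gap = 0L) {
  ord <- order(start, end)
  s <- start[ord]
  e <- end[ord]
  run_max <- cummax(e)
  new_cluster <- c(TRUE, s[-1] >= utils::head(run_max, -1) + gap)
  ids <- integer(length(s))
  ids[ord] <- cumsum(new_cluster)
  ids
}

#' Cluster overlapping read hits into tag clusters
#'
#' Builds the connected components of the interval-overlap relation among the
#' aligned spans of one sample's reads, separately per reference and strand.
#' Each cluster is a candidate transcript 3'-end site: its interval is the
#' union span of its members, `n_reads` the member count and `n_polya_reads`
#' the number of members carrying polyA evidence (from [detect_polya()]; if
#' the column is absent it is taken as zero).
#'
#' @param alignments Filtered alignment tibble for one sample.
#' @param sample_id Sample identifier recorded on each cluster.
#' @param gap Maximum separation (nt) still merged into one cluster; 0
#'   (default) requires strict overlap.
#' @return Tibble of clusters: `sample_id`, `reference`, `strand`, `start`,
#'   `end`, `n_reads`, `n_polya_reads`, ordered by (reference, strand,
#'   start). Output is invariant to the input record order.
#' @export
build_clusters <- function(alignments, sample_id, gap = 0L) {
  a <- alignments
  if (!"has_polya" %in% names(a)) a$has_polya <- FALSE
  if (!nrow(a)) {
    return(tibble::tibble(
      sample_id = character(), reference = character(), strand = character(),
      start = integer(), end = integer(), n_reads = integer(),
      n_polya_reads = integer()
    ))
  }
  a |>
    dplyr::group_by(.data$reference, .data$strand) |>
    dplyr::mutate(.cluster = overlap_components(.data$start, .data$end,
                                                gap = gap)) |>
    dplyr::group_by(.data$reference, .data$strand, .data$.cluster) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_reads = dplyr::n(),
      n_polya_reads = sum(.data$has_polya),
      .groups = "drop"
    ) |>
    dplyr::mutate(sample_id = sample_id, .before = 1) |>
    dplyr::select(-".cluster") |>
    dplyr::arrange(.data$reference, .data$strand, .data$start)
}

#' Merge per-replicate clusters into meta-clusters
#'
#' Within each biological-replicate group, clusters from different samples on
#' the same reference and strand are merged by transitive interval overlap
#' into meta-clusters — the unit on which the polyA validation rule applies.
#'
#' @param clusters Row-bound per-sample cluster tibbles (from
#'   [build_clusters()]).
#' @param replicate_sets Tibble mapping `sample_id` to a replicate `group`
#'   (e.g. genotype x time point).
#' @param gap Merge gap as in [build_clusters()].
#' @return `clusters` augmented with `group`, `meta_id`, `meta_start`,
#'   `meta_end`; one row per member cluster.
#' @export
group_replicates <- function(clusters, replicate_sets, gap = 0L) {
  stopifnot(all(c("sample_id", "group") %in% names(replicate_sets)))
  missing <- setdiff(unique(clusters$sample_id), replicate_sets$sample_id)
  if (length(missing)) {
    stop("samples present in clusters but not in replicate_sets: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(clusters)) {
    return(dplyr::mutate(clusters, group = character(), meta_id = character(),
                         meta_start = integer(), meta_end = integer()))
  }
  clusters |>
    dplyr::inner_join(
      dplyr::select(replicate_sets, "sample_id", "group"),
      by = "sample_id"
    ) |>
    dplyr::group_by(.data$group, .data$reference, .data$strand) |>
    dplyr::mutate(.meta = overlap_components(.data$start, .data$end,
                                             gap = gap)) |>
    dplyr::group_by(.data$group, .data$reference, .data$strand,
                    .data$.meta) |>
    dplyr::mutate(
      meta_start = min(.data$start),
      meta_end = max(.data$end)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      meta_id = sprintf("%s:%s:%s:%d-%d", .data$group, .data$reference,
                        .data$strand, .data$meta_start, .data$meta_end)
    ) |>
    dplyr::select(-".meta") |>
    dplyr::arrange(.data$group, .data$reference, .data$strand,
                   .data$meta_start, .data$sample_id)
}

#' Replicate-based polyA validation rule
#'
#' A meta-cluster is accepted as a genuine transcript 3' end when its polyA
#' evidence meets the replicate rule. Under `mode = "per_replicate"` (the
#' default) at least one member cluster must individually contain
#' `min_polya_reads` polyA-tailed reads; under `mode = "pooled"` the member
#' counts are summed across replicates first.
#'
#' @param n_polya_reads Integer vector of per-member polyA read counts of one
#'   meta-cluster.
#' @param min_polya_reads Required evidence. Default 2.
#' @param mode `"per_replicate"` or `"pooled"`.
#' @return Logical scalar.
#' @export
validate_metacluster <- function(n_polya_reads, min_polya_reads = 2L,
                                 mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(length(n_polya_reads) >= 1)
  if (mode == "per_replicate") {
    max(n_polya_reads) >= min_polya_reads
  } else {
    sum(n_polya_reads) >= min_polya_reads
  }
}

#' Validate all meta-clusters in a member table
#'
#' @param members Output of [group_replicates()].
#' @inheritParams validate_metacluster
#' @return `members` with a logical `validated` column (constant within each
#'   meta-cluster).
#' @export
validate_metaclusters <- function(members, min_polya_reads = 2L,
                                  mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  if (!nrow(members)) {
    return(dplyr::mutate(members, validated = logical(0)))
  }
  members |>
    dplyr::group_by(.data$group, .data$meta_id) |>
    dplyr::mutate(validated = validate_metacluster(
      .data$n_polya_reads, min_polya_reads = min_polya_reads, mode = mode
    )) |>
    dplyr::ungroup()
}

#' Assign validated meta-clusters to genes and build the count matrix
#'
#' Each validated meta-cluster is assigned to the strand-matched gene with
#' the largest overlap with the meta interval (ties broken by `gene_id`).
#' A gene's count in a sample is the sum of `n_reads` over that sample's
#' member clusters of meta-clusters assigned to the gene. Validated clusters
#' overlapping no gene are reported separately as intergenic and excluded
#' from the matrix; genes with no validated cluster get zero counts.
#'
#' @param members Validated member table from [validate_metaclusters()].
#' @param genes Gene models from [load_annotation()].
#' @param samples Sample sheet tibble with at least `sample_id` (its order
#'   fixes the column order).
#' @param stranded Require strand-matched assignment? Default `TRUE`.
#' @return A list with `counts` (tibble, `gene_id` plus one integer column
#'   per sample), `intergenic` (BED6-style tibble of unassigned validated
#'   meta-clusters) and `assignment` (meta-cluster to gene map).
#' @export
assign_and_count <- function(members, genes, samples, stranded = TRUE) {
  stopifnot("validated" %in% names(members))
  sample_ids <- samples$sample_id
  gene_ids <- sort(genes$gene_id)
  zero <- tibble::as_tibble(c(
    list(gene_id = gene_ids),
    stats::setNames(
      rep(list(rep(0L, length(gene_ids))), length(sample_ids)), sample_ids
    )
  ))
  valid <- dplyr::filter(members, .data$validated)
  metas <- dplyr::summarise(
    dplyr::group_by(valid, .data$group, .data$meta_id, .data$reference,
                    .data$strand, .data$meta_start, .data$meta_end),
    total_reads = sum(.data$n_reads), .groups = "drop"
  )
  if (!nrow(metas)) {
    return(list(
      counts = zero,
      intergenic = tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        name = character(), score = integer(), strand = character()
      ),
      assignment = tibble::tibble(meta_id = character(),
                                  gene_id = character(),
                                  overlap = integer())
    ))
  }
  bad_ref <- setdiff(unique(metas$reference), unique(genes$reference))
  if (length(bad_ref)) {
    stop("meta-cluster references absent from the annotation: ",
         paste(bad_ref, collapse = ", "), call. = FALSE)
  }
  q <- GenomicRanges::GRanges(
    metas$reference,
    IRanges::IRanges(metas$meta_start + 1L, metas$meta_end),
    strand = if (stranded) metas$strand else "*"
  )
  subj <- genes_granges(genes)
  hits <- GenomicRanges::findOverlaps(q, subj, ignore.strand = !stranded)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- if (length(qi)) {
    as.integer(GenomicRanges::width(
      GenomicRanges::pintersect(q[qi], subj[si])
    ))
  } else {
    integer()
  }
  assignment <- tibble::tibble(
    meta_id = metas$meta_id[qi],
    group = metas$group[qi],
    gene_id = genes$gene_id[si],
    overlap = ov
  ) |>
    dplyr::arrange(dplyr::desc(.data$overlap), .data$gene_id) |>
    dplyr::distinct(.data$group, .data$meta_id, .keep_all = TRUE)

  assigned <- dplyr::inner_join(valid, assignment,
                                by = c("group", "meta_id"))
  long <- assigned |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$n_reads), .groups = "drop")
  counts <- zero
  if (nrow(long)) {
    for (sid in unique(long$sample_id)) {
      sub <- long[long$sample_id == sid, ]
      m <- match(sub$gene_id, counts$gene_id)
      counts[[sid]][m] <- counts[[sid]][m] + sub$count
    }
  }
  unhit <- dplyr::anti_join(metas, assignment, by = c("group", "meta_id"))
  intergenic <- tibble::tibble(
    chrom = unhit$reference,
    start = unhit$meta_start,
    end = unhit$meta_end,
    name = unhit$meta_id,
    score = unhit$total_reads,
    strand = unhit$strand
  )
  list(counts = counts, intergenic = intergenic, assignment = assignment)
}

#' End-to-end tag-cluster quantification
#'
#' Runs the full quantifier: read alignments, apply quality filters, tally
#' polyA evidence, build per-sample overlap clusters, merge them across
#' biological replicates, validate meta-clusters by the polyA replicate rule,
#' assign validated clusters to genes, and emit the gene x sample count
#' matrix. Replicate groups are genotype x time point.
#'
#' @param sample_sheet Tibble (or path to a headered delimited file) with
#'   columns `sample_id`, `path`, `genotype`, `time_point`, `replicate`.
#' @param annotation Gene models from [load_annotation()], or a GFF3 path.
#' @param filter_policy A [filter_policy()].
#' @param polya_policy A [polya_policy()].
#' @param min_polya_reads,validation_mode Passed to
#'   [validate_metaclusters()].
#' @param gap Cluster merge gap, see [build_clusters()].
#' @param stranded Strand-matched gene assignment? Default `TRUE`.
#' @return An object of class `tag_quant`: a list with `counts`, `samples`,
#'   `intergenic`, `members` (the validated meta-cluster member table) and
#'   `log` (per-sample record counts by stage).
#' @export
quantify <- function(sample_sheet, annotation,
                     filter_policy = tagseq3p::filter_policy(),
                     polya_policy = tagseq3p::polya_policy(),
                     min_polya_reads = 2L,
                     validation_mode = c("per_replicate", "pooled"),
                     gap = 0L, stranded = TRUE) {
  validation_mode <- match.arg(validation_mode)
  if (is.character(sample_sheet) && length(sample_sheet) == 1) {
    sample_sheet <- tibble::as_tibble(
      utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
    )
  }
  need <- c("sample_id", "path", "genotype", "time_point", "replicate")
  if (!all(need %in% names(sample_sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(annotation)) annotation <- load_annotation(annotation)

  per_sample <- purrr::map(seq_len(nrow(sample_sheet)), function(i) {
    row <- sample_sheet[i, ]
    aln <- read_alignments(row$path)
    flagged <- passes_filters(aln, filter_policy)
    kept <- dplyr::filter(flagged, .data$pass)
    kept <- detect_polya(kept, polya_policy)
    cl <- build_clusters(kept, sample_id = row$sample_id, gap = gap)
    if (!nrow(kept)) {
      warning("sample '", row$sample_id, "' has no reads passing filters",
              call. = FALSE)
    }
    list(
      clusters = cl,
      log = tibble::tibble(
        sample_id = row$sample_id,
        n_records = nrow(aln),
        n_pass = nrow(kept),
        n_polya = sum(kept$has_polya),
        n_clusters = nrow(cl)
      )
    )
  })
  clusters <- dplyr::bind_rows(purrr::map(per_sample, "clusters"))
  log <- dplyr::bind_rows(purrr::map(per_sample, "log"))

  replicate_sets <- dplyr::mutate(
    sample_sheet,
    group = paste(.data$genotype, .data$time_point, sep = "_")
  )
  members <- group_replicates(clusters, replicate_sets, gap = gap)
  members <- validate_metaclusters(members,
                                   min_polya_reads = min_polya_reads,
                                   mode = validation_mode)
  res <- assign_and_count(members, annotation, sample_sheet,
                          stranded = stranded)
  structure(
    list(
      counts = res$counts,
      samples = dplyr::select(sample_sheet, -"path"),
      intergenic = res$intergenic,
      assignment = res$assignment,
      members = members,
      log = log,
      params = list(
        filter_policy = filter_policy, polya_policy = polya_policy,
        min_polya_reads = min_polya_reads,
        validation_mode = validation_mode, gap = gap, stranded = stranded
      )
    ),
    class = "tag_quant"
  )
}

#' @export
print.tag_quant <- function(x, ...) {
  cat("<tag_quant> ", nrow(x$counts), " genes x ", nrow(x$samples),
      " samples; ", sum(x$log$n_pass), " reads passing filters; ",
      nrow(x$intergenic), " intergenic meta-cluster(s)\n", sep = "")
  invisible(x)
}

#' Write an intergenic-cluster report as BED6
#'
#' @param intergenic The `intergenic` tibble from [quantify()] or
#'   [assign_and_count()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intergenic_bed <- function(intergenic, path) {
  utils::write.table(intergenic, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
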
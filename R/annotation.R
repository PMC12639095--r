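#' Load gene models from a GFF3 annotation
#'
#' Imports features of one type (by default `gene`) and converts their
#' 1-based inclusive GFF3 coordinates to the package's 0-based half-open
#' convention. Gene IDs come from the `ID` attribute.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type to keep (GFF3 column 3). Default
#'   `"gene"`.
#' @return A tibble of gene models: `gene_id`, `reference`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
load_annotation <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  keep <- types == feature_type
  if (!any(keep)) {
    stop("no '", feature_type, "' features in ", path, "; types found: ",
         paste(sort(unique(types)), collapse = ", "), call. = FALSE)
  }
  gr <- gr[keep]
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == "")) {
    stop("'", feature_type, "' features without an ID attribute in ", path,
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    gene_id = ids,
    reference = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

# Gene models -> GRanges (internal; converts back to 1-based inclusive)
genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$reference,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}

#' Genes overlapping an interval, strand-aware
#'
#' @param genes Gene-model tibble from [load_annotation()].
#' @param reference Reference (chromosome) name.
#' @param strand `"+"` or `"-"`; ignored when `stranded = FALSE`.
#' @param start,end Query interval, 0-based half-open.
#' @param stranded Require strand match? Default `TRUE`.
#' @return Tibble of overlapping gene models with an `overlap` column
#'   (overlap length in nt), sorted by decreasing overlap, ties broken by
#'   `gene_id`.
#' @export
overlapping_genes <- function(genes, reference, strand, start, end,
                              stranded = TRUE) {
  stopifnot(end > start)
  if (!reference %in% genes$reference) {
    warning("reference '", reference, "' absent from the annotation",
            call. = FALSE)
    return(dplyr::mutate(genes[0, ], overlap = integer()))
  }
  q <- GenomicRanges::GRanges(reference,
                              IRanges::IRanges(start + 1L, end),
                              strand = if (stranded) strand else "*")
  subj <- genes_granges(genes)
  hits <- GenomicRanges::findOverlaps(q, subj,
                                      ignore.strand = !stranded)
  idx <- S4Vectors::subjectHits(hits)
  if (!length(idx)) return(dplyr::mutate(genes[0, ], overlap = integer()))
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    rep(q, length(idx)), subj[idx]
  ))
  out <- dplyr::mutate(genes[idx, ], overlap = as.integer(ov))
  dplyr::arrange(out, dplyr::desc(.data$overlap), .data$gene_id)
}
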
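#' Post-alignment quality filter policy
#'
#' Thresholds applied to aligned tag reads after mapping. A record passes when
#' its matched length exceeds `min_match_frac` of the read length, it has
#' strictly fewer than `max_mismatches` mismatches, its aligner score exceeds
#' `min_score_frac` of the read length, and (if `unique_only`) it maps to a
#' single locus. All comparisons are strict.
#'
#' @param min_match_frac Minimum matched fraction of the read length
#'   (exclusive bound). Default 0.5.
#' @param max_mismatches Exclusive upper bound on mismatches (NM tag).
#'   Default 4 (i.e. at most 3 mismatches pass).
#' @param min_score_frac Minimum alignment score as a fraction of read length
#'   (exclusive bound), on the aligner's read-length score scale. Default 0.66.
#' @param unique_only Drop multi-mapping records (NH > 1)? Default `TRUE`.
#' @return A `filter_policy` object (a validated list).
#' @export
filter_policy <- function(min_match_frac = 0.5, max_mismatches = 4L,
                          min_score_frac = 0.66, unique_only = TRUE) {
  stopifnot(
    min_match_frac > 0, min_match_frac <= 1,
    min_score_frac > 0, min_score_frac <= 1,
    max_mismatches >= 1
  )
  structure(
    list(
      min_match_frac = min_match_frac,
      max_mismatches = as.integer(max_mismatches),
      min_score_frac = min_score_frac,
      unique_only = isTRUE(unique_only)
    ),
    class = "filter_policy"
  )
}

#' Read aligned tag reads from SAM or BAM into a tibble
#'
#' Reads mapped records (unmapped records are skipped) together with the
#' NM/AS/NH tags used by [passes_filters()]. SAM input is converted to BAM
#' internally via Rsamtools. Coordinates are returned 0-based half-open;
#' SAM `POS` is 1-based inclusive.
#'
#' @param path Path to a SAM or BAM file with a header naming all references.
#' @param region Optional region restriction as a `GRanges` (requires
#'   coordinate-sorted, indexable input).
#' @return A tibble with one row per mapped record: `query_id`, `reference`,
#'   `start`, `end` (0-based half-open), `strand`, `cigar`, `read_length`,
#'   `matched_length`, `n_mismatches`, `align_score`, `n_hits`, `sequence`.
#'   The header's reference lengths are attached as attribute `"references"`.
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) {
    path
  } else {
    tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = TRUE),
      error = function(e) {
        stop("unparseable SAM/BAM file '", path, "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }
  header <- tryCatch(
    Rsamtools::scanBamHeader(bam)[[1]]$targets,
    error = function(e) {
      stop("unparseable SAM/BAM header in '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  what <- c("qname", "flag", "rname", "pos", "cigar", "seq")
  tags <- c("NM", "AS", "NH")
  keep <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, tag = tags, flag = keep)
  } else {
    Rsamtools::ScanBamParam(what = what, tag = tags, flag = keep,
                            which = region)
  }
  res <- tryCatch(
    Rsamtools::scanBam(bam, param = param),
    error = function(e) {
      stop("unparseable SAM/BAM file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  res <- if (length(res) > 1) {
    # region queries return one list per range; concatenate fields
    nm <- setdiff(names(res[[1]]), "tag")
    flat <- stats::setNames(lapply(nm, function(f) {
      do.call(c, lapply(res, `[[`, f))
    }), nm)
    flat$tag <- stats::setNames(lapply(names(res[[1]]$tag), function(t) {
      do.call(c, lapply(res, function(r) r$tag[[t]]))
    }), names(res[[1]]$tag))
    flat
  } else {
    res[[1]]
  }
  n <- length(res$qname)
  tag1 <- function(x) if (is.null(x)) rep(NA_integer_, n) else x
  cg <- if (n) cigar_summary(res$cigar) else cigar_summary(character())
  refs <- as.character(res$rname)
  unknown <- setdiff(unique(refs), names(header))
  if (length(unknown)) {
    stop("records reference sequences absent from the header: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    query_id = res$qname,
    reference = refs,
    start = res$pos - 1L,
    end = res$pos - 1L + cg$ref_width,
    strand = ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+"),
    cigar = res$cigar,
    read_length = cg$read_length,
    matched_length = cg$matched_length,
    n_mismatches = tag1(res$tag$NM),
    align_score = tag1(res$tag$AS),
    n_hits = tag1(res$tag$NH),
    sequence = as.character(res$seq)
  )
  attr(out, "references") <- header
  out
}

#' Apply post-alignment quality filters with a per-criterion breakdown
#'
#' Evaluates the three mapping-quality criteria (matched fraction, mismatch
#' count, alignment score) plus the unique-mapping requirement on each record.
#' A criterion whose tag is missing (`NA`) is skipped for that record and a
#' single warning reports how many records were affected — the criterion is
#' never silently failed.
#'
#' @param alignments Tibble from [read_alignments()] (or with the same
#'   columns).
#' @param policy A [filter_policy()].
#' @return The input with added logical columns `pass_match`,
#'   `pass_mismatch`, `pass_score`, `pass_unique` and their conjunction
#'   `pass`.
#' @export
passes_filters <- function(alignments, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  a <- alignments
  pass_match <- a$matched_length > policy$min_match_frac * a$read_length
  pass_mismatch <- a$n_mismatches < policy$max_mismatches
  pass_score <- a$align_score > policy$min_score_frac * a$read_length
  pass_unique <- if (policy$unique_only) a$n_hits == 1L else rep(TRUE, nrow(a))
  skip <- function(x, label) {
    n_na <- sum(is.na(x))
    if (n_na > 0) {
      warning(sprintf("%d record(s) missing the tag for the %s criterion; criterion skipped for those records", n_na, label), call. = FALSE)
      x[is.na(x)] <- TRUE
    }
    x
  }
  pass_mismatch <- skip(pass_mismatch, "mismatch")
  pass_score <- skip(pass_score, "score")
  pass_unique <- skip(pass_unique, "unique-mapping")
  dplyr::mutate(
    a,
    pass_match = pass_match,
    pass_mismatch = pass_mismatch,
    pass_score = pass_score,
    pass_unique = pass_unique,
    pass = pass_match & pass_mismatch & pass_score & pass_unique
  )
}

#' Keep only records passing the quality filters
#'
#' @inheritParams passes_filters
#' @return The passing subset of `alignments`, without breakdown columns.
#' @export
filter_alignments <- function(alignments, policy = filter_policy()) {
  flagged <- passes_filters(alignments, policy)
  dplyr::select(
    dplyr::filter(flagged, .data$pass),
    -dplyr::starts_with("pass")
  )
}
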
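#' Split CIGAR strings into operations
#'
#' @param cigar Character vector of CIGAR strings (e.g. `"5S65M5S"`).
#' @return A list, one element per input, each a list with integer `len` and
#'   character `op` vectors in CIGAR order.
#' @keywords internal
cigar_ops <- function(cigar) {
  parts <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  lapply(parts, function(p) {
    list(
      len = as.integer(sub(".$", "", p)),
      op = substr(p, nchar(p), nchar(p))
    )
  })
}

# Per-record CIGAR arithmetic. Reference width counts M/D/N/=/X, query width
# counts M/I/S/=/X, matched length counts M/=/X only (query bases aligned to
# the reference; insertions and clips are not matches).
cigar_summary <- function(cigar) {
  ops <- cigar_ops(cigar)
  row1 <- function(o) {
    ref <- sum(o$len[o$op %in% c("M", "D", "N", "=", "X")])
    qry <- sum(o$len[o$op %in% c("M", "I", "S", "=", "X")])
    mat <- sum(o$len[o$op %in% c("M", "=", "X")])
    # soft clips sit at the ends, possibly inside hard clips
    n <- length(o$op)
    soft <- o$op == "S"
    first <- if (n >= 1 && o$op[1] == "H") 2L else 1L
    last <- if (n >= 1 && o$op[n] == "H") n - 1L else n
    clip5 <- if (first <= n && soft[first]) o$len[first] else 0L
    clip3 <- if (last >= 1 && last != first && soft[last]) o$len[last] else 0L
    if (last == first && soft[first]) clip3 <- 0L  # single-op degenerate case
    c(ref, qry, mat, clip5, clip3)
  }
  out <- vapply(ops, row1, numeric(5))
  tibble::tibble(
    ref_width = as.integer(out[1, ]),
    read_length = as.integer(out[2, ]),
    matched_length = as.integer(out[3, ]),
    clip_left = as.integer(out[4, ]),
    clip_right = as.integer(out[5, ])
  )
}

#' Aligned (matched) length of a read from its CIGAR
#'
#' Number of query bases aligned to the reference: the sum of the lengths of
#' `M`, `=` and `X` operations. Insertions, deletions, introns (`N`) and clips
#' do not count.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of matched lengths.
#' @examples
#' matched_length(c("10S60M5S", "30M100N30M15S", "20M2I20M1D20M"))
#' @export
matched_length <- function(cigar) {
  cigar_summary(cigar)$matched_length
}
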
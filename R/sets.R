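#' Disjoint-region decomposition of per-genotype gene sets
#'
#' Decomposes the union of significant gene sets (one per genotype) into the
#' disjoint membership regions of an UpSet plot: each gene falls in exactly
#' one region defined by the combination of genotypes it appears in. Region
#' counts therefore sum to the size of the union. The all-genotype
#' intersection — the shared DEGs — is attached as an attribute.
#'
#' @param sets Named list (length >= 2) of character vectors of gene ids, one
#'   per genotype.
#' @return Tibble with one row per non-empty region: one logical column per
#'   genotype, `combination` (genotype names joined by `&`), `degree`,
#'   `n_genes` and a `genes` list-column; attribute `"shared"` holds the
#'   intersection of all sets.
#' @export
shared_deg_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  union_genes <- sort(unique(unlist(sets)))
  if (!length(union_genes)) {
    out <- tibble::tibble(combination = character(), degree = integer(),
                          n_genes = integer(), genes = list())
    attr(out, "shared") <- character()
    return(out)
  }
  member <- vapply(sets, function(s) union_genes %in% s,
                   logical(length(union_genes)))
  if (length(union_genes) == 1) member <- matrix(member, nrow = 1,
                                                 dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, paste, collapse = "")
  regions <- lapply(split(seq_along(union_genes), key), function(idx) {
    flags <- member[idx[1], ]
    c(
      as.list(flags),
      list(
        combination = paste(names(sets)[flags], collapse = "&"),
        degree = sum(flags),
        n_genes = length(idx),
        genes = list(union_genes[idx])
      )
    )
  })
  out <- dplyr::bind_rows(regions)
  out <- dplyr::arrange(out, dplyr::desc(.data$degree),
                        dplyr::desc(.data$n_genes), .data$combination)
  attr(out, "shared") <- Reduce(intersect, sets)
  out
}

#' Classify gene re-regulation across two consecutive transitions
#'
#' For each gene of a shared set, compares its significance class in two
#' consecutive season transitions. A gene is re-regulated when it is a
#' significant DEG in exactly one of the transitions (`sig_in_one`) or when
#' it is significant in both with opposite direction (`reversed`) —
#' transcriptional resetting after the stress is removed.
#'
#' @param t1,t2 `tag_de`-style tibbles (with `gene_id` and `sig_class`) for
#'   transition 1 and transition 2.
#' @param shared Character vector of genes to classify; defaults to the genes
#'   present in both result sets.
#' @return Tibble: `gene_id`, `status_t1`, `status_t2`, `reregulated`,
#'   `criterion` (`sig_in_one`/`reversed`/`none`).
#' @export
classify_reregulation <- function(t1, t2, shared = NULL) {
  if (is.null(shared)) shared <- intersect(t1$gene_id, t2$gene_id)
  miss1 <- setdiff(shared, t1$gene_id)
  miss2 <- setdiff(shared, t2$gene_id)
  if (length(miss1) || length(miss2)) {
    stop("shared genes missing from the DE results: ",
         paste(unique(c(miss1, miss2)), collapse = ", "), call. = FALSE)
  }
  s1 <- t1$sig_class[match(shared, t1$gene_id)]
  s2 <- t2$sig_class[match(shared, t2$gene_id)]
  sig1 <- s1 != "ns"
  sig2 <- s2 != "ns"
  criterion <- dplyr::case_when(
    xor(sig1, sig2) ~ "sig_in_one",
    sig1 & sig2 & s1 != s2 ~ "reversed",
    TRUE ~ "none"
  )
  tibble::tibble(
    gene_id = shared,
    status_t1 = s1,
    status_t2 = s2,
    reregulated = criterion != "none",
    criterion = criterion
  )
}
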
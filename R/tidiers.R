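#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname run_pca
#' @param x A `tag_pca` object.
#' @param ... Unused.
#' @export
tidy.tag_pca <- function(x, ...) x$scores

#' @rdname run_pca
#' @export
glance.tag_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = length(x$var_explained),
    pc1_frac = x$var_explained[1],
    pc2_frac = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_,
    n_zero_variance_dropped = x$n_dropped
  )
}

#' @rdname run_pca
#' @param object A `tag_pca` object.
#' @param colour_by Metadata column used for point colour (if present in the
#'   scores).
#' @export
autoplot.tag_pca <- function(object, colour_by = NULL, ...) {
  sc <- object$scores
  lab <- function(i) sprintf("PC%d (%.1f%%)", i,
                             100 * object$var_explained[i])
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour_by) && colour_by %in% names(sc)) {
    p <- ggplot2::ggplot(
      sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                       colour = .data[[colour_by]])
    )
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_bw()
}

#' @rdname sample_correlation
#' @param x,object A `tag_cor` object.
#' @param ... Unused.
#' @export
tidy.tag_cor <- function(x, ...) {
  r <- x$r
  tibble::as_tibble(as.data.frame.table(r, responseName = "r",
                                        stringsAsFactors = FALSE)) |>
    dplyr::rename(sample_a = "Var1", sample_b = "Var2")
}

#' @rdname sample_correlation
#' @export
autoplot.tag_cor <- function(object, ...) {
  long <- tidy(object)
  long$sample_a <- factor(long$sample_a, levels = object$order)
  long$sample_b <- factor(long$sample_b, levels = object$order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0.5,
                                  limits = c(min(long$r), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname run_de
#' @param x,object A `tag_de` tibble.
#' @param ... Unused.
#' @export
tidy.tag_de <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname run_de
#' @export
glance.tag_de <- function(x, ...) {
  tibble::tibble(
    contrast = attr(x, "contrast") %||% NA_character_,
    n_genes = nrow(x),
    n_up = sum(x$sig_class == "up"),
    n_down = sum(x$sig_class == "down"),
    n_deg = sum(x$sig_class != "ns")
  )
}

#' @rdname run_de
#' @export
autoplot.tag_de <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(pmax(.data$fdr, 1e-300)),
                                  colour = .data$sig_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#B2182B", down = "#2166AC", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  colour = NULL,
                  title = attr(object, "contrast")) +
    ggplot2::theme_bw()
}
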
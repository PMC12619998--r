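#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a hit table
#'
#' Tiles query x target with fill `-log10(p)`; orientation of the best
#' alignment is overprinted when the table is small enough to read.
#'
#' @param object A `"ttl_hits"` table from [tomtom()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ttl_hits <- function(object, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$target, levels = unique(.data$target)),
    y = factor(.data$query, levels = rev(unique(.data$query))),
    fill = -log10(.data$p_value)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10 P") +
    ggplot2::labs(x = "target", y = "query") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
  if (nrow(d) <= 400) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$orientation), size = 3)
  }
  p
}

#' Bar chart of seqlet annotation counts
#' @param object A `"ttl_annotation"` from [annotate_seqlets()].
#' @param top Show at most this many motifs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ttl_annotation <- function(object, top = 20, ...) {
  d <- utils::head(object$counts, top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$n,
    y = stats::reorder(.data$match, .data$n)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "seqlets assigned", y = NULL) +
    ggplot2::theme_minimal()
}

#' Quick motif plot
#'
#' For frequency motifs, a stacked-bar logo with per-position letter heights
#' `p_a * IC` (information content in bits); for attribution motifs, grouped
#' bars of the raw contribution values.
#'
#' @param m A [motif()].
#' @return A ggplot object.
#' @export
plot_motif <- function(m) {
  stopifnot(inherits(m, "ttl_motif"))
  w <- motif_width(m)
  d <- tibble::tibble(
    letter = rep(m$alphabet, times = w),
    position = rep(seq_len(w), each = length(m$alphabet)),
    value = as.vector(m$matrix)
  )
  if (m$semantics == "frequency") {
    ic <- information_content(m)
    d$height <- d$value * ic[d$position]
    ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$height, fill = .data$letter)) +
      ggplot2::geom_col(colour = "grey30", linewidth = 0.1) +
      ggplot2::labs(title = m$name, y = "bits") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$value, fill = .data$letter)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(title = m$name, y = "contribution") +
      ggplot2::theme_minimal()
  }
}
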
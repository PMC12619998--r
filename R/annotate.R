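#' Annotate seqlets against a motif database
#'
#' Seqlets -- short spans of high-attribution positions extracted from a
#' model's attribution track, represented as CWMs (or as frequency matrices)
#' -- are compared against a motif database with [tomtom()]; each seqlet is
#' assigned its lowest-P-value database hit when that P-value passes the
#' threshold, otherwise labelled `"unassigned"`. A P threshold of 0 leaves
#' everything unassigned because P-values are strictly positive.
#'
#' @param seqlets A [motif_set()] of seqlet matrices (may be empty).
#' @param database A [motif_set()] of database motifs.
#' @param p_threshold Assignment threshold on the best hit's P-value.
#' @param ... Further arguments passed to [tomtom()] (e.g. `strand = "given"`
#'   for attribution matrices whose sign convention is strand-specific).
#' @return An object of class `"ttl_annotation"`: a list with `assignments`
#'   (tibble: `seqlet`, `match`, `p_value`, `e_value`, `offset`,
#'   `orientation`) and `counts` (tibble: `match`, `n`, assigned seqlets per
#'   database motif, descending).
#' @export
annotate_seqlets <- function(seqlets, database, p_threshold = 0.05, ...) {
  stopifnot(inherits(seqlets, "ttl_motif_set"), inherits(database, "ttl_motif_set"))
  if (length(seqlets) == 0) {
    out <- list(
      assignments = tibble::tibble(
        seqlet = character(0), match = character(0), p_value = double(0),
        e_value = double(0), offset = integer(0), orientation = character(0)
      ),
      counts = tibble::tibble(match = character(0), n = integer(0))
    )
    return(structure(out, class = "ttl_annotation"))
  }
  hits <- tomtom(seqlets, database, top_k = 1L, ...)
  assignments <- hits |>
    dplyr::transmute(
      seqlet = .data$query,
      match = dplyr::if_else(.data$p_value <= p_threshold, .data$target, "unassigned"),
      p_value = .data$p_value, e_value = .data$e_value,
      offset = .data$offset, orientation = .data$orientation
    )
  counts <- assignments |>
    dplyr::filter(.data$match != "unassigned") |>
    dplyr::count(.data$match, sort = TRUE)
  structure(list(assignments = assignments, counts = counts), class = "ttl_annotation")
}

#' @export
print.ttl_annotation <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf(
    "<seqlet annotation> %d seqlets, %d assigned to %d motifs\n",
    n, sum(x$assignments$match != "unassigned"), nrow(x$counts)
  ))
  if (nrow(x$counts) > 0) print(utils::head(x$counts, 10))
  invisible(x)
}
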
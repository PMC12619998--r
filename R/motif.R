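#' Construct a motif
#'
#' A motif is an alphabet-by-width real matrix together with its semantics:
#' `"frequency"` for position-weight matrices (PWMs), whose columns are
#' probability vectors over the alphabet, or `"attribution"` for
#' contribution-weight matrices (CWMs), whose entries carry model-attribution
#' values and may be negative or unnormalised.
#'
#' @param name Identifier string, unique within a [motif_set()].
#' @param matrix Numeric matrix with `length(alphabet)` rows (alphabet order)
#'   and one column per motif position.
#' @param alphabet Ordered character vector of symbols; default `A,C,G,T`.
#' @param semantics `"frequency"` or `"attribution"`.
#' @param background Length-`A` probability vector used for information
#'   content and for the unaligned-position adjustment; default uniform.
#'
#' @return An object of class `"ttl_motif"`.
#' @examples
#' m <- motif("ex", matrix(c(1, 0, 0, 0, 0, 0, 0, 1), nrow = 4))
#' motif_width(m)
#' @export
motif <- function(name, matrix,
                  alphabet = c("A", "C", "G", "T"),
                  semantics = c("frequency", "attribution"),
                  background = NULL) {
  semantics <- match.arg(semantics)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    rlang::abort("`matrix` must be a numeric matrix.", class = "ttl_value_error")
  }
  storage.mode(matrix) <- "double"
  if (is.null(background)) {
    background <- rep(1 / length(alphabet), length(alphabet))
  }
  m <- structure(
    list(
      name = as.character(name),
      matrix = matrix,
      alphabet = as.character(alphabet),
      semantics = semantics,
      background = as.double(background)
    ),
    class = "ttl_motif"
  )
  validate_motif(m)
}

#' Validate a motif against its type invariants
#'
#' Checks finiteness, minimum dimensions (at least one column, alphabet of at
#' least two symbols), column normalisation for frequency motifs (each column
#' must sum to 1 within `1e-4`, all entries non-negative), and background
#' normalisation. Attribution motifs carry no sign or normalisation
#' constraint. Returns the motif unchanged when every invariant holds.
#'
#' @param m A [motif()].
#' @return `m`, invisibly unchanged.
#' @export
validate_motif <- function(m) {
  stopifnot(inherits(m, "ttl_motif"))
  A <- length(m$alphabet)
  if (A < 2) {
    rlang::abort("Alphabet must have at least 2 symbols.", class = "ttl_value_error")
  }
  if (ncol(m$matrix) < 1) {
    rlang::abort(
      sprintf("Motif '%s' has zero width.", m$name),
      class = "ttl_width_error"
    )
  }
  if (nrow(m$matrix) != A) {
    rlang::abort(
      sprintf(
        "Motif '%s': matrix has %d rows but alphabet has %d symbols.",
        m$name, nrow(m$matrix), A
      ),
      class = "ttl_shape_error"
    )
  }
  if (!all(is.finite(m$matrix))) {
    rlang::abort(
      sprintf("Motif '%s' contains non-finite entries.", m$name),
      class = "ttl_value_error"
    )
  }
  if (length(m$background) != A || any(m$background < 0) ||
    abs(sum(m$background) - 1) > 1e-9) {
    rlang::abort(
      sprintf("Motif '%s': background is not a probability vector.", m$name),
      class = "ttl_value_error"
    )
  }
  if (m$semantics == "frequency") {
    if (any(m$matrix < 0)) {
      rlang::abort(
        sprintf("Motif '%s': frequency matrix has negative entries.", m$name),
        class = "ttl_normalization_error"
      )
    }
    csum <- colSums(m$matrix)
    if (any(abs(csum - 1) > 1e-4)) {
      bad <- which(abs(csum - 1) > 1e-4)[1]
      rlang::abort(
        sprintf(
          "Motif '%s': column %d sums to %.6f (must be 1 within 1e-4).",
          m$name, bad, csum[bad]
        ),
        class = "ttl_normalization_error"
      )
    }
  }
  m
}

#' @export
print.ttl_motif <- function(x, ...) {
  cat(sprintf(
    "<motif '%s'> %s, %d x %d (%s)\n",
    x$name, x$semantics, nrow(x$matrix), ncol(x$matrix),
    paste(x$alphabet, collapse = "")
  ))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Motif width (number of positions)
#' @param m A [motif()].
#' @return Integer number of columns.
#' @export
motif_width <- function(m) ncol(m$matrix)

#' Reverse complement of a motif
#'
#' Columns are reversed and rows are swapped positionally, row `i` with row
#' `A - 1 - i` (0-based), which for the default `ACGT` order pairs A with T
#' and C with G. Only 4-letter alphabets are complemented; other alphabets
#' are rejected rather than silently mis-complemented.
#'
#' @param m A [motif()] over a 4-symbol alphabet.
#' @return The reverse-complement motif (same width and semantics).
#' @export
reverse_complement <- function(m) {
  stopifnot(inherits(m, "ttl_motif"))
  A <- length(m$alphabet)
  if (A != 4) {
    rlang::abort(
      sprintf("Reverse complement requires a 4-letter alphabet (got %d).", A),
      class = "ttl_alphabet_error"
    )
  }
  out <- m
  out$matrix <- rc_matrix(m$matrix)
  out
}

# positional complement + reversal of an A x W matrix (internal; no validation)
rc_matrix <- function(x) {
  x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE]
}

#' Per-column information content in bits
#'
#' For a frequency motif, column information content is the Kullback-Leibler
#' divergence from the background, `sum_a p_a * log2(p_a / bg_a)`, with
#' `0 * log 0` taken as 0. The total information content of the motif is the
#' sum over columns.
#'
#' @param m A frequency [motif()].
#' @return Numeric vector of per-column bits; `sum()` gives the total.
#' @export
information_content <- function(m) {
  stopifnot(inherits(m, "ttl_motif"))
  if (m$semantics != "frequency") {
    rlang::abort(
      "Information content is defined for frequency motifs only.",
      class = "ttl_semantics_error"
    )
  }
  p <- m$matrix
  lr <- log2(p / m$background)
  lr[p == 0] <- 0
  colSums(p * lr)
}

#' Construct a motif set
#'
#' An ordered collection of motifs sharing one alphabet, with unique names.
#'
#' @param motifs List of [motif()] objects.
#' @param source Provenance string (file path, generator call, ...).
#' @return An object of class `"ttl_motif_set"`; motifs are retrievable by
#'   name with `$motifs[[name]]` and the set supports `length()` and `[`.
#' @export
motif_set <- function(motifs, source = "") {
  if (!is.list(motifs) || !all(vapply(motifs, inherits, TRUE, "ttl_motif"))) {
    rlang::abort("`motifs` must be a list of motif objects.", class = "ttl_value_error")
  }
  nm <- vapply(motifs, function(m) m$name, "")
  if (anyDuplicated(nm)) {
    rlang::abort(
      sprintf(
        "Duplicate motif names: %s.",
        paste(unique(nm[duplicated(nm)]), collapse = ", ")
      ),
      class = "ttl_uniqueness_error"
    )
  }
  if (length(motifs) > 0) {
    alph <- motifs[[1]]$alphabet
    same <- vapply(motifs, function(m) identical(m$alphabet, alph), TRUE)
    if (!all(same)) {
      rlang::abort("All motifs in a set must share one alphabet.", class = "ttl_alphabet_error")
    }
  }
  names(motifs) <- nm
  structure(list(motifs = motifs, source = source), class = "ttl_motif_set")
}

#' @export
length.ttl_motif_set <- function(x) length(x$motifs)

#' @export
`[.ttl_motif_set` <- function(x, i) motif_set(x$motifs[i], source = x$source)

#' @export
print.ttl_motif_set <- function(x, ...) {
  cat(sprintf("<motif set> %d motifs", length(x$motifs)))
  if (nzchar(x$source)) cat(sprintf(" [%s]", x$source))
  cat("\n")
  if (length(x$motifs) > 0) {
    w <- vapply(x$motifs, motif_width, 1L)
    cat(sprintf(
      "  names: %s\n  widths: %d-%d\n",
      paste(utils::head(names(x$motifs), 5), collapse = ", "),
      min(w), max(w)
    ))
  }
  invisible(x)
}

motif_names <- function(s) names(s$motifs)

set_alphabet <- function(s) {
  if (length(s$motifs) == 0) c("A", "C", "G", "T") else s$motifs[[1]]$alphabet
}
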
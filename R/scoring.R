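#' Similarity score between two aligned motif columns
#'
#' The per-column summand of the ungapped alignment score. Two kinds are
#' provided: `"neg_euclidean"` (negative Euclidean distance, maximal at 0 for
#' identical columns) and `"pearson"` (sample correlation, in `[-1, 1]`).
#' Both are symmetric in their arguments. Pearson correlation against a
#' constant column is defined as 0 rather than an error.
#'
#' @param q,t Numeric vectors of equal length (one column each).
#' @param kind `"neg_euclidean"` (default) or `"pearson"`.
#' @return A single numeric score (higher = more similar).
#' @export
column_score <- function(q, t, kind = c("neg_euclidean", "pearson")) {
  kind <- match.arg(kind)
  if (length(q) != length(t)) {
    rlang::abort("Column lengths differ.", class = "ttl_shape_error")
  }
  drop(score_columns(matrix(q, ncol = 1), matrix(t, ncol = 1), kind))
}

# Score every column of Q (A x w) against every column of C (A x m).
# Computed one query column at a time with per-column reductions so results
# do not depend on how the target columns are batched (hashing on/off must
# be bit-identical).
score_columns <- function(Q, C, kind = c("neg_euclidean", "pearson")) {
  kind <- match.arg(kind)
  w <- ncol(Q)
  m <- ncol(C)
  out <- matrix(0, w, m)
  if (kind == "neg_euclidean") {
    A <- nrow(C)
    for (i in seq_len(w)) {
      D <- (C - Q[, i])^2
      # pair row k with row A+1-k before summing: reversal (and hence
      # reverse complementation) permutes terms only within commutative
      # two-term sums, so scores against a column and against its reverse
      # complement round identically
      d2 <- if (A == 4) (D[1, ] + D[4, ]) + (D[2, ] + D[3, ]) else colSums(D)
      d2[d2 < 0] <- 0
      out[i, ] <- -sqrt(d2)
    }
  } else {
    cc <- sweep(C, 2, colMeans(C), "-")
    css <- colSums(cc^2)
    flat <- css == 0
    if (any(flat)) {
      rlang::inform("Pearson score against a constant column defined as 0.")
    }
    for (i in seq_len(w)) {
      qc <- Q[, i] - mean(Q[, i])
      qss <- sum(qc^2)
      if (qss == 0) {
        out[i, ] <- 0
        next
      }
      r <- colSums(cc * qc) / sqrt(qss * css)
      r[flat] <- 0
      out[i, ] <- r
    }
  }
  out
}

#' Deduplicate target-database columns (column hashing)
#'
#' Collects every column of every target motif (and, in `"both"` strand mode,
#' every column of each reverse complement), groups bitwise-identical columns
#' (keys are rounded to `10^-digits` first so formatting noise does not split
#' equal columns), and returns the distinct columns with integer
#' multiplicities plus a position-to-slot map. Scoring the distinct slots and
#' expanding through the map is exactly equivalent to scoring every column.
#'
#' @param targets A [motif_set()].
#' @param strand `"given"` (use targets as written) or `"both"` (also index
#'   reverse-complement columns).
#' @param hash If `FALSE`, every column gets its own slot (multiplicity 1);
#'   results downstream are identical either way.
#' @param digits Decimal places of the rounding applied to hash keys.
#' @return An object of class `"ttl_column_table"` with elements `columns`
#'   (A x m matrix of distinct columns), `mult` (integer multiplicities),
#'   `slots` (per target: slot indices of its `plus` columns and, in both
#'   mode, of the columns of its reverse complement as `minus`), `n_total`,
#'   and `lengths` (target widths).
#' @export
hash_target_columns <- function(targets, strand = c("both", "given"),
                                hash = TRUE, digits = 6) {
  strand <- match.arg(strand)
  stopifnot(inherits(targets, "ttl_motif_set"))
  if (length(targets) == 0) {
    rlang::abort("Empty target set.", class = "ttl_empty_input_error")
  }
  if (strand == "both" && length(set_alphabet(targets)) != 4) {
    rlang::abort(
      "Both-strand mode requires a 4-letter alphabet.",
      class = "ttl_alphabet_error"
    )
  }
  mats <- lapply(targets$motifs, function(m) m$matrix)
  widths <- vapply(mats, ncol, 1L)
  all_cols <- do.call(cbind, mats)
  if (strand == "both") {
    all_cols <- cbind(all_cols, do.call(cbind, lapply(mats, rc_matrix)))
  }
  ncols <- ncol(all_cols)

  if (hash) {
    keys <- apply(round(all_cols, digits), 2, paste, collapse = ",")
    slot_id <- match(keys, unique(keys)) # slot = rank of first occurrence
    columns <- all_cols[, !duplicated(keys), drop = FALSE]
    mult <- tabulate(slot_id, nbins = ncol(columns))
  } else {
    slot_id <- seq_len(ncols)
    columns <- all_cols
    mult <- rep(1L, ncols)
  }

  # cut the flat slot vector back into per-target (and per-strand) pieces
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  slots <- vector("list", length(mats))
  names(slots) <- names(targets$motifs)
  for (k in seq_along(mats)) {
    entry <- list(plus = slot_id[starts[k]:ends[k]])
    if (strand == "both") {
      off <- sum(widths)
      entry$minus <- slot_id[(off + starts[k]):(off + ends[k])]
    }
    slots[[k]] <- entry
  }

  structure(
    list(
      columns = columns, mult = as.integer(mult), slots = slots,
      n_total = ncols, lengths = widths, strand = strand, hashed = hash
    ),
    class = "ttl_column_table"
  )
}

#' @export
print.ttl_column_table <- function(x, ...) {
  cat(sprintf(
    "<column table> %d distinct columns for %d total (%d targets, strand=%s)\n",
    ncol(x$columns), x$n_total, length(x$slots), x$strand
  ))
  invisible(x)
}

#' Center raw column scores on their per-query-column median
#'
#' For each query column (each row of `scores`), the median of its scores
#' against every target-database column -- weighted by column multiplicity --
#' is subtracted. This is what makes alignment scores comparable across query
#' columns of different information content. The `"approximate"` method takes
#' the midpoint of the histogram bin containing the 50% mass point (histogram
#' of `bins` equal-width bins over that row's range), which by construction
#' agrees with the exact weighted median within one final quantization bin
#' width.
#'
#' @param scores Numeric matrix, query columns x distinct target columns.
#' @param mult Integer multiplicities of the target columns (default all 1).
#' @param method `"exact"` or `"approximate"`.
#' @param bins Histogram bin count used by the approximate method.
#' @return List with `medians` (per row) and `centered` (scores - medians).
#' @export
center_scores <- function(scores, mult = NULL,
                          method = c("exact", "approximate"), bins = 100L) {
  method <- match.arg(method)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) == 0) {
    rlang::abort("Empty target database.", class = "ttl_empty_input_error")
  }
  if (is.null(mult)) mult <- rep(1L, ncol(scores))
  medians <- apply(scores, 1, function(v) {
    if (method == "exact") {
      weighted_median(v, mult)
    } else {
      histogram_median(v, mult, bins)
    }
  })
  list(medians = medians, centered = scores - medians)
}

# exact weighted median: the median of each value repeated `w` times
weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]
  w <- w[o]
  n <- sum(w)
  cw <- cumsum(w)
  k1 <- (n + 1) %/% 2
  k2 <- n %/% 2 + 1
  i1 <- which(cw >= k1)[1]
  i2 <- which(cw >= k2)[1]
  (v[i1] + v[i2]) / 2
}

# approximate median: midpoint of the histogram bin holding the 50% mass point
histogram_median <- function(v, w, bins) {
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) {
    return(lo)
  }
  bw <- (hi - lo) / bins
  idx <- pmin(floor((v - lo) / bw), bins - 1) + 1
  counts <- as.numeric(tapply(w, factor(idx, levels = seq_len(bins)), sum, default = 0))
  b <- which(cumsum(counts) >= sum(w) / 2)[1]
  lo + (b - 0.5) * bw
}

#' Quantize centered scores into integer bins
#'
#' Uniform-width bins over `range`; the lower endpoint maps to bin 0 and the
#' upper endpoint to bin `bins - 1`. Quantization is monotone, and a value
#' reconstructed at its bin midpoint is within half a bin width of the
#' original. A degenerate range (max = min) yields a single-bin grid.
#'
#' @param x Numeric vector or matrix of centered scores.
#' @param bins Number of bins, at least 2.
#' @param range Length-2 numeric covering the observed scores.
#' @return Integer object shaped like `x`, with attributes `range`,
#'   `bin_width` and `bins` (the effective bin count).
#' @export
quantize <- function(x, bins = 100L, range = base::range(x)) {
  if (bins < 2) rlang::abort("Need at least 2 bins.", class = "ttl_value_error")
  lo <- range[1]
  hi <- range[2]
  if (hi <= lo) {
    out <- x
    out[] <- 0L
    storage.mode(out) <- "integer"
    rlang::inform("Degenerate score range; using a single bin.")
    return(structure(out, range = c(lo, hi), bin_width = 0, bins = 1L))
  }
  bw <- (hi - lo) / bins
  out <- pmin(floor((x - lo) / bw), bins - 1)
  out[out < 0] <- 0
  storage.mode(out) <- "integer"
  structure(out, range = c(lo, hi), bin_width = bw, bins = as.integer(bins))
}

bin_midpoint <- function(b, range, bin_width) {
  if (bin_width == 0) {
    return(rep(range[1], length(b)))
  }
  range[1] + (b + 0.5) * bin_width
}

#' Build the binned score grid for one query against a column table
#'
#' Runs the scoring stage end to end for a single query motif: raw column
#' scores of every query column (plus, when the unaligned-position adjustment
#' is enabled, one background column) against every distinct target column,
#' median centering, and integer quantization.
#'
#' @param query A [motif()].
#' @param coltab A [hash_target_columns()] table.
#' @param score Column score kind, see [column_score()].
#' @param bins Quantization bin count.
#' @param median_method `"exact"` or `"approximate"`, see [center_scores()].
#' @param adjust Include the background row used by the unaligned-position
#'   adjustment.
#' @return An object of class `"ttl_score_grid"`.
#' @export
score_grid <- function(query, coltab, score = c("neg_euclidean", "pearson"),
                       bins = 100L, median_method = c("exact", "approximate"),
                       adjust = TRUE) {
  score <- match.arg(score)
  median_method <- match.arg(median_method)
  stopifnot(inherits(query, "ttl_motif"), inherits(coltab, "ttl_column_table"))
  if (nrow(query$matrix) != nrow(coltab$columns)) {
    rlang::abort("Query and target alphabets differ in size.", class = "ttl_alphabet_error")
  }
  Q <- query$matrix
  if (adjust) Q <- cbind(Q, query$background)
  raw <- score_columns(Q, coltab$columns, score)
  cen <- center_scores(raw, coltab$mult, method = median_method, bins = bins)
  binned <- quantize(cen$centered, bins = bins)
  structure(
    list(
      binned = binned,
      bins = attr(binned, "bins"),
      range = attr(binned, "range"),
      bin_width = attr(binned, "bin_width"),
      medians = cen$medians,
      mult = coltab$mult,
      n_total = coltab$n_total,
      w = motif_width(query),
      has_bg = adjust,
      score_kind = score,
      query_name = query$name
    ),
    class = "ttl_score_grid"
  )
}

#' @export
print.ttl_score_grid <- function(x, ...) {
  cat(sprintf(
    "<score grid> query '%s' (w=%d%s) x %d distinct columns, %d bins [%s]\n",
    x$query_name, x$w, if (x$has_bg) " + bg" else "", ncol(x$binned),
    x$bins, x$score_kind
  ))
  invisible(x)
}
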
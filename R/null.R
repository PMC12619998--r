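#' Binned score distribution
#'
#' Probability mass over the integer score support `offset + 0:(length(pmf)-1)`.
#' Mass is accumulated in double precision and renormalised once at
#' construction when `|1 - sum|` exceeds `1e-12`.
#'
#' @param pmf Non-negative numeric vector summing to 1.
#' @param offset Integer mapping bin index 1 back to score space.
#' @return An object of class `"ttl_binned_dist"`.
#' @export
binned_dist <- function(pmf, offset = 0L) {
  pmf <- as.double(pmf)
  pmf[pmf < 0] <- 0 # FFT convolution can leave -1e-17 noise
  s <- sum(pmf)
  if (s <= 0) rlang::abort("Empty distribution.", class = "ttl_value_error")
  if (abs(1 - s) > 1e-12) pmf <- pmf / s
  structure(list(pmf = pmf, offset = as.integer(offset)), class = "ttl_binned_dist")
}

#' @export
print.ttl_binned_dist <- function(x, ...) {
  cat(sprintf(
    "<binned distribution> support [%d, %d], mass 1 within %.1e\n",
    x$offset, x$offset + length(x$pmf) - 1L, abs(1 - sum(x$pmf))
  ))
  invisible(x)
}

#' Survival function of a binned distribution
#' @param d A [binned_dist()].
#' @return Numeric vector `Q[i] = P(X >= support[i])`, same length as the pmf.
#' @export
survival_function <- function(d) {
  rev(cumsum(rev(d$pmf)))
}

# Open (full) convolution of two pmf vectors by direct summation (compiled;
# see src/conv.cpp). Direct summation of non-negative products keeps
# *relative* precision in the far tail, where FFT convolution only bounds
# the absolute error and would corrupt small P-values.
conv_pmf <- function(a, b) {
  if (length(b) == 1) {
    return(a * b[1])
  }
  if (length(a) == 1) {
    return(b * a[1])
  }
  .conv_dense(a, b)
}

#' Null distribution of one query column's score against a random target column
#'
#' The empirical, multiplicity-weighted distribution of the binned score of
#' query column `i` across all distinct target-column slots: the elementary
#' null from which alignment nulls are built by convolution.
#'
#' @param grid A [score_grid()].
#' @param i Query column index (use `"bg"` for the background row).
#' @return A [binned_dist()] over bins `0:(bins-1)`.
#' @export
column_null <- function(grid, i) {
  stopifnot(inherits(grid, "ttl_score_grid"))
  row <- grid_row(grid, i)
  counts <- numeric(grid$bins)
  tb <- rowsum(as.numeric(grid$mult), group = row)
  counts[as.integer(rownames(tb)) + 1L] <- tb
  binned_dist(counts / sum(grid$mult), offset = 0L)
}

grid_row <- function(grid, i) {
  if (identical(i, "bg")) {
    if (!grid$has_bg) {
      rlang::abort("Grid was built without a background row.", class = "ttl_value_error")
    }
    grid$binned[grid$w + 1L, ]
  } else {
    stopifnot(i >= 1, i <= grid$w)
    grid$binned[i, ]
  }
}

#' Null distribution of the alignment score over a run of query columns
#'
#' Under the null, target columns are independent draws from the database's
#' empirical column distribution, so the score of an alignment covering query
#' columns `cols` is the convolution of their per-column nulls.
#'
#' @param grid A [score_grid()].
#' @param cols Contiguous run of query column indices.
#' @return A [binned_dist()] over `0:(length(cols) * (bins - 1))`.
#' @export
sum_null <- function(grid, cols) {
  if (length(cols) == 0) {
    rlang::abort("Empty column run.", class = "ttl_empty_input_error")
  }
  pmf <- column_null(grid, cols[1])$pmf
  for (i in cols[-1]) {
    pmf <- conv_pmf(pmf, column_null(grid, i)$pmf)
  }
  binned_dist(pmf)
}

#' Apply the unaligned-position adjustment to an alignment null
#'
#' With the adjustment, every target column is scored: target positions not
#' covered by the query are scored against a background column (equivalently,
#' the query is padded with background columns). For a null distribution over
#' an `overlap`-column alignment this convolves in `n_t - overlap` copies of
#' the background-column null. When `overlap = min(w_q, n_t)` and
#' `n_t <= w_q` there are no unaligned target positions and the adjustment is
#' the identity.
#'
#' @param x A [binned_dist()] (or bare pmf vector) for the aligned columns.
#' @param overlap Number of aligned columns, in `[1, min(w_q, n_t)]`.
#' @param n_t Target width.
#' @param grid The [score_grid()] supplying the background-column null (must
#'   have been built with `adjust = TRUE`).
#' @return A [binned_dist()] over `0:(n_t * (bins - 1))`.
#' @export
adjust_for_unaligned <- function(x, overlap, n_t, grid) {
  w_q <- grid$w
  if (overlap < 1 || overlap > min(w_q, n_t)) {
    rlang::abort(
      sprintf("Overlap %d outside [1, %d].", overlap, min(w_q, n_t)),
      class = "ttl_value_error"
    )
  }
  pmf <- if (inherits(x, "ttl_binned_dist")) x$pmf else as.double(x)
  extra <- n_t - overlap
  if (extra > 0) {
    pmf <- conv_pmf(pmf, pmf_power(column_null(grid, "bg")$pmf, extra))
  }
  binned_dist(pmf)
}

# k-fold self-convolution (k >= 0; k = 0 is the point mass at 0)
pmf_power <- function(pmf, k) {
  out <- 1
  for (i in seq_len(k)) out <- conv_pmf(out, pmf)
  out
}

#' Exact null distribution of the maximum ungapped-alignment score
#'
#' The engine's core statistic. A query of width `w_q` admits ungapped
#' offsets `-(w_q - 1), ..., n_t - 1` against a width-`n_t` target (each with
#' overlap at least one column); in both-strand mode the offset set is
#' doubled across orientations. Under the null each offset's alignment score
#' is the sum of independent binned column scores (plus, with the
#' unaligned-position adjustment, background-column scores for uncovered
#' target positions), and the offsets are independent draws, so the maximum
#' has survival function `Q(x) = 1 - prod_o F_o(x - 1)` with each per-offset
#' CDF `F_o` built exactly by convolution. The product is accumulated in log
#' space (`log1p` of per-offset survivals) so far-tail P-values keep relative
#' precision.
#'
#' @param grid A [score_grid()] for the query.
#' @param n_t Target width (number of columns), at least 1.
#' @param strand `"both"` or `"given"`.
#' @param adjust Apply the unaligned-position adjustment (requires a grid
#'   built with its background row).
#' @return A [binned_dist()] with a precomputed `survival` element.
#' @export
max_alignment_null <- function(grid, n_t, strand = c("both", "given"),
                               adjust = TRUE) {
  strand <- match.arg(strand)
  stopifnot(inherits(grid, "ttl_score_grid"))
  w <- grid$w
  if (w < 1 || n_t < 1) {
    rlang::abort("Query and target widths must be at least 1.", class = "ttl_value_error")
  }
  if (adjust && !grid$has_bg) {
    rlang::abort(
      "Adjusted null requires a grid built with adjust = TRUE.",
      class = "ttl_value_error"
    )
  }
  B <- grid$bins
  S <- if (adjust) n_t * (B - 1L) else min(w, n_t) * (B - 1L)

  col_pmfs <- lapply(seq_len(w), function(i) column_null(grid, i)$pmf)
  bg_pow <- NULL
  if (adjust) {
    bg <- column_null(grid, "bg")$pmf
    bg_pow <- vector("list", n_t) # bg_pow[[k+1]] = bg^(*k)
    bg_pow[[1]] <- 1
    for (k in seq_len(n_t - 1)) bg_pow[[k + 1]] <- conv_pmf(bg_pow[[k]], bg)
  }

  # Every admissible offset aligns either a prefix (query overhangs the
  # right end), a suffix (overhangs the left end), or all of the query, so
  # only prefix and suffix run convolutions are ever needed; build each
  # family incrementally in O(w) convolutions.
  prefix <- vector("list", w) # prefix[[b]] = conv of columns 1..b
  prefix[[1]] <- col_pmfs[[1]]
  for (b in seq_len(w - 1L)) prefix[[b + 1L]] <- conv_pmf(prefix[[b]], col_pmfs[[b + 1L]])
  suffix <- vector("list", w) # suffix[[a]] = conv of columns a..w
  suffix[[w]] <- col_pmfs[[w]]
  if (w > 1L) {
    for (a in seq(w - 1L, 1L)) suffix[[a]] <- conv_pmf(col_pmfs[[a]], suffix[[a + 1L]])
  }
  run_pmf <- function(a, b) {
    if (a == 1L) {
      return(prefix[[b]])
    }
    if (b == w) {
      return(suffix[[a]])
    }
    # n_t < w can require interior runs (query overhangs both ends)
    out <- col_pmfs[[a]]
    if (b > a) {
      for (i in seq(a + 1L, b)) out <- conv_pmf(out, col_pmfs[[i]])
    }
    out
  }

  log_cdf_sum <- numeric(S + 1L)
  for (o in seq(-(w - 1L), n_t - 1L)) {
    a <- max(0L, -o) + 1L
    b <- min(w, n_t - o)
    k <- b - a + 1L
    pmf_o <- run_pmf(a, b)
    if (adjust && n_t - k > 0) pmf_o <- conv_pmf(pmf_o, bg_pow[[n_t - k + 1L]])
    q_o <- rev(cumsum(rev(pmf_o))) # P(S_o >= x) on the offset's own support
    q_o <- pmin(pmax(q_o, 0), 1)
    # embed into the common support [0, S]: survival is 0 above it
    lc <- log1p(-c(q_o, numeric(S + 1L - length(q_o))))
    log_cdf_sum <- log_cdf_sum + lc
  }
  if (strand == "both") log_cdf_sum <- 2 * log_cdf_sum

  surv <- -expm1(log_cdf_sum) # Q(x) = 1 - prod_o F_o(x - 1)
  surv <- pmin(pmax(surv, 0), 1)
  pmf <- surv - c(surv[-1L], 0)
  pmf[pmf < 0] <- 0
  out <- binned_dist(pmf, offset = 0L)
  out$survival <- surv
  out
}

#' Convert an observed maximum score to its P-value
#'
#' Inclusive survival `P(X >= x)` under the null, which keeps the test
#' conservative under quantization ties. Scores below the support give 1;
#' scores above it give the smallest positive representable value rather
#' than 0.
#'
#' @param null A [binned_dist()], typically from [max_alignment_null()].
#' @param x Observed integer score (sum of binned column scores).
#' @return P-value in `(0, 1]`.
#' @export
pvalue <- function(null, x) {
  stopifnot(inherits(null, "ttl_binned_dist"))
  surv <- null$survival
  if (is.null(surv)) surv <- survival_function(null)
  idx <- x - null$offset + 1L
  if (idx <= 0) {
    return(1)
  }
  if (idx > length(surv)) {
    return(.Machine$double.xmin)
  }
  max(surv[idx], .Machine$double.xmin)
}

#' Create an empty null-distribution cache
#'
#' Null distributions of the maximum alignment score depend on the query's
#' grid, the target *length*, the strand mode, and the scoring configuration
#' -- not on the target's actual columns -- so two equal-length targets under
#' one query share one entry. A cache hit returns the stored object itself,
#' so cached and recomputed runs are bitwise identical.
#'
#' @return An environment used as a key-value store.
#' @export
new_null_cache <- function() new.env(parent = emptyenv())

# key includes a digest of everything the null depends on, so a
# configuration change can never serve a stale distribution
null_cache_key <- function(grid, n_t, strand, adjust) {
  paste(grid$query_name, n_t, strand, adjust,
    grid$score_kind, grid$bins, grid$has_bg,
    format(grid$range[1], digits = 17), format(grid$range[2], digits = 17),
    sep = "|"
  )
}

cached_max_null <- function(cache, grid, n_t, strand, adjust) {
  if (is.null(cache)) {
    return(max_alignment_null(grid, n_t, strand, adjust))
  }
  key <- null_cache_key(grid, n_t, strand, adjust)
  val <- cache[[key]]
  if (is.null(val)) {
    val <- max_alignment_null(grid, n_t, strand, adjust)
    cache[[key]] <- val
  }
  val
}
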
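#' Compare query motifs against a target motif database
#'
#' For every query-target pair, scores all ungapped alignments (every offset,
#' and both orientations in `"both"` strand mode), keeps the maximum
#' similarity score, and converts it to a P-value under the exact binned null
#' distribution of that maximum. The null for a pair depends only on the
#' query, the target's width, and the scoring configuration, so it is cached
#' across targets of equal length. E-values are `p * n_targets`;
#' Benjamini-Hochberg q-values are computed per query across its targets.
#'
#' Results are deterministic: they do not depend on `threads`, on `cache`,
#' or (for databases whose duplicated columns are bitwise equal) on `hash`.
#'
#' @param queries,targets [motif_set()]s sharing one alphabet.
#' @param score Column score kind, see [column_score()].
#' @param bins Integer quantization bin count (default 100).
#' @param strand `"both"` scores each target as given and reverse
#'   complemented; `"given"` uses only the written orientation (use for CWMs
#'   or non-DNA alphabets).
#' @param adjust Apply the unaligned-position adjustment: uncovered target
#'   positions contribute the query-background column score, so scores at
#'   different overlaps are comparable.
#' @param median_method Median used for score centering, see [center_scores()].
#' @param hash Deduplicate target-database columns before scoring.
#' @param cache Reuse max-score nulls across equal-length targets.
#' @param threads Partition queries over this many worker processes; the
#'   per-query pipeline is sequential, so any thread count yields the same
#'   table.
#' @param p_threshold Optional filter: keep hits with `p_value <= p_threshold`.
#' @param top_k Optional filter: keep the `top_k` best hits per query.
#' @param verbose Emit per-stage timing and cache statistics.
#'
#' @return A tibble of class `"ttl_hits"` with one row per retained pair:
#'   `query`, `target`, `score` (bin-midpoint reconstructed centered score),
#'   `offset` (query start relative to target start, 0-based, negative when
#'   the query overhangs on the left; for `-` orientation relative to the
#'   reverse-complemented target), `orientation`, `overlap`, `p_value`,
#'   `e_value`, `q_value`; sorted by query (input order) then p-value.
#' @examples
#' db <- random_pwm_set(5, width = c(6, 8), seed = 1)
#' hits <- tomtom(db[1], db)
#' head(hits, 3)
#' @export
tomtom <- function(queries, targets,
                   score = c("neg_euclidean", "pearson"),
                   bins = 100L,
                   strand = c("both", "given"),
                   adjust = TRUE,
                   median_method = c("exact", "approximate"),
                   hash = TRUE,
                   cache = TRUE,
                   threads = 1L,
                   p_threshold = NULL,
                   top_k = NULL,
                   verbose = FALSE) {
  score <- match.arg(score)
  strand <- match.arg(strand)
  median_method <- match.arg(median_method)
  stopifnot(inherits(queries, "ttl_motif_set"), inherits(targets, "ttl_motif_set"))
  if (length(queries) == 0 || length(targets) == 0) {
    rlang::abort("Query and target sets must be non-empty.", class = "ttl_empty_input_error")
  }
  if (!identical(set_alphabet(queries), set_alphabet(targets))) {
    rlang::abort("Query and target alphabets differ.", class = "ttl_alphabet_error")
  }

  t0 <- proc.time()[["elapsed"]]
  coltab <- hash_target_columns(targets, strand = strand, hash = hash)
  if (verbose) {
    rlang::inform(sprintf(
      "column table: %d distinct of %d columns (%.2fs)",
      ncol(coltab$columns), coltab$n_total, proc.time()[["elapsed"]] - t0
    ))
  }

  n_targets <- length(targets)
  tnames <- motif_names(targets)
  n_t_all <- coltab$lengths

  one_query <- function(qi) {
    q <- queries$motifs[[qi]]
    grid <- score_grid(q,
      coltab,
      score = score, bins = bins,
      median_method = median_method, adjust = adjust
    )
    qcache <- if (cache) new_null_cache() else NULL
    rows <- vector("list", n_targets)
    for (ti in seq_len(n_targets)) {
      n_t <- n_t_all[ti]
      null <- cached_max_null(qcache, grid, n_t, strand, adjust)
      obs <- best_alignment(grid, coltab$slots[[ti]], n_t, strand, adjust)
      p <- pvalue(null, obs$total)
      n_terms <- if (adjust) n_t else obs$overlap
      rows[[ti]] <- list(
        query = q$name, target = tnames[ti],
        score = reconstruct_score(obs$total, n_terms, grid),
        offset = obs$offset, orientation = obs$orientation,
        overlap = obs$overlap, p_value = p
      )
    }
    out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    if (cache && verbose) {
      rlang::inform(sprintf(
        "query '%s': %d null distributions for %d targets",
        q$name, length(ls(qcache)), n_targets
      ))
    }
    out
  }

  qidx <- seq_len(length(queries))
  if (threads > 1L && .Platform$OS.type == "unix") {
    parts <- parallel::mclapply(qidx, one_query, mc.cores = threads, mc.preschedule = TRUE)
    failed <- vapply(parts, inherits, TRUE, "try-error")
    if (any(failed)) rlang::abort(as.character(parts[[which(failed)[1]]]))
    hits <- dplyr::bind_rows(parts)
  } else {
    hits <- dplyr::bind_rows(lapply(qidx, one_query))
  }

  hits$e_value <- hits$p_value * n_targets
  hits <- hits |>
    dplyr::group_by(.data$query) |>
    dplyr::mutate(q_value = bh_qvalues(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::arrange(
      factor(.data$query, levels = motif_names(queries)),
      .data$p_value,
      factor(.data$target, levels = tnames)
    )

  if (!is.null(p_threshold)) hits <- dplyr::filter(hits, .data$p_value <= p_threshold)
  if (!is.null(top_k)) {
    hits <- hits |>
      dplyr::group_by(.data$query) |>
      dplyr::slice_head(n = top_k) |>
      dplyr::ungroup()
  }
  if (verbose) {
    rlang::inform(sprintf("total: %.2fs", proc.time()[["elapsed"]] - t0))
  }
  structure(hits,
    class = c("ttl_hits", class(hits)),
    config = list(
      score = score, bins = bins, strand = strand, adjust = adjust,
      median_method = median_method, n_targets = n_targets
    )
  )
}

# Best (maximum) alignment of one query grid against one target's slots.
# Ties broken deterministically: smallest offset first, then '+' orientation.
best_alignment <- function(grid, target_slots, n_t, strand, adjust) {
  offs <- seq(-(grid$w - 1L), n_t - 1L)
  s_plus <- offset_scores(grid, target_slots$plus, offs, adjust)
  s_minus <- if (strand == "both") {
    offset_scores(grid, target_slots$minus, offs, adjust)
  } else {
    NULL
  }

  best <- max(s_plus, if (!is.null(s_minus)) max(s_minus) else -Inf)
  po <- offs[s_plus == best]
  mo <- if (!is.null(s_minus)) offs[s_minus == best] else integer(0)
  if (length(po) > 0 && (length(mo) == 0 || min(po) <= min(mo))) {
    o <- min(po)
    orient <- "+"
  } else {
    o <- min(mo)
    orient <- "-"
  }
  overlap <- min(grid$w, n_t - o) - max(0L, -o)
  list(total = best, offset = o, orientation = orient, overlap = overlap)
}

# Integer alignment score at every offset: sum of aligned binned scores,
# plus (when adjusted) background-column scores at uncovered target positions.
offset_scores <- function(grid, slots, offs, adjust) {
  w <- grid$w
  n_t <- length(slots)
  M <- grid$binned[seq_len(w), slots, drop = FALSE]
  if (adjust) {
    bgv <- grid$binned[w + 1L, slots]
    s <- rep(sum(bgv), length(offs))
  } else {
    bgv <- NULL
    s <- numeric(length(offs))
  }
  for (i in seq_len(w)) {
    ok <- which(offs >= 1L - i & offs <= n_t - i)
    tpos <- offs[ok] + i
    s[ok] <- s[ok] + if (adjust) M[i, tpos] - bgv[tpos] else M[i, tpos]
  }
  s
}

# real-valued centered score from an integer bin total over n_terms columns
reconstruct_score <- function(total, n_terms, grid) {
  if (grid$bin_width == 0) {
    return(n_terms * grid$range[1])
  }
  n_terms * grid$range[1] + (total + 0.5 * n_terms) * grid$bin_width
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i} n p_(j) / j`
#' clipped at 1, returned in input order.
#'
#' @param p Numeric vector of P-values in `(0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    rlang::abort("P-values must lie in (0, 1].", class = "ttl_value_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' @importFrom generics glance
#' @export
generics::glance

#' Summarise a hit table
#' @param x A `"ttl_hits"` table from [tomtom()].
#' @param ... Unused.
#' @return One-row tibble: query/target counts, best P-value, hits at
#'   `q < 0.05`.
#' @export
glance.ttl_hits <- function(x, ...) {
  tibble::tibble(
    n_queries = dplyr::n_distinct(x$query),
    n_targets = attr(x, "config")$n_targets,
    n_pairs = nrow(x),
    min_p_value = min(x$p_value),
    n_q_sig_05 = sum(x$q_value < 0.05)
  )
}
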
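# Independent oracles and tiny constructors shared across tests.

# Assemble a score grid directly from a binned matrix, bypassing the scoring
# pipeline, so null-engine behaviour can be pinned on hand-chosen inputs.
# `binned`: (w [+1 bg]) x m integer matrix of bin indices in [0, bins-1].
fake_grid <- function(binned, bins, mult = rep(1L, ncol(binned)), has_bg = FALSE,
                      bin_width = 1, lo = 0) {
  w <- nrow(binned) - as.integer(has_bg)
  structure(
    list(
      binned = matrix(as.integer(binned), nrow(binned)),
      bins = as.integer(bins),
      range = c(lo, lo + bins * bin_width),
      bin_width = bin_width,
      medians = rep(0, nrow(binned)),
      mult = as.integer(mult),
      n_total = sum(mult),
      w = w,
      has_bg = has_bg,
      score_kind = "neg_euclidean",
      query_name = "fake"
    ),
    class = "ttl_score_grid"
  )
}

# Exhaustive-enumeration oracle for the max-alignment null: for every offset
# (and orientation), enumerate all m^n_t target-column sequences, histogram
# the offset's (adjusted) alignment score, and combine the per-offset CDFs by
# the null model's definition of the maximum of independent draws. No
# convolution, caching, or log-space machinery is shared with the
# implementation.
oracle_max_null <- function(grid, n_t, strand = "given", adjust = FALSE) {
  w <- grid$w
  B <- grid$bins
  m <- ncol(grid$binned)
  probs <- grid$mult / sum(grid$mult)
  S <- if (adjust) n_t * (B - 1L) else min(w, n_t) * (B - 1L)

  seqs <- as.matrix(expand.grid(rep(list(seq_len(m)), n_t)))
  seq_prob <- Reduce(`*`, lapply(seq_len(n_t), function(j) probs[seqs[, j]]))

  cdf_prod <- rep(1, S + 1L)
  for (o in seq(-(w - 1L), n_t - 1L)) {
    sc <- integer(nrow(seqs))
    for (j in seq_len(n_t)) {
      qi <- j - o # 1-based query column aligned with target position j
      if (qi >= 1 && qi <= w) {
        sc <- sc + grid$binned[qi, seqs[, j]]
      } else if (adjust) {
        sc <- sc + grid$binned[w + 1L, seqs[, j]]
      }
    }
    pmf_o <- as.vector(rowsum(seq_prob, sc + 1L))
    full <- numeric(S + 1L)
    full[sort(unique(sc)) + 1L] <- pmf_o
    cdf_o <- cumsum(full)
    cdf_prod <- cdf_prod * cdf_o
    if (strand == "both") cdf_prod <- cdf_prod * cdf_o
  }
  diff(c(0, cdf_prod))
}

# Direct double-loop scorer: every query column against every column of every
# target, no hashing.
oracle_direct_scores <- function(query, targets, kind = "neg_euclidean") {
  cols <- do.call(cbind, lapply(targets$motifs, function(m) m$matrix))
  out <- matrix(0, motif_width(query), ncol(cols))
  for (i in seq_len(motif_width(query))) {
    for (k in seq_len(ncol(cols))) {
      out[i, k] <- column_score(query$matrix[, i], cols[, k], kind)
    }
  }
  out
}

# Independent Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- n * p[o] / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Tiny frequency motif from a column list.
tiny_motif <- function(name, ..., semantics = "frequency") {
  motif(name, do.call(cbind, list(...)), semantics = semantics)
}
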
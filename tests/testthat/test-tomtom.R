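test_that("a planted copy outranks random decoys", {
  hits_rank1 <- 0L
  for (seed in 1:20) {
    db <- random_pwm_set(51, width = 8, seed = seed, name_prefix = "t")
    q <- db$motifs[[1]]
    q$name <- "query"
    hits <- tomtom(motif_set(list(q)), db)
    if (hits$target[1] == "t_1") hits_rank1 <- hits_rank1 + 1L
  }
  expect_gte(hits_rank1, 19L)
})

test_that("the degenerate 1x1 comparison is the survival of the 1x1 null", {
  a <- tiny_motif("a", c(0.9, 0.1, 0, 0))
  b <- tiny_motif("b", c(0.7, 0.1, 0.1, 0.1))
  c3 <- tiny_motif("c", c(0, 0, 0.5, 0.5))
  targets <- motif_set(list(b, c3))
  hits <- tomtom(motif_set(list(a)), targets, strand = "given", adjust = FALSE)

  tab <- hash_target_columns(targets, strand = "given")
  grid <- score_grid(a, tab, adjust = FALSE)
  null <- max_alignment_null(grid, 1, strand = "given", adjust = FALSE)
  obs_b <- grid$binned[1, tab$slots[["b"]]$plus]
  expect_equal(
    hits$p_value[hits$target == "b"],
    pvalue(null, obs_b)
  )
  expect_identical(hits$overlap, c(1L, 1L))
  expect_identical(hits$offset, c(0L, 0L))
})

test_that("hit tables are deterministic across threads, cache, and hashing", {
  queries <- random_pwm_set(6, width = c(5, 8), seed = 41, name_prefix = "q")
  base_t <- random_pwm_set(15, width = c(6, 10), seed = 42, name_prefix = "t")
  dup <- lapply(base_t$motifs[1:5], function(m) {
    m$name <- paste0(m$name, "_dup")
    m
  })
  targets <- motif_set(c(base_t$motifs, dup))

  ref <- tomtom(queries, targets)
  expect_identical(tomtom(queries, targets, cache = FALSE), ref)
  expect_identical(tomtom(queries, targets, hash = FALSE), ref)
  expect_identical(tomtom(queries, targets, threads = 4L), ref)
})

test_that("reverse-complemented queries give the same p-values, flipped", {
  db <- random_pwm_set(12, width = c(5, 9), seed = 43)
  q <- db$motifs[[1]]
  fwd <- tomtom(motif_set(list(q)), db)
  rev <- tomtom(motif_set(list(reverse_complement(q))), db)
  expect_lt(max(abs(rev$p_value - fwd$p_value) / fwd$p_value), 1e-12)
  expect_identical(rev$target, fwd$target)
  informative <- fwd$p_value <= 0.25 # cross-orientation score ties live above
  expect_identical(
    rev$orientation[informative],
    ifelse(fwd$orientation[informative] == "+", "-", "+")
  )
})

test_that("duplicating the target set doubles E-values, not p-values", {
  db <- random_pwm_set(10, width = 7, seed = 44)
  q <- db[1]
  dup <- lapply(db$motifs, function(m) {
    m$name <- paste0(m$name, "_b")
    m
  })
  doubled <- motif_set(c(db$motifs, dup))
  h1 <- tomtom(q, db)
  h2 <- tomtom(q, doubled)
  idx <- match(h1$target, h2$target)
  expect_identical(h2$p_value[idx], h1$p_value)
  expect_identical(h2$e_value[idx], 2 * h1$e_value)
})

test_that("self-comparison puts each query's best equal-length hit on itself", {
  db <- random_pwm_set(8, width = 6, seed = 45)
  hits <- tomtom(db, db)
  best <- hits |>
    dplyr::group_by(query) |>
    dplyr::slice_min(p_value, n = 1, with_ties = FALSE)
  expect_identical(best$target, best$query)
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  set.seed(46)
  for (k in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_qvalues(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q[order(p)] == cummax(q[order(p)]))) # monotone step function
  }
  expect_error(bh_qvalues(c(0.5, 0)), class = "ttl_value_error")
  expect_error(bh_qvalues(c(0.5, 1.2)), class = "ttl_value_error")
})

test_that("input validation rejects empty sets and mismatched alphabets", {
  db <- random_pwm_set(3, width = 5, seed = 47)
  expect_error(tomtom(motif_set(list()), db), class = "ttl_empty_input_error")
  expect_error(tomtom(db, motif_set(list())), class = "ttl_empty_input_error")
  prot <- motif_set(list(motif("p", matrix(0.05, 20, 3), alphabet = LETTERS[1:20])))
  expect_error(tomtom(prot, db), class = "ttl_alphabet_error")
  # non-DNA alphabets work single-stranded but cannot be complemented
  expect_error(tomtom(prot, prot, strand = "both"), class = "ttl_alphabet_error")
  h <- tomtom(prot, prot, strand = "given")
  expect_equal(nrow(h), 1L)
})

test_that("output filters keep the table shape contracts", {
  db <- random_pwm_set(10, width = 6, seed = 48)
  h_all <- tomtom(db[1:2], db)
  expect_identical(nrow(h_all), 20L)
  h_top <- tomtom(db[1:2], db, top_k = 3)
  expect_identical(nrow(h_top), 6L)
  h_thr <- tomtom(db[1:2], db, p_threshold = 0.01)
  expect_true(all(h_thr$p_value <= 0.01))
  # sorted by query then p-value with deterministic ties
  expect_false(is.unsorted(h_all$p_value[h_all$query == h_all$query[1]]))
  gl <- glance(h_all)
  expect_identical(gl$n_pairs, 20L)
  expect_identical(gl$n_targets, 10L)
})

test_that("seqlet annotation recovers planted sources and labels the rest", {
  fx <- planted_database(
    n_database = 30, n_seqlets = 12, n_decoys = 4,
    max_shift = 2, rc_prob = 0.5, noise = 0, seed = 49
  )
  ann <- annotate_seqlets(fx$seqlets, fx$database, p_threshold = 0.05)
  joined <- dplyr::inner_join(ann$assignments, fx$truth, by = "seqlet")
  expect_identical(joined$match, joined$source)
  # per-motif counts over the planted seqlets equal the copy multiplicities
  planted_counts <- joined |>
    dplyr::count(match) |>
    dplyr::arrange(match)
  truth_counts <- fx$truth |>
    dplyr::count(source) |>
    dplyr::arrange(source)
  expect_identical(planted_counts$n, truth_counts$n)

  # threshold 0 leaves everything unassigned (p-values are strictly positive)
  ann0 <- annotate_seqlets(fx$seqlets, fx$database, p_threshold = 0)
  expect_true(all(ann0$assignments$match == "unassigned"))
  expect_identical(nrow(ann0$counts), 0L)

  empty <- annotate_seqlets(motif_set(list()), fx$database)
  expect_identical(nrow(empty$assignments), 0L)
  expect_identical(nrow(empty$counts), 0L)
})

test_that("attribution-matrix queries run through the same pipeline", {
  db <- random_pwm_set(8, width = 6, seed = 50)
  cwm_mat <- db$motifs[[2]]$matrix * 2 - 0.2 # rescaled, sign-carrying copy
  cwm <- motif("cwm", cwm_mat, semantics = "attribution")
  hits <- tomtom(motif_set(list(cwm)), db, strand = "given")
  expect_identical(nrow(hits), 8L)
  expect_true(all(hits$p_value > 0 & hits$p_value <= 1))
})
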
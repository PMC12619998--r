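test_that("per-column nulls are the multiplicity-weighted bin frequencies", {
  # all target columns identical -> point mass
  g <- fake_grid(matrix(c(3L, 3L, 3L), 1), bins = 8)
  expect_equal(column_null(g, 1)$pmf, c(0, 0, 0, 1, 0, 0, 0, 0))

  # two distinct slots, equal multiplicity, different bins -> (0.5, 0.5)
  g2 <- fake_grid(matrix(c(1L, 4L), 1), bins = 6, mult = c(2L, 2L))
  expect_equal(column_null(g2, 1)$pmf, c(0, 0.5, 0, 0, 0.5, 0))

  # pmf matches the empirical histogram of Monte-Carlo draws within 3 sigma
  set.seed(31)
  g3 <- fake_grid(matrix(sample(0:9, 12, replace = TRUE), 1),
    bins = 10,
    mult = sample(1:5, 12, replace = TRUE)
  )
  pmf <- column_null(g3, 1)$pmf
  n <- 100000
  draws <- sample(seq_len(12), n, replace = TRUE, prob = g3$mult / sum(g3$mult))
  emp <- tabulate(g3$binned[1, draws] + 1L, nbins = 10) / n
  sigma <- sqrt(pmf * (1 - pmf) / n)
  expect_true(all(abs(emp - pmf) <= 3 * sigma + 1e-12))
})

test_that("sum nulls convolve per-column nulls", {
  # point masses add their bins
  g <- fake_grid(rbind(rep(2L, 3), rep(5L, 3)), bins = 8)
  s <- sum_null(g, 1:2)
  expect_equal(s$pmf[8], 1, tolerance = 1e-12)
  expect_lt(max(s$pmf[-8]), 1e-12)

  # two fair {0, 1} columns -> (0.25, 0.5, 0.25)
  g2 <- fake_grid(rbind(c(0L, 1L), c(0L, 1L)), bins = 2)
  expect_equal(sum_null(g2, 1:2)$pmf, c(0.25, 0.5, 0.25))

  # three columns vs exhaustive enumeration of all 4^3 target triples
  set.seed(32)
  g3 <- fake_grid(matrix(sample(0:4, 12, replace = TRUE), 3), bins = 5)
  pmf <- sum_null(g3, 1:3)$pmf
  outcomes <- expand.grid(1:4, 1:4, 1:4)
  sums <- g3$binned[1, outcomes[, 1]] + g3$binned[2, outcomes[, 2]] +
    g3$binned[3, outcomes[, 3]]
  expect_equal(pmf, tabulate(sums + 1L, nbins = 13) / 64, tolerance = 1e-14)

  expect_error(sum_null(g3, integer(0)), class = "ttl_empty_input_error")
})

test_that("the unaligned-position adjustment pads with background-column nulls", {
  set.seed(33)
  g <- fake_grid(matrix(sample(0:5, 18, replace = TRUE), 3),
    bins = 6,
    has_bg = TRUE
  ) # 2 query columns + bg row
  full <- sum_null(g, 1:2)
  # full overlap with n_t <= w_q: identity
  expect_equal(adjust_for_unaligned(full, 2, 2, g)$pmf, full$pmf)
  # padding one unaligned target position convolves in one bg null
  adj <- adjust_for_unaligned(full, 2, 3, g)
  bg <- column_null(g, "bg")
  manual <- stats::convolve(full$pmf, rev(bg$pmf), type = "open")
  expect_equal(adj$pmf, manual, tolerance = 1e-12)
  expect_error(adjust_for_unaligned(full, 0, 3, g), class = "ttl_value_error")
  expect_error(adjust_for_unaligned(full, 3, 3, g), class = "ttl_value_error")
})

test_that("max-alignment null matches exhaustive enumeration on small grids", {
  set.seed(34)
  for (w in 1:3) {
    for (n_t in 1:4) {
      for (adjust in c(FALSE, TRUE)) {
        for (strand in c("given", "both")) {
          g <- fake_grid(
            matrix(sample(0:7, (w + 1) * 5, replace = TRUE), w + 1),
            bins = 8, mult = sample(1:3, 5, replace = TRUE), has_bg = TRUE
          )
          got <- max_alignment_null(g, n_t, strand = strand, adjust = adjust)
          want <- oracle_max_null(g, n_t, strand = strand, adjust = adjust)
          expect_lt(max(abs(got$pmf - want)), 1e-12)
        }
      }
    }
  }
})

test_that("degenerate offset sets reduce to known forms", {
  set.seed(35)
  # single admissible configuration (w_q = n_t = 1): max over one element
  g1 <- fake_grid(matrix(sample(0:7, 5, replace = TRUE), 1),
    bins = 8,
    mult = sample(1:3, 5, replace = TRUE)
  )
  one <- max_alignment_null(g1, 1, strand = "given", adjust = FALSE)
  expect_equal(one$pmf, sum_null(g1, 1)$pmf, tolerance = 1e-14)

  # w_q = 1: maximum of n_t i.i.d. draws, CDF = F(x)^n_t
  Fcdf <- cumsum(column_null(g1, 1)$pmf)
  for (n_t in c(1, 5, 20)) {
    got <- cumsum(max_alignment_null(g1, n_t, strand = "given", adjust = FALSE)$pmf)
    expect_lt(max(abs(got - Fcdf^n_t)), 1e-12)
  }
})

test_that("p-values are inclusive survival probabilities with safe tails", {
  pmf <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  d <- binned_dist(pmf)
  expect_equal(pvalue(d, 0), 1)
  expect_equal(pvalue(d, 4), 0.15)
  expect_equal(pvalue(d, 2), 0.3 + 0.25 + 0.15)
  expect_equal(pvalue(d, -3), 1)
  expect_gt(pvalue(d, 99), 0) # never exactly zero above the support
  # monotone non-increasing in the observed score
  ps <- vapply(0:6, function(x) pvalue(d, x), 1.0)
  expect_true(all(diff(ps) <= 0))

  # Monte-Carlo check: empirical tail of simulated null maxima matches
  set.seed(36)
  g <- fake_grid(matrix(sample(0:5, 18, replace = TRUE), 3),
    bins = 6,
    has_bg = TRUE
  ) # 2 query rows + 1 background row, 6 column slots
  n_t <- 3
  null <- max_alignment_null(g, n_t, strand = "given", adjust = FALSE)
  nsim <- 100000
  offs <- seq(-1, n_t - 1)
  sims <- rep(-Inf, nsim)
  for (o in offs) {
    # each offset draws its own i.i.d. target columns under the null
    sc <- integer(nsim)
    for (j in seq_len(n_t)) {
      qi <- j - o
      if (qi >= 1 && qi <= 2) {
        sc <- sc + g$binned[qi, sample(ncol(g$binned), nsim, replace = TRUE)]
      }
    }
    sims <- pmax(sims, sc)
  }
  for (probe in stats::quantile(sims, c(0.5, 0.75, 0.9, 0.95, 0.99), type = 1)) {
    p_hat <- mean(sims >= probe)
    p <- pvalue(null, probe)
    sigma <- sqrt(p * (1 - p) / nsim)
    expect_lt(abs(p_hat - p), 3 * sigma + 1e-6)
  }
})

test_that("null cache returns bitwise-identical distributions", {
  set.seed(37)
  g <- fake_grid(matrix(sample(0:9, 24, replace = TRUE), 4),
    bins = 10,
    has_bg = TRUE
  )
  cache <- new_null_cache()
  a <- tomtomlite:::cached_max_null(cache, g, 5, "given", TRUE)
  b <- tomtomlite:::cached_max_null(cache, g, 5, "given", TRUE)
  fresh <- max_alignment_null(g, 5, strand = "given", adjust = TRUE)
  expect_identical(a, b)
  expect_identical(a$pmf, fresh$pmf)
  # equal target lengths share one entry; config changes do not collide
  tomtomlite:::cached_max_null(cache, g, 5, "both", TRUE)
  tomtomlite:::cached_max_null(cache, g, 7, "given", TRUE)
  expect_identical(length(ls(cache)), 3L)
})
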
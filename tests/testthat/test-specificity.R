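test_that("midranks average tied positions and conserve the rank sum", {
  rs <- rank_transform(c(1, 2), c(2, 3))
  expect_equal(c(rs$ranks_pos, rs$ranks_neg), c(1, 2.5, 2.5, 4))
  ident <- rank_transform(c(5, 1, 9), c(5, 1, 9))
  expect_equal(ident$mean_pos, ident$mean_neg)
  set.seed(2)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    a <- sample(round(runif(n, 0, 20)) / 7)
    b <- sample(round(runif(n, 0, 20)) / 7)
    rs <- rank_transform(a, b)
    N <- 2 * n
    expect_equal(sum(rs$ranks_pos) + sum(rs$ranks_neg), N * (N + 1) / 2)
  }
  expect_error(rank_transform(1, 1), "at least 2")
  expect_error(rank_transform(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("Welch statistics match direct-formula oracles to 1e-12", {
  mk <- function(a, b) {
    structure(
      list(
        ranks_pos = a, ranks_neg = b,
        mean_pos = mean(a), mean_neg = mean(b),
        sd_pos = sd(a), sd_neg = sd(b),
        n_pos = length(a), n_neg = length(b)
      ),
      class = "ranked_samples"
    )
  }
  a <- c(1, 4, 6, 9, 12, 13.5)
  b <- c(2, 3, 5, 7, 8, 13.5)
  s <- mk(a, b)
  # independent direct evaluation of the three expressions
  t_direct <- (mean(a) - mean(b)) / sqrt(var(a) / 6 + var(b) / 6)
  f_direct <- (var(a) / 6 + var(b) / 6)^2 /
    ((var(a) / 6)^2 / 5 + (var(b) / 6)^2 / 5)
  d_direct <- (mean(a) - mean(b)) / sqrt((5 * var(a) + 5 * var(b)) / 10)
  expect_equal(welch_t(s), t_direct, tolerance = 1e-12)
  expect_equal(welch_df(s), f_direct, tolerance = 1e-12)
  expect_equal(cohens_d(s), d_direct, tolerance = 1e-12)
  # stats::t.test as an independent cross-check of t and f
  tt <- t.test(a, b)
  expect_equal(welch_t(s), unname(tt$statistic), tolerance = 1e-12)
  expect_equal(welch_df(s), unname(tt$parameter), tolerance = 1e-12)

  # closed-form limits
  eqv <- mk(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(welch_df(eqv), 2 * (4 - 1))
  onesided <- mk(c(1, 3, 5), c(2, 2, 2))
  expect_equal(welch_df(onesided), 3 - 1)
  # antisymmetry under sample swap
  expect_equal(welch_t(mk(b, a)), -welch_t(s))
  expect_equal(cohens_d(mk(b, a)), -cohens_d(s))
  # equal means
  expect_equal(welch_t(mk(c(1, 5), c(2, 4))), 0)
  expect_equal(cohens_d(mk(c(1, 5), c(2, 4))), 0)
  # d is invariant under a common positive affine map
  expect_equal(cohens_d(mk(3 * a + 7, 3 * b + 7)), cohens_d(s), tolerance = 1e-12)
  # degenerate: zero pooled variance
  expect_true(is.na(welch_t(mk(c(2, 2), c(2, 2)))))
})

test_that("the t tail probability matches quadrature and the normal limit", {
  expect_equal(t_tail_p(0, 3)$p, 0.5)
  expect_equal(t_tail_p(0, 123.4)$p, 0.5)
  # limits
  expect_lt(t_tail_p(60, 5)$p, 1e-6)
  expect_gt(t_tail_p(-60, 5)$p, 1 - 1e-6)
  # quadrature oracle over a (t, f) grid
  for (t in c(-5, -1, -0.2, 0.7, 2, 6)) {
    for (f in c(1.5, 4, 17, 120)) {
      expect_equal(
        t_tail_p(t, f)$p, bf_t_upper_tail(t, f),
        tolerance = 1e-10, info = paste(t, f)
      )
    }
  }
  # log-space path survives p underflow: log10_p finite and consistent
  deep <- t_tail_p(400, 800)
  expect_equal(deep$p, 0)
  expect_true(is.finite(deep$log10_p))
  expect_lt(deep$log10_p, -300)
  mid <- t_tail_p(9, 40)
  expect_equal(mid$log10_p, log10(mid$p), tolerance = 1e-10)
  # large-f convergence to the standard normal tail
  for (t in c(-2, 0, 1, 3)) {
    expect_lt(abs(t_tail_p(t, 1e6)$p - pnorm(-t)), 1e-6)
  }
  expect_error(t_tail_p(Inf, 3), "non-finite")
})

test_that("candidates identical across pools score t = 0, p = 0.5", {
  tab <- tibble::tibble(
    l3 = "AAA", h1 = "YY", h2 = "SS",
    h3 = sprintf("Y%02dY", 1:60), count = 5
  )
  pos <- selection_pool(tab, "positive")
  neg <- selection_pool(tab, "negative")
  s <- score_candidate(
    tab[1, ], pos, neg,
    constraints = motif_constraints(min_positive_support = 5)
  )
  expect_false(s$unscorable)
  expect_equal(s$t, 0)
  expect_equal(s$p, 0.5)
  expect_false(s$specific)
  # swapping the pools negates t and reflects p
  s2 <- score_candidate(
    tab[1, ], neg, pos,
    constraints = motif_constraints(min_positive_support = 5)
  )
  expect_equal(s2$t, -s$t)
  expect_equal(s2$p, 1 - s$p, tolerance = 1e-12)
})

test_that("pool swap reflects p and negates d over a fixed motif set", {
  # The statistic stage is antisymmetric for a given motif profile (motif
  # enumeration itself conditions on whichever pool plays the positive
  # role, so full reruns need not be).
  sim <- simulate_pools(small_sim_config(seed = 61, chimera_rate = 0))
  fam <- sim$truth[sim$truth$label == "specific" & sim$truth$family == 1, ]
  cand <- fam[2, c("l3", "h1", "h2", "h3")]
  cons <- motif_constraints(min_positive_support = 50)
  fwd <- score_candidate(cand, sim$pos, sim$neg, constraints = cons)
  expect_false(fwd$unscorable)
  expect_true(fwd$specific)
  prof <- tidy(fwd)
  swapped <- rank_transform(prof$freq_neg, prof$freq_pos)
  t_sw <- welch_t(swapped)
  expect_equal(t_sw, -fwd$t, tolerance = 1e-12)
  expect_equal(t_tail_p(t_sw, welch_df(swapped))$p, 1 - fwd$p, tolerance = 1e-9)
  expect_equal(cohens_d(swapped), -fwd$d, tolerance = 1e-12)
})

test_that("unscorable candidates are flagged instead of given a p value", {
  pos <- make_pool(c("YY", "WW"), l3 = "AAA")
  neg <- make_pool("YY", l3 = "AAA", label = "negative")
  s <- score_candidate(
    list(l3 = "AAA", h1 = "YY", h2 = "SS", h3 = "YY"),
    pos, neg
  )
  expect_true(s$unscorable)
  expect_true(is.na(s$p))
  expect_false(s$specific)
  expect_equal(glance(s)$unscorable, TRUE)
  expect_equal(nrow(tidy(s)), 0)
})

test_that("enrichment quadrant applies strict boundaries and INF convention", {
  pos <- selection_pool(
    tibble::tibble(
      l3 = sprintf("A%02d", 1:4), h1 = "YY", h2 = "SS",
      h3 = c("AAAA", "BBBB", "CCCC", "DDDD"),
      count = c(201, 200, 5000, 201)
    ),
    "positive"
  )
  neg <- selection_pool(
    tibble::tibble(
      l3 = sprintf("A%02d", 3:4), h1 = "YY", h2 = "SS",
      h3 = c("CCCC", "DDDD"), count = c(4000, 60)
    ),
    "negative"
  )
  q <- enrichment_quadrant(pos, neg)
  qt <- tibble::as_tibble(q)
  # count 201 and absent in negative: in (infinite ratio)
  expect_true(qt$in_quadrant[qt$h3 == "AAAA"])
  expect_equal(qt$fold_ratio[qt$h3 == "AAAA"], Inf)
  # count 200: excluded by the strict count threshold
  expect_false(qt$in_quadrant[qt$h3 == "BBBB"])
  # abundant in both pools: ratio below fourfold
  expect_false(qt$in_quadrant[qt$h3 == "CCCC"])
  # hand-computed ratio
  r <- (201 / pool_total_reads(pos)) / (60 / pool_total_reads(neg))
  expect_equal(qt$fold_ratio[qt$h3 == "DDDD"], r)
  expect_equal(qt$in_quadrant[qt$h3 == "DDDD"], r > 4)
  # the scatter table covers every positive clone
  expect_equal(nrow(qt), nrow(pos))
  p <- ggplot2::autoplot(q)
  expect_s3_class(p, "ggplot")
})

test_that("family clustering matches brute-force single linkage", {
  twins <- tibble::tibble(
    l3 = c("SFFPI", "SFFPI"), h3 = c("WYGAM", "WYGAM"), count = c(2, 1)
  )
  expect_equal(cluster_families(twins)$family, c(1, 1))
  # 3 edits over concatenated length 10: identity 0.7 < 0.8
  far <- tibble::tibble(l3 = c("AAAAA", "AAAAA"), h3 = c("BBBBB", "CCCBB"))
  expect_equal(sort(cluster_families(far)$family), c(1, 2))
  set.seed(33)
  alph <- c("Y", "S", "G", "W", "F")
  for (rep in 1:6) {
    n <- sample(5:14, 1)
    clones <- tibble::tibble(
      l3 = vapply(1:n, function(i) paste(sample(alph, 5, TRUE), collapse = ""), ""),
      h3 = vapply(1:n, function(i) {
        paste(sample(alph, sample(4:8, 1), TRUE), collapse = "")
      }, ""),
      count = sample(1000, n)
    )
    got <- cluster_families(clones, 0.6)$family
    want <- bf_families(clones, 0.6)
    # same partition (family labels may differ)
    expect_equal(
      unname(split(seq_along(got), got)[order(vapply(split(seq_along(got), got), min, 1))]),
      unname(split(seq_along(want), want)[order(vapply(split(seq_along(want), want), min, 1))])
    )
  }
  # deterministic ordering: family 1 carries the top positive count
  set.seed(34)
  clones <- tibble::tibble(
    l3 = c("AAAAA", "AAAAA", "GGGGG"),
    h3 = c("WWWWW", "WWWWV", "SSSSS"),
    count_pos = c(10, 5, 400)
  )
  fam <- cluster_families(clones)
  expect_equal(fam$family, c(2, 2, 1))
})
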
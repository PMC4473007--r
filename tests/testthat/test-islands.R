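test_that("background rate follows reads * W / (fraction * genome length)", {
  tr <- make_track(list(chr1 = rep(1, 25000), chr2 = rep(1, 25000)))
  tr$n_summarized <- 10000
  p <- island_params(effective_genome_fraction = 1)
  expect_equal(background_rate(tr, p), 10000 * 200 / 1e7)
  p2 <- island_params(effective_genome_fraction = 0.5)
  expect_equal(background_rate(p = p2, track = tr), 0.4)
  empty <- make_track(list(chr1 = rep(0, 100)))
  expect_error(background_rate(empty, p), "empty track")
  expect_error(background_rate(normalize_per_million(tr), p), "raw")
})

test_that("window eligibility matches the direct Poisson tail computation", {
  # lambda = 0.2, p = 0.2: P(X >= 1) = 0.181 < 0.2, so threshold count is 1
  expect_equal(islandscape:::eligibility_threshold(0.2, 0.2), 1L)
  expect_lt(ppois(0, 0.2, lower.tail = FALSE), 0.2)
  # independent check across a grid: smallest c with P(X >= c) < p
  for (lambda in c(0.2, 1, 4.5, 9)) {
    for (p in c(0.05, 0.2, 0.5)) {
      c0 <- islandscape:::eligibility_threshold(lambda, p)
      want <- 1L
      while (1 - sum(dpois(0:(want - 1), lambda)) >= p) want <- want + 1L
      expect_equal(c0, want)
    }
  }
  tr <- make_track(list(chr1 = c(0, 1, 3, 0)))
  mask <- eligible_windows(tr, 0.2, 0.2)
  expect_equal(mask$chr1, c(FALSE, TRUE, TRUE, FALSE))
  # zero-count windows are never eligible; raising p never shrinks the mask
  m1 <- eligible_windows(tr, 5, 0.1)$chr1
  m2 <- eligible_windows(tr, 5, 0.4)$chr1
  expect_true(all(m2 | !m1))
  expect_false(any(eligible_windows(tr, 3, 0.5)$chr1[c(1, 4)]))
})

test_that("island aggregation merges runs across allowed gaps", {
  counts <- rep(0, 12)
  counts[c(4, 5, 8)] <- 5   # eligible windows at 0-based indices {3,4,7}
  tr <- make_track(list(chr1 = counts))
  p <- island_params(gap_size = 400, effective_genome_fraction = 1)
  lambda <- 0.2
  isl <- aggregate_islands(eligible_windows(tr, lambda, 0.2), tr, p, lambda)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 3 * 200)
  expect_equal(isl$end, 8 * 200)
  expect_equal(isl$n_eligible, 3L)
  expect_equal(isl$read_count, 15)

  counts2 <- rep(0, 12); counts2[c(4, 9)] <- 5  # eligible at {3, 8}: gap 4 > 2
  tr2 <- make_track(list(chr1 = counts2))
  isl2 <- aggregate_islands(eligible_windows(tr2, lambda, 0.2), tr2, p, lambda)
  expect_equal(nrow(isl2), 2)
})

test_that("aggregation matches the brute-force oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_island_instance(seed)
    expect_equal(nrow(inst$got), nrow(inst$want), info = paste("seed", seed))
    if (nrow(inst$got)) {
      expect_equal(inst$got$start, inst$want$start, info = paste("seed", seed))
      expect_equal(inst$got$end, inst$want$end, info = paste("seed", seed))
      expect_equal(inst$got$read_count, inst$want$read_count)
      expect_equal(inst$got$score, inst$want$score, tolerance = 1e-9)
    }
  }
})

test_that("score threshold limits and monotonicity behave as specified", {
  p_hi <- island_params(e_value = 1e12, effective_genome_fraction = 1)
  lambda <- 0.2
  s_hi <- score_threshold(p_hi, lambda, 1e5)
  # huge E: threshold at (or below) the minimum possible island score
  min_score <- -ppois(0, lambda, lower.tail = FALSE, log.p = TRUE)
  expect_lte(s_hi, min_score)
  # E -> 0: threshold grows without bound, eventually +Inf
  s_small <- score_threshold(island_params(e_value = 1e-9,
                                           effective_genome_fraction = 1),
                             lambda, 1e5)
  expect_gt(s_small, 4 * score_threshold(
    island_params(e_value = 100, effective_genome_fraction = 1), lambda, 1e5))
  expect_identical(score_threshold(island_params(e_value = 1e-300,
                                                 effective_genome_fraction = 1),
                                   lambda, 1e5), Inf)
  # larger E => smaller or equal threshold
  es <- c(1, 10, 100, 1000)
  th <- sapply(es, function(e)
    score_threshold(island_params(e_value = e, effective_genome_fraction = 1),
                    lambda, 1e5))
  expect_true(all(diff(th) <= 0))
})

test_that("null threshold is calibrated against Monte-Carlo simulation", {
  p <- island_params(e_value = 100, effective_genome_fraction = 1)
  lambda <- 0.2
  L <- 2e4
  s_star <- score_threshold(p, lambda, L)
  set.seed(123)
  hits <- replicate(10, {
    tr <- make_track(list(chr1 = rpois(L, lambda)))
    cand <- aggregate_islands(eligible_windows(tr, lambda, p$p_window),
                              tr, p, lambda)
    sum(cand$score >= s_star)
  })
  se <- sd(hits) / sqrt(length(hits))
  expect_lte(mean(hits), 100 + 3 * se)
})

test_that("call_islands recovers planted enrichment and returns disjoint islands", {
  cfg <- small_config(n_genes = 40, chrom_length = 2e6,
                      enrichment_reads_per_active_gene = 120,
                      duplicate_fraction = 0, multimap_fraction = 0)
  ds <- simulate_dataset(cfg)
  tr <- reads_to_track(ds$reads$tender, ds$genome)
  p <- island_params(effective_genome_fraction = 1)
  isl <- call_islands(tr, p)
  expect_true(all(isl$end > isl$start))
  expect_true(all(isl$start %% 200 == 0))
  for (ch in unique(isl$chrom)) {
    x <- isl[isl$chrom == ch, ]
    expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
  ti <- ds$truth$true_islands$tender
  hit <- sapply(seq_len(nrow(ti)), function(i)
    any(isl$chrom == ti$chrom[i] & isl$start < ti$end[i] & isl$end > ti$start[i]))
  expect_gt(mean(hit), 0.9)
  # adding reads inside an island never decreases its score
  tr2 <- tr
  w0 <- isl$start[1] / 200 + 1
  tr2$counts[[isl$chrom[1]]][w0] <- tr2$counts[[isl$chrom[1]]][w0] + 10
  lam <- attr(isl, "lambda")
  a1 <- aggregate_islands(eligible_windows(tr, lam, 0.2), tr, p, lam)
  a2 <- aggregate_islands(eligible_windows(tr2, lam, 0.2), tr2, p, lam)
  s1 <- a1$score[a1$chrom == isl$chrom[1] & a1$start <= isl$start[1] &
                   a1$end >= isl$end[1]]
  s2 <- a2$score[a2$chrom == isl$chrom[1] & a2$start <= isl$start[1] &
                   a2$end >= isl$end[1]]
  expect_gte(max(s2), max(s1))
})

test_that("gap size monotonicity: wider gaps never increase island count", {
  set.seed(9)
  counts <- rpois(500, 0.5)
  hot <- sample(500, 30)
  counts[hot] <- counts[hot] + 8
  tr <- make_track(list(chr1 = counts))
  lambda <- 0.5
  ns <- sapply(c(0, 200, 400, 800), function(gap) {
    p <- island_params(gap_size = gap, effective_genome_fraction = 1)
    nrow(aggregate_islands(eligible_windows(tr, lambda, 0.2), tr, p, lambda))
  })
  expect_true(all(diff(ns) <= 0))
})

test_that("all-zero tracks yield no islands", {
  tr <- make_track(list(chr1 = rep(0, 100)))
  expect_equal(nrow(call_islands(tr, island_params(effective_genome_fraction = 1))), 0)
})

test_that("condition comparison satisfies the accounting identities", {
  a <- data.frame(chrom = "chr1", start = c(100, 500, 900),
                  end = c(200, 700, 1000))
  cmp_same <- compare_conditions(a, a)
  expect_equal(cmp_same$shared_a, 3); expect_equal(cmp_same$unique_a, 0)
  b <- data.frame(chrom = "chr1", start = c(2000, 3000), end = c(2100, 3100))
  cmp_disj <- compare_conditions(a, b)
  expect_equal(cmp_disj$shared_a, 0)
  expect_equal(cmp_disj$unique_a, 3); expect_equal(cmp_disj$unique_b, 2)
  # one large island over two small ones: shared counts are asymmetric
  big <- data.frame(chrom = "chr1", start = 0, end = 1000)
  two <- data.frame(chrom = "chr1", start = c(100, 600), end = c(200, 700))
  cmp <- compare_conditions(big, two)
  expect_equal(cmp$shared_a, 1); expect_equal(cmp$shared_b, 2)
  expect_equal(cmp$shared_a + cmp$unique_a, cmp$total_a)
  expect_equal(cmp$shared_b + cmp$unique_b, cmp$total_b)
})
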
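# diffmod: pooling, depth filter, Fisher test, logFC, classification.

test_that("pool_counts sums replicates and zero-fills absent sides", {
  pooled <- pool_counts(mc_fixture())
  a <- pooled[transcript_id == "txA"]
  expect_equal(c(a$N_c, a$m_c), c(50L, 5L))   # (20,2) + (30,3)
  expect_equal(c(a$N_t, a$m_t), c(50L, 25L))
  expect_identical(attr(pooled, "reference"), "control")

  # a position present in one condition only pools with N = 0 on the other
  one_sided <- modcall_table(
    data.frame(transcript_id = "tx", position = 0L, ref_base = "A",
               sample_id = "c1", coverage = 30L, modified_count = 3L),
    c(c1 = "control", t1 = "treated"))
  p1 <- pool_counts(one_sided)
  expect_equal(c(p1$N_c, p1$N_t), c(30L, 0L))

  # single replicate per condition: pooling is the identity
  p2 <- pool_counts(mc_single(5L, 50L, 25L, 50L))
  expect_equal(c(p2$m_c, p2$N_c, p2$m_t, p2$N_t), c(5L, 50L, 25L, 50L))
})

test_that("coverage_filter keeps >= min_cov in both conditions, boundary inclusive", {
  pooled <- pool_counts(mc_single(5L, 49L, 25L, 200L))
  expect_equal(nrow(coverage_filter(pooled, 50L)), 0L)
  pooled <- pool_counts(mc_single(5L, 50L, 25L, 50L))
  kept <- coverage_filter(pooled, 50L)
  expect_equal(nrow(kept), 1L)
  expect_equal(attr(kept, "removed"), 0L)
  expect_equal(nrow(coverage_filter(pooled[0], 50L)), 0L)
  expect_error(coverage_filter(pooled, 0L), "min_cov")
})

test_that("fisher_exact_2x2 matches enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(10, 90, 10, 90), 1.0)
  # frozen from the enumeration oracle: margins (10,10,10,10), observed (0,10)
  expect_equal(fisher_exact_2x2(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 10, 10, 0), fisher_oracle(0, 10, 10, 0),
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(5, 45, 25, 25), fisher_oracle(5, 45, 25, 25),
               tolerance = 1e-9)
  expect_error(fisher_exact_2x2(-1, 10, 10, 0), "negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "margins")

  # exhaustive sweep at small margins against the independent oracle
  grid <- do.call(rbind, lapply(1:12, function(N1) do.call(rbind, lapply(1:12, function(N2)
    expand.grid(mc = 0:N1, mt = 0:N2, N1 = N1, N2 = N2)))))
  ours <- fisher_exact_2x2(grid$mc, grid$N1 - grid$mc, grid$mt, grid$N2 - grid$mt)
  oracle <- mapply(fisher_oracle, grid$mc, grid$N1 - grid$mc, grid$mt,
                   grid$N2 - grid$mt)
  expect_lt(max(abs(ours - oracle)), 1e-9)

  # random tables against stats::fisher.test (same two-sided convention)
  set.seed(101)
  for (i in 1:200) {
    N1 <- sample(1:400, 1); N2 <- sample(1:400, 1)
    mc <- rbinom(1, N1, runif(1)); mt <- rbinom(1, N2, runif(1))
    ours <- fisher_exact_2x2(mc, N1 - mc, mt, N2 - mt)
    ref <- stats::fisher.test(matrix(c(mc, N1 - mc, mt, N2 - mt), 2))$p.value
    expect_equal(ours, min(1, ref), tolerance = 1e-9)
  }
})

test_that("log2fc_mod uses the Haldane pseudocount and is antisymmetric", {
  expect_equal(log2fc_mod(5, 50, 25, 50), log2(25.5 / 5.5), tolerance = 1e-12)
  expect_equal(log2fc_mod(7, 80, 7, 80), 0)
  expect_error(log2fc_mod(0, 0, 0, 0), "zero")
  set.seed(7)
  for (i in 1:50) {
    N1 <- sample(0:200, 1); N2 <- sample(0:200, 1)
    if (N1 + N2 == 0) N1 <- 1
    m1 <- if (N1) rbinom(1, N1, 0.3) else 0
    m2 <- if (N2) rbinom(1, N2, 0.3) else 0
    expect_equal(log2fc_mod(m1, N1, m2, N2), -log2fc_mod(m2, N2, m1, N1),
                 tolerance = 1e-12)
  }
})

test_that("diffmod_scan classifies positions and tallies transcripts", {
  # clear treatment gain -> over; p and lfc both checked
  x <- mc_single(10L, 100L, 35L, 100L)
  res <- diffmod_scan(x, min_cov = 50L)
  expect_identical(res$status, "over")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$log2fc, 0.5)
  expect_equal(sign(res$log2fc), sign(res$f_t - res$f_c))

  # large effect but hopeless p -> ns (alpha gate)
  tiny <- mc_single(1L, 60L, 4L, 60L)
  expect_identical(diffmod_scan(tiny, min_cov = 50L)$status, "ns")

  # below coverage -> tested set is empty
  expect_error(diffmod_scan(mc_single(0L, 0L, 0L, 0L)[0]), "empty")

  # BH gate is at least as conservative as the raw-p gate
  set.seed(11)
  nul <- simulate_null_positions(400L, coverage = 80L, f0 = 0.2, seed = 5L)
  raw <- diffmod_scan(nul)
  bh <- diffmod_scan(nul, adjust = "BH")
  expect_lte(sum(bh$status != "ns"), sum(raw$status != "ns"))
  expect_equal(bh$q_value, stats::p.adjust(bh$p_value, "BH"))

  # transcript tallies: two over + one under on txA, one over on txB
  recs <- rbind(
    data.frame(transcript_id = "txA", position = 0L, ref_base = "A",
               sample_id = c("c1", "t1"), coverage = 100L,
               modified_count = c(10L, 40L)),
    data.frame(transcript_id = "txA", position = 1L, ref_base = "C",
               sample_id = c("c1", "t1"), coverage = 100L,
               modified_count = c(40L, 10L)),
    data.frame(transcript_id = "txB", position = 0L, ref_base = "G",
               sample_id = c("c1", "t1"), coverage = 100L,
               modified_count = c(10L, 40L)))
  res <- diffmod_scan(modcall_table(recs, c(c1 = "control", t1 = "treated")))
  tl <- attr(res, "tally")
  expect_equal(tl$n_over_positions, 2L)
  expect_equal(tl$n_under_positions, 1L)
  expect_equal(tl$n_transcripts_over, 2L)
  expect_equal(tl$n_transcripts_under, 1L)
  expect_equal(tl$n_transcripts_both, 1L)
  expect_equal(tl$n_transcripts_modified, 2L)
  # union arithmetic mirrors the report check: over + under - both
  expect_equal(tl$n_transcripts_over + tl$n_transcripts_under - tl$n_transcripts_both,
               tl$n_transcripts_modified)
})

test_that("diffmod_scan is invariant to row order and replicate relabeling", {
  b <- simulate_dataset(sim_config(n_transcripts = 30L, n_planted = 5L,
                                   coverage_mean = 40, seed = 3L))
  x <- b$modcalls
  res1 <- diffmod_scan(x, min_cov = 30L)
  shuffled <- data.table::as.data.table(x)[sample(.N)]
  res2 <- diffmod_scan(modcall_table(shuffled, condition_map(x)), min_cov = 30L)
  expect_equal(as.data.frame(res1), as.data.frame(res2))
  # swap replicate labels within the control condition
  cm <- condition_map(x)
  relab <- data.table::as.data.table(x)
  relab[sample_id == "control_1", sample_id := "tmp"]
  relab[sample_id == "control_2", sample_id := "control_1"]
  relab[sample_id == "tmp", sample_id := "control_2"]
  res3 <- diffmod_scan(modcall_table(relab, cm), min_cov = 30L)
  expect_equal(as.data.frame(res1), as.data.frame(res3))
})

test_that("base_composition counts reference bases per condition", {
  pos <- data.frame(ref_base = c("A", "A", "G", "U"))
  bc <- base_composition(pos)
  expect_equal(bc[bc$base == "A", ]$percent, 50)
  expect_equal(bc[bc$base == "G", ]$percent, 25)
  expect_equal(bc[bc$base == "C", ]$percent, 0)
  expect_equal(sum(bc$percent), 100, tolerance = 1e-9)
  expect_equal(base_composition(data.frame(ref_base = rep("A", 5)))[base == "A"]$percent, 100)
  expect_error(base_composition(data.frame(ref_base = character())), "empty")
  # lookup from sequences when ref_base is absent
  bc2 <- base_composition(data.frame(transcript_id = "tx", position = 0:2),
                          sequences = c(tx = "GAU"))
  expect_equal(sort(bc2[bc2$percent > 0]$base), c("A", "G", "U"))
})

test_that("transcript_mod_ratio pools counts within transcript", {
  recs <- rbind(
    data.frame(transcript_id = "tx", position = 0L, ref_base = "A",
               sample_id = c("c1", "t1"), coverage = 50L,
               modified_count = c(5L, 0L)),
    data.frame(transcript_id = "tx", position = 1L, ref_base = "A",
               sample_id = c("c1", "t1"), coverage = 50L,
               modified_count = c(15L, 0L)))
  pooled <- pool_counts(modcall_table(recs, c(c1 = "control", t1 = "treated")))
  expect_equal(transcript_mod_ratio(pooled, "reference")$mod_ratio, 0.2)
  expect_equal(transcript_mod_ratio(pooled, "treatment")$mod_ratio, 0)
  p1 <- pool_counts(mc_single(50L, 50L, 0L, 10L))
  expect_equal(transcript_mod_ratio(p1, "reference")$mod_ratio, 1.0)
})
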
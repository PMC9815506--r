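# integrate: CPM, expression filter, Pearson suite, overlap report.

test_that("cpm_normalize scales columns to one million", {
  m <- abundance_matrix(matrix(c(10, 90, 0, 50, 50, 0), nrow = 3,
                               dimnames = list(c("a", "b", "z"), c("s1", "s2"))),
                        "counts")
  cpm <- cpm_normalize(m)
  expect_equal(unname(cpm[, "s1"]), c(1e5, 9e5, 0))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6), tolerance = 1e-6)
  expect_identical(attr(cpm, "kind"), "cpm")
  # all-zero row survives as all-zero
  expect_equal(unname(cpm["z", ]), c(0, 0))
  bad <- abundance_matrix(matrix(c(1, 0), 1, dimnames = list("a", c("s1", "s2"))),
                          "counts")
  expect_error(cpm_normalize(bad), "zero library size.*s2")
})

test_that("expression_filter applies the >= min_cpm in >= min_samples rule", {
  m <- matrix(c(2, 2, 0, 0, 0, 0,
                5, 0, 0, 0, 0, 0,
                9, 9, 9, 9, 9, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("boundary", "single", "high"), paste0("s", 1:6)))
  attr(m, "kind") <- "cpm"
  kept <- expression_filter(m)
  expect_true("boundary" %in% rownames(kept))   # 2 cpm in exactly 2 samples passes
  expect_false("single" %in% rownames(kept))
  expect_equal(nrow(expression_filter(m, min_cpm = 0)), 3L)
  expect_error(expression_filter(unclass_m <- `attr<-`(m, "kind", "counts")),
               "CPM")
  # monotone: raising min_cpm never keeps a dropped row
  set.seed(5)
  r <- matrix(runif(60, 0, 10), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  attr(r, "kind") <- "cpm"
  for (th in c(1, 2, 4, 8)) {
    lo <- rownames(expression_filter(r, min_cpm = th))
    hi <- rownames(expression_filter(r, min_cpm = th + 1))
    expect_true(all(hi %in% lo))
  }
})

test_that("pearson_with_p matches the closed form and cor.test", {
  expect_equal(pearson_with_p(1:3, c(2, 4, 6))$r, 1.0)
  expect_equal(pearson_with_p(1:3, c(3, 2, 1))$r, -1.0)
  expect_error(pearson_with_p(1:5, rep(2, 5)), "constant")
  expect_error(pearson_with_p(1:2, 2:3), "at least 3")

  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(50); y <- 0.3 * x + rnorm(50)
    got <- pearson_with_p(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$n, 50L)
    # affine invariance / sign flip
    expect_equal(pearson_with_p(2 * x + 5, y)$r, got$r, tolerance = 1e-12)
    expect_equal(pearson_with_p(-x, y)$r, -got$r, tolerance = 1e-12)
  }
  # NA pairs removed pairwise-complete with adjusted n
  x <- c(rnorm(20), NA); y <- c(rnorm(20), 1)
  expect_equal(pearson_with_p(x, y)$n, 20L)
})

test_that("correlation_suite computes the six pairs per condition", {
  b <- simulate_dataset(sim_config(n_transcripts = 200L, seed = 37L))
  out <- run_pipeline(b, config = list(min_cov = 50L))
  suite <- out$integrate$correlations
  expect_setequal(unique(suite$pair),
                  c("mod_ratio~abundance", "m6a_ratio~abundance",
                    "polya~m6a_ratio", "polya~abundance",
                    "m6a_ratio~protein", "polya~protein"))
  expect_true(all(suite$n >= 3))
  expect_true(all(abs(suite$r) <= 1))
  expect_true(all(suite$p_value > 0 & suite$p_value <= 1))

  # permuted feature ids destroy the correlation
  ab <- out$integrate$abundance[condition == "control"]
  mr <- out$mod_ratio[condition == "control", .(transcript_id, condition,
                                                value = mod_ratio)]
  set.seed(41)
  mr_perm <- data.table::copy(mr)[, transcript_id := sample(transcript_id)]
  r_perm <- correlation_suite(mod_ratio = mr_perm, abundance = ab)$r
  expect_lt(abs(r_perm), 0.2)

  # fewer than 3 common features skips the pair with a warning
  expect_warning(
    correlation_suite(mod_ratio = mr[1:2], abundance = ab),
    "only 2 common")
})

test_that("multiomics_overlap does exclusive-set arithmetic", {
  ov <- multiomics_overlap(c("1", "2", "3"), c("2", "3"), "3")
  expect_equal(ov$de_mod, 1L)       # {2}
  expect_equal(ov$de_prot, 0L)
  expect_equal(ov$mod_prot, 0L)
  expect_equal(ov$all_three, 1L)    # {3}
  expect_equal(ov$total_ge2, 2L)

  ov <- multiomics_overlap(letters[1:3], letters[4:6], letters[7:9])
  expect_equal(ov$total_ge2, 0L)
  ov <- multiomics_overlap(letters[1:4], letters[1:4], letters[1:4])
  expect_equal(ov$all_three, 4L)
  expect_equal(ov$de_mod + ov$de_prot + ov$mod_prot, 0L)

  # inclusion-exclusion on random sets
  set.seed(43)
  for (i in 1:20) {
    A <- sample(letters, sample(5:20, 1))
    B <- sample(letters, sample(5:20, 1))
    C <- sample(letters, sample(5:20, 1))
    ov <- multiomics_overlap(A, B, C)
    expect_equal(ov$de_only + ov$mod_only + ov$prot_only +
                   ov$de_mod + ov$de_prot + ov$mod_prot + ov$all_three,
                 length(union(union(A, B), C)))
    expect_equal(ov$total_ge2,
                 ov$de_mod + ov$de_prot + ov$mod_prot + ov$all_three)
  }
})
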
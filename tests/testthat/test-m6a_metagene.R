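# m6a_metagene: RRACH scanning, kmer table, metagene profiles, m6a diff.

test_that("find_rrach_sites implements the RRACH consensus", {
  s <- find_rrach_sites("GGACU", "tx")
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 2L)
  expect_equal(s$kmer, "GGACU")
  # AAACA is a valid RRACH variant (the predominant kmer in conifer roots)
  expect_equal(find_rrach_sites("AAACA", "tx")$kmer, "AAACA")
  # center base must be A
  expect_equal(nrow(find_rrach_sites("AAUCA", "tx")), 0L)
  # overlapping sites are all reported: GGAACA has none, AAACAACA has two? use known:
  two <- find_rrach_sites("AGAACU", "tx")   # AGAAC? no; construct AAACAACU
  sites <- find_rrach_sites("AAACAACU", "tx")  # AAACA at 2 and ACAAC? not RRACH
  expect_true(all(sites$position >= 2 & sites$position <= 8 - 3))
  expect_error(find_rrach_sites("GGANU", "tx"), "non-alphabet.*offset 3")
})

test_that("find_rrach_sites agrees with a regex lookahead oracle", {
  set.seed(19)
  for (i in 1:25) {
    seq <- paste0(sample(c("A", "C", "G", "U"), 200, replace = TRUE,
                         prob = c(0.35, 0.15, 0.3, 0.2)), collapse = "")
    got <- find_rrach_sites(seq, "tx")$position
    m <- gregexpr("(?=[AG][AG]AC[AUC])", seq, perl = TRUE)[[1]]
    want <- if (m[1] == -1) integer() else as.integer(m) + 1L  # 0-based A offset
    expect_equal(got, want)
  }
})

test_that("kmer_frequencies covers the 12 RRACH variants and sums to one", {
  expect_equal(length(rrach_kmers()), 12L)
  sites <- data.table::data.table(kmer = c("AAACA", "AAACA", "GGACC", "GGACU"))
  kf <- kmer_frequencies(sites)
  expect_equal(nrow(kf), 12L)
  expect_equal(kf[kmer == "AAACA"]$frequency, 0.5)
  expect_equal(kf[kmer == "GGACC"]$frequency, 0.25)
  expect_equal(sum(kf$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(kf$frequency == 0), 9L)

  empty <- kmer_frequencies(data.table::data.table(kmer = character()))
  expect_true(attr(empty, "degenerate"))
  expect_equal(sum(empty$count), 0L)
  expect_error(kmer_frequencies(data.table::data.table(kmer = "AAUCA")),
               "non-RRACH")
})

test_that("uniform kmer placement recovers uniform frequencies", {
  set.seed(23)
  n <- 12000L
  sites <- data.table::data.table(kmer = sample(rrach_kmers(), n, replace = TRUE))
  kf <- kmer_frequencies(sites)
  se <- sqrt((1 / 12) * (11 / 12) / n)
  expect_true(all(abs(kf$frequency - 1 / 12) <= 3 * se))
})

test_that("metagene coordinates follow the stated conventions", {
  ann <- small_annotations()
  # full axis boundaries
  sites <- data.table::data.table(transcript_id = "txA", position = c(0L, 99L, 50L))
  cc <- metagene_coords(sites, ann, axis = "full")
  expect_equal(sort(cc$coord), sort(c(0, 1, 50 / 99)))
  prof <- metagene_full(sites, ann, n_bins = 10L)
  expect_equal(prof$count[1], 1L)                  # coord 0 in first bin
  expect_equal(prof$count[10], 1L)                 # coord 1 in last (right-closed) bin

  # region axis: cds [20,80) on length 100
  rs <- data.table::data.table(transcript_id = "txA", position = c(10L, 20L, 90L, 79L, 80L))
  rc <- metagene_coords(rs, ann, axis = "regions")
  expect_equal(rc[position == 10L]$coord, 0.5)         # 5'UTR half
  expect_equal(rc[position == 20L]$coord, 1.0)         # cds_start is CDS (start-inclusive)
  expect_equal(rc[position == 90L]$coord, 2.5)         # 3'UTR half
  expect_equal(rc[position == 79L]$region, "CDS")
  expect_equal(rc[position == 80L]$region, "3UTR")     # cds_end is 3'UTR
  expect_error(metagene_coords(
    data.table::data.table(transcript_id = "txA", position = 100L), ann,
    axis = "regions"), "outside")
})

test_that("profiles integrate to unit area per condition", {
  set.seed(31)
  ann <- data.table::data.table(transcript_id = "tx1", length = 1000L,
                                cds_start = 150L, cds_end = 750L)
  sites <- data.table::data.table(
    transcript_id = "tx1",
    position = sample(0:999, 500, replace = TRUE),
    condition = sample(c("control", "treated"), 500, replace = TRUE))
  for (prof in list(metagene_full(sites, ann),
                    metagene_regions(sites, ann))) {
    areas <- prof[, sum(density * (bin_right - bin_left)), by = condition]$V1
    expect_equal(areas, rep(1, 2), tolerance = 1e-9)
  }
  # region profile is a refinement: site totals match the full profile
  full <- metagene_full(sites, ann)
  reg <- metagene_regions(sites, ann)
  expect_equal(reg[, sum(count), by = condition], full[, sum(count), by = condition])
})

test_that("m6a_diff restricts to RRACH sites and reports the two-tier summary", {
  # one RRACH site with a strong planted effect + one non-RRACH position
  seqs <- c(tx = "AAGGACUAAA")
  sites <- find_rrach_sites(seqs)       # GGACU at offset 4
  expect_equal(sites$position, 4L)
  recs <- rbind(
    data.frame(transcript_id = "tx", position = 4L, ref_base = "A",
               sample_id = c("c1", "t1"), coverage = 200L,
               modified_count = c(20L, 100L)),
    data.frame(transcript_id = "tx", position = 8L, ref_base = "A",
               sample_id = c("c1", "t1"), coverage = 200L,
               modified_count = c(20L, 100L)),
    data.frame(transcript_id = "tx", position = 0L, ref_base = "A",
               sample_id = c("c1", "t1"), coverage = c(30L, 200L),
               modified_count = c(3L, 100L)))
  x <- modcall_table(recs, c(c1 = "control", t1 = "treated"))
  res <- m6a_diff(x, sites)
  expect_equal(nrow(res), 1L)           # non-RRACH and low-coverage rows absent
  expect_equal(res$position, 4L)
  expect_identical(res$status, "over")
  tt <- attr(res, "two_tier")
  expect_equal(tt$n_p_sig, 1L)
  expect_equal(tt$n_lfc_sig, 1L)
})

test_that("3'UTR-biased planted sites shift the treatment region profile", {
  b <- simulate_dataset(sim_config(n_transcripts = 300L, n_planted = 80L,
                                   placement_3utr_prob = 0.9, seed = 17L))
  base <- b$truth$transcripts
  # truth-level sites: constitutive RRACH sites in both conditions, planted
  # sites added to the treatment condition only
  all_sites <- find_rrach_sites(b$sequences)
  planted <- b$truth$sites
  ctrl <- data.table::as.data.table(all_sites)[
    !planted, on = c("transcript_id", "position")][, condition := "control"]
  trt <- rbind(ctrl[, .(transcript_id, position)],
               planted[, .(transcript_id, position)])[, condition := "treated"]
  prof <- metagene_regions(rbind(ctrl[, .(transcript_id, position, condition)], trt),
                           b$annotations)
  mass3 <- prof[bin_left >= 2, sum(density * (bin_right - bin_left)), by = condition]
  expect_gt(mass3[condition == "treated"]$V1, mass3[condition == "control"]$V1)
})
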
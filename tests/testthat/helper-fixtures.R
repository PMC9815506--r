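options(epidiff.quiet = TRUE)

# two transcripts, two replicates per condition on txA, one on txB
mc_fixture <- function() {
  recs <- rbind(
    data.frame(transcript_id = "txA", position = 0L, ref_base = "A",
               sample_id = c("c1", "c2", "t1", "t2"),
               coverage = c(20L, 30L, 25L, 25L),
               modified_count = c(2L, 3L, 20L, 5L)),
    data.frame(transcript_id = "txB", position = 4L, ref_base = "G",
               sample_id = c("c1", "t1"),
               coverage = c(60L, 80L),
               modified_count = c(30L, 10L)))
  modcall_table(recs, c(c1 = "control", c2 = "control",
                        t1 = "treated", t2 = "treated"))
}

# one pooled 2x2 position as a modcall table (one sample per condition)
mc_single <- function(m_c, N_c, m_t, N_t, transcript = "txA", position = 0L,
                      ref_base = "A") {
  recs <- data.frame(transcript_id = transcript, position = position,
                     ref_base = ref_base, sample_id = c("c1", "t1"),
                     coverage = c(N_c, N_t), modified_count = c(m_c, m_t))
  modcall_table(recs, c(c1 = "control", t1 = "treated"))
}

small_annotations <- function() {
  data.table::data.table(transcript_id = c("txA", "txB"),
                         length = c(100L, 200L),
                         cds_start = c(20L, 50L),
                         cds_end = c(80L, 150L))
}

# independent enumeration oracle for the two-sided Fisher p (lchoose route)
fisher_oracle <- function(m_c, u_c, m_t, u_t, rel_tol = 1e-7) {
  N1 <- m_c + u_c; N2 <- m_t + u_t; K <- m_c + m_t
  k <- max(0, K - N2):min(K, N1)
  p <- exp(lchoose(N1, k) + lchoose(N2, K - k) - lchoose(N1 + N2, K))
  pobs <- p[k == m_c]
  min(1, sum(p[p <= pobs * (1 + rel_tol)]))
}
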
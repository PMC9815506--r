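# Synthetic direct-RNA epitranscriptome datasets with planted ground truth.
#
# The generator emits every input the pipeline consumes (sequences,
# annotations, per-position modification calls, poly(A) records, count and
# protein matrices, id map) under a two-condition, three-replicate design:
# negative-binomial per-sample coverage, Bernoulli per-read modification
# around a per-transcript propensity, planted treatment effects placed
# preferentially in 3'-UTR RRACH sites, truncated-Gamma poly(A) tails whose
# per-transcript mean rises with the modification ratio, log-scale transcript
# abundance falling with it, and protein abundance coupled to it in the
# treated condition only. Couplings use an exact-correlation construction
# (noise orthogonalised against the standardized propensity), so the latent
# sample correlation hits the configured target for any seed; the poly(A)
# coupling additionally applies an attenuation correction whose read-level
# noise variance is derived from the truncated-Gamma sd at run time.

#' Configuration for the synthetic dataset generator
#'
#' Defaults state the emulated world: 2 conditions x 3 replicates, baseline
#' modification probability 0.05 with logit-normal per-transcript spread,
#' 100 planted differential sites at treatment probability 0.4 placed in the
#' 3'-UTR with probability 0.8, poly(A) tails truncated to 40-250 nt with
#' mean 91 nt and coupling r = +0.2 to the modification ratio, log-abundance
#' coupling r = -0.4, and a treatment-only protein coupling r = +0.18.
#'
#' @param n_transcripts number of transcripts.
#' @param length_range min/max transcript length (nt).
#' @param utr5_frac,utr3_frac UTR fractions of the transcript length.
#' @param samples_per_condition replicates per condition.
#' @param condition_labels two condition labels (reference first).
#' @param coverage_mean,coverage_dispersion negative-binomial per-sample,
#'   per-site coverage model (mean and size).
#' @param sites_per_transcript generic (non-RRACH) modified sites per
#'   transcript.
#' @param m6a_sites_per_transcript RRACH sites implanted per transcript.
#' @param f0 baseline modification probability (logit-normal centre).
#' @param mod_spread sd of the per-transcript spread on the logit scale.
#' @param n_planted number of planted differential sites (one per chosen
#'   transcript), each an implanted RRACH site.
#' @param f1 treatment modification probability at planted sites.
#' @param placement_3utr_prob probability a planted site goes to the 3'-UTR.
#' @param polya_mean,polya_bounds,polya_shape truncated-Gamma tail model.
#' @param polya_sd_shift sd (nt) of the per-transcript tail-mean shift.
#' @param polya_mod_r target r between tail mean and modification ratio.
#' @param polya_reads_per_sample poly(A) reads per transcript per sample.
#' @param abundance_mod_r target r between log-abundance and modification
#'   ratio.
#' @param log_abundance_mean,log_abundance_sd log2-scale abundance model.
#' @param count_dispersion negative-binomial size of the count matrix.
#' @param protein_mod_r treatment-only target r between protein abundance
#'   and modification ratio.
#' @param protein_fraction fraction of transcripts with a mapped protein.
#' @param protein_noise_sd per-sample log2 protein replicate noise.
#' @param qc_pass_prob fraction of poly(A) reads tagged PASS.
#' @param seed RNG seed, recorded in the output bundle.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 1000L, length_range = c(500L, 3000L),
                       utr5_frac = 0.15, utr3_frac = 0.25,
                       samples_per_condition = 3L,
                       condition_labels = c("control", "treated"),
                       coverage_mean = 30, coverage_dispersion = 10,
                       sites_per_transcript = 5L, m6a_sites_per_transcript = 2L,
                       f0 = 0.05, mod_spread = 1,
                       n_planted = 100L, f1 = 0.4, placement_3utr_prob = 0.8,
                       polya_mean = 91, polya_bounds = c(40, 250),
                       polya_shape = 6, polya_sd_shift = 10, polya_mod_r = 0.2,
                       polya_reads_per_sample = 15L,
                       abundance_mod_r = -0.4, log_abundance_mean = 8,
                       log_abundance_sd = 1.5, count_dispersion = 20,
                       protein_mod_r = 0.18, protein_fraction = 0.5,
                       protein_noise_sd = 0.3, qc_pass_prob = 0.97,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (f0 < 0 || f0 > 1 || f1 < 0 || f1 > 1) stopf("sim_config: f0, f1 must be in [0,1]")
  pos <- c(n_transcripts = n_transcripts,
           samples_per_condition = samples_per_condition,
           coverage_mean = coverage_mean, polya_reads_per_sample = polya_reads_per_sample)
  if (any(pos <= 0)) stopf("sim_config: %s must be positive", names(pos)[pos <= 0][1])
  if (length(condition_labels) != 2L || anyDuplicated(condition_labels)) {
    stopf("sim_config: exactly two distinct condition labels required")
  }
  if (n_planted > n_transcripts) stopf("sim_config: n_planted > n_transcripts")
  if (n_planted > 0L && f1 == f0) {
    warning("sim_config: f1 equals f0 with planted sites; power will be nil",
            call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Mix noise into standardized s with an exactly attained sample correlation r.
mix_exact <- function(s, r) {
  n <- length(s)
  if (n < 3L || sd(s) == 0) stopf("mix_exact: need >= 3 values with spread")
  s_std <- (s - mean(s)) / sd(s)
  e <- rnorm(n)
  e <- e - mean(e)
  e <- e - s_std * sum(e * s_std) / sum(s_std^2)
  r * s_std + sqrt(1 - r^2) * e / sd(e)
}

# Truncated-Gamma helpers: scale solved so the truncated mean hits `mean`.
trunc_gamma_scale <- function(mean, shape, lower, upper) {
  f <- function(scale) trunc_gamma_moment(shape, scale, lower, upper, 1L) - mean
  uniroot(f, c(mean / shape / 3, mean / shape * 3), extendInt = "upX",
          tol = 1e-10)$root
}

trunc_gamma_moment <- function(shape, scale, lower, upper, order) {
  mass <- pgamma(upper, shape, scale = scale) - pgamma(lower, shape, scale = scale)
  raw <- if (order == 1L) {
    shape * scale *
      (pgamma(upper, shape + 1, scale = scale) - pgamma(lower, shape + 1, scale = scale))
  } else {
    shape * (shape + 1) * scale^2 *
      (pgamma(upper, shape + 2, scale = scale) - pgamma(lower, shape + 2, scale = scale))
  }
  raw / mass
}

rtrunc_gamma <- function(n, shape, scale, lower, upper) {
  lo <- pgamma(lower, shape, scale = scale)
  hi <- pgamma(upper, shape, scale = scale)
  qgamma(runif(n, lo, hi), shape, scale = scale)
}

# Pick an implant position for the methylated A inside `region` of a
# transcript, keeping >= 5 nt from previous implants so kmers never collide.
implant_position <- function(region, cds_start, cds_end, len, taken) {
  bounds <- switch(region,
                   "5UTR" = c(0L, cds_start),
                   "CDS" = c(cds_start, cds_end),
                   "3UTR" = c(cds_end, len))
  lo <- max(2L, bounds[1]); hi <- min(len - 3L, bounds[2] - 1L)
  if (hi < lo) return(NA_integer_)
  for (i in seq_len(100L)) {
    p <- if (hi == lo) lo else sample(lo:hi, 1L)
    if (!length(taken) || min(abs(taken - p)) >= 5L) return(p)
  }
  NA_integer_
}

sample_rrach <- function(n) {
  paste0(sample(c("A", "G"), n, replace = TRUE),
         sample(c("A", "G"), n, replace = TRUE), "A", "C",
         sample(c("A", "C", "U"), n, replace = TRUE))
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' See the package vignette for the generative model. Identical seeds give
#' identical bundles.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_bundle`: `modcalls` ([modcall_table()]),
#'   `sequences` (named RNA character vector), `annotations`, `polya`
#'   records, `counts` and `proteins` matrices, `id_map`, `truth` (lists
#'   `sites` and `transcripts`), and the `config` (seed included).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed, {
    n <- config$n_transcripts
    tx_ids <- sprintf("tx%05d", seq_len(n))
    lens <- sample(config$length_range[1]:config$length_range[2], n, replace = TRUE)
    cds_start <- pmax(1L, as.integer(round(config$utr5_frac * lens)))
    cds_end <- pmin(lens - 1L, lens - as.integer(round(config$utr3_frac * lens)))
    ann <- data.table::data.table(transcript_id = tx_ids, length = lens,
                                  cds_start = cds_start, cds_end = cds_end)
    validate_annotations(ann)

    seq_chars <- lapply(lens, function(L)
      sample(RNA_BASES, L, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)))

    # planted differential sites: one implanted RRACH site per chosen transcript
    planted_tx <- if (config$n_planted > 0L) sort(sample.int(n, config$n_planted)) else integer()
    planted_region <- data.table::fifelse(
      runif(length(planted_tx)) < config$placement_3utr_prob, "3UTR",
      sample(c("5UTR", "CDS"), length(planted_tx), replace = TRUE))

    implants <- vector("list", n)  # per transcript: positions already implanted
    place_site <- function(i, region) {
      p <- implant_position(region, cds_start[i], cds_end[i], lens[i], implants[[i]])
      if (is.na(p)) stopf("simulate_dataset: transcript %s too short to host requested sites", tx_ids[i])
      kmer <- strsplit(sample_rrach(1L), "")[[1]]
      seq_chars[[i]][(p - 1L):(p + 3L)] <<- kmer
      implants[[i]] <<- c(implants[[i]], p)
      p
    }
    planted_pos <- integer(length(planted_tx))
    for (k in seq_along(planted_tx)) {
      planted_pos[k] <- place_site(planted_tx[k], planted_region[k])
    }
    # constitutive RRACH sites on every transcript (region ~ length-weighted)
    m6a_rows <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(config$m6a_sites_per_transcript)) {
        spans <- c(`5UTR` = cds_start[i], CDS = cds_end[i] - cds_start[i],
                   `3UTR` = lens[i] - cds_end[i])
        region <- sample(names(spans), 1L, prob = spans / sum(spans))
        m6a_rows[[length(m6a_rows) + 1L]] <-
          data.table::data.table(tx = i, position = place_site(i, region))
      }
    }
    m6a_sites <- data.table::rbindlist(m6a_rows)

    sequences <- setNames(vapply(seq_chars, paste0, "", collapse = ""), tx_ids)

    # generic background sites (any base), avoiding implanted positions
    bg_rows <- lapply(seq_len(n), function(i) {
      cand <- setdiff(sample.int(lens[i], min(lens[i], config$sites_per_transcript + 10L)) - 1L,
                      implants[[i]])
      data.table::data.table(tx = i, position = head(cand, config$sites_per_transcript))
    })
    bg_sites <- data.table::rbindlist(bg_rows)

    sites <- rbind(
      data.table::data.table(tx = planted_tx, position = planted_pos, type = "planted"),
      m6a_sites[, .(tx, position, type = "m6a")],
      bg_sites[, .(tx, position, type = "bg")])
    sites[, transcript_id := tx_ids[tx]]
    data.table::setkey(sites, tx, position)

    # per-transcript modification propensity (logit-normal around f0)
    f_tx <- plogis(qlogis(config$f0) + config$mod_spread * rnorm(n))
    sites[, f_ctrl := f_tx[tx]]
    sites[, f_treat := data.table::fifelse(type == "planted", config$f1, f_tx[tx])]
    sites[, ref_base := substr(sequences[transcript_id], position + 1L, position + 1L)]

    # per-sample coverage and modified counts
    labs <- config$condition_labels
    samples <- c(sprintf("%s_%d", labs[1], seq_len(config$samples_per_condition)),
                 sprintf("%s_%d", labs[2], seq_len(config$samples_per_condition)))
    cmap <- setNames(rep(labs, each = config$samples_per_condition), samples)
    calls <- data.table::rbindlist(lapply(samples, function(sm) {
      trt <- cmap[sm] == labs[2]
      cov <- rnbinom(nrow(sites), mu = config$coverage_mean,
                     size = config$coverage_dispersion)
      f <- if (trt) sites$f_treat else sites$f_ctrl
      data.table::data.table(transcript_id = sites$transcript_id,
                             position = sites$position,
                             ref_base = sites$ref_base,
                             sample_id = sm,
                             coverage = cov,
                             modified_count = rbinom(nrow(sites), cov, f))
    }))
    modcalls <- modcall_table(calls, cmap)

    # true transcript-level modification ratios (coverage-expected weights equal)
    truth_tx <- sites[, .(f_true_control = mean(f_ctrl),
                          f_true_treated = mean(f_treat)), by = .(tx, transcript_id)]
    data.table::setkey(truth_tx, tx)
    s <- f_tx  # couplings act on the baseline propensity (f scale)

    # abundance: log2 scale, exact target correlation with the propensity
    a <- config$log_abundance_mean +
      config$log_abundance_sd * mix_exact(s, config$abundance_mod_r)
    lib <- exp(rnorm(length(samples), 0, 0.1))
    mu <- outer(2^a, lib)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = config$count_dispersion),
                     nrow = n, dimnames = list(tx_ids, samples))
    counts <- abundance_matrix(counts, "counts")

    # poly(A): truncated-Gamma base + per-transcript shift; the shift's
    # latent correlation is inflated to offset read-sampling attenuation
    lb <- config$polya_bounds[1]; ub <- config$polya_bounds[2]
    scale <- trunc_gamma_scale(config$polya_mean, config$polya_shape, lb, ub)
    m1 <- trunc_gamma_moment(config$polya_shape, scale, lb, ub, 1L)
    v_read <- trunc_gamma_moment(config$polya_shape, scale, lb, ub, 2L) - m1^2
    reads_per_cond <- config$polya_reads_per_sample * config$samples_per_condition
    rho_eff <- min(0.99, config$polya_mod_r *
                     sqrt(config$polya_sd_shift^2 + v_read / reads_per_cond) /
                     config$polya_sd_shift)
    d <- config$polya_sd_shift * mix_exact(s, rho_eff)
    nr <- config$polya_reads_per_sample
    polya <- data.table::rbindlist(lapply(samples, function(sm) {
      base <- rtrunc_gamma(n * nr, config$polya_shape, scale, lb, ub)
      len <- pmin(ub, pmax(lb, base + rep(d, each = nr)))
      data.table::data.table(
        read_id = sprintf("%s_%s_r%02d", rep(tx_ids, each = nr), sm, seq_len(nr)),
        transcript_id = rep(tx_ids, each = nr),
        polya_length = len,
        qc_tag = data.table::fifelse(runif(n * nr) < config$qc_pass_prob, "PASS",
                                     sample(setdiff(NANOPOLISH_QC_TAGS, "PASS"),
                                            n * nr, replace = TRUE)),
        sample_id = sm)
    }))

    # proteins: coupled to the propensity in the treated condition only;
    # the control latent is orthogonalised, so its sample correlation is ~0
    n_prot <- as.integer(round(config$protein_fraction * n))
    prot_tx <- sort(sample.int(n, n_prot))
    prot_ids <- sub("^tx", "prot", tx_ids[prot_tx])
    id_map <- data.table::data.table(transcript_id = tx_ids[prot_tx],
                                     protein_id = prot_ids)
    lat_t <- mix_exact(s[prot_tx], config$protein_mod_r)
    lat_c <- mix_exact(s[prot_tx], 0)
    prot_log <- vapply(samples, function(sm) {
      lat <- if (cmap[sm] == labs[2]) lat_t else lat_c
      10 + lat + rnorm(n_prot, 0, config$protein_noise_sd)
    }, numeric(n_prot))
    proteins <- abundance_matrix(
      matrix(2^prot_log, nrow = n_prot, dimnames = list(prot_ids, samples)),
      "protein")

    truth_sites <- if (length(planted_tx)) {
      data.table::data.table(
        transcript_id = tx_ids[planted_tx], position = planted_pos,
        region = planted_region, f0 = f_tx[planted_tx], f1 = config$f1)
    } else {
      data.table::data.table(transcript_id = character(), position = integer(),
                             region = character(), f0 = numeric(), f1 = numeric())
    }
    truth_transcripts <- truth_tx[, .(
      transcript_id, f_true_control, f_true_treated,
      polya_mean_true = config$polya_mean + d[tx],
      log2_abundance = a[tx],
      protein_id = ifelse(tx %in% prot_tx,
                          sub("^tx", "prot", transcript_id), NA_character_))]

    structure(list(modcalls = modcalls, sequences = sequences,
                   annotations = ann, polya = polya, counts = counts,
                   proteins = proteins, id_map = id_map,
                   truth = list(sites = truth_sites,
                                transcripts = truth_transcripts),
                   condition_map = cmap, config = config),
              class = "sim_bundle")
  })
}

#' Simulate null positions (both conditions at the same probability)
#'
#' Type-I-error harness: every position is drawn from the same modification
#' probability in both conditions, one pooled pseudo-sample per condition.
#'
#' @param n number of positions (each on its own transcript).
#' @param coverage reads per condition; fixed when `dispersion` is `NULL`,
#'   else negative-binomial with that mean.
#' @param f0 shared modification probability.
#' @param seed RNG seed.
#' @param dispersion optional negative-binomial size for the coverage.
#' @param condition_labels two condition labels.
#' @return A [modcall_table()] with samples `<label>_1` per condition.
#' @export
simulate_null_positions <- function(n, coverage = 50L, f0 = 0.2, seed = 1L,
                                    dispersion = NULL,
                                    condition_labels = c("control", "treated")) {
  if (n < 1L) stopf("simulate_null_positions: n must be >= 1")
  simulate_two_group_positions(n, coverage, f0, f0, seed, dispersion,
                               condition_labels)
}

#' Simulate planted differential positions
#'
#' Power harness: control positions at probability `f0`, treatment at `f1`.
#'
#' @inheritParams simulate_null_positions
#' @param f1 treatment modification probability.
#' @return A [modcall_table()].
#' @export
simulate_planted_positions <- function(n, coverage = 150L, f0 = 0.1, f1 = 0.4,
                                       seed = 1L, dispersion = NULL,
                                       condition_labels = c("control", "treated")) {
  if (n < 1L) stopf("simulate_planted_positions: n must be >= 1")
  simulate_two_group_positions(n, coverage, f0, f1, seed, dispersion,
                               condition_labels)
}

simulate_two_group_positions <- function(n, coverage, f_ctrl, f_treat, seed,
                                         dispersion, condition_labels) {
  if (f_ctrl < 0 || f_ctrl > 1 || f_treat < 0 || f_treat > 1) {
    stopf("modification probabilities must be in [0,1]")
  }
  with_rng(seed, {
    draw_cov <- function() {
      if (is.null(dispersion)) rep(as.integer(coverage), n)
      else rnbinom(n, mu = coverage, size = dispersion)
    }
    labs <- condition_labels
    ids <- sprintf("null%06d", seq_len(n))
    cov_c <- draw_cov(); cov_t <- draw_cov()
    calls <- data.table::data.table(
      transcript_id = rep(ids, 2L), position = 0L, ref_base = "A",
      sample_id = rep(sprintf("%s_1", labs), each = n),
      coverage = c(cov_c, cov_t),
      modified_count = c(rbinom(n, cov_c, f_ctrl), rbinom(n, cov_t, f_treat)))
    modcall_table(calls, setNames(labs, sprintf("%s_1", labs)))
  })
}

#' Write a synthetic bundle to disk in the pipeline's file dialects
#'
#' @param bundle a `sim_bundle` from [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_sim_bundle <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_modcalls(bundle$modcalls, p("modcalls.tsv"))
  write_fasta(bundle$sequences, p("transcripts.fasta"))
  write_annotations(bundle$annotations, p("annotations.tsv"))
  polya <- bundle$polya[, .(readname = read_id, contig = transcript_id,
                            polya_length, qc_tag, sample_id)]
  data.table::fwrite(polya, p("polya.tsv"), sep = "\t")
  write_matrix(bundle$counts, p("counts.tsv"), id_col = "transcript_id")
  write_matrix(bundle$proteins, p("proteins.tsv"), id_col = "protein_id")
  data.table::fwrite(bundle$id_map, p("id_map.tsv"), sep = "\t")
  ts <- data.table::copy(bundle$truth$sites)[, position := position + 1L]
  data.table::fwrite(ts, p("truth_sites.tsv"), sep = "\t")
  data.table::fwrite(bundle$truth$transcripts, p("truth_transcripts.tsv"), sep = "\t")
  cm <- data.table::data.table(sample_id = names(bundle$condition_map),
                               condition = unname(bundle$condition_map))
  data.table::fwrite(cm, p("conditions.tsv"), sep = "\t")
  cfg <- bundle$config
  cfg_lines <- vapply(names(cfg), function(k)
    sprintf("%s: %s", k, paste(cfg[[k]], collapse = ",")), "")
  writeLines(cfg_lines, p("sim_config.txt"))
  files <- c("modcalls.tsv", "transcripts.fasta", "annotations.tsv", "polya.tsv",
             "counts.tsv", "proteins.tsv", "id_map.tsv", "truth_sites.tsv",
             "truth_transcripts.tsv", "conditions.tsv", "sim_config.txt")
  invisible(setNames(file.path(outdir, files), files))
}
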
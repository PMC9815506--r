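# End-to-end orchestration: io -> diffmod -> m6a -> polya -> integrate,
# with a machine-readable run report.

#' Read a flat key:value run configuration file
#'
#' One `key: value` per line, `#` comments allowed; numeric-looking values
#' are coerced, comma-separated values become vectors.
#'
#' @param path config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")])
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stopf("read_run_config: unparseable line: %s", lines[bad][1])
  out <- lapply(kv, function(m) {
    v <- strsplit(m[3], ",\\s*")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  setNames(out, vapply(kv, function(m) trimws(m[2]), ""))
}

default_run_config <- function() {
  list(min_cov = 50L, alpha = 0.05, lfc_min = 0.5, adjust = "none",
       min_cpm = 2, min_samples = 2L, n_bins = 30L, bins_per_region = 20L,
       polya_accept = "PASS", min_mod_frac = 0.1, reference = NULL)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage %s: %s", name, conditionMessage(e))
  })
}

#' Run the full differential epitranscriptome pipeline
#'
#' Stages run in dependency order: input loading, per-position differential
#' modification calling, RRACH/m6A metagene analysis, poly(A) summarisation,
#' and multi-omics integration. Any stage error aborts with the stage name.
#' Rerunning with an identical bundle and config reproduces the outputs.
#'
#' For the metagene profiles a RRACH site is counted as methylated in a
#' condition when its pooled modified fraction there is at least
#' `min_mod_frac` (default 0.1) after the coverage filter.
#'
#' @param bundle either a `sim_bundle` from [simulate_dataset()] or a named
#'   list with `modcalls` (a [modcall_table()]) and optionally `sequences`,
#'   `annotations`, `polya`, `counts`, `proteins`, `id_map`, plus optional
#'   significance sets `sig_de` / `sig_prot` (character id vectors) for the
#'   overlap report.
#' @param config named list overriding the defaults (`min_cov = 50`,
#'   `alpha = 0.05`, `lfc_min = 0.5`, `adjust = "none"`, `min_cpm = 2`,
#'   `min_samples = 2`, `n_bins = 30`, `bins_per_region = 20`,
#'   `polya_accept = "PASS"`, `min_mod_frac = 0.1`), or a path readable by
#'   [read_run_config()].
#' @param outdir optional directory; when given, every stage table plus
#'   `report.json` is written there.
#' @return List with the stage outputs and `report` (thresholds, per-stage
#'   filter counts whose arithmetic is self-consistent, package version).
#' @export
run_pipeline <- function(bundle, config = list(), outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  out <- list()
  report <- list(package_version = as.character(packageVersion("epidiff")),
                 thresholds = cfg[c("min_cov", "alpha", "lfc_min", "adjust",
                                    "min_cpm", "min_samples", "min_mod_frac")],
                 seed = bundle$config$seed %||% NA)

  modcalls <- stage("io", {
    if (is.null(bundle$modcalls) || !nrow(bundle$modcalls)) {
      stopf("empty modification table")
    }
    bundle$modcalls
  })

  # --- diffmod ---------------------------------------------------------
  res <- stage("diffmod", diffmod_scan(
    modcalls, min_cov = cfg$min_cov, alpha = cfg$alpha, lfc_min = cfg$lfc_min,
    adjust = cfg$adjust, reference = cfg$reference))
  out$diffmod <- res
  pooled <- pool_counts(modcalls, reference = cfg$reference)
  filt <- coverage_filter(pooled, min_cov = cfg$min_cov)
  tally <- attr(res, "tally", exact = TRUE)
  report$diffmod <- c(
    list(positions_in = nrow(pooled),
         positions_retained = nrow(res),
         positions_removed = attr(res, "removed", exact = TRUE)),
    tally[c("n_over_positions", "n_under_positions", "n_sig_positions",
            "n_transcripts_over", "n_transcripts_under", "n_transcripts_both",
            "n_transcripts_modified")])
  report$diffmod$split_check <- check_count_split(
    c(report$diffmod$n_over_positions, report$diffmod$n_under_positions),
    report$diffmod$n_sig_positions)
  ref_lab <- attr(res, "reference", exact = TRUE)
  trt_lab <- attr(res, "treatment", exact = TRUE)

  mod_ratio <- rbind(transcript_mod_ratio(filt, "reference"),
                     transcript_mod_ratio(filt, "treatment"))
  out$mod_ratio <- mod_ratio

  # --- m6a -------------------------------------------------------------
  if (!is.null(bundle$sequences)) {
    out$m6a <- stage("m6a", {
      sites <- find_rrach_sites(bundle$sequences)
      kmers <- kmer_frequencies(sites)
      filt_sites <- data.table::as.data.table(filt)[
        sites, on = c("transcript_id", "position"), nomatch = NULL]
      meth <- rbind(
        filt_sites[N_c >= cfg$min_cov & m_c / N_c >= cfg$min_mod_frac,
                   .(transcript_id, position, kmer, condition = ref_lab)],
        filt_sites[N_t >= cfg$min_cov & m_t / N_t >= cfg$min_mod_frac,
                   .(transcript_id, position, kmer, condition = trt_lab)])
      prof_full <- prof_reg <- NULL
      if (!is.null(bundle$annotations) && nrow(meth)) {
        prof_full <- metagene_full(meth, bundle$annotations, n_bins = cfg$n_bins)
        prof_reg <- metagene_regions(meth, bundle$annotations,
                                     bins_per_region = cfg$bins_per_region)
      }
      diff <- if (nrow(filt_sites)) {
        m6a_diff(modcalls, sites, min_cov = cfg$min_cov, alpha = cfg$alpha,
                 lfc_min = cfg$lfc_min, adjust = cfg$adjust,
                 reference = cfg$reference)
      }
      m6a_ratio <- if (nrow(filt_sites)) {
        fs <- filt_sites
        for (a in c("reference", "treatment")) data.table::setattr(fs, a, attr(filt, a))
        rbind(transcript_mod_ratio(fs, "reference"),
              transcript_mod_ratio(fs, "treatment"))
      }
      list(sites = sites, kmers = kmers, methylated = meth,
           profile_full = prof_full, profile_regions = prof_reg,
           diff = diff, m6a_ratio = m6a_ratio)
    })
    report$m6a <- list(
      n_rrach_sites = nrow(out$m6a$sites),
      n_methylated_calls = nrow(out$m6a$methylated),
      two_tier = attr(out$m6a$diff, "two_tier", exact = TRUE))
  }

  # --- polya -----------------------------------------------------------
  if (!is.null(bundle$polya)) {
    out$polya <- stage("polya", {
      kept <- filter_polya_pass(bundle$polya, accepted_tags = cfg$polya_accept)
      summ <- polya_summaries(kept, condition_map(modcalls))
      hist <- polya_histogram(kept, condition_map = condition_map(modcalls))
      list(records = kept, summaries = summ, histogram = hist)
    })
    report$polya <- list(records_in = nrow(bundle$polya),
                         records_kept = nrow(out$polya$records),
                         records_removed = nrow(bundle$polya) - nrow(out$polya$records))
  }

  # --- integrate -------------------------------------------------------
  if (!is.null(bundle$counts)) {
    out$integrate <- stage("integrate", {
      cpm <- cpm_normalize(bundle$counts)
      kept <- expression_filter(cpm, min_cpm = cfg$min_cpm,
                                min_samples = cfg$min_samples)
      cmap <- condition_map(modcalls)
      cond_of <- unname(cmap[colnames(kept)])
      ab <- data.table::rbindlist(lapply(unique(cond_of), function(cn) {
        data.table::data.table(
          transcript_id = rownames(kept), condition = cn,
          value = rowMeans(log2(kept[, cond_of == cn, drop = FALSE] + 1)))
      }))
      polya_layer <- if (!is.null(out$polya)) {
        out$polya$summaries$per_transcript[
          , .(transcript_id, condition, value = mean_length)]
      }
      prot_layer <- if (!is.null(bundle$proteins)) {
        pcond <- unname(cmap[colnames(bundle$proteins)])
        data.table::rbindlist(lapply(unique(pcond), function(cn) {
          data.table::data.table(
            protein_id = rownames(bundle$proteins), condition = cn,
            value = rowMeans(log2(bundle$proteins[, pcond == cn, drop = FALSE] + 1)))
        }))
      }
      suite <- correlation_suite(
        mod_ratio = mod_ratio[, .(transcript_id, condition, value = mod_ratio)],
        m6a_ratio = if (!is.null(out$m6a$m6a_ratio))
          out$m6a$m6a_ratio[, .(transcript_id, condition, value = mod_ratio)],
        abundance = ab, polya = polya_layer,
        protein = prot_layer, id_map = bundle$id_map)
      overlap <- NULL
      if (!is.null(bundle$sig_de) && !is.null(bundle$sig_prot)) {
        sig_mod <- unique(out$diffmod[status != "ns"]$transcript_id)
        prot_tx <- if (!is.null(bundle$id_map)) {
          map <- data.table::as.data.table(bundle$id_map)
          map[protein_id %in% bundle$sig_prot]$transcript_id
        } else bundle$sig_prot
        overlap <- multiomics_overlap(bundle$sig_de, sig_mod, prot_tx)
      }
      list(cpm = cpm, filtered = kept, abundance = ab,
           correlations = suite, overlap = overlap)
    })
    report$integrate <- list(
      transcripts_in = nrow(out$integrate$cpm),
      transcripts_retained = nrow(out$integrate$filtered),
      transcripts_removed = nrow(out$integrate$cpm) - nrow(out$integrate$filtered),
      overlap = if (!is.null(out$integrate$overlap))
        unclass(out$integrate$overlap))
  }

  # planted-site recovery against the generator's truth ledger, if present
  if (!is.null(bundle$truth$sites) && nrow(bundle$truth$sites)) {
    ts <- data.table::as.data.table(bundle$truth$sites)
    hit <- out$diffmod[ts, on = c("transcript_id", "position"), nomatch = NULL]
    report$recovery <- list(
      n_planted = nrow(ts), n_tested = nrow(hit),
      n_flagged_over = sum(hit$status == "over"),
      sensitivity = if (nrow(hit)) sum(hit$status == "over") / nrow(hit) else NA)
  }

  out$report <- report
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  dm <- data.table::copy(out$diffmod)[, position := position + 1L]
  data.table::fwrite(dm, p("diffmod.tsv"), sep = "\t")
  if (!is.null(out$m6a)) {
    st <- data.table::copy(out$m6a$sites)[, position := position + 1L]
    data.table::fwrite(st, p("m6a_sites.tsv"), sep = "\t")
    data.table::fwrite(out$m6a$kmers, p("kmer_frequencies.tsv"), sep = "\t")
    if (!is.null(out$m6a$profile_full)) {
      data.table::fwrite(out$m6a$profile_full, p("metagene_full.tsv"), sep = "\t")
      data.table::fwrite(out$m6a$profile_regions, p("metagene_regions.tsv"), sep = "\t")
    }
  }
  if (!is.null(out$polya)) {
    data.table::fwrite(out$polya$summaries$per_transcript,
                       p("polya_summaries.tsv"), sep = "\t")
    data.table::fwrite(out$polya$summaries$per_condition,
                       p("polya_condition_means.tsv"), sep = "\t")
    data.table::fwrite(out$polya$histogram, p("polya_histogram.tsv"), sep = "\t")
  }
  if (!is.null(out$integrate)) {
    data.table::fwrite(out$integrate$correlations, p("correlations.tsv"), sep = "\t")
    if (!is.null(out$integrate$overlap)) {
      ov <- out$integrate$overlap
      data.table::fwrite(data.table::data.table(metric = names(unclass(ov)),
                                                value = unlist(unclass(ov))),
                         p("overlap.tsv"), sep = "\t")
    }
  }
  jsonlite::write_json(out$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(outdir)
}
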
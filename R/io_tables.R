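# Table and sequence I/O.
#
# All positions are 0-based half-open internally; every file dialect uses
# 1-based inclusive positions (the convention of genome browsers and of the
# "position 462 on the contig" style of reporting).

RNA_BASES <- c("A", "C", "G", "U")

NANOPOLISH_QC_TAGS <- c("PASS", "ADAPTER", "NOREGION", "SUFFCLIP", "READ_FAILED_LOAD")

read_tsv_nocomment <- function(path, what) {
  if (!file.exists(path)) stopf("%s: file not found: %s", what, path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stopf("%s: no data rows in %s", what, path)
  data.table::fread(text = lines, sep = "\t", header = TRUE, data.table = TRUE)
}

map_t_to_u <- function(base, context) {
  nT <- sum(base %in% c("T", "t"))
  if (nT > 0) {
    ed_log("%s: mapped %d ref_base values T -> U (RNA alphabet)", context, nT)
    base[base %in% c("T", "t")] <- "U"
  }
  toupper(base)
}

#' Construct and validate a per-position modification-call table
#'
#' The central object of the pipeline: one row per (transcript, position,
#' sample) holding read coverage and the number of reads carrying a
#' modification at that position, plus a sample-to-condition mapping with
#' exactly two condition labels (the two-group design).
#'
#' @param records data.frame with columns `transcript_id`, `position`
#'   (0-based), `ref_base` (A/C/G/U; T silently mapped to U and logged),
#'   `sample_id`, `coverage`, `modified_count`.
#' @param condition_map named character vector mapping every `sample_id` to
#'   one of exactly two condition labels.
#' @return A `data.table` of class `modcall_table` with a `condition_map`
#'   attribute.
#' @export
modcall_table <- function(records, condition_map) {
  assert_cols(records, c("transcript_id", "position", "ref_base", "sample_id",
                         "coverage", "modified_count"), "modcall_table")
  dt <- data.table::as.data.table(records)[
    , .(transcript_id = as.character(transcript_id),
        position = as.integer(position),
        ref_base = as.character(ref_base),
        sample_id = as.character(sample_id),
        coverage = as.integer(coverage),
        modified_count = as.integer(modified_count))]
  dt[, ref_base := map_t_to_u(ref_base, "modcall_table")]
  bad <- which(!dt$ref_base %in% RNA_BASES)
  if (length(bad)) stopf("modcall_table: invalid ref_base %s at row %d",
                         dt$ref_base[bad[1]], bad[1])
  bad <- which(dt$position < 0L | dt$coverage < 0L | dt$modified_count < 0L)
  if (length(bad)) stopf("modcall_table: negative position/coverage/modified_count at row %d", bad[1])
  bad <- which(dt$modified_count > dt$coverage)
  if (length(bad)) {
    stopf("modcall_table: modified_count (%d) > coverage (%d) at row %d (%s pos %d sample %s)",
          dt$modified_count[bad[1]], dt$coverage[bad[1]], bad[1],
          dt$transcript_id[bad[1]], dt$position[bad[1]] + 1L, dt$sample_id[bad[1]])
  }
  if (anyDuplicated(dt, by = c("transcript_id", "position", "sample_id"))) {
    d <- dt[duplicated(dt, by = c("transcript_id", "position", "sample_id"))][1]
    stopf("modcall_table: duplicate record for (%s, %d, %s)",
          d$transcript_id, d$position + 1L, d$sample_id)
  }
  condition_map <- validate_condition_map(condition_map, unique(dt$sample_id))
  data.table::setkey(dt, transcript_id, position, sample_id)
  data.table::setattr(dt, "condition_map", condition_map)
  data.table::setattr(dt, "class", c("modcall_table", class(data.table::data.table())))
  dt[]
}

validate_condition_map <- function(condition_map, samples) {
  if (is.null(names(condition_map)) || any(!nzchar(names(condition_map)))) {
    stopf("condition_map must be a named character vector (sample -> condition)")
  }
  condition_map <- setNames(as.character(condition_map), names(condition_map))
  unknown <- setdiff(samples, names(condition_map))
  if (length(unknown)) stopf("unknown sample_id(s) not in condition_map: %s",
                             paste(unknown, collapse = ", "))
  conds <- sort(unique(unname(condition_map)))
  if (length(conds) != 2L) {
    stopf("exactly two condition labels are required, got %d (%s)",
          length(conds), paste(conds, collapse = ", "))
  }
  condition_map
}

#' Condition map of a modification-call table
#' @param x a `modcall_table`.
#' @return Named character vector mapping sample ids to condition labels.
#' @export
condition_map <- function(x) attr(x, "condition_map", exact = TRUE)

#' Read a modification-call table from the canonical TSV dialect
#'
#' Columns `transcript_id, position, ref_base, sample_id, coverage,
#' modified_count`, tab-separated, `#` comment lines allowed, positions
#' 1-based in the file.
#'
#' @inheritParams modcall_table
#' @param path path to the TSV file.
#' @return A validated [modcall_table()].
#' @export
read_modcalls <- function(path, condition_map) {
  dt <- read_tsv_nocomment(path, "read_modcalls")
  assert_cols(dt, c("transcript_id", "position", "ref_base", "sample_id",
                    "coverage", "modified_count"), "read_modcalls")
  dt[, position := as.integer(position) - 1L]
  modcall_table(dt, condition_map)
}

#' Write a modification-call table (1-based positions)
#' @param x a `modcall_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_modcalls <- function(x, path) {
  out <- data.table::as.data.table(x)
  out[, position := position + 1L]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Import Tombo-style coverage and fraction browser tracks for one sample
#'
#' Consumes the per-position `coverage` and `fraction` (modified) text tracks
#' emitted per sample and converts the fraction to an integer modified-read
#' count: `round(fraction * coverage)` with ties rounded away from zero (the
#' tracks carry fractions; the Fisher machinery needs counts).
#'
#' @param coverage_track,fraction_track data.frame (`transcript_id`,
#'   `position` 1-based, `value`) or path to such a TSV.
#' @param sample_id sample label attached to every record.
#' @return `data.table` fragment with `ref_base = NA` (fill via
#'   [set_ref_base()]), positions 0-based.
#' @export
import_tombo_tracks <- function(coverage_track, fraction_track, sample_id) {
  load_track <- function(x, what) {
    if (is.character(x) && length(x) == 1L) x <- read_tsv_nocomment(x, what)
    assert_cols(x, c("transcript_id", "position", "value"), what)
    data.table::as.data.table(x)[, .(transcript_id = as.character(transcript_id),
                                     position = as.integer(position),
                                     value = as.numeric(value))]
  }
  cov <- load_track(coverage_track, "coverage track")
  frac <- load_track(fraction_track, "fraction track")
  kc <- paste(cov$transcript_id, cov$position)
  kf <- paste(frac$transcript_id, frac$position)
  only_c <- setdiff(kc, kf); only_f <- setdiff(kf, kc)
  if (length(only_c) || length(only_f)) {
    stopf("tracks do not cover identical keys; e.g. %s",
          paste(head(c(only_c, only_f), 5L), collapse = "; "))
  }
  if (any(frac$value < 0 | frac$value > 1)) {
    bad <- frac[value < 0 | value > 1][1]
    stopf("fraction outside [0,1]: %s position %d has %g",
          bad$transcript_id, bad$position, bad$value)
  }
  merged <- merge(cov, frac, by = c("transcript_id", "position"),
                  suffixes = c(".cov", ".frac"))
  merged[, .(transcript_id,
             position = position - 1L,
             ref_base = NA_character_,
             sample_id = sample_id,
             coverage = as.integer(round_away(value.cov)),
             modified_count = as.integer(round_away(value.frac * value.cov)))]
}

#' Fill ref_base of a modcall fragment from transcript sequences
#' @param tbl data.frame with `transcript_id` and 0-based `position`.
#' @param sequences named character vector or `RNAStringSet`.
#' @return The table with `ref_base` looked up from the sequences.
#' @export
set_ref_base <- function(tbl, sequences) {
  seqs <- as_rna_character(sequences)
  dt <- data.table::as.data.table(tbl)
  miss <- setdiff(unique(dt$transcript_id), names(seqs))
  if (length(miss)) stopf("set_ref_base: no sequence for %s", miss[1])
  if (any(dt$position >= nchar(seqs[dt$transcript_id]))) {
    stopf("set_ref_base: position beyond sequence length")
  }
  dt[, ref_base := substr(seqs[transcript_id], position + 1L, position + 1L)]
  dt[]
}

as_rna_character <- function(sequences) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) && length(sequences) == 1L) names(sequences) <- "seq1"
  out <- toupper(sequences)
  chartr("T", "U", out)
}

#' Read transcript annotations (CDS intervals) from GFF3 or TSV
#'
#' GFF3: one `CDS` feature span per transcript, transcript ids in the seqid
#' column; transcript lengths come from `##sequence-region` pragmas unless
#' supplied via `lengths`. TSV: columns `transcript_id, length, cds_start,
#' cds_end` (1-based inclusive CDS). Coordinates are converted to the
#' internal 0-based half-open convention, so 5'UTR = `[0, cds_start)`,
#' CDS = `[cds_start, cds_end)`, 3'UTR = `[cds_end, length)`.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or TSV file.
#' @param lengths optional named vector of transcript lengths (nt), needed
#'   for GFF3 files without `##sequence-region` pragmas.
#' @return `data.table` (`transcript_id`, `length`, `cds_start`, `cds_end`),
#'   0-based half-open.
#' @export
read_annotations <- function(path, lengths = NULL) {
  if (!file.exists(path)) stopf("read_annotations: file not found: %s", path)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    startsWith(readLines(path, n = 1L), "##gff-version")
  if (is_gff) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    if (!length(gr)) stopf("read_annotations: no CDS features in %s", path)
    dt <- data.table::data.table(
      transcript_id = as.character(GenomicRanges::seqnames(gr)),
      start1 = GenomicRanges::start(gr), end1 = GenomicRanges::end(gr))
    dt <- dt[, .(start1 = min(start1), end1 = max(end1)), by = transcript_id]
    if (is.null(lengths)) {
      sl <- GenomeInfoDb::seqlengths(gr)
      lengths <- sl[!is.na(sl)]
      if (!length(lengths)) {
        # fall back to parsing ##sequence-region pragmas directly
        prag <- grep("^##sequence-region", readLines(path), value = TRUE)
        if (length(prag)) {
          parts <- strsplit(trimws(prag), "\\s+")
          lengths <- setNames(vapply(parts, function(p) as.integer(p[4]), 1L),
                              vapply(parts, function(p) p[2], ""))
        }
      }
    }
    miss <- setdiff(dt$transcript_id, names(lengths))
    if (length(miss)) {
      stopf("read_annotations: no length for transcript %s (add ##sequence-region pragmas or pass `lengths`)",
            miss[1])
    }
    ann <- dt[, .(transcript_id,
                  length = as.integer(lengths[transcript_id]),
                  cds_start = as.integer(start1 - 1L),
                  cds_end = as.integer(end1))]
  } else {
    dt <- read_tsv_nocomment(path, "read_annotations")
    assert_cols(dt, c("transcript_id", "length", "cds_start", "cds_end"),
                "read_annotations")
    ann <- dt[, .(transcript_id = as.character(transcript_id),
                  length = as.integer(length),
                  cds_start = as.integer(cds_start) - 1L,
                  cds_end = as.integer(cds_end))]
  }
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  ann <- data.table::as.data.table(ann)
  if (anyDuplicated(ann$transcript_id)) {
    stopf("annotations: duplicate transcript_id %s",
          ann$transcript_id[duplicated(ann$transcript_id)][1])
  }
  bad <- ann[!(cds_start >= 0L & cds_start < cds_end & cds_end <= length)]
  if (nrow(bad)) {
    stopf("annotations: invalid CDS interval for %s (cds [%d,%d) on length %d)",
          bad$transcript_id[1], bad$cds_start[1], bad$cds_end[1], bad$length[1])
  }
  data.table::setkey(ann, transcript_id)
  ann[]
}

#' Write annotations as the TSV dialect (1-based inclusive CDS)
#' @param ann annotation table from [read_annotations()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path) {
  out <- data.table::as.data.table(ann)[
    , .(transcript_id, length, cds_start = cds_start + 1L, cds_end = cds_end)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Assign a transcript region to positions
#' @param position 0-based positions.
#' @param cds_start,cds_end 0-based half-open CDS bounds.
#' @param length transcript lengths.
#' @return Character vector in `{5UTR, CDS, 3UTR}`.
#' @export
assign_region <- function(position, cds_start, cds_end, length) {
  if (any(position < 0L | position >= length)) {
    stopf("assign_region: position outside [0, length)")
  }
  data.table::fifelse(position < cds_start, "5UTR",
                      data.table::fifelse(position < cds_end, "CDS", "3UTR"))
}

#' Read per-read poly(A) length estimates (nanopolish-polya dialect)
#'
#' Requires at least `readname, contig, polya_length, qc_tag`; extra columns
#' are ignored. Unrecognised qc tags are kept verbatim with a warning.
#'
#' @param path TSV file.
#' @param sample_id sample label; required unless the file has a
#'   `sample_id` column.
#' @return `data.table` (`read_id`, `transcript_id`, `polya_length`,
#'   `qc_tag`, `sample_id`).
#' @export
read_polya <- function(path, sample_id = NULL) {
  dt <- read_tsv_nocomment(path, "read_polya")
  assert_cols(dt, c("readname", "contig", "polya_length", "qc_tag"), "read_polya")
  out <- dt[, .(read_id = as.character(readname),
                transcript_id = as.character(contig),
                polya_length = as.numeric(polya_length),
                qc_tag = as.character(qc_tag))]
  if ("sample_id" %in% names(dt)) {
    out[, sample_id := as.character(dt$sample_id)]
  } else if (!is.null(sample_id)) {
    out[, sample_id := sample_id]
  } else {
    stopf("read_polya: supply sample_id or include a sample_id column")
  }
  if (any(out$polya_length < 0)) stopf("read_polya: negative polya_length")
  if (any(!nzchar(out$qc_tag))) stopf("read_polya: empty qc_tag")
  novel <- setdiff(unique(out$qc_tag), NANOPOLISH_QC_TAGS)
  if (length(novel)) {
    warning(sprintf("read_polya: unrecognised qc_tag value(s) kept verbatim: %s",
                    paste(novel, collapse = ", ")), call. = FALSE)
  }
  out[]
}

#' Read an abundance matrix (counts, CPM or protein) from TSV
#'
#' First column is the feature id, remaining columns are samples.
#'
#' @param path TSV file.
#' @param kind one of `"counts"`, `"cpm"`, `"protein"`; recorded as the
#'   matrix's `kind` attribute.
#' @return Numeric matrix with a `kind` attribute.
#' @export
read_matrix <- function(path, kind = c("counts", "cpm", "protein")) {
  kind <- match.arg(kind)
  dt <- read_tsv_nocomment(path, "read_matrix")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  abundance_matrix(m, kind)
}

#' Validate a numeric abundance matrix
#' @param m numeric matrix, rows = features, columns = samples.
#' @param kind matrix flavour flag.
#' @return `m` with a `kind` attribute set.
#' @export
abundance_matrix <- function(m, kind = c("counts", "cpm", "protein")) {
  kind <- match.arg(kind)
  if (anyNA(m) || any(m < 0)) stopf("abundance_matrix: negative or missing cells")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stopf("abundance_matrix: duplicate row or column identifiers")
  }
  attr(m, "kind") <- kind
  m
}

#' Write an abundance matrix as TSV
#' @param m matrix from [abundance_matrix()].
#' @param path output path.
#' @param id_col name for the feature-id column.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  out <- cbind(dt, data.table::as.data.table(unclass(m)))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a transcript-to-protein identifier map
#' @param path TSV with columns `transcript_id`, `protein_id`.
#' @return `data.table` with the two id columns.
#' @export
read_id_map <- function(path) {
  dt <- read_tsv_nocomment(path, "read_id_map")
  assert_cols(dt, c("transcript_id", "protein_id"), "read_id_map")
  dt[, .(transcript_id = as.character(transcript_id),
         protein_id = as.character(protein_id))]
}

#' Read transcript sequences from FASTA as RNA
#'
#' Any T bases are mapped to U (logged once per file).
#'
#' @param path FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(setNames(as.character(ss), names(ss)))
  if (any(grepl("T", seqs, fixed = TRUE))) {
    ed_log("read_fasta: DNA-alphabet input, mapping T -> U")
    seqs <- chartr("T", "U", seqs)
  }
  seqs
}

#' Write RNA sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Per-sample read-run summary statistics with a grand-mean row
#'
#' Either computes mean/median/max read lengths per sample from raw lengths,
#' or accepts pre-computed per-sample summaries (the published-table
#' reproduction path) and only appends the grand-mean row. The grand-mean row
#' is the arithmetic mean of each per-sample column, reported to two decimals
#' with halves rounded away from zero.
#'
#' @param lengths named list of per-sample read-length vectors (bp).
#' @param quality_max named numeric vector of per-sample maximum quality.
#' @param precomputed data.frame with columns `sample`, `mean_length`,
#'   `median_length`, `max_length`, `max_quality`; used instead of `lengths`.
#' @return `data.frame` with one row per sample plus a final `"mean"` row.
#' @export
summarize_read_stats <- function(lengths = NULL, quality_max = NULL,
                                 precomputed = NULL) {
  if (is.null(precomputed)) {
    if (is.null(lengths) || !length(lengths)) {
      stopf("summarize_read_stats: supply lengths or precomputed")
    }
    empty <- names(lengths)[vapply(lengths, length, 1L) == 0L]
    if (length(empty)) stopf("summarize_read_stats: sample %s has no reads", empty[1])
    per <- data.frame(
      sample = names(lengths),
      mean_length = vapply(lengths, mean, 1),
      median_length = vapply(lengths, median, 1),
      max_length = vapply(lengths, max, 1),
      max_quality = if (is.null(quality_max)) NA_real_
        else as.numeric(quality_max[names(lengths)]),
      row.names = NULL)
  } else {
    assert_cols(precomputed, c("sample", "mean_length", "median_length",
                               "max_length", "max_quality"),
                "summarize_read_stats")
    per <- as.data.frame(precomputed)
  }
  if (any(per$max_length < per$mean_length | per$mean_length < 0)) {
    stopf("summarize_read_stats: per-sample invariant max >= mean >= 0 violated")
  }
  grand <- data.frame(
    sample = "mean",
    mean_length = round_away(mean(per$mean_length), 2),
    median_length = round_away(mean(per$median_length), 2),
    max_length = round_away(mean(per$max_length), 2),
    max_quality = round_away(mean(per$max_quality), 2))
  rbind(per, grand)
}
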
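#' Run configuration for the MDS pipeline
#'
#' Bundles the amplicon, read layout, calling mode and thresholds. Every
#' threshold defaults to the study value (minimum family size 3 in
#' carcinogen mode / 2 in spike-in mode, 0.90 per-position agreement,
#' 1.5e5 barcode-family QC floor, detection-limit constant 1/1.5e5) and all
#' effective values are echoed into the run report.
#'
#' @param amplicon a [reference_amplicon()].
#' @param layout a [layout_spec()].
#' @param mode `"carcinogen"` or `"spikein"`.
#' @param spikein a [spikein_design()] (spikein mode only).
#' @param min_size minimum family size; `NULL` picks the mode default.
#' @param agreement per-position supermajority fraction.
#' @param qc_threshold minimum barcode families per sample.
#' @param correction detection-limit constant.
#' @return object of class `run_config`.
#' @export
run_config <- function(amplicon, layout, mode = c("carcinogen", "spikein"),
                       spikein = NULL, min_size = NULL, agreement = 0.90,
                       qc_threshold = 1.5e5, correction = 1 / 1.5e5) {
  mode <- match.arg(mode)
  if (is.null(min_size)) min_size <- if (mode == "carcinogen") 3L else 2L
  structure(list(amplicon = amplicon, layout = layout, mode = mode,
                 spikein = spikein, min_size = as.integer(min_size),
                 agreement = agreement, qc_threshold = qc_threshold,
                 correction = correction), class = "run_config")
}

#' Run the MDS calling pipeline on a batch of reads
#'
#' End-to-end: quality filter, demultiplex/trim, barcode-family grouping,
#' per-sample barcode-recovery QC, consensus calling and (carcinogen mode)
#' per-mutation frequencies. Deterministic given inputs and configuration.
#' Samples failing QC are excluded from calling but reported.
#'
#' @param reads data.frame of reads (`id`, `sequence`, `quality`) or a FASTQ
#'   path; pre-demultiplexed `(sample, barcode, target)` records (e.g.
#'   `simulate_library(emit = "records")$reads`) are also accepted and skip
#'   the read-processing stage (their `pass_qc` column is honoured).
#' @param config a [run_config()].
#' @param out_dir optional output directory: writes per-sample calls TSV,
#'   frequency TSV, and a JSON run report.
#' @return list with `calls` (named list of [call_families()] tables),
#'   `frequencies` (carcinogen mode; named list of [compute_frequencies()]
#'   tables), `excluded` (samples failing QC) and `report`.
#' @export
run_pipeline <- function(reads, config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(reads)) reads <- read_fastq(reads)
  if (nrow(reads) == 0L) stop2("no input reads")

  if (all(c("sample", "barcode", "target") %in% names(reads))) {
    if (!is.null(reads$pass_qc)) {
      n_in <- nrow(reads)
      records <- reads[reads$pass_qc, c("sample", "barcode", "target")]
      report_reads <- c(reads_in = n_in,
                        quality_fail = n_in - nrow(records),
                        unassigned = 0L, length_fail = 0L,
                        passed = nrow(records))
    } else {
      records <- reads[, c("sample", "barcode", "target")]
      report_reads <- c(reads_in = nrow(reads), quality_fail = 0L,
                        unassigned = 0L, length_fail = 0L,
                        passed = nrow(records))
    }
  } else {
    proc <- process_reads(reads, config$layout)
    records <- proc$records
    report_reads <- proc$report
  }

  lib <- if (config$mode == "carcinogen")
    build_variant_library(config$amplicon) else NULL
  samples <- sort(unique(records$sample))
  calls <- list(); freqs <- list(); excluded <- character(0)
  per_sample <- list()
  for (s in samples) {
    rec <- records[records$sample == s, , drop = FALSE]
    n_fam <- length(unique(rec$barcode))
    if (!sample_qc(n_fam, config$qc_threshold)) {
      excluded <- c(excluded, s)
      per_sample[[s]] <- list(n_families = n_fam, included = FALSE)
      next
    }
    cl <- call_families(rec, config$amplicon, mode = config$mode,
                        variant_library = lib, spikein = config$spikein,
                        min_size = config$min_size,
                        agreement = config$agreement)
    calls[[s]] <- cl
    status_counts <- as.list(table(cl$status))
    per_sample[[s]] <- list(n_families = n_fam, included = TRUE,
                            families_min_size = sum(cl$size >= config$min_size),
                            status_counts = status_counts)
    if (config$mode == "carcinogen") {
      freqs[[s]] <- compute_frequencies(cl, lib,
                                        correction = config$correction)
    }
  }
  report <- list(
    parameters = list(mode = config$mode, min_size = config$min_size,
                      agreement = config$agreement,
                      qc_threshold = config$qc_threshold,
                      correction = config$correction,
                      amplicon = config$amplicon$name),
    reads = as.list(report_reads),
    samples = per_sample,
    excluded = excluded)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(calls)) {
      utils::write.table(calls[[s]],
                         file.path(out_dir, paste0("calls_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(freqs[[s]]))
        write_frequency_table(freqs[[s]],
                              file.path(out_dir, paste0("freq_", s, ".tsv")),
                              sample = s)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(calls = calls, frequencies = freqs, excluded = excluded,
       report = report)
}

#' Spike-in dilution-series benchmark
#'
#' For each spike-in frequency: simulates a library carrying the engineered
#' co-occurring mutations at that frequency, applies the quality filter, and
#' compares the frequency of mutants *present* (families containing the
#' co-occurring mutations, any size) against the frequency *detected* by the
#' spike-in caller (families with >= `min_size` reads and >= `agreement`
#' agreement at the engineered positions), both divided by the total family
#' count. Dilutions whose expected mutant template count falls below one are
#' flagged `sub_poisson` but still run.
#'
#' @param present_frequencies numeric vector of spike-in frequencies.
#' @param n_templates templates per dilution.
#' @param amplicon a [reference_amplicon()].
#' @param mutations data.frame (`cdna_pos`, `alt`) of 2-3 engineered
#'   co-occurring mutations.
#' @param seed integer seed (incremented per dilution).
#' @param min_size,agreement spike-in caller thresholds (defaults 2, 0.90).
#' @param ... further arguments to [simulation_config()] (error rates etc.).
#' @return data.frame with one row per dilution: `present_freq`,
#'   `n_templates`, `total_families`, `present_families`,
#'   `detected_families`, `present_mf`, `detected_mf`, `ratio`
#'   (detected/present), `sub_poisson`.
#' @export
run_benchmark <- function(present_frequencies, n_templates, amplicon,
                          mutations, seed = 1L, min_size = 2L,
                          agreement = 0.90, ...) {
  stopifnot(length(present_frequencies) >= 1L)
  rows <- lapply(seq_along(present_frequencies), function(i) {
    f <- present_frequencies[i]
    spk <- spikein_design(mutations, f)
    cfg <- simulation_config(amplicon, n_templates, spikeins = list(spk),
                             seed = seed + i - 1L, ...)
    sub_poisson <- f * n_templates < 1
    sim <- withCallingHandlers(
      simulate_library(cfg, emit = "records"),
      warning = function(w) {
        if (grepl("below one", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    rec <- sim$reads[sim$reads$pass_qc, ]
    total <- length(unique(rec$barcode))
    det <- call_families(rec, amplicon, mode = "spikein", spikein = spk,
                         min_size = min_size, agreement = agreement)
    pres <- call_families(rec, amplicon, mode = "spikein", spikein = spk,
                          min_size = 1L, agreement = agreement)
    n_det <- sum(det$status == "DETECTED")
    n_pres <- sum(pres$status == "DETECTED")
    data.frame(present_freq = f, n_templates = n_templates,
               total_families = total, present_families = n_pres,
               detected_families = n_det, present_mf = n_pres / total,
               detected_mf = n_det / total,
               ratio = if (n_pres > 0) n_det / n_pres else NA_real_,
               sub_poisson = sub_poisson)
  })
  do.call(rbind, rows)
}
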
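#' Read layout specification
#'
#' Describes the `[index][barcode][primer][target]` layout of an MDS read.
#' Demultiplexing anchors on the known gene-specific primer at offset
#' `nchar(index) + barcode_len`, trying longer indexes first; a zero-length
#' index acts as a fallback only.
#'
#' @param index_assignments named character vector sample -> index (0-7 nt).
#' @param barcode_len barcode length (default 14).
#' @param primer gene-specific primer sequence following the barcode.
#' @param target_len exact required target length; reads whose trimmed target
#'   differs in length (e.g. indels) are rejected.
#' @param primer_max_mismatch maximum mismatches tolerated when anchoring the
#'   primer.
#' @return object of class `layout_spec`.
#' @export
layout_spec <- function(index_assignments, barcode_len = 14L, primer,
                        target_len, primer_max_mismatch = 2L) {
  if (is.null(names(index_assignments)))
    stop2("index_assignments must be named (sample -> index)")
  if (any(nchar(index_assignments) > 7L)) stop2("indexes are 0-7 nt")
  if (anyDuplicated(index_assignments)) stop2("indexes must be distinct")
  if (barcode_len < 1L) stop2("barcode_len must be >= 1")
  assert_dna(primer, "primer")
  structure(list(index_assignments = index_assignments,
                 barcode_len = as.integer(barcode_len), primer = primer,
                 target_len = as.integer(target_len),
                 primer_max_mismatch = as.integer(primer_max_mismatch)),
            class = "layout_spec")
}

#' Single sequencing read with per-base qualities
#' @param id read identifier.
#' @param sequence DNA string.
#' @param qualities integer vector of Phred scores, one per base.
#' @return object of class `read_record`.
#' @export
read_record <- function(id, sequence, qualities) {
  if (nchar(sequence) != length(qualities))
    stop2("sequence and qualities differ in length")
  if (any(qualities < 0)) stop2("Phred values must be >= 0")
  structure(list(id = id, sequence = sequence,
                 qualities = as.integer(qualities)), class = "read_record")
}

#' Merge a read pair by best overlap
#'
#' Reverse-complements read 2 and searches for the best overlap of length at
#' least `min_overlap` whose mismatch fraction is at most
#' `max_mismatch_frac`; among admissible overlaps the one with the lowest
#' mismatch fraction wins (ties broken towards the longer overlap).
#' Disagreeing overlap bases are resolved to the higher-quality base; on a
#' quality tie the read-1 base is kept. The emitted quality of a disagreeing
#' base is the lower of the two.
#'
#' @param r1,r2 [read_record()] objects (r2 in sequencing orientation).
#' @param min_overlap minimum overlap length.
#' @param max_mismatch_frac maximum tolerated mismatch fraction in the
#'   overlap.
#' @return merged [read_record()], or a rejection (see [is_rejection()])
#'   with reason `"no_overlap"` when no admissible overlap exists.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.1) {
  stopifnot(inherits(r1, "read_record"), inherits(r2, "read_record"))
  s1 <- strsplit(r1$sequence, "", fixed = TRUE)[[1]]
  s2 <- rev(chartr("ACGT", "TGCA", strsplit(r2$sequence, "",
                                            fixed = TRUE)[[1]]))
  q1 <- r1$qualities
  q2 <- rev(r2$qualities)
  n1 <- length(s1); n2 <- length(s2)
  best <- NULL
  ovs <- if (min(n1, n2) >= min_overlap)
    seq.int(min(n1, n2), min_overlap) else integer(0)
  for (ov in ovs) {
    a <- s1[(n1 - ov + 1L):n1]
    b <- s2[seq_len(ov)]
    mm <- sum(a != b)
    frac <- mm / ov
    if (frac <= max_mismatch_frac &&
        (is.null(best) || frac < best$frac)) {
      best <- list(ov = ov, frac = frac)
    }
  }
  if (is.null(best)) return(rejection("no_overlap"))
  ov <- best$ov
  i1 <- (n1 - ov + 1L):n1
  i2 <- seq_len(ov)
  oseq <- s1[i1]
  oq <- pmin(q1[i1], q2[i2])
  agree <- s1[i1] == s2[i2]
  oq[agree] <- pmax(q1[i1], q2[i2])[agree]
  from2 <- !agree & q2[i2] > q1[i1]
  oseq[from2] <- s2[i2][from2]
  read_record(
    id = r1$id,
    sequence = paste(c(s1[seq_len(n1 - ov)], oseq, s2[-i2]), collapse = ""),
    qualities = c(q1[seq_len(n1 - ov)], oq, q2[-i2]))
}

#' Base-quality filter
#'
#' A read passes when at least `min_frac` of its bases have Phred quality
#' `>= min_q`; the boundary is inclusive (exactly 90% qualifying bases
#' passes).
#'
#' @param read a [read_record()].
#' @param min_frac minimum fraction of qualifying bases (default 0.90).
#' @param min_q Phred threshold (default 20).
#' @return `TRUE`/`FALSE`; an empty read fails with attribute
#'   `reason = "empty"`.
#' @export
quality_filter <- function(read, min_frac = 0.90, min_q = 20L) {
  q <- read$qualities
  if (length(q) == 0L) {
    out <- FALSE
    attr(out, "reason") <- "empty"
    return(out)
  }
  mean(q >= min_q) >= min_frac
}

# vectorised 90%/Q20 filter on Phred+33 quality strings
quality_pass_chr <- function(quality, min_frac = 0.90, min_q = 20L) {
  ql <- methods::as(Biostrings::PhredQuality(quality), "IntegerList")
  n <- S4Vectors::elementNROWS(ql)
  hi <- sum(ql >= as.integer(min_q))
  hi / pmax(n, 1L) >= min_frac & n > 0L
}

# mismatches between substrings of x at [offset+1, offset+nchar(pattern)]
# and pattern, vectorised over x
pattern_mismatches <- function(x, pattern, offset) {
  mm <- integer(length(x))
  for (j in seq_len(nchar(pattern))) {
    mm <- mm + (substr(x, offset + j, offset + j) != substr(pattern, j, j))
  }
  mm
}

#' Demultiplex and trim one read
#'
#' Identifies the sample index by anchoring the gene-specific primer (at most
#' `primer_max_mismatch` mismatches) at offset `nchar(index) + barcode_len`,
#' trying the longest indexes first, then excises barcode and target.
#'
#' @param read a [read_record()] (or any list with a `sequence` element).
#' @param layout a [layout_spec()].
#' @return list `(sample, barcode, target)`, or a rejection (see
#'   [is_rejection()]) with reason `"unassigned"` (no index/primer anchor)
#'   or `"length_fail"` (target length differs from `target_len`).
#' @export
demultiplex_and_trim <- function(read, layout) {
  seq <- read$sequence
  idx <- layout$index_assignments[order(-nchar(layout$index_assignments))]
  for (s in names(idx)) {
    il <- nchar(idx[[s]])
    if (il > 0L && substr(seq, 1L, il) != idx[[s]]) next
    off <- il + layout$barcode_len
    if (pattern_mismatches(seq, layout$primer, off) >
        layout$primer_max_mismatch) next
    barcode <- substr(seq, il + 1L, off)
    target <- substr(seq, off + nchar(layout$primer) + 1L, nchar(seq))
    if (nchar(target) != layout$target_len) return(rejection("length_fail"))
    return(list(sample = s, barcode = barcode, target = target))
  }
  rejection("unassigned")
}

#' Read a Phred+33 FASTQ file
#' @param path FASTQ path (`.gz` accepted).
#' @return data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  ## the reader warns that FASTQ per-record metadata columns are dropped;
  ## ids and qualities are retained, so that warning is noise here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  S4Vectors::mcols(x) <- NULL
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quality-filter, demultiplex and trim a batch of reads
#'
#' Vectorised pipeline front-end: applies the 90%/Q20 quality filter, then
#' index/primer demultiplexing and layout trimming with an exact target
#' length requirement. Deterministic and order-independent: permuting the
#' input permutes the outputs identically.
#'
#' @param reads data.frame with `id`, `sequence` and optionally `quality`
#'   (from [read_fastq()] or [simulate_library()]).
#' @param layout a [layout_spec()].
#' @param min_frac,min_q quality-filter parameters (see [quality_filter()]).
#' @return list with `records` (data.frame `id`, `sample`, `barcode`,
#'   `target`), `rejects` (data.frame `id`, `reason`) and `report` (named
#'   counts: `reads_in`, `quality_fail`, `unassigned`, `length_fail`,
#'   `passed`).
#' @export
process_reads <- function(reads, layout, min_frac = 0.90, min_q = 20L) {
  stopifnot(inherits(layout, "layout_spec"))
  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  ok <- rep(TRUE, n)
  if (!is.null(reads$quality)) {
    qpass <- quality_pass_chr(reads$quality, min_frac, min_q)
    reason[!qpass] <- "quality_fail"
    ok <- qpass
  }
  sample <- rep(NA_character_, n)
  barcode <- rep(NA_character_, n)
  target <- rep(NA_character_, n)
  idx <- layout$index_assignments[order(-nchar(layout$index_assignments))]
  unassigned <- ok
  for (s in names(idx)) {
    if (!any(unassigned)) break
    il <- nchar(idx[[s]])
    cand <- which(unassigned)
    if (il > 0L)
      cand <- cand[substr(reads$sequence[cand], 1L, il) == idx[[s]]]
    if (!length(cand)) next
    off <- il + layout$barcode_len
    mm <- pattern_mismatches(reads$sequence[cand], layout$primer, off)
    cand <- cand[mm <= layout$primer_max_mismatch]
    if (!length(cand)) next
    sample[cand] <- s
    barcode[cand] <- substr(reads$sequence[cand], il + 1L, off)
    target[cand] <- substr(reads$sequence[cand],
                           off + nchar(layout$primer) + 1L,
                           nchar(reads$sequence[cand]))
    unassigned[cand] <- FALSE
  }
  reason[ok & unassigned] <- "unassigned"
  ok <- ok & !unassigned
  badlen <- ok & nchar(target) != layout$target_len
  reason[badlen] <- "length_fail"
  ok <- ok & !badlen
  ids <- if (!is.null(reads$id)) reads$id else as.character(seq_len(n))
  report <- c(reads_in = n,
              quality_fail = sum(reason == "quality_fail", na.rm = TRUE),
              unassigned = sum(reason == "unassigned", na.rm = TRUE),
              length_fail = sum(reason == "length_fail", na.rm = TRUE),
              passed = sum(ok))
  list(records = data.frame(id = ids[ok], sample = sample[ok],
                            barcode = barcode[ok], target = target[ok],
                            stringsAsFactors = FALSE),
       rejects = data.frame(id = ids[!ok], reason = reason[!ok],
                            stringsAsFactors = FALSE),
       report = report)
}
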
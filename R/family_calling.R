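#' Group records into barcode families
#'
#' Exact-match grouping: every record belongs to exactly one family and the
#' family count equals the number of distinct barcodes. No edit-distance
#' clustering is attempted; barcode sequencing errors create spurious
#' families which predominantly fail the minimum-size filter downstream.
#'
#' @param records data.frame with columns `barcode` and `target` (one sample,
#'   one amplicon).
#' @return data.table keyed by barcode with columns `barcode`, `size`,
#'   `members` (list column of target sequences).
#' @export
group_by_barcode <- function(records) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L)
    return(data.table::data.table(barcode = character(0), size = integer(0),
                                  members = list()))
  fam <- dt[, list(size = .N, members = list(target)), by = "barcode"]
  data.table::setkeyv(fam, "barcode")
  fam[]
}

#' Consensus-call a single barcode family
#'
#' Reference implementation operating on one family; [call_families()] is the
#' vectorised equivalent used by the pipeline (the two agree exactly).
#'
#' In `carcinogen` mode a family is callable when it has at least
#' `min_size_carcinogen` members and a unique consensus: at every position
#' one base carried by at least `agreement` of the members (for families of
#' up to 9 members the 0.90 default equals unanimity). The consensus is then
#' exact-matched against the reference and the single-substitution variant
#' library, giving `WT`, `SINGLE` (with its mutation key) or `OTHER`
#' (multi-substitution consensus, retained in frequency denominators).
#'
#' In `spikein` mode a family counts as a detected spike-in when it has at
#' least `min_size_spikein` members and at each engineered position at least
#' `agreement` of the members carry the engineered alternate base
#' (`match = "all"`), or at one specified engineered position
#' (`match = "single"`).
#'
#' @param family one row of [group_by_barcode()] output (or a list with
#'   `barcode`, `size`, `members`).
#' @param mode `"carcinogen"` or `"spikein"`.
#' @param amplicon the [reference_amplicon()] the records belong to.
#' @param variant_library [build_variant_library()] output for `amplicon`
#'   (built on the fly when omitted).
#' @param spikein a [spikein_design()] (required in spikein mode).
#' @param min_size_carcinogen,min_size_spikein minimum family sizes (defaults
#'   3 and 2).
#' @param agreement per-position supermajority fraction (default 0.90).
#' @param match spikein mode: require the engineered base at `"all"`
#'   engineered positions or at a `"single"` specified one.
#' @param spikein_position cdna position used when `match = "single"`
#'   (defaults to the design's first).
#' @return list with `barcode`, `size`, `status` (one of `WT`, `SINGLE`,
#'   `OTHER`, `NO_CONSENSUS`, `TOO_SMALL`, `DETECTED`, `NOT_DETECTED`),
#'   `consensus_seq`, and for `SINGLE` the mutation key fields (`cdna_pos`,
#'   `ref`, `alt`, `aa_change`, classes).
#' @export
call_family <- function(family, mode = c("carcinogen", "spikein"), amplicon,
                        variant_library = NULL, spikein = NULL,
                        min_size_carcinogen = 3L, min_size_spikein = 2L,
                        agreement = 0.90, match = c("all", "single"),
                        spikein_position = NULL) {
  mode <- match.arg(mode)
  match <- match.arg(match)
  members <- as.character(unlist(family$members))
  size <- length(members)
  out <- list(barcode = family$barcode, size = size,
              consensus_seq = NA_character_)
  if (length(unique(nchar(members))) > 1L) {
    out$status <- "NO_CONSENSUS"; out$reason <- "mixed_lengths"
    return(out)
  }
  if (mode == "carcinogen") {
    if (size < min_size_carcinogen) { out$status <- "TOO_SMALL"; return(out) }
    L <- nchar(members[1])
    mat <- matrix(unlist(strsplit(members, "", fixed = TRUE)),
                  nrow = size, byrow = TRUE)
    cons <- character(L)
    for (j in seq_len(L)) {
      tab <- tabulate(match(mat[, j], DNA_BASES), nbins = 4L)
      if (max(tab) / size < agreement) {
        out$status <- "NO_CONSENSUS"; out$reason <- "no_supermajority"
        return(out)
      }
      cons[j] <- DNA_BASES[which.max(tab)]
    }
    consensus <- paste(cons, collapse = "")
    out$consensus_seq <- consensus
    if (is.null(variant_library))
      variant_library <- build_variant_library(amplicon)
    if (consensus == amplicon$sequence) {
      out$status <- "WT"
    } else {
      hit <- which(variant_library$variant_seq == consensus)
      if (length(hit) == 1L) {
        out$status <- "SINGLE"
        out <- c(out, variant_library[hit, c("cdna_pos", "ref", "alt",
                                             "context5", "context3",
                                             "aa_change", "sub_class",
                                             "tri_class", "comp_class")])
      } else {
        out$status <- "OTHER"
      }
    }
    return(out)
  }
  ## spikein mode
  if (is.null(spikein)) stop2("spikein mode requires a spikein design")
  if (size < min_size_spikein) { out$status <- "TOO_SMALL"; return(out) }
  muts <- spikein$mutations
  if (match == "single") {
    pos0 <- if (is.null(spikein_position)) muts$cdna_pos[1] else
      spikein_position
    muts <- muts[muts$cdna_pos == pos0, , drop = FALSE]
    if (nrow(muts) == 0L) stop2("spikein_position not in the design")
  }
  detected <- TRUE
  for (j in seq_len(nrow(muts))) {
    rp <- cdna_to_read(amplicon, muts$cdna_pos[j])
    alt_read <- if (amplicon$read_strand == "non_transcribed") muts$alt[j]
                else comp_base(muts$alt[j])
    frac <- mean(substr(members, rp, rp) == alt_read)
    if (frac < agreement) { detected <- FALSE; break }
  }
  out$status <- if (detected) "DETECTED" else "NOT_DETECTED"
  out
}

#' Vectorised barcode-family consensus calling
#'
#' Carcinogen mode: groups records by barcode, drops families below
#' `min_size` as `TOO_SMALL`, requires a per-position supermajority
#' (`agreement`) consensus, and matches consensus sequences against the
#' reference and the exhaustive single-substitution library. Families whose
#' members are all identical take the fast path; mixed families are resolved
#' by per-position base tallies.
#'
#' Spikein mode: a family of at least `min_size` members is `DETECTED` when
#' at least `agreement` of its members carry the engineered alternate base
#' at every engineered position (`match = "all"`) or at one specified
#' position (`match = "single"`).
#'
#' @param records data.frame with `barcode`, `target` (one sample).
#' @param amplicon the [reference_amplicon()].
#' @param mode `"carcinogen"` or `"spikein"`.
#' @param variant_library optional precomputed [build_variant_library()].
#' @param spikein a [spikein_design()] (spikein mode).
#' @param min_size minimum family size (defaults: 3 carcinogen, 2 spikein).
#' @param agreement per-position supermajority fraction (default 0.90).
#' @inheritParams call_family
#' @return data.table with one row per family: `barcode`, `size`, `status`,
#'   and mutation key columns (`cdna_pos`, `ref`, `alt`, `aa_change`,
#'   `sub_class`, `tri_class`, `comp_class`) filled for `SINGLE` calls.
#' @export
call_families <- function(records, amplicon,
                          mode = c("carcinogen", "spikein"),
                          variant_library = NULL, spikein = NULL,
                          min_size = NULL, agreement = 0.90,
                          match = c("all", "single"),
                          spikein_position = NULL) {
  mode <- match.arg(mode)
  match <- match.arg(match)
  if (is.null(min_size)) min_size <- if (mode == "carcinogen") 3L else 2L
  dt <- data.table::as.data.table(records)[, c("barcode", "target")]
  if (mode == "spikein") {
    if (is.null(spikein)) stop2("spikein mode requires a spikein design")
    muts <- spikein$mutations
    if (match == "single") {
      pos0 <- if (is.null(spikein_position)) muts$cdna_pos[1] else
        spikein_position
      muts <- muts[muts$cdna_pos == pos0, , drop = FALSE]
      if (nrow(muts) == 0L) stop2("spikein_position not in the design")
    }
    hit <- rep(TRUE, nrow(dt))
    for (j in seq_len(nrow(muts))) {
      rp <- cdna_to_read(amplicon, muts$cdna_pos[j])
      alt_read <- if (amplicon$read_strand == "non_transcribed") muts$alt[j]
                  else comp_base(muts$alt[j])
      hit <- hit & substr(dt$target, rp, rp) == alt_read
    }
    dt[, "hit" := hit]
    fam <- dt[, list(size = .N, frac = mean(hit)), by = "barcode"]
    fam[, "status" := data.table::fifelse(
      fam$size < min_size, "TOO_SMALL",
      data.table::fifelse(fam$frac >= agreement, "DETECTED",
                          "NOT_DETECTED"))]
    return(fam[, c("barcode", "size", "status", "frac")])
  }

  ## carcinogen mode
  if (is.null(variant_library)) variant_library <- build_variant_library(amplicon)
  L <- amplicon$length
  fam <- dt[, list(size = .N, n_seq = data.table::uniqueN(target),
                   first = target[1L]), by = "barcode"]
  fam[, "status" := NA_character_]
  fam[, "consensus" := NA_character_]
  fam[fam$size < min_size, "status" := "TOO_SMALL"]
  ## uniform families: consensus is the shared sequence
  uni <- is.na(fam$status) & fam$n_seq == 1L
  fam[uni, "consensus" := fam$first[uni]]
  ## mixed families: per-position tallies in long form
  mixed_bc <- fam$barcode[is.na(fam$status) & fam$n_seq > 1L]
  if (length(mixed_bc)) {
    sub <- dt[dt$barcode %in% mixed_bc]
    if (any(nchar(sub$target) != L)) {
      badlen <- unique(sub$barcode[nchar(sub$target) != L])
      fam[fam$barcode %in% badlen, "status" := "NO_CONSENSUS"]
      sub <- sub[!sub$barcode %in% badlen]
      mixed_bc <- setdiff(mixed_bc, badlen)
    }
    if (nrow(sub)) {
      chars <- strsplit(sub$target, "", fixed = TRUE)
      long <- data.table::data.table(
        barcode = rep(sub$barcode, each = L),
        pos = rep.int(seq_len(L), nrow(sub)),
        base = unlist(chars))
      tal <- long[, list(n = .N), by = c("barcode", "pos", "base")]
      data.table::setorderv(tal, c("barcode", "pos", "n"),
                            order = c(1L, 1L, -1L))
      top <- unique(tal, by = c("barcode", "pos"))  # sorted: keeps max n
      top <- merge(top, fam[, c("barcode", "size")], by = "barcode")
      agree_ok <- top[, list(ok = all(n / size >= agreement)),
                      by = "barcode"]
      bad <- agree_ok$barcode[!agree_ok$ok]
      fam[fam$barcode %in% bad, "status" := "NO_CONSENSUS"]
      good <- top[!top$barcode %in% bad]
      if (nrow(good)) {
        data.table::setorderv(good, c("barcode", "pos"))
        cons <- good[, list(consensus2 = paste(base, collapse = "")),
                     by = "barcode"]
        fam[cons, "consensus" := i.consensus2, on = "barcode"]
      }
    }
  }
  ## match consensi against reference + library
  lib_idx <- match(fam$consensus, variant_library$variant_seq)
  is_wt <- !is.na(fam$consensus) & fam$consensus == amplicon$sequence
  fam[is.na(fam$status) & is_wt, "status" := "WT"]
  fam[is.na(fam$status) & !is.na(lib_idx), "status" := "SINGLE"]
  fam[is.na(fam$status) & !is.na(fam$consensus), "status" := "OTHER"]
  keycols <- c("cdna_pos", "ref", "alt", "context5", "context3", "aa_change",
               "sub_class", "tri_class", "comp_class")
  for (cn in keycols) {
    v <- variant_library[[cn]][lib_idx]
    v[fam$status != "SINGLE"] <- NA
    fam[, (cn) := v]
  }
  data.table::setnames(fam, "consensus", "consensus_seq")
  fam[, c("n_seq", "first") := NULL]
  fam[]
}

#' Sample-level barcode-recovery QC
#'
#' A sample is excluded when it recovered fewer than `threshold` barcode
#' families (strictly fewer: exactly the threshold is included).
#'
#' @param n_families number of barcode families recovered.
#' @param threshold minimum family count (default 1.5e5).
#' @return `TRUE` to include the sample, `FALSE` to exclude it.
#' @export
sample_qc <- function(n_families, threshold = 1.5e5) {
  if (n_families < 0) stop2("n_families must be >= 0")
  n_families >= threshold
}

#' Family-size histogram
#' @param families output of [group_by_barcode()] or [call_families()].
#' @return data.frame with `size` and `n_families`.
#' @export
family_size_histogram <- function(families) {
  tab <- table(families$size)
  data.frame(size = as.integer(names(tab)), n_families = as.integer(tab))
}
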
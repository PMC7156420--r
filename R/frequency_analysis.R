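#' Per-mutation family frequencies for one sample
#'
#' The frequency of a mutation is the number of families whose consensus
#' carries it divided by the total number of selected families. Every key of
#' the exhaustive single-substitution library gets a row (explicit zeros),
#' and the detection-limit pseudo-count is recorded alongside the raw
#' frequency.
#'
#' @param calls [call_families()] output in carcinogen mode.
#' @param variant_library [build_variant_library()] output for the amplicon.
#' @param total_families frequency denominator; defaults to the number of
#'   families passing size and unique-consensus selection
#'   (`WT` + `SINGLE` + `OTHER`).
#' @param correction detection-limit constant added to `mf` to give
#'   `mf_corrected` (default `1 / 1.5e5`, the reciprocal of the minimum
#'   accepted barcode-family count).
#' @return data.frame with the library key columns plus `n_families`,
#'   `total_families`, `mf`, `mf_corrected`.
#' @export
compute_frequencies <- function(calls, variant_library,
                                total_families = NULL,
                                correction = 1 / 1.5e5) {
  if (is.null(total_families))
    total_families <- sum(calls$status %in% c("WT", "SINGLE", "OTHER"))
  if (total_families == 0L) stop2("no selected families: cannot compute frequencies")
  singles <- calls[calls$status == "SINGLE", ]
  key <- paste(variant_library$cdna_pos, variant_library$ref,
               variant_library$alt)
  n_fam <- integer(nrow(variant_library))
  if (nrow(singles)) {
    cnt <- table(paste(singles$cdna_pos, singles$ref, singles$alt))
    hit <- match(names(cnt), key)
    n_fam[hit] <- as.integer(cnt)
  }
  out <- variant_library[, c("cdna_pos", "ref", "alt", "context5",
                             "context3", "aa_change", "sub_class",
                             "tri_class", "comp_class")]
  out$n_families <- n_fam
  out$total_families <- total_families
  out$mf <- n_fam / total_families
  out$mf_corrected <- out$mf + correction
  rownames(out) <- NULL
  out
}

freq_group_key <- function(tab, group_by) {
  switch(group_by,
         position = as.character(tab$cdna_pos),
         substitution = tab$sub_class,
         a2t = ifelse(tab$sub_class == "A>T",
                      sprintf("%d:%s_%s", tab$cdna_pos,
                              ifelse(is.na(tab$context5), "-", tab$context5),
                              ifelse(is.na(tab$context3), "-", tab$context3)),
                      NA_character_),
         stop2(sprintf("unknown group_by '%s'", group_by)))
}

#' Detection-limit correction and fold-change heatmap matrix
#'
#' Applies the fixed transform order: add the detection-limit constant to
#' every key's frequency, sum corrected frequencies within each group key
#' per sample, then (in `"pbs"` mode) divide each sample's sums by the mean
#' of the PBS samples' sums and log10-transform. `"none"` mode emits the
#' log10 corrected sums without normalisation (per-A>T-transversion style).
#' The constant guarantees finite entries (no log of zero).
#'
#' @param tables named list of [compute_frequencies()] tables, one per
#'   sample.
#' @param meta data.frame with columns `sample` and `treatment` (values
#'   `"UR"`/`"PBS"`); further columns (tissue, week) are carried through.
#' @param constant detection-limit constant (default `1 / 1.5e5`); applied
#'   to `mf`, replacing any correction already present in the tables.
#' @param group_by `"position"` (sum all substitutions at a nucleotide),
#'   `"substitution"` (sum per substitution type) or `"a2t"` (each A>T
#'   transversion separately, labelled `cdna:5'flank_3'flank`).
#' @param normalize `"pbs"` (fold change over the PBS mean, log10) or
#'   `"none"` (log10 corrected sums).
#' @return object of class `heatmap_matrix`: list with `values` (samples x
#'   group keys matrix of log10 entries), `meta`, `group_by`, `normalize`.
#' @export
correct_and_fold_change <- function(tables, meta, constant = 1 / 1.5e5,
                                    group_by = c("position", "substitution",
                                                 "a2t"),
                                    normalize = c("pbs", "none")) {
  group_by <- match.arg(group_by)
  normalize <- match.arg(normalize)
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(meta$sample %in% names(tables)))
  if (normalize == "pbs" && !any(meta$treatment == "PBS"))
    stop2("fold-change normalisation requires at least one PBS sample")
  sums <- lapply(meta$sample, function(s) {
    tab <- tables[[s]]
    keyv <- freq_group_key(tab, group_by)
    keep <- !is.na(keyv)
    tapply((tab$mf + constant)[keep], keyv[keep], sum)
  })
  keys <- sort(unique(unlist(lapply(sums, names))))
  m <- do.call(rbind, lapply(sums, function(x) {
    v <- x[keys]; names(v) <- keys
    v[is.na(v)] <- NA
    v
  }))
  rownames(m) <- meta$sample
  if (group_by == "position")
    m <- m[, order(as.numeric(keys)), drop = FALSE]
  if (normalize == "pbs") {
    pbs_mean <- colMeans(m[meta$treatment == "PBS", , drop = FALSE])
    m <- sweep(m, 2L, pbs_mean, "/")
  }
  structure(list(values = log10(m), meta = meta, group_by = group_by,
                 normalize = normalize, constant = constant),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("<heatmap_matrix> %d samples x %d keys (group_by=%s, %s)\n",
              nrow(x$values), ncol(x$values), x$group_by,
              if (x$normalize == "pbs") "log10 FC over PBS"
              else "log10 corrected MF"))
  invisible(x)
}

#' Write a heatmap matrix as TSV (samples as rows with their metadata)
#' @param x a `heatmap_matrix`.
#' @param path output path.
#' @export
write_heatmap_matrix <- function(x, path) {
  df <- cbind(x$meta, as.data.frame(x$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# substitution class as read on a given assay strand, for coding-strand keys
as_read_class <- function(ref, alt, read_strand) {
  if (read_strand == "non_transcribed") paste0(ref, ">", alt)
  else paste0(comp_base(ref), ">", comp_base(alt))
}

#' Merge opposite-strand assays, masking deamination/oxidation artifacts
#'
#' C>T and G>T substitutions, as read on the strand processed by MDS, carry
#' a high artifactual background (cytosine deamination, guanine oxidation
#' during library preparation). For those classes the reported coding-strand
#' frequency is taken from the assay where the same genomic change reads as
#' the complementary G>A or C>A; every other class passes through from its
#' native (default: non-transcribed) assay. With only one table supplied,
#' artifact-prone keys that have no alternative source are flagged `masked`
#' (frequencies set to `NA`, excluded from sums).
#'
#' @param table_nt [compute_frequencies()] table from the non-transcribed
#'   strand assay (or `NULL`).
#' @param table_t matching table from the transcribed-strand assay (or
#'   `NULL`).
#' @return merged coding-strand frequency table with additional columns
#'   `source_strand` and `masked`.
#' @export
mask_strand_artifacts <- function(table_nt, table_t = NULL) {
  if (is.null(table_nt) && is.null(table_t))
    stop2("at least one strand table is required")
  base <- if (!is.null(table_nt)) table_nt else table_t
  out <- base
  artifact <- c("C>T", "G>T")
  native <- if (!is.null(table_nt)) "non_transcribed" else "transcribed"
  out$source_strand <- native
  out$masked <- FALSE
  keyv <- function(tab) paste(tab$cdna_pos, tab$ref, tab$alt)
  for (i in seq_len(nrow(out))) {
    prone_here <- as_read_class(out$ref[i], out$alt[i], native) %in% artifact
    if (!prone_here) next
    alt_strand <- setdiff(c("non_transcribed", "transcribed"), native)
    alt_tab <- if (alt_strand == "transcribed") table_t else table_nt
    if (is.null(alt_tab)) {
      out$masked[i] <- TRUE
      out$n_families[i] <- NA_integer_
      out$mf[i] <- NA_real_
      out$mf_corrected[i] <- NA_real_
      next
    }
    j <- match(keyv(out)[i], keyv(alt_tab))
    if (is.na(j)) { out$masked[i] <- TRUE; next }
    out$n_families[i] <- alt_tab$n_families[j]
    out$total_families[i] <- alt_tab$total_families[j]
    out$mf[i] <- alt_tab$mf[j]
    out$mf_corrected[i] <- alt_tab$mf_corrected[j]
    out$source_strand[i] <- alt_strand
  }
  out
}

#' Write a tidy frequency table as TSV
#' @param table [compute_frequencies()] output.
#' @param path output path.
#' @param sample optional sample id column to prepend.
#' @export
write_frequency_table <- function(table, path, sample = NULL) {
  if (!is.null(sample)) table <- cbind(sample = sample, table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
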
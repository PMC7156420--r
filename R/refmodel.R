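#' Reference amplicon
#'
#' A sequenced target region of a gene, stored in read orientation together
#' with the mapping onto coding-strand cDNA coordinates.
#'
#' `cdna_start` is the 1-based cDNA coordinate (coding strand) of the read's
#' first target base. For a `non_transcribed` assay the read walks the cDNA
#' forwards and the read base equals the coding base; for a `transcribed`
#' assay the read walks the cDNA backwards and the coding base is the
#' complement of the read base.
#'
#' @param name amplicon identifier.
#' @param gene gene identifier.
#' @param exon exon number.
#' @param read_strand `"non_transcribed"` or `"transcribed"`.
#' @param sequence uppercase DNA string in read orientation (A/C/G/T only).
#' @param cdna_start 1-based cDNA coordinate of the read's first target base.
#' @return an object of class `reference_amplicon`.
#' @export
reference_amplicon <- function(name, gene, exon, read_strand, sequence,
                               cdna_start) {
  read_strand <- match.arg(read_strand, c("non_transcribed", "transcribed"))
  sequence <- toupper(sequence)
  assert_dna(sequence, sprintf("amplicon '%s'", name))
  len <- nchar(sequence)
  if (len < 1L) stop2("amplicon sequence is empty")
  if (read_strand == "non_transcribed") {
    cdna_lo <- cdna_start
    cdna_hi <- cdna_start + len - 1L
    coding <- sequence
  } else {
    cdna_hi <- cdna_start
    cdna_lo <- cdna_start - len + 1L
    coding <- revcomp_chr(sequence)
  }
  if (cdna_lo < 1L) stop2("amplicon extends below cDNA position 1")
  structure(list(name = name, gene = gene, exon = as.integer(exon),
                 read_strand = read_strand, sequence = sequence,
                 cdna_start = as.integer(cdna_start), length = len,
                 cdna_lo = as.integer(cdna_lo), cdna_hi = as.integer(cdna_hi),
                 coding_sequence = coding),
            class = "reference_amplicon")
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat(sprintf("<reference_amplicon> %s (%s exon %d, %s strand)\n",
              x$name, x$gene, x$exon, x$read_strand))
  cat(sprintf("  %d nt, cDNA %d-%d, read starts at cDNA %d\n",
              x$length, x$cdna_lo, x$cdna_hi, x$cdna_start))
  invisible(x)
}

#' Map read-orientation positions to coding-strand cDNA positions
#'
#' The mapping is a bijection between read positions `1..length` and the
#' amplicon's cDNA span; [cdna_to_read()] is its inverse.
#'
#' @param amplicon a [reference_amplicon()].
#' @param read_pos integer vector of read positions (1-based).
#' @return integer vector of cDNA positions.
#' @export
read_to_cdna <- function(amplicon, read_pos) {
  if (any(read_pos < 1L | read_pos > amplicon$length))
    stop2("read position outside amplicon")
  if (amplicon$read_strand == "non_transcribed")
    amplicon$cdna_start + read_pos - 1L
  else
    amplicon$cdna_start - read_pos + 1L
}

#' @rdname read_to_cdna
#' @param cdna_pos integer vector of cDNA positions.
#' @export
cdna_to_read <- function(amplicon, cdna_pos) {
  if (any(cdna_pos < amplicon$cdna_lo | cdna_pos > amplicon$cdna_hi))
    stop2("cDNA position outside amplicon span")
  if (amplicon$read_strand == "non_transcribed")
    cdna_pos - amplicon$cdna_start + 1L
  else
    amplicon$cdna_start - cdna_pos + 1L
}

#' Coding-strand base at a cDNA position
#' @inheritParams cdna_to_read
#' @export
coding_base <- function(amplicon, cdna_pos) {
  substring(amplicon$coding_sequence,
            cdna_pos - amplicon$cdna_lo + 1L,
            cdna_pos - amplicon$cdna_lo + 1L)
}

#' Codon annotations covered by an amplicon
#'
#' Codon `i` spans coding-strand cDNA positions `3i-2 .. 3i`; only codons
#' fully contained in the amplicon's cDNA span are annotated.
#'
#' @param amplicon a [reference_amplicon()].
#' @return data.frame with columns `codon_index`, `cdna_first`, `ref_codon`,
#'   `ref_aa`.
#' @export
codon_annotations <- function(amplicon) {
  first <- ceiling((amplicon$cdna_lo + 2L) / 3)   # first fully covered codon
  last <- floor(amplicon$cdna_hi / 3)
  if (last < first) {
    return(data.frame(codon_index = integer(0), cdna_first = integer(0),
                      ref_codon = character(0), ref_aa = character(0)))
  }
  idx <- first:last
  starts <- 3L * idx - 2L
  codons <- substring(amplicon$coding_sequence,
                      starts - amplicon$cdna_lo + 1L,
                      starts - amplicon$cdna_lo + 3L)
  data.frame(codon_index = idx, cdna_first = starts, ref_codon = codons,
             ref_aa = translate_codon(codons), stringsAsFactors = FALSE)
}

#' Amino-acid consequence of a coding-strand substitution
#'
#' @param amplicon a [reference_amplicon()].
#' @param cdna_pos coding-strand cDNA position of the substitution.
#' @param alt_base coding-strand alternate base.
#' @return `"Q61L"`-style string for missense changes, `"silent"`,
#'   `"nonsense"`, or `NA` when the position lies in a partially covered codon.
#' @export
annotate_codon_change <- function(amplicon, cdna_pos, alt_base) {
  if (cdna_pos < amplicon$cdna_lo || cdna_pos > amplicon$cdna_hi)
    stop2("cDNA position outside amplicon span")
  codons <- codon_annotations(amplicon)
  idx <- ceiling(cdna_pos / 3)
  row <- codons[codons$codon_index == idx, ]
  if (nrow(row) == 0L) return(NA_character_)
  offset <- cdna_pos - row$cdna_first + 1L
  ref <- substr(row$ref_codon, offset, offset)
  if (alt_base == ref) stop2("alternate base equals the reference base")
  mut_codon <- row$ref_codon
  substr(mut_codon, offset, offset) <- alt_base
  alt_aa <- translate_codon(mut_codon)
  if (alt_aa == row$ref_aa) return("silent")
  if (alt_aa == "*") return("nonsense")
  paste0(row$ref_aa, row$codon_index, alt_aa)
}

#' Classify a single-nucleotide substitution
#'
#' All inputs are coding-strand. `tri_class` anchors the trinucleotide on the
#' 5' flank (e.g. `"CAN>CTN"`), `tri_class_3p` on the 3' flank, and
#' `comp_class` is the label the same genomic event carries when read on the
#' complementary strand (e.g. `"NTG>NAG"` for a `CAN>CTN` key). Missing
#' flanks (amplicon edge) yield `"undefined"` context classes; the
#' substitution class is always returned.
#'
#' @param ref_base,alt_base coding-strand reference and alternate base.
#' @param context5,context3 coding-strand flanking bases (`NA` if unknown).
#' @return list with `sub_class`, `tri_class`, `tri_class_3p`, `comp_class`.
#' @export
classify_substitution <- function(ref_base, alt_base, context5 = NA,
                                  context3 = NA) {
  if (ref_base == alt_base) stop2("ref and alt base are identical")
  sub_class <- paste0(ref_base, ">", alt_base)
  tri <- if (is.na(context5)) "undefined" else
    sprintf("%s%sN>%s%sN", context5, ref_base, context5, alt_base)
  tri3 <- if (is.na(context3)) "undefined" else
    sprintf("N%s%s>N%s%s", ref_base, context3, alt_base, context3)
  comp <- if (is.na(context5)) "undefined" else
    sprintf("N%s%s>N%s%s", comp_base(ref_base), comp_base(context5),
            comp_base(alt_base), comp_base(context5))
  list(sub_class = sub_class, tri_class = tri, tri_class_3p = tri3,
       comp_class = comp)
}

#' Exhaustive single-substitution variant library
#'
#' Enumerates every single-nucleotide substitution of the amplicon (3 per
#' position), annotated in coding-strand cDNA notation: position, ref/alt,
#' flanking context, codon consequence, and substitution/context classes.
#' Family consensus sequences are matched against `variant_seq` (read
#' orientation) to assign mutations.
#'
#' @param amplicon a [reference_amplicon()].
#' @return data.frame with one row per variant (`3 * length` rows): columns
#'   `name`, `read_pos`, `variant_seq`, `cdna_pos`, `ref`, `alt`, `context5`,
#'   `context3`, `codon_index`, `aa_change`, `sub_class`, `tri_class`,
#'   `comp_class`.
#' @export
build_variant_library <- function(amplicon) {
  stopifnot(inherits(amplicon, "reference_amplicon"))
  L <- amplicon$length
  read_chars <- strsplit(amplicon$sequence, "", fixed = TRUE)[[1]]
  rows <- vector("list", 3L * L)
  k <- 0L
  codons <- codon_annotations(amplicon)
  for (i in seq_len(L)) {
    ref_read <- read_chars[i]
    cdna_pos <- read_to_cdna(amplicon, i)
    for (alt_read in setdiff(DNA_BASES, ref_read)) {
      vseq <- amplicon$sequence
      substr(vseq, i, i) <- alt_read
      if (amplicon$read_strand == "non_transcribed") {
        ref <- ref_read; alt <- alt_read
      } else {
        ref <- comp_base(ref_read); alt <- comp_base(alt_read)
      }
      c5 <- if (cdna_pos - 1L >= amplicon$cdna_lo)
        coding_base(amplicon, cdna_pos - 1L) else NA_character_
      c3 <- if (cdna_pos + 1L <= amplicon$cdna_hi)
        coding_base(amplicon, cdna_pos + 1L) else NA_character_
      idx <- ceiling(cdna_pos / 3)
      aa <- if (idx %in% codons$codon_index)
        annotate_codon_change(amplicon, cdna_pos, alt) else NA_character_
      cls <- classify_substitution(ref, alt, c5, c3)
      k <- k + 1L
      rows[[k]] <- data.frame(
        name = amplicon$name, read_pos = i, variant_seq = vseq,
        cdna_pos = cdna_pos, ref = ref, alt = alt,
        context5 = c5, context3 = c3,
        codon_index = if (idx %in% codons$codon_index) idx else NA_integer_,
        aa_change = aa, sub_class = cls$sub_class, tri_class = cls$tri_class,
        comp_class = cls$comp_class, stringsAsFactors = FALSE)
    }
  }
  lib <- do.call(rbind, rows)
  rownames(lib) <- NULL
  lib
}

#' Write a variant library as TSV
#' @param library output of [build_variant_library()].
#' @param path output file path.
#' @export
write_variant_library <- function(library, path) {
  cols <- c("name", "cdna_pos", "ref", "alt", "context5", "context3",
            "aa_change", "sub_class", "tri_class")
  utils::write.table(library[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Enumerate oncogenic hotspot point mutations
#'
#' Exhaustively substitutes each base of each hotspot codon (9 single-
#' nucleotide substitutions per codon), translates the mutant codons, and
#' counts (a) point mutations producing a missense change (synonymous and
#' stop-gain excluded) and (b) distinct (gene, codon, target amino acid)
#' substitutions after collapsing point mutations yielding the same
#' amino-acid change. The default codon set covers the Ras G12/G13/Q61
#' hotspots across the three Ras genes.
#'
#' @param hotspots named character vector of hotspot codons
#'   (name = codon label, value = reference 3-mer).
#' @param genes character vector of gene names carrying each hotspot.
#' @return list with `n_point_mutations`, `n_distinct_substitutions`,
#'   `aa_sets` (per-codon missense amino-acid sets) and `table` (one row per
#'   gene x codon x point mutation).
#' @export
enumerate_hotspot_mutations <- function(hotspots = c(G12 = "GGT", G13 = "GGC",
                                                     Q61 = "CAA"),
                                        genes = c("Hras", "Kras", "Nras")) {
  stopifnot(length(hotspots) > 0, !is.null(names(hotspots)))
  per_codon <- lapply(names(hotspots), function(label) {
    codon <- hotspots[[label]]
    if (nchar(codon) != 3L) stop2(sprintf("codon '%s' is not a 3-mer", label))
    assert_dna(codon, sprintf("codon '%s'", label))
    ref_aa <- translate_codon(codon)
    out <- list()
    for (pos in 1:3) {
      ref_b <- substr(codon, pos, pos)
      for (alt_b in setdiff(DNA_BASES, ref_b)) {
        mut <- codon
        substr(mut, pos, pos) <- alt_b
        alt_aa <- translate_codon(mut)
        out[[length(out) + 1L]] <- data.frame(
          codon_label = label, codon = codon, pos = pos, ref = ref_b,
          alt = alt_b, mut_codon = mut, ref_aa = ref_aa, alt_aa = alt_aa,
          consequence = if (alt_aa == ref_aa) "synonymous"
                        else if (alt_aa == "*") "nonsense" else "missense",
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  per_codon <- do.call(rbind, per_codon)
  tab <- do.call(rbind, lapply(genes, function(g)
    cbind(gene = g, per_codon, stringsAsFactors = FALSE)))
  mis <- tab[tab$consequence == "missense", ]
  aa_sets <- lapply(split(mis$alt_aa, mis$codon_label), function(x) sort(unique(x)))
  list(n_point_mutations = nrow(mis),
       n_distinct_substitutions =
         nrow(unique(mis[, c("gene", "codon_label", "alt_aa")])),
       aa_sets = aa_sets[names(hotspots)],
       table = tab)
}

#' Load reference amplicons from FASTA + YAML fixtures
#'
#' @param fasta path to a FASTA of amplicon sequences in read orientation.
#' @param meta path to a YAML file with an `amplicons:` list of blocks
#'   `{name, gene, exon, read_strand, cdna_start}`.
#' @return named list of [reference_amplicon()] objects.
#' @export
load_amplicons <- function(fasta, meta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  info <- yaml::read_yaml(meta)$amplicons
  amps <- lapply(info, function(a) {
    if (!a$name %in% names(seqs))
      stop2(sprintf("amplicon '%s' not present in FASTA", a$name))
    reference_amplicon(a$name, a$gene, a$exon, a$read_strand,
                       as.character(seqs[[a$name]]), a$cdna_start)
  })
  names(amps) <- vapply(info, `[[`, character(1), "name")
  amps
}

#' Built-in synthetic reference amplicons
#'
#' Loads the synthetic stand-in amplicons shipped with the package. These
#' sequences are not the real murine exons; they carry the hotspot features
#' used throughout (GGT at cDNA 34-36, GGC at 37-39, CAA at 181-183) so that
#' every analysis stage is exercisable without genome data.
#'
#' @return named list of [reference_amplicon()] objects.
#' @export
mds_amplicons <- function() {
  load_amplicons(
    system.file("extdata", "synthetic_amplicons.fasta", package = "mdseq"),
    system.file("extdata", "synthetic_amplicons.yaml", package = "mdseq"))
}
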
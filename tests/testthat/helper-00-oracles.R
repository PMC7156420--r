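# Independent brute-force oracles kept deliberately simple; they never call
# the vectorised implementation paths they are used to check.

# reverse complement written differently from the package helper
revcomp_chr_test <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
  }, character(1), USE.NAMES = FALSE)
}

# per-position tally consensus over a character vector of equal-length
# sequences; returns list(status, consensus)
oracle_consensus <- function(members, agreement = 0.90) {
  L <- nchar(members[1])
  cons <- character(L)
  for (j in seq_len(L)) {
    bases <- substr(members, j, j)
    tab <- sort(table(bases), decreasing = TRUE)
    if (tab[1] / length(members) < agreement)
      return(list(status = "NO_CONSENSUS", consensus = NA_character_))
    cons[j] <- names(tab)[1]
  }
  list(status = "OK", consensus = paste(cons, collapse = ""))
}

# CAN>CTN rows of a frequency table, written out longhand
tri_class_rows_test <- function(tab) {
  !is.na(tab$context5) & tab$context5 == "C" & tab$ref == "A" &
    tab$alt == "T"
}

# enumerate all 9 single-nucleotide substitutions of a codon and translate
# through the standard genetic code (expand.grid route, independent of the
# package's nested-loop enumeration)
oracle_codon_substitutions <- function(codon) {
  gc_tab <- Biostrings::GENETIC_CODE
  grid <- expand.grid(pos = 1:3, alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid$ref <- substring(codon, grid$pos, grid$pos)
  grid <- grid[grid$ref != grid$alt, ]
  grid$mut <- vapply(seq_len(nrow(grid)), function(i) {
    m <- codon
    substr(m, grid$pos[i], grid$pos[i]) <- grid$alt[i]
    m
  }, character(1))
  grid$ref_aa <- unname(gc_tab[codon])
  grid$alt_aa <- unname(gc_tab[grid$mut])
  grid
}
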
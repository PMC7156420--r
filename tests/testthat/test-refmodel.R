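test_that("variant library enumerates all distinct single substitutions", {
  amp <- reference_amplicon("mini", "g", 1, "non_transcribed",
                            "ACGTACGTAC", cdna_start = 1)
  lib <- build_variant_library(amp)
  expect_equal(nrow(lib), 30L)
  expect_equal(length(unique(lib$variant_seq)), 30L)
  expect_false(amp$sequence %in% lib$variant_seq)
  # matching a library sequence back recovers exactly one substitution
  for (i in sample.int(30L, 5L)) {
    diff <- which(strsplit(lib$variant_seq[i], "")[[1]] !=
                    strsplit(amp$sequence, "")[[1]])
    expect_equal(diff, lib$read_pos[i])
  }
})

test_that("non-ACGT reference bases are rejected with the offending position", {
  expect_error(reference_amplicon("bad", "g", 1, "non_transcribed",
                                  "ACGTNACGT", cdna_start = 1),
               "position 5")
})

test_that("codon 61 substitutions carry the oncogenic annotations", {
  lib <- build_variant_library(fixture_amplicons$Kras_ex2_nt)
  pick <- function(pos, alt) lib[lib$cdna_pos == pos & lib$alt == alt, ]
  expect_equal(pick(182, "T")$aa_change, "Q61L")
  expect_equal(pick(182, "G")$aa_change, "Q61R")
  expect_equal(pick(183, "T")$aa_change, "Q61H")
  expect_equal(pick(182, "T")$tri_class, "CAN>CTN")
  expect_equal(pick(182, "T")$comp_class, "NTG>NAG")
})

test_that("both read orientations yield identical coding-strand key sets", {
  key_set <- function(amp) {
    lib <- build_variant_library(amp)
    sort(paste(lib$cdna_pos, lib$ref, lib$alt, lib$context5, lib$context3,
               lib$aa_change, lib$sub_class, lib$tri_class))
  }
  expect_identical(key_set(fixture_amplicons$Kras_ex2_nt),
                   key_set(fixture_amplicons$Kras_ex2_t))
  expect_identical(key_set(fixture_amplicons$Kras_ex1_nt),
                   key_set(fixture_amplicons$Kras_ex1_t))
  expect_identical(key_set(toy_nt), key_set(toy_t))
})

test_that("orientation mapping is an involution on every amplicon", {
  for (amp in c(fixture_amplicons, list(toy_nt, toy_t))) {
    pos <- seq_len(amp$length)
    expect_identical(cdna_to_read(amp, read_to_cdna(amp, pos)), pos)
  }
  # transcribed-strand coding base is the complement of the read base
  amp <- fixture_amplicons$Kras_ex2_t
  for (i in c(1, 17, 60)) {
    expect_identical(coding_base(amp, read_to_cdna(amp, i)),
                     chartr("ACGT", "TGCA", substr(amp$sequence, i, i)))
  }
})

test_that("codon-change annotation translates through the genetic code", {
  # toy codons: ATG CAA GGT TCA
  expect_equal(annotate_codon_change(toy_nt, 5, "T"), "Q2L")   # CAA -> CTA
  expect_equal(annotate_codon_change(toy_nt, 6, "G"), "silent") # CAA -> CAG
  expect_equal(annotate_codon_change(toy_nt, 4, "T"), "nonsense") # CAA -> TAA
  expect_error(annotate_codon_change(toy_nt, 99, "A"), "outside")
})

test_that("substitution classes are strand-consistent", {
  cls <- classify_substitution("A", "T", "C", "A")
  expect_equal(cls$sub_class, "A>T")
  expect_equal(cls$tri_class, "CAN>CTN")
  expect_equal(cls$comp_class, "NTG>NAG")
  # involution: complement class of a key equals the (3'-anchored) class of
  # the reverse-complemented key
  set.seed(11)
  for (i in 1:50) {
    b <- sample(c("A", "C", "G", "T"), 4)
    ref <- b[1]; alt <- b[2]; c5 <- b[3]; c3 <- b[4]
    k <- classify_substitution(ref, alt, c5, c3)
    rc <- classify_substitution(chartr("ACGT", "TGCA", ref),
                                chartr("ACGT", "TGCA", alt),
                                chartr("ACGT", "TGCA", c3),
                                chartr("ACGT", "TGCA", c5))
    expect_identical(k$comp_class, rc$tri_class_3p)
  }
  # missing flank: context class undefined, substitution class still present
  edge <- classify_substitution("A", "G", NA, "C")
  expect_equal(edge$sub_class, "A>G")
  expect_equal(edge$tri_class, "undefined")
})

test_that("G34 substitutions never fall in the CAN class on either strand", {
  lib <- build_variant_library(fixture_amplicons$Kras_ex1_nt)
  # the oncogenic glycine positions of codons 12 (G34GT) and 13 (G37GC)
  g34 <- lib[lib$cdna_pos %in% c(34, 35, 37, 38), ]
  is_can <- function(ref, alt, c5) !is.na(c5) & ref == "A" & alt == "T" &
    c5 == "C"
  expect_false(any(is_can(g34$ref, g34$alt, g34$context5)))
  # and on the complementary strand (flanks swap and complement)
  expect_false(any(is_can(chartr("ACGT", "TGCA", g34$ref),
                          chartr("ACGT", "TGCA", g34$alt),
                          chartr("ACGT", "TGCA", g34$context3))))
})

test_that("hotspot enumeration matches a brute-force genetic-code oracle", {
  res <- enumerate_hotspot_mutations()
  for (codon in c(GGT = "GGT", GGC = "GGC", CAA = "CAA")) {
    oracle <- oracle_codon_substitutions(codon)
    mis <- oracle[oracle$alt_aa != oracle$ref_aa & oracle$alt_aa != "*", ]
    got <- res$table[res$table$codon == codon &
                       res$table$gene == "Kras", ]
    expect_equal(sum(got$consequence == "missense"), nrow(mis))
    expect_setequal(unique(got$alt_aa[got$consequence == "missense"]),
                    unique(mis$alt_aa))
  }
  # CAA position-1 C>T produces a stop and is excluded from missense
  caa <- res$table[res$table$codon == "CAA" & res$table$pos == 1 &
                     res$table$alt == "T" & res$table$gene == "Kras", ]
  expect_equal(caa$consequence, "nonsense")
})

test_that("A>T and A>G are two of the three possible changes of an A", {
  lib <- build_variant_library(fixture_amplicons$Kras_ex2_nt)
  a_pos <- unique(lib$cdna_pos[lib$ref == "A"])
  for (p in a_pos) {
    alts <- lib$alt[lib$cdna_pos == p]
    expect_equal(length(alts), 3L)
    expect_true(all(c("T", "G") %in% alts))
  }
})
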
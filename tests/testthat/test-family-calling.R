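amp2 <- fixture_amplicons$Kras_ex2_nt
lib2 <- build_variant_library(amp2)

# read-orientation sequence carrying a single coding-strand substitution
variant_seq <- function(amp, cdna_pos, alt) {
  lib <- if (identical(amp, amp2)) lib2 else build_variant_library(amp)
  lib$variant_seq[lib$cdna_pos == cdna_pos & lib$alt == alt]
}

test_that("exact-match grouping partitions records into families", {
  rec <- data.frame(barcode = c("X", "X", "X", "Y", "Y"),
                    target = rep("ACGT", 5))
  fam <- group_by_barcode(rec)
  expect_equal(sort(fam$size), c(2L, 3L))
  expect_equal(nrow(group_by_barcode(rec[0, ])), 0L)
})

test_that("family counts agree with the simulation manifest", {
  cfg <- simulation_config(amp2, n_templates = 500, p_seq_error = 0,
                           seed = 31)
  sim <- simulate_library(cfg, emit = "records")
  fam <- group_by_barcode(sim$reads)
  expect_equal(nrow(fam),
               length(unique(sim$manifest$barcode[sim$manifest$n_reads > 0])))
})

test_that("carcinogen-mode consensus calls follow the selection rules", {
  v182T <- variant_seq(amp2, 182, "T")
  # three identical mutant members -> SINGLE with the Q61L key
  cl <- call_family(list(barcode = "B1", members = list(rep(v182T, 3))),
                    mode = "carcinogen", amplicon = amp2,
                    variant_library = lib2)
  expect_equal(cl$status, "SINGLE")
  expect_equal(cl$aa_change, "Q61L")
  expect_equal(cl$cdna_pos, 182)
  # a family of two is below the three-read floor
  expect_equal(call_family(list(barcode = "B2", members = list(rep(v182T, 2))),
                           mode = "carcinogen", amplicon = amp2,
                           variant_library = lib2)$status, "TOO_SMALL")
  # one member with an extra lone error: 2/3 agreement < 0.90
  odd <- v182T
  substr(odd, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(odd, 5, 5))[1]
  expect_equal(call_family(list(barcode = "B3",
                                members = list(c(v182T, v182T, odd))),
                           mode = "carcinogen", amplicon = amp2,
                           variant_library = lib2)$status, "NO_CONSENSUS")
  # wild-type family
  expect_equal(call_family(list(barcode = "B4",
                                members = list(rep(amp2$sequence, 4))),
                           mode = "carcinogen", amplicon = amp2,
                           variant_library = lib2)$status, "WT")
})

test_that("spike-in mode detects co-occurring engineered mutations", {
  spk <- spikein_design(data.frame(cdna_pos = c(170, 182),
                                   alt = c("G", "T")), 0.1)
  mut <- amp2$sequence
  for (j in 1:2) {
    rp <- cdna_to_read(amp2, spk$mutations$cdna_pos[j])
    substr(mut, rp, rp) <- spk$mutations$alt[j]
  }
  cl <- call_family(list(barcode = "S", members = list(rep(mut, 2))),
                    mode = "spikein", amplicon = amp2, spikein = spk)
  expect_equal(cl$status, "DETECTED")
  # a family of two wild types is not detected
  expect_equal(call_family(list(barcode = "S2",
                                members = list(rep(amp2$sequence, 2))),
                           mode = "spikein", amplicon = amp2,
                           spikein = spk)$status, "NOT_DETECTED")
  # single read is below the spike-in floor
  expect_equal(call_family(list(barcode = "S3", members = list(mut)),
                           mode = "spikein", amplicon = amp2,
                           spikein = spk)$status, "TOO_SMALL")
})

test_that("calls are invariant under member permutation and consensus growth", {
  v <- variant_seq(amp2, 175, "T")
  members <- c(rep(v, 8), amp2$sequence)  # 8/9 agreement < 0.90 at one spot?
  base <- call_family(list(barcode = "P", members = list(members)),
                      mode = "carcinogen", amplicon = amp2,
                      variant_library = lib2)
  for (i in 1:5) {
    perm <- sample(members)
    expect_equal(call_family(list(barcode = "P", members = list(perm)),
                             mode = "carcinogen", amplicon = amp2,
                             variant_library = lib2)$status, base$status)
  }
  # adding a member identical to the current consensus never changes the call
  solid <- call_family(list(barcode = "Q", members = list(rep(v, 5))),
                       mode = "carcinogen", amplicon = amp2,
                       variant_library = lib2)
  grown <- call_family(list(barcode = "Q", members = list(rep(v, 6))),
                       mode = "carcinogen", amplicon = amp2,
                       variant_library = lib2)
  expect_equal(grown$status, solid$status)
  expect_equal(grown$cdna_pos, solid$cdna_pos)
})

test_that("vectorised calling agrees with the per-family reference on random families", {
  set.seed(47)
  n_fam <- 300
  families <- lapply(seq_len(n_fam), function(i) {
    size <- sample(1:8, 1)
    base <- if (runif(1) < 0.5) amp2$sequence else
      lib2$variant_seq[sample.int(nrow(lib2), 1)]
    members <- rep(base, size)
    # sprinkle independent errors
    n_err <- rpois(1, 0.7)
    for (e in seq_len(n_err)) {
      j <- sample.int(size, 1)
      p <- sample.int(nchar(base), 1)
      substr(members[j], p, p) <-
        sample(setdiff(c("A", "C", "G", "T"), substr(members[j], p, p)), 1)
    }
    members
  })
  rec <- make_records(families)
  vec <- call_families(rec, amp2, mode = "carcinogen", variant_library = lib2)
  for (i in seq_len(n_fam)) {
    bc <- sprintf("BC%04d", i)
    ref <- call_family(list(barcode = bc, members = list(families[[i]])),
                       mode = "carcinogen", amplicon = amp2,
                       variant_library = lib2)
    row <- vec[vec$barcode == bc, ]
    expect_equal(row$status, ref$status)
    if (ref$status == "SINGLE") {
      expect_equal(row$cdna_pos, ref$cdna_pos)
      expect_equal(row$alt, ref$alt)
    }
    # oracle consensus agrees where a call was attempted
    if (!ref$status %in% c("TOO_SMALL")) {
      orc <- oracle_consensus(families[[i]])
      if (orc$status == "NO_CONSENSUS") {
        expect_equal(ref$status, "NO_CONSENSUS")
      } else if (ref$status != "NO_CONSENSUS") {
        expect_equal(ref$consensus_seq, orc$consensus)
      }
    }
  }
})

test_that("zero-error families match the manifest exactly", {
  spk <- spikein_design(data.frame(cdna_pos = c(170, 182),
                                   alt = c("G", "T")), 0.02)
  cfg <- simulation_config(amp2, n_templates = 600, spikeins = list(spk),
                           p_linear_error = 0, p_seq_error = 0,
                           lambda_reads = 6, seed = 53)
  sim <- simulate_library(cfg, emit = "records")
  cl <- call_families(sim$reads, amp2, mode = "carcinogen",
                      variant_library = lib2)
  expect_equal(sum(cl$status == "NO_CONSENSUS"), 0L)
  # spiked templates are double mutants: consensus present but OTHER
  mut_bc <- sim$manifest$barcode[sim$manifest$mutations != "" &
                                   sim$manifest$n_reads >= 3]
  expect_setequal(cl$barcode[cl$status == "OTHER"], mut_bc)
  wt_bc <- sim$manifest$barcode[sim$manifest$mutations == "" &
                                  sim$manifest$n_reads >= 3]
  expect_setequal(cl$barcode[cl$status == "WT"], wt_bc)
})

test_that("sample QC excludes below the barcode-recovery floor", {
  expect_false(sample_qc(140000))
  expect_true(sample_qc(150000))
  expect_false(sample_qc(0))
  expect_true(sample_qc(40, threshold = 40))
})
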
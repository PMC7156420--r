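amp2 <- fixture_amplicons$Kras_ex2_nt
lib2 <- build_variant_library(amp2)

# minimal calls table: n_single families carrying one key, rest WT
fake_calls <- function(n_single, n_total, cdna_pos = 182, alt = "T") {
  ref <- lib2$ref[lib2$cdna_pos == cdna_pos & lib2$alt == alt]
  data.frame(
    barcode = sprintf("B%07d", seq_len(n_total)),
    size = 3L,
    status = c(rep("SINGLE", n_single), rep("WT", n_total - n_single)),
    cdna_pos = c(rep(cdna_pos, n_single), rep(NA, n_total - n_single)),
    ref = c(rep(ref, n_single), rep(NA, n_total - n_single)),
    alt = c(rep(alt, n_single), rep(NA, n_total - n_single)))
}

test_that("mutation frequency is families-with-mutation over total families", {
  # one mutant family among 2e6 gives the assay's 5e-7 sensitivity floor
  fr <- compute_frequencies(fake_calls(1, 10), lib2, total_families = 2e6)
  expect_equal(fr$mf[fr$cdna_pos == 182 & fr$alt == "T"], 5e-7)
  fr2 <- compute_frequencies(fake_calls(3, 12), lib2)
  expect_equal(fr2$total_families[1], 12)
  expect_equal(fr2$mf[fr2$cdna_pos == 182 & fr2$alt == "T"], 0.25)
  # unobserved keys get explicit zero rows for all 3L library keys
  expect_equal(nrow(fr2), nrow(lib2))
  expect_equal(sum(fr2$mf > 0), 1L)
  expect_error(compute_frequencies(fake_calls(0, 10), lib2,
                                   total_families = 0), "no selected")
})

test_that("detection-limit correction and conservation hold", {
  fr <- compute_frequencies(fake_calls(2, 100), lib2)
  expect_equal(fr$mf_corrected[fr$mf == 0][1], 1 / 1.5e5)
  expect_equal(1 / 1.5e5, 6.67e-6, tolerance = 5e-4)
  expect_true(all(fr$mf_corrected >= 1 / 1.5e5))
  expect_lte(sum(fr$n_families), fr$total_families[1])
  # correction is a strictly monotone shift: ordering preserved
  expect_identical(order(fr$mf), order(fr$mf_corrected))
})

test_that("fold-change over PBS follows the correct-sum-normalise-log order", {
  mk_tab <- function(n_single) compute_frequencies(fake_calls(n_single, 1000),
                                                   lib2)
  tables <- list(pbs1 = mk_tab(0), pbs2 = mk_tab(0), ur1 = mk_tab(0),
                 ur2 = mk_tab(9))
  meta <- data.frame(sample = names(tables),
                     treatment = c("PBS", "PBS", "UR", "UR"))
  hm <- correct_and_fold_change(tables, meta, group_by = "position")
  key182 <- "182"
  # UR sample equal to the PBS mean -> log10 FC = 0
  expect_equal(unname(hm$values["ur1", key182]), 0)
  # at position 182: PBS-corrected sum is 3 * constant; ur2 adds 9/1000
  c0 <- 1 / 1.5e5
  expected <- log10((9 / 1000 + 3 * c0) / (3 * c0))
  expect_equal(unname(hm$values["ur2", key182]), expected)
  # PBS fold-changes against their own mean have log10 mean 0 per key
  expect_equal(mean(hm$values[c("pbs1", "pbs2"), key182]), 0,
               tolerance = 1e-12)
  expect_error(correct_and_fold_change(tables,
                                       within(meta, treatment <- "UR")),
               "PBS")
})

test_that("a pure corrected-sum fold change of 10 gives log10 FC of 1", {
  # engineered: UR corrected sum 6.67e-5 vs PBS mean 6.67e-6
  tab_pbs <- compute_frequencies(fake_calls(0, 1000), lib2)
  tab_ur <- tab_pbs
  i <- which(tab_ur$cdna_pos == 182 & tab_ur$alt == "T")
  tab_ur$mf[i] <- 9 / 1.5e5  # corrected: 10/1.5e5 vs 1/1.5e5
  hm <- correct_and_fold_change(list(p = tab_pbs, u = tab_ur),
                                data.frame(sample = c("p", "u"),
                                           treatment = c("PBS", "UR")),
                                group_by = "a2t")
  key <- grep("^182:", colnames(hm$values), value = TRUE)
  expect_equal(unname(hm$values["u", key]), 1)
})

test_that("C>T and G>T artifacts are sourced from the complementary strand", {
  tab_nt <- compute_frequencies(fake_calls(0, 1000), lib2)
  lib2t <- build_variant_library(fixture_amplicons$Kras_ex2_t)
  calls_t <- fake_calls(0, 500)
  tab_t <- compute_frequencies(calls_t, lib2t, total_families = 500)
  # plant a G>T key count in the transcribed-strand table (reads as C>A there)
  gt <- which(tab_t$sub_class == "G>T")[1]
  tab_t$n_families[gt] <- 5L
  tab_t$mf[gt] <- 5 / 500
  tab_t$mf_corrected[gt] <- tab_t$mf[gt] + 1 / 1.5e5
  merged <- mask_strand_artifacts(tab_nt, tab_t)
  key <- paste(merged$cdna_pos, merged$ref, merged$alt)
  tkey <- paste(tab_t$cdna_pos, tab_t$ref, tab_t$alt)
  i <- match(tkey[gt], key)
  expect_equal(merged$mf[i], 5 / 500)
  expect_equal(merged$source_strand[i], "transcribed")
  # all C>T and G>T coding keys come from the transcribed assay
  prone <- merged$sub_class %in% c("C>T", "G>T")
  expect_true(all(merged$source_strand[prone] == "transcribed"))
  # A>T keys pass through unchanged from the native strand
  a2t <- merged$sub_class == "A>T"
  expect_true(all(merged$source_strand[a2t] == "non_transcribed"))
  expect_equal(merged$mf[a2t], tab_nt$mf[tab_nt$sub_class == "A>T"])
  # without the complementary assay, artifact-prone keys are masked
  solo <- mask_strand_artifacts(tab_nt, NULL)
  expect_true(all(solo$masked[solo$sub_class %in% c("C>T", "G>T")]))
  expect_true(all(is.na(solo$mf[solo$masked])))
  expect_false(any(solo$masked[solo$sub_class == "A>T"]))
})

test_that("symmetric error-free strand tables merge without distortion", {
  cfg_nt <- simulation_config(amp2, n_templates = 400, p_linear_error = 0,
                              p_seq_error = 0, seed = 61)
  sim_nt <- simulate_library(cfg_nt, emit = "records")
  cl_nt <- call_families(sim_nt$reads, amp2, mode = "carcinogen",
                         variant_library = lib2)
  tab_nt <- compute_frequencies(cl_nt, lib2)
  ampt <- fixture_amplicons$Kras_ex2_t
  libt <- build_variant_library(ampt)
  cfg_t <- simulation_config(ampt, n_templates = 400, p_linear_error = 0,
                             p_seq_error = 0, seed = 62)
  sim_t <- simulate_library(cfg_t, emit = "records")
  cl_t <- call_families(sim_t$reads, ampt, mode = "carcinogen",
                        variant_library = libt)
  tab_t <- compute_frequencies(cl_t, libt)
  merged <- mask_strand_artifacts(tab_nt, tab_t)
  # no mutations simulated: all frequencies zero on both strands, so the
  # merged table equals either input's frequencies exactly
  expect_true(all(merged$mf == 0))
  expect_false(any(merged$masked))
})
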
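# small config used throughout: quick to generate but retains the
# two-strain 2x3 design and plantable large proteins
small_cfg <- function(seed = 7, ...) {
  sim_config(n_proteins = 40, n_up = 3, n_down = 3,
             n_exclusive_a = 4, n_exclusive_b = 3,
             dispersion = 0, seed = seed, ...)
}

test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- small_cfg()
  p1 <- generate_proteome(cfg)
  p2 <- generate_proteome(cfg)
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(p1, f1)
  write_proteome_fasta(p2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  s1 <- simulate_counts(p1, cfg)
  s2 <- simulate_counts(p2, cfg)
  expect_identical(s1$counts, s2$counts)
  # different seed changes the draw
  expect_false(identical(
    s1$counts, simulate_counts(p1, small_cfg(seed = 8))$counts))
})

test_that("generated proteomes stay in the canonical alphabet with OP >= 1", {
  prot <- generate_proteome(small_cfg())
  expect_identical(nrow(prot), 40L)
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", prot$sequence)))
  expect_true(all(prot$op >= 1))
  expect_true(all(prot$length >= 90 & prot$length <= 900))
  expect_true(all(prot$category %in% functional_categories()))
})

test_that("FASTA output is 60-column wrapped with accession headers", {
  prot <- generate_proteome(small_cfg())
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(prot, fa)
  lines <- readLines(fa)
  seq_lines <- lines[!startsWith(lines, ">")]
  expect_true(all(nchar(seq_lines) <= 60))
  back <- Biostrings::readAAStringSet(fa)
  expect_identical(unname(as.character(back)), prot$sequence)
})

test_that("planted effects shift mean counts by the configured fold", {
  # enough planted proteins that the empirical mean ratio is tight
  cfg <- sim_config(n_proteins = 120, n_up = 10, n_down = 10,
                    n_exclusive_a = 0, n_exclusive_b = 0,
                    dispersion = 0, seed = 9)
  prot <- generate_proteome(cfg)
  sim <- simulate_counts(prot, cfg)
  wide <- merge(sim$counts, sim$design, by = "run_id")
  up_acc <- sim$truth$accession[sim$truth$role == "up"]
  mean_by <- function(acc, strain) {
    mean(wide$spectral_count[wide$accession %in% acc &
                               wide$strain == strain])
  }
  # pooled over planted up proteins, PR2/ref ratio within 10% of 5
  ratio <- mean_by(up_acc, "PR2") / mean_by(up_acc, "SP06081")
  expect_lt(abs(ratio - 5) / 5, 0.10)
  down_acc <- sim$truth$accession[sim$truth$role == "down"]
  ratio_d <- mean_by(down_acc, "PR2") / mean_by(down_acc, "SP06081")
  expect_lt(abs(ratio_d - 0.2) / 0.2, 0.10)
})

test_that("exclusive proteins are absent from the other strain", {
  cfg <- small_cfg(seed = 10)
  prot <- generate_proteome(cfg)
  sim <- simulate_counts(prot, cfg)
  wide <- merge(sim$counts, sim$design, by = "run_id")
  ex_a <- sim$truth$accession[sim$truth$role == "exclusive_a"]
  ex_b <- sim$truth$accession[sim$truth$role == "exclusive_b"]
  expect_identical(sum(wide$spectral_count[wide$accession %in% ex_a &
                                             wide$strain == "PR2"]), 0L)
  expect_identical(sum(wide$spectral_count[wide$accession %in% ex_b &
                                             wide$strain == "SP06081"]), 0L)
  # dropout mode leaves a small nonzero mean instead
  cfg_d <- small_cfg(seed = 10, exclusive_mode = "dropout",
                     dropout_factor = 0.5)
  sim_d <- simulate_counts(prot, cfg_d)
  wide_d <- merge(sim_d$counts, sim_d$design, by = "run_id")
  expect_gt(sum(wide_d$spectral_count[wide_d$accession %in% ex_a &
                                        wide_d$strain == "PR2"]), 0L)
})

test_that("null configuration gives equal strain means within Poisson error", {
  cfg <- sim_config(n_proteins = 60, n_up = 0, n_down = 0,
                    n_exclusive_a = 0, n_exclusive_b = 0,
                    effect_fold = 1, dispersion = 0, seed = 11)
  prot <- generate_proteome(cfg)
  sim <- simulate_counts(prot, cfg)
  wide <- merge(sim$counts, sim$design, by = "run_id")
  tot <- tapply(wide$spectral_count, wide$strain, sum)
  # two Poisson totals with the same expectation: z-score below 4
  z <- (tot[1] - tot[2]) / sqrt(tot[1] + tot[2])
  expect_lt(abs(z), 4)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_proteins = 10, n_up = 8, n_down = 8),
               "n_up", class = "empaiq_invalid_config")
  expect_error(sim_config(effect_fold = 0), "effect_fold",
               class = "empaiq_invalid_config")
  expect_error(sim_config(length_range = c(10, 50)), "length_range",
               class = "empaiq_invalid_config")
  expect_error(sim_config(dispersion = -1), "dispersion",
               class = "empaiq_invalid_config")
  cfg <- sim_config(n_proteins = 5, n_up = 2, n_down = 2,
                    n_exclusive_a = 0, n_exclusive_b = 0,
                    length_range = c(90, 120), seed = 3)
  prot <- generate_proteome(cfg)
  expect_error(simulate_counts(prot, cfg), "plant_min_op",
               class = "empaiq_invalid_config")
})

test_that("Ct generator inverts exactly at zero noise", {
  ct <- generate_ct_table(c("gA", "gB"), c(1, 8), seed = 5)
  resA <- ddct(ct, "gA", "sigA", "SP06081")
  expect_equal(resA$rel_expression[resA$sample == "SP06081"], 1)
  expect_equal(resA$rel_expression[resA$sample == "PR2"], 1)
  resB <- ddct(ct, "gB", "sigA", "SP06081")
  expect_equal(resB$rel_expression[resB$sample == "PR2"], 8)
  # fold 2 shifts the test-sample target Ct by exactly -1 cycle
  ct2 <- generate_ct_table("g", 2, seed = 5)
  cal <- mean(ct2$ct[ct2$sample == "SP06081" & ct2$gene == "g"])
  tst <- mean(ct2$ct[ct2$sample == "PR2" & ct2$gene == "g"])
  expect_equal(tst - cal, -1)
  expect_error(generate_ct_table("g", -2), class = "empaiq_invalid_config")
})
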
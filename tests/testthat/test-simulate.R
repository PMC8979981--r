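test_that("mass_to_copies reproduces the reference conversions", {
  expect_equal(mass_to_copies(10), 2790L)
  expect_equal(mass_to_copies(0.003584), 1L)
  expect_equal(mass_to_copies(8.3), 2316L)
  expect_error(mass_to_copies(0), "positive")
  expect_error(mass_to_copies(10, 0), "positive")
})

test_that("sim_config enforces its invariants", {
  expect_error(sim_config(), "exactly one")
  expect_error(sim_config(input_mass_ng = 1, input_copies = 10), "exactly one")
  expect_error(sim_config(input_copies = 10, conversion_yield = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(input_copies = 10,
                          spiked_variants = data.frame(module_id = "M",
                                                       offset = 1, alt = "A",
                                                       vaf = 2)), "VAF")
})

test_that("input molecule sampling is Poisson with the ploidy-scaled mean", {
  panel <- random_panel(genes = c(G = 10L), n_reference = 40L, seed = 10)
  cfg <- sim_config(input_copies = 2790, seed = 1)
  set.seed(11)
  draws <- as.vector(replicate(20, sample_input_molecules(cfg, panel)))
  se <- sqrt(2790 / length(draws))
  expect_lt(abs(mean(draws) - 2790), 3 * se)

  cfg4 <- sim_config(input_copies = 2790, ploidy_map = c(G = 4.0), seed = 1)
  set.seed(12)
  d4 <- replicate(20, sample_input_molecules(cfg4, panel))
  g_rows <- which(panel$modules$gene == "G")
  ratio <- mean(d4[g_rows, ]) / mean(d4[-g_rows, ])
  expect_lt(abs(ratio - 2), 0.05)

  cfg0 <- sim_config(input_copies = 0, seed = 1)
  expect_true(all(sample_input_molecules(cfg0, panel) == 0L))
})

test_that("UMI barcoding thins molecules binomially", {
  cfg1 <- sim_config(input_copies = 1, conversion_yield = 1.0, seed = 1)
  counts <- c(M1 = 100L)
  set.seed(13)
  expect_length(attach_umis(counts, cfg1)$M1, 100L)

  cfg0 <- sim_config(input_copies = 1, conversion_yield = 0.0, seed = 1)
  expect_length(attach_umis(counts, cfg0)$M1, 0L)

  cfg86 <- sim_config(input_copies = 1, conversion_yield = 0.86, seed = 1)
  set.seed(14)
  n_bar <- replicate(50, length(attach_umis(c(M = 2790L), cfg86)$M))
  se <- sqrt(2790 * 0.86 * 0.14 / 50)
  expect_lt(abs(mean(n_bar) - 0.86 * 2790), 3 * se)

  set.seed(15)
  umis <- attach_umis(counts, cfg1, umi_length = 12L)$M1
  expect_true(all(nchar(umis) == 12L))
  expect_true(all(grepl("^[ACGT]+$", umis)))
})

test_that("amplification follows branching-process expectations", {
  # deterministic doubling
  expect_equal(amplify_family(5, cycles = 5, efficiency = 1.0,
                              efficiency_sd = 0, high_eff_cycles = 0),
               rep(32L, 5))
  expect_equal(amplify_family(3, cycles = 0, efficiency = 0.9,
                              efficiency_sd = 0, high_eff_cycles = 0),
               rep(1L, 3))
  # classical fixed-efficiency mode: mean (1 + e)^C
  set.seed(16)
  s <- amplify_family(5000, cycles = 12, efficiency = 0.9,
                      efficiency_sd = 0, high_eff_cycles = 0)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1.9^12), 3 * se)
})

test_that("family sizes above the cutoff are log-normal in shape", {
  set.seed(17)
  s <- amplify_family(10000)
  cutoff <- family_size_cutoff(s)
  ls <- log(s[s >= cutoff])
  expect_lt(abs(skewness(ls)), 0.5)
})

test_that("simulate_run is byte-deterministic given a seed", {
  panel <- random_panel(genes = c(G = 2L), n_reference = 2L, seed = 20)
  cfg <- sim_config(input_copies = 100, mean_depth_per_module = 2000, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  simulate_run(cfg, panel, out_fastq = f1, out_truth = t1)
  simulate_run(cfg, panel, out_fastq = f2, out_truth = t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("error-free runs conserve reads and assign perfectly", {
  panel <- random_panel(genes = c(G = 2L), n_reference = 2L, seed = 21)
  cfg <- sim_config(input_copies = 200, mean_depth_per_module = 4000,
                    per_base_error_rate = 0, off_target_fraction = 0.25,
                    seed = 7)
  tr <- simulate_run(cfg, panel)
  expect_equal(length(tr$reads),
               sum(tr$modules$n_reads_on_target) + tr$n_off_target)
  # off-target close to its nominal fraction by construction
  expect_equal(tr$n_off_target,
               round(sum(tr$modules$n_reads_on_target) * 0.25 / 0.75))

  asg <- assign_reads(tr$reads, panel, read_ids = tr$read_ids)
  on <- !is.na(asg$module_id)
  expect_equal(sum(on), sum(tr$modules$n_reads_on_target))
  expect_true(all(asg$mismatches[on] == 0L))
})

test_that("spiked variants hit their binomial truth", {
  panel <- two_plex_panel()
  cfg <- sim_config(input_copies = 1000, conversion_yield = 1.0,
                    mean_depth_per_module = 8000,
                    spiked_variants = data.frame(module_id = "ERBB2_1",
                                                 offset = 4, alt = "G",
                                                 vaf = 0.10),
                    seed = 3)
  tr <- simulate_run(cfg, panel)
  expect_equal(nrow(tr$variants), 1L)
  se <- sqrt(1000 * 0.1 * 0.9)
  expect_lt(abs(tr$variants$true_alt_families - 100), 3 * se)
  # a sub-molecule spike warns
  cfg_low <- sim_config(input_copies = 100, conversion_yield = 1.0,
                        spiked_variants = data.frame(module_id = "ERBB2_1",
                                                     offset = 4, alt = "G",
                                                     vaf = 1e-4),
                        seed = 4)
  expect_warning(simulate_run(cfg_low, panel), "may be absent")
})

test_that("simulate_counts mirrors the molecular layers of simulate_run", {
  panel <- random_panel(genes = c(G = 3L), n_reference = 5L, seed = 22)
  cfg <- sim_config(input_copies = 2000, seed = 5)
  ct <- simulate_counts(cfg, panel)
  expect_s3_class(ct, "molecule_counts")
  expect_equal(nrow(ct), 8L)
  se <- 3 * sqrt(2000 * 0.86 / 8)
  expect_lt(abs(mean(ct$molecule_count) - 2000 * 0.86), se * 3)
})
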
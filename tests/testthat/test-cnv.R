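make_counts <- function(panel, counts) {
  df <- data.frame(module_id = panel$modules$module_id,
                   gene = panel$modules$gene, role = panel$modules$role,
                   n_families_raw = as.integer(counts), size_cutoff = 3,
                   molecule_count = as.integer(counts),
                   stringsAsFactors = FALSE)
  class(df) <- c("molecule_counts", "data.frame")
  df
}

test_that("module and gene ploidy are count ratios against the reference mean", {
  panel <- random_panel(genes = c(G = 3L), n_reference = 4L, seed = 50)
  ct <- make_counts(panel, c(110, 90, 100, 100, 100, 100, 100))
  mp <- module_ploidy(ct, panel)
  expect_equal(unname(mp["M001"]), 2.2)
  expect_equal(unname(mp["M004"]), 2.0)
  expect_equal(gene_ploidy(ct, panel, "G"), 2.0)

  ct150 <- make_counts(panel, c(150, 150, 150, 100, 100, 100, 100))
  expect_equal(gene_ploidy(ct150, panel, "G"), 3.0)

  expect_error(module_ploidy(make_counts(panel, rep(0, 7)), panel), "zero")
})

test_that("2-plex ploidy reduces to twice the count ratio", {
  panel <- two_plex_panel()
  ct <- make_counts(panel, c(2400, 2400))
  expect_equal(gene_ploidy(ct, panel, "ERBB2"), 2.00)
  ct2 <- make_counts(panel, c(2376, 2400))
  expect_equal(gene_ploidy(ct2, panel, "ERBB2"), 1.98)
})

test_that("mw_test_gene handles exact, tied and refused cases", {
  expect_equal(mw_test_gene(rep(2, 5), rep(2, 20)), 1.0)
  set.seed(51)
  p <- mw_test_gene(c(3.0, 3.1, 2.9), 2 + rnorm(20, 0, 0.01))
  expect_lt(p, 0.01)
  expect_error(mw_test_gene(c(2, 2.1), rep(2, 10)), "untestable")
})

test_that("exact Mann-Whitney p matches brute-force rank enumeration", {
  # independent oracle: enumerate all placements of the gene sample's ranks
  brute_p <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(seq_len(n1 + n2)[combos], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p_le <- mean(u_all <= u_obs)
    p_ge <- mean(u_all >= u_obs)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(52)
  for (n1 in 3:6) {
    for (n2 in 3:6) {
      for (rep in 1:3) {
        x <- rnorm(n1)
        y <- rnorm(n2)
        expect_equal(mw_test_gene(x, y), brute_p(x, y), tolerance = 1e-12)
      }
    }
  }
})

test_that("call_cnvs reports neutral genes at exactly 2.00", {
  panel <- random_panel(genes = c(A = 5L, B = 5L), n_reference = 30L, seed = 53)
  cfg <- sim_config(input_copies = 2300, seed = 1)
  ct <- simulate_counts(cfg, panel, seed = 530)
  calls <- call_cnvs(ct, panel)
  expect_equal(nrow(calls), 2L)
  expect_true(all(calls$call == "neutral"))
  expect_true(all(calls$reported_ploidy == 2.00))
})

test_that("call_cnvs detects a strong amplification and leaves others alone", {
  panel <- random_panel(genes = c(ERBB2 = 10L, OTHER = 5L),
                        n_reference = 30L, seed = 54)
  cfg <- sim_config(input_copies = 2300, ploidy_map = c(ERBB2 = 6.0), seed = 1)
  ct <- simulate_counts(cfg, panel, seed = 540)
  calls <- call_cnvs(ct, panel)
  erbb2 <- calls[calls$gene == "ERBB2", ]
  expect_equal(erbb2$call, "gain")
  expect_lt(abs(erbb2$reported_ploidy - 6), 0.3)
  expect_equal(calls$call[calls$gene == "OTHER"], "neutral")
  # calls are ordered by effect size, largest first
  expect_equal(calls$gene[1], "ERBB2")
})

test_that("genes below the module threshold never appear in calls", {
  panel <- random_panel(genes = c(BIG = 5L, TINY = 2L), n_reference = 20L,
                        seed = 55)
  cfg <- sim_config(input_copies = 2000, ploidy_map = c(TINY = 6.0), seed = 1)
  ct <- simulate_counts(cfg, panel, seed = 550)
  calls <- call_cnvs(ct, panel)
  expect_false("TINY" %in% calls$gene)
})

test_that("null calibration: non-neutral call rate stays below alpha", {
  panel <- random_panel(genes = c(A = 4L, B = 4L, C = 4L, D = 4L),
                        n_reference = 40L, seed = 56)
  cfg <- sim_config(input_copies = 2000, seed = 1)
  calls <- unlist(lapply(1:50, function(s) {
    ct <- simulate_counts(cfg, panel, seed = 5600 + s)
    call_cnvs(ct, panel)$call
  }))
  expect_lte(mean(calls != "neutral"), 0.05)
})

test_that("simulated gene ploidies are recovered within 5%", {
  truth <- c(A = 1.5, B = 2.2, C = 3.0, D = 6.0)
  panel <- random_panel(genes = c(A = 10L, B = 10L, C = 10L, D = 10L),
                        n_reference = 40L, seed = 57)
  cfg <- sim_config(input_copies = 2300, ploidy_map = truth, seed = 1)
  est <- rowMeans(vapply(1:5, function(s) {
    ct <- simulate_counts(cfg, panel, seed = 5700 + s)
    vapply(names(truth), function(g) gene_ploidy(ct, panel, g), 0)
  }, numeric(4)))
  expect_true(all(abs(est - truth) / truth < 0.05))
})

test_that("LoD brackets follow mean +/- k sd", {
  lod <- lod_from_replicates(c(2, 2, 2, 2, 2))
  expect_equal(lod$lod_loss, 2.00)
  expect_equal(lod$lod_gain, 2.00)

  # replicate CV of 0.69% around mean 2.00
  set.seed(58)
  reps <- c(1.9862, 2.0138, 2.0000, 1.9931, 2.0069)
  reps <- 2 + (reps - mean(reps)) / sd(reps) * 0.0138  # exact mean/sd
  lod2 <- lod_from_replicates(reps)
  expect_equal(round(lod2$lod_loss, 3), 1.959)
  expect_equal(round(lod2$lod_gain, 3), 2.041)
  expect_lt(lod2$lod_loss, lod2$mean_ploidy)

  lod0 <- lod_from_replicates(c(1.9, 2.0, 2.1), k_sigma = 0)
  expect_equal(lod0$lod_loss, lod0$lod_gain)
  expect_error(lod_from_replicates(c(2, 2)), "3 replicates")
})

test_that("cv_vs_modules obeys degenerate and scaling sanity checks", {
  # large reference set so the m_ref term in the theoretical CV is negligible
  panel <- random_panel(genes = c(G = 16L), n_reference = 200L, seed = 59)
  ct <- simulate_counts(sim_config(input_copies = 2000, seed = 1), panel,
                        seed = 590)
  identical_reps <- list(ct, ct, ct)
  curve <- cv_vs_modules(identical_reps, panel, "G", c(1, 4, 16),
                         n_random = 5, seed = 2)
  expect_true(all(curve$cv == 0))
  # theoretical curve halves when m quadruples
  expect_equal(curve$theoretical_cv[1] / curve$theoretical_cv[2], 2,
               tolerance = 0.01)
  expect_error(cv_vs_modules(identical_reps, panel, "G", 17), "exceeds")
  expect_error(cv_vs_modules(list(ct), panel, "G", 4), "2 replicates")
})

test_that("equivalent_assay_count is n choose 2", {
  expect_equal(equivalent_assay_count(175), 15225L)
  expect_equal(equivalent_assay_count(2), 1L)
  expect_equal(equivalent_assay_count(223), 24753L)
  expect_error(equivalent_assay_count(1), ">= 2")
})

test_that("chi-square independence matches the hand-computed oracle", {
  tab <- matrix(c(8, 0, 4, 3), 2, byrow = TRUE)
  # oracle: sum (O - E)^2 / E with E from the margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_oracle <- sum((tab - E)^2 / E)
  res <- chi_square_independence(tab)
  expect_equal(res$statistic, stat_oracle, tolerance = 1e-12)
  expect_equal(res$statistic, 30 / 7, tolerance = 1e-12)
  expect_equal(round(res$p_value, 3), 0.038)

  flat <- chi_square_independence(matrix(5, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # with Yates correction the worked example is no longer significant
  yates <- chi_square_independence(tab, continuity = TRUE)
  expect_gt(yates$p_value, 0.1)
  expect_error(chi_square_independence(matrix(c(0, 0, 4, 3), 2)), "margin")
})

test_that("two_sample_t is a Welch two-sided test with degenerate handling", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(two_sample_t(rep(2, 3), rep(2, 4)), 1)
  expect_equal(two_sample_t(rep(2, 3), rep(2.1, 4)), 0)
  set.seed(60)
  a <- rnorm(4, 2.00, 1e-4)
  b <- rnorm(4, 2.05, 1e-4)
  expect_lt(two_sample_t(a, b), 0.05)
  expect_equal(two_sample_t(a, b), stats::t.test(a, b)$p.value,
               tolerance = 1e-12)
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
})
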
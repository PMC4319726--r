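test_that("marginal exact mode reproduces target counts exactly", {
  cfg <- sim_config("marginal")
  sim <- simulate_marginal(cfg, seed = 3, exact = TRUE)
  cnts <- gastric_genotype_counts()
  for (id in names(cnts))
    expect_equal(tabulate_genotypes(sim, id)$counts, cnts[[id]]$counts)
  # covariate margins too
  s <- sim$subjects
  expect_equal(sum(s$status == "case" & s$smoking == "ever"), 265L)
  expect_equal(sum(s$status == "control" & s$bmi_cat == "high"), 525L)
})

test_that("simulation is deterministic given (seed, config)", {
  cfg <- sim_config("marginal", n_cases = 120, n_controls = 150)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_subject_table(simulate_marginal(cfg, seed = 17), f1)
  write_subject_table(simulate_marginal(cfg, seed = 17), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_subject_table(simulate_marginal(cfg, seed = 18), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("degenerate group sizes work", {
  cfg <- sim_config("marginal", n_cases = 0, n_controls = 50)
  sim <- simulate_marginal(cfg, seed = 1)
  expect_equal(nrow(sim$subjects), 50L)
  expect_true(all(sim$subjects$status == "control"))
})

test_that("copy pairs reproduce tight linkage in the limit rho = 1", {
  cfg <- sim_config("marginal", n_cases = 200, n_controls = 200,
                    copy_pairs = list(list(from = "rs2294008",
                                           to = "rs2976392", rho = 1)))
  sim <- simulate_marginal(cfg, seed = 5)
  idx <- function(id) match(sim$subjects[[id]],
                            genotype_labels(sim$panel[[id]]))
  expect_equal(idx("rs2976392"), idx("rs2294008"))
})

test_that("causal truth predicts the case genotype margin", {
  panel <- snp_panel(snp_def("rsA", "G", "A>G"))
  cfg <- sim_config("causal", n_cases = 2500, n_controls = 500,
                    panel = panel,
                    snps = list(rsA = list(q = 0.3, or_het = 1.4,
                                           or_hom = 2.0)))
  sim <- simulate_causal(cfg, seed = 21)
  want <- case_genotype_probs(sim$truth, "rsA")
  got <- tabulate_genotypes(sim$cohort, "rsA")$counts["case", ] / 2500
  se <- sqrt(want * (1 - want) / 2500)
  expect_true(all(abs(got - want) < 4 * se))
})

test_that("null causal configuration is unbiased (scaled)", {
  panel <- snp_panel(snp_def("rsA", "G", "A>G"))
  cfg <- sim_config("causal", n_cases = 400, n_controls = 400,
                    panel = panel,
                    snps = list(rsA = list(q = 0.3, or_het = 1,
                                           or_hom = 1)))
  lnors <- vapply(1:40, function(r) {
    sim <- simulate_causal(cfg, seed = 100 + r)
    log(crude_or(make_contrast(tabulate_genotypes(sim$cohort, "rsA"),
                               "dominant"))$or_hat)
  }, 0)
  # mean log-OR within 3 standard errors of zero
  expect_lt(abs(mean(lnors)), 3 * sd(lnors) / sqrt(length(lnors)))
})

test_that("rare-disease controls stay in HWE", {
  panel <- snp_panel(snp_def("rsA", "G", "A>G"))
  cfg <- sim_config("causal", n_cases = 100, n_controls = 800,
                    panel = panel, baseline_odds = 0.02,
                    snps = list(rsA = list(q = 0.25, or_het = 1.3,
                                           or_hom = 1.7)))
  ps <- vapply(1:60, function(r) {
    sim <- simulate_causal(cfg, seed = 4000 + r)
    hwe_chisq(tabulate_genotypes(sim$cohort, "rsA"))$p
  }, 0)
  # p-values approximately uniform: Kolmogorov-Smirnov sanity check
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("unreachable case counts error with advice", {
  panel <- snp_panel(snp_def("rsA", "G", "A>G"))
  cfg <- sim_config("causal", n_cases = 5000, n_controls = 10,
                    panel = panel, baseline_odds = 0.001,
                    max_pop_factor = 3,
                    snps = list(rsA = list(q = 0.3, or_het = 1,
                                           or_hom = 1)))
  expect_error(simulate_causal(cfg, seed = 1), "max_pop_factor")
})

test_that("cohort-level marginal draws match the counts-level fast path", {
  probs <- c(0.5, 0.4, 0.1)
  panel <- snp_panel(snp_def("rsA", "G", "A>G"))
  cfg <- sim_config("marginal", n_cases = 300, n_controls = 0, panel = panel,
                    snps = list(rsA = list(case_probs = probs,
                                           control_probs = probs)))
  coh <- t(vapply(1:150, function(r)
    tabulate_genotypes(simulate_marginal(cfg, seed = r),
                       "rsA")$counts["case", ], numeric(3)))
  fast <- simulate_null_counts(150, 300, 0, probs, seed = 99)$cases
  # same multinomial law: compare genotype-frequency means and spread
  expect_equal(unname(colMeans(coh) / 300), probs, tolerance = 0.05)
  expect_equal(unname(colMeans(fast) / 300), probs, tolerance = 0.05)
  expect_equal(unname(apply(coh, 2, sd)), unname(apply(fast, 2, sd)),
               tolerance = 0.35)
})

test_that("sim_config validates its inputs", {
  expect_error(sim_config("marginal",
                          snps = list(rs2294008 = list(
                            case_probs = c(0.6, 0.6, 0.1),
                            control_probs = c(0.5, 0.4, 0.1)))),
               "simplex")
  expect_error(sim_config("causal",
                          snps = list(rs2294008 = list(q = 2, or_het = 1,
                                                       or_hom = 1))),
               "q in \\[0,1\\]")
  expect_error(sim_config("marginal",
                          snps = list(rs_unknown = list())),
               "not declared")
})
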
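# printed crude ORs of the bundled study, frozen after verifying they
# reproduce from the count tables: (model, OR, L, U) per SNP
published_crude <- list(
  rs2294008 = list(het_vs_ref = c(1.31, 1.05, 1.62),  # upper bound: see note
                   dominant   = c(1.26, 1.03, 1.55)),
  rs2976392 = list(het_vs_ref = c(1.30, 1.05, 1.62),
                   dominant   = c(1.27, 1.03, 1.56)),
  rs2274223 = list(het_vs_ref = c(1.43, 1.14, 1.78),
                   dominant   = c(1.40, 1.13, 1.73)),
  rs4072037 = list(het_vs_ref = c(0.75, 0.58, 0.95),
                   # publication prints lower bound 0.62; the Woolf bound
                   # from its own counts is 0.6147 -> 0.61
                   dominant   = c(0.78, 0.61, 0.98)))

test_that("crude_or reproduces the published odds ratios at 2 decimals", {
  cnts <- gastric_genotype_counts()
  for (id in names(published_crude)) {
    for (m in names(published_crude[[id]])) {
      est <- crude_or(make_contrast(cnts[[id]], m))
      expect_equal(round(est$or_hat, 2), published_crude[[id]][[m]][1],
                   info = paste(id, m))
      expect_equal(round(est$ci_low, 2), published_crude[[id]][[m]][2],
                   info = paste(id, m))
      expect_equal(round(est$ci_high, 2), published_crude[[id]][[m]][3],
                   info = paste(id, m))
    }
  }
})

test_that("crude_or handles symmetry, zero cells and corrections", {
  est <- crude_or(two_by_two(10, 10, 10, 10))
  expect_equal(est$or_hat, 1)
  expect_equal(est$p, 1)
  expect_error(crude_or(two_by_two(0, 5, 5, 5)), "correction")
  est_c <- crude_or(two_by_two(0, 5, 5, 5), correction = TRUE)
  expect_equal(est_c$or_hat, (0.5 * 5.5) / (5.5 * 5.5))
  # Wald CI reconstruction invariant
  expect_equal(exp(log(est_c$or_hat) + qnorm(.975) * est_c$se_log),
               est_c$ci_high)
})

test_that("crude_or is antisymmetric under exposure swap (property)", {
  set.seed(7)
  for (i in 1:20) {
    x <- sample(1:200, 4)
    e1 <- crude_or(two_by_two(x[1], x[2], x[3], x[4]))
    e2 <- crude_or(two_by_two(x[2], x[1], x[4], x[3]))
    expect_equal(e2$or_hat, 1 / e1$or_hat)
    expect_equal(e2$ci_low, 1 / e1$ci_high)
    expect_equal(e2$p, e1$p)
  }
})

test_that("2-df genotype test reproduces published p-values", {
  cnts <- gastric_genotype_counts()
  expected <- c(rs2294008 = 0.048, rs2976392 = 0.058,
                rs2274223 = 0.007, rs4072037 = 0.055)
  for (id in names(expected)) {
    r <- genotype_distribution_test(cnts[[id]])
    expect_equal(r$df, 2L)
    expect_equal(round(r$p, 3), unname(expected[id]), info = id)
  }
})

test_that("Pearson tests agree with the stats::chisq.test oracle", {
  for (seed in 1:20) {
    cn <- random_genotype_counts(seed)
    mine <- genotype_distribution_test(cn)
    oracle <- suppressWarnings(stats::chisq.test(cn$counts, correct = FALSE))
    expect_equal(mine$chi2, unname(oracle$statistic))
    expect_equal(mine$p, oracle$p.value)
    t <- make_contrast(cn, "dominant")
    m2 <- matrix(c(t$a, t$c, t$b, t$d), 2)
    o2 <- suppressWarnings(stats::chisq.test(m2, correct = FALSE))
    expect_equal(chisq_2x2(t)$chi2, unname(o2$statistic))
  }
})

test_that("degenerate tables are handled", {
  cn <- genotype_counts("z", c(10, 20, 0), c(12, 18, 0))
  expect_warning(r <- genotype_distribution_test(cn), "dropping")
  expect_equal(r$df, 1L)
  w <- capture_warnings(r2 <- chisq_2x2(two_by_two(5, 0, 5, 0)))
  expect_match(w, "degenerate", all = FALSE)
  expect_equal(r2$p, 1)
  same <- genotype_counts("s", c(30, 20, 10), c(30, 20, 10))
  r3 <- genotype_distribution_test(same)
  expect_equal(r3$chi2, 0)
  expect_equal(r3$p, 1)
})

test_that("trend test matches the prop.trend.test oracle", {
  for (seed in 1:10) {
    cn <- random_genotype_counts(seed)
    mine <- trend_test(cn)
    oracle <- stats::prop.trend.test(cn$counts[1, ], colSums(cn$counts),
                                     score = 0:2)
    expect_equal(mine$chi2, unname(oracle$statistic))
    expect_equal(mine$p, oracle$p.value)
  }
})

test_that("one-predictor logistic equals the crude odds ratio", {
  co <- gastric_fixture_cohort()
  for (m in c("het_vs_ref", "dominant", "recessive")) {
    est <- fit_logistic(co, "rs2976392", m)
    crude <- crude_or(make_contrast(tabulate_genotypes(co, "rs2976392"), m))
    expect_equal(est$or_hat, crude$or_hat, tolerance = 1e-7)
    expect_equal(est$se_log, crude$se_log, tolerance = 1e-5)
  }
})

test_that("adjusted logistic recovers a confounded genotype effect", {
  # smoking doubles disease odds and shifts allele frequency -> crude is
  # biased away from the true conditional OR 1.5; adjustment removes it
  panel <- snp_panel(snp_def("rsC", "G", "C>T"))
  cov <- default_sim_covariates("causal")
  cov$pack_years_cat$or <- c(1, 2, 2)   # ever smoking doubles odds
  cfg <- sim_config("causal", n_cases = 4000, n_controls = 4000,
                    panel = panel,
                    snps = list(rsC = list(q = NA, or_het = 1.5,
                                           or_hom = 1.5,
                                           q_levels = c(none = 0.15,
                                                        le_mean = 0.45,
                                                        gt_mean = 0.45),
                                           confounder = "pack_years_cat")),
                    covariates = cov)
  sim <- simulate_causal(cfg, seed = 11)
  crude <- fit_logistic(sim$cohort, "rsC", "dominant")
  adj <- fit_logistic(sim$cohort, "rsC", "dominant", covariates = "smoking")
  expect_gt(crude$or_hat, adj$or_hat)   # confounding inflates the crude OR
  expect_gt(adj$ci_high, 1.5)
  expect_lt(adj$ci_low, 1.5)
})

test_that("separation and validation errors are raised", {
  panel <- tiny_panel()
  co <- make_cohort(panel, status = rep(c("case", "control"), each = 20),
                    genotypes = list(rs1 = rep(c("CT", "CC"), each = 20)))
  expect_error(fit_logistic(co, "rs1", "dominant"), "separation|converge")
  expect_error(fit_logistic(co, "rs1", "dominant", covariates = "height"),
               "unknown covariate")
  # constant covariate in the sample
  expect_error(fit_logistic(co, "rs1", "dominant", covariates = "sex"),
               "constant")
})

test_that("Wald and Pearson p agree closely on the study contrasts", {
  cnts <- gastric_genotype_counts()
  for (id in names(cnts)) {
    for (m in c("het_vs_ref", "dominant")) {
      t <- make_contrast(cnts[[id]], m)
      expect_equal(crude_or(t)$p, chisq_2x2(t)$p, tolerance = 0.03)
    }
  }
})
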
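test_that("subject TSV round-trips and genotypes are canonicalized", {
  panel <- tiny_panel()
  lines <- subject_tsv(list(subj_row("a1", "case", "CT"),
                            subj_row("a2", "control", "CC")))
  co <- read_subject_table(lines, panel)
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co$subjects), 2L)
  expect_equal(co$subjects$status, c("case", "control"))

  # reversed heterozygote is stored canonically
  co2 <- read_subject_table(
    subject_tsv(list(subj_row("a1", "case", "TC"))), panel)
  expect_equal(co2$subjects$rs1, "CT")

  # write -> read is the identity on canonical tables
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_subject_table(co, tmp)
  co3 <- read_subject_table(tmp, panel)
  expect_identical(co3$subjects, co$subjects)
})

test_that("malformed input is rejected with row context", {
  panel <- tiny_panel()
  expect_error(
    read_subject_table(subject_tsv(list(subj_row("a1", "case", "CA"))),
                       panel),
    "allele.*A|A.*allele")
  expect_error(
    read_subject_table(subject_tsv(list(subj_row("a1", "case", "CT"),
                                        subj_row("a1", "case", "TT"))),
                       panel),
    "duplicate subject_id 'a1' at row 2")
  expect_error(
    read_subject_table(c("subject_id\tstatus", "a\tcase"), panel),
    "missing column")
  # undeclared genotype column
  expect_error(
    read_subject_table(subject_tsv(list(c(subj_row("a1", "case", "CT"),
                                          "GG")),
                                   snp_ids = c("rs1", "rs_undeclared")),
      panel),
    "unknown column")
  # controls must not carry tumour site/stage
  expect_error(
    read_subject_table(subject_tsv(list(
      subj_row("a1", "control", "CT", site = "cardia"))), panel),
    "not_applicable")
})

test_that("tabulate_genotypes applies the complete-case rule", {
  panel <- tiny_panel()
  co <- make_cohort(panel,
                    status = c("case", "case", "case", "control", "control"),
                    genotypes = list(rs1 = c("CC", "CT", NA, "TT", "CC")))
  cn <- tabulate_genotypes(co, "rs1")
  expect_equal(unname(cn$counts["case", ]), c(1L, 1L, 0L))
  expect_equal(unname(cn$counts["control", ]), c(1L, 0L, 1L))
  expect_equal(cn$n_cases, 2L)  # missing genotype excluded from the margin
  expect_error(tabulate_genotypes(co, "nope"), "unknown snp_id")

  empty <- co
  empty$subjects <- co$subjects[0, , drop = FALSE]
  cn0 <- tabulate_genotypes(empty, "rs1")
  expect_equal(sum(cn0$counts), 0L)
})

test_that("tabulate_genotypes reproduces the bundled study margins", {
  co <- gastric_fixture_cohort()
  cnts <- gastric_genotype_counts()
  for (id in names(cnts))
    expect_equal(tabulate_genotypes(co, id)$counts, cnts[[id]]$counts)
})

test_that("counts_from_percentages resolves printed tables", {
  # the study's inconsistent printed case count (332) resolves to 322
  expect_equal(counts_from_percentages(692, c(46.53, 44.65, 8.82)),
               c(322L, 309L, 61L))
  expect_equal(counts_from_percentages(774, c(52.33, 38.37, 9.30)),
               c(405L, 297L, 72L))
  expect_equal(counts_from_percentages(100, c(50, 50, 0)), c(50L, 50L, 0L))
  expect_error(counts_from_percentages(100, c(49.4, 49.4, 0)),
               "candidate correction")
})

test_that("make_contrast builds the four genetic-model tables", {
  cnts <- gastric_genotype_counts()
  dom <- make_contrast(cnts$rs2274223, "dominant")
  expect_equal(c(dom$a, dom$b, dom$c, dom$d), c(287L, 405L, 260L, 514L))
  het <- make_contrast(cnts$rs2976392, "het_vs_ref")
  expect_equal(c(het$a, het$b, het$c, het$d), c(308L, 319L, 299L, 403L))
  rec <- make_contrast(cnts$rs2294008, "recessive")
  expect_equal(c(rec$a, rec$b, rec$c, rec$d), c(61L, 631L, 72L, 702L))
  zero <- make_contrast(genotype_counts("z", c(0, 0, 0), c(0, 0, 0)),
                        "dominant")
  expect_equal(c(zero$a, zero$b, zero$c, zero$d), rep(0L, 4))
})

test_that("contrast margins are conserved (property)", {
  for (seed in 1:25) {
    cn <- random_genotype_counts(seed)
    dom <- make_contrast(cn, "dominant")
    het <- make_contrast(cn, "het_vs_ref")
    rec <- make_contrast(cn, "recessive")
    expect_identical(dom$a + het$b, cn$n_cases)
    expect_identical(rec$a + rec$b, cn$n_cases)
    expect_identical(dom$c + dom$d, cn$n_controls)
  }
})

test_that("snp_def validates alleles and risk sets", {
  expect_error(snp_def("rs1", "G", "C>C"), "distinct")
  expect_error(snp_def("rs1", "G", "C>T", risk_genotypes = "AA"),
               "subset")
  d <- snp_def("rs9", "G", "G>A")
  expect_equal(genotype_labels(d), c("GG", "AG", "AA"))  # alphabetical het
  expect_equal(d$risk_genotypes, c("AG", "AA"))
})

test_that("SNP config JSON round-trips", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_snp_config(gastric_snp_panel(), tmp)
  panel <- read_snp_config(tmp)
  expect_equal(names(panel), names(gastric_snp_panel()))
  expect_equal(panel$rs4072037$risk_genotypes, "TT")
  expect_equal(panel$rs4072037$direction, "protective")
})
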
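# shared builders for small in-code fixtures

tiny_panel <- function() {
  snp_panel(snp_def("rs1", "GENE1", "C>T", risk_genotypes = c("CT", "TT")))
}

# minimal subject TSV lines for a given panel; genotypes as supplied
subject_tsv <- function(rows, snp_ids = "rs1") {
  header <- paste(c("subject_id", "status", "age", "sex", "smoking",
                    "pack_years_cat", "drinking", "bmi_cat", "site",
                    "stage", snp_ids), collapse = "\t")
  c(header, vapply(rows, paste, "", collapse = "\t"))
}

subj_row <- function(id, status, genotype,
                     site = if (status == "case") "non_cardia"
                            else "not_applicable",
                     stage = if (status == "case") "III_IV"
                             else "not_applicable") {
  c(id, status, "60", "male", "never", "none", "never", "normal",
    site, stage, genotype)
}

# a bare cohort with chosen genotype vectors per SNP (one covariate profile)
make_cohort <- function(panel, status, genotypes) {
  n <- length(status)
  df <- data.frame(
    subject_id = sprintf("s%04d", seq_len(n)), status = status,
    age = 60L, sex = "male", smoking = "never", pack_years_cat = "none",
    drinking = "never", bmi_cat = "normal",
    site = ifelse(status == "case", "non_cardia", "not_applicable"),
    stage = ifelse(status == "case", "III_IV", "not_applicable"),
    stringsAsFactors = FALSE)
  for (id in names(genotypes)) df[[id]] <- genotypes[[id]]
  cohort_table(df, panel)
}

random_genotype_counts <- function(seed) {
  set.seed(seed)
  genotype_counts("rsX", rmultinom(1, sample(50:300, 1), c(.5, .4, .1)),
                  rmultinom(1, sample(50:300, 1), c(.45, .45, .1)))
}
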
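#' Bundled gastric-cancer example data
#'
#' A published hospital-based case-control study of stomach cancer in a Han
#' Chinese population (692 cases, 774 controls, frequency matched on age and
#' sex) genotyped four GWAS-identified SNPs: *PSCA* rs2294008 C>T and
#' rs2976392 G>A, *PLCE1* rs2274223 A>G, and *MUC1* rs4072037 T>C. The
#' printed genotype count tables of that study are bundled here as example
#' data; they are the canonical worked example throughout this package.
#'
#' The study's printed rs2294008 case counts are internally inconsistent
#' (they sum to 702, not 692); the bundled counts use the
#' percentage-derived resolution 322/309/61, which reproduces the study's
#' own crude OR and confidence interval.
#'
#' For rs4072037 the *reference homozygote* TT is the risk genotype (the
#' variant C allele is protective), so its risk set is `"TT"` and its
#' direction is `"protective"`.
#'
#' @return `gastric_snp_panel()`: a [snp_panel] of the four SNPs.
#' @export
gastric_snp_panel <- function() {
  snp_panel(
    snp_def("rs2294008", "PSCA", "C>T",
            risk_genotypes = c("CT", "TT"), direction = "risk"),
    snp_def("rs2976392", "PSCA", "G>A",
            risk_genotypes = c("AG", "AA"), direction = "risk"),
    snp_def("rs2274223", "PLCE1", "A>G",
            risk_genotypes = c("AG", "GG"), direction = "risk"),
    snp_def("rs4072037", "MUC1", "T>C",
            risk_genotypes = "TT", direction = "protective"))
}

#' @rdname gastric_snp_panel
#' @return `gastric_genotype_counts()`: named list of [genotype_counts],
#'   one per SNP, counts in genotype order (ref hom, het, var hom).
#' @export
gastric_genotype_counts <- function() {
  panel <- gastric_snp_panel()
  lab <- function(id) genotype_labels(panel[[id]])
  list(
    rs2294008 = genotype_counts("rs2294008", c(322, 309, 61),
                                c(405, 297, 72), lab("rs2294008")),
    rs2976392 = genotype_counts("rs2976392", c(319, 308, 65),
                                c(403, 299, 72), lab("rs2976392")),
    rs2274223 = genotype_counts("rs2274223", c(405, 254, 33),
                                c(514, 226, 34), lab("rs2274223")),
    rs4072037 = genotype_counts("rs4072037", c(528, 143, 21),
                                c(553, 201, 20), lab("rs4072037")))
}

#' @rdname gastric_snp_panel
#' @return `gastric_risk_group_counts()`: the study's combined
#'   risk-genotype contrast (2-4 risk genotypes vs 0-1) as a [two_by_two].
#' @export
gastric_risk_group_counts <- function() {
  two_by_two(404, 288, 405, 369, exposed = "2-4", unexposed = "0-1")
}

#' @rdname gastric_snp_panel
#' @return `gastric_reported_power()`: the study's published statistical
#'   power values (power to detect OR 1.50 / 0.67 at its sample size) for
#'   the whole-cohort contrasts, named `<snp>.<model>`. The study's exact
#'   power recipe is not recoverable from the publication, so these are
#'   carried as reported inputs for FPRP reproduction, not recomputed.
#' @export
gastric_reported_power <- function() {
  c(rs2294008.het_vs_ref = 0.919, rs2294008.dominant = 0.951,
    rs2976392.het_vs_ref = 0.927, rs2976392.dominant = 0.943,
    rs2274223.het_vs_ref = 0.697, rs2274223.dominant = 0.739,
    rs4072037.het_vs_ref = 0.795, rs4072037.dominant = 0.881,
    combined.high_vs_low = 0.933)
}

#' Reconstruct a subject-level cohort matching the gastric study margins
#'
#' Builds a deterministic subject table whose per-SNP genotype margins equal
#' the bundled count tables exactly, whose combined risk-genotype split is
#' the published 288/404 (cases) and 369/405 (controls) low/high division,
#' and whose covariate margins match the study's characteristics table.
#' The joint distribution across SNPs and covariates is otherwise
#' artificial (constructed, not sampled), so only marginal/crude statistics
#' are meaningful on this fixture.
#'
#' @return A [cohort_table] of 692 cases and 774 controls.
#' @export
gastric_fixture_cohort <- function() {
  panel <- gastric_snp_panel()
  cnts <- gastric_genotype_counts()

  build_group <- function(n, low_n, high_n, carrier_counts, genos) {
    # risk-carrier indicator matrix with per-subject totals in {1} for the
    # low group and {2,3,4} for the high group, and per-SNP column sums
    # equal to the printed risk-carrier counts
    total <- sum(carrier_counts)
    high_sum <- total - low_n            # low subjects carry exactly 1
    base <- high_sum %/% high_n; extra <- high_sum %% high_n
    row_sums <- c(rep(1L, low_n),
                  rep(base + 1L, extra), rep(base, high_n - extra))
    stopifnot(sum(row_sums) == total, all(row_sums[-seq_len(low_n)] >= 2L),
              all(row_sums <= length(carrier_counts)))
    M <- realize_binary_matrix(row_sums, carrier_counts)
    # expand each SNP's carrier column into genotype labels
    out <- matrix(NA_character_, n, length(carrier_counts))
    for (j in seq_along(carrier_counts)) {
      gj <- genos[[j]]
      carriers <- which(M[, j] == 1L)
      non <- which(M[, j] == 0L)
      stopifnot(length(carriers) == sum(lengths2(gj$risk_n)),
                length(non) == sum(lengths2(gj$nonrisk_n)))
      out[carriers, j] <- rep(gj$risk_labels, gj$risk_n)
      out[non, j] <- rep(gj$nonrisk_labels, gj$nonrisk_n)
    }
    out
  }

  geno_spec <- function(id, group_row) {
    def <- panel[[id]]
    labs <- genotype_labels(def)
    cn <- cnts[[id]]$counts[group_row, ]
    risk <- labs %in% def$risk_genotypes
    list(risk_labels = labs[risk], risk_n = unname(cn[risk]),
         nonrisk_labels = labs[!risk], nonrisk_n = unname(cn[!risk]))
  }
  ids <- names(panel)
  case_spec <- lapply(ids, geno_spec, group_row = 1L)
  ctrl_spec <- lapply(ids, geno_spec, group_row = 2L)
  case_car <- vapply(case_spec, function(g) sum(g$risk_n), 0)
  ctrl_car <- vapply(ctrl_spec, function(g) sum(g$risk_n), 0)

  g_case <- build_group(692L, 288L, 404L, as.integer(case_car), case_spec)
  g_ctrl <- build_group(774L, 369L, 405L, as.integer(ctrl_car), ctrl_spec)

  cov_fill <- function(n, counts, levels, stride) {
    v <- rep(levels, counts)
    stopifnot(length(v) == n)
    # deterministic stride permutation decorrelates block assignment across
    # variables without randomness
    v[order((seq_len(n) * stride) %% n, seq_len(n))]
  }
  mk_subjects <- function(n, prefix, geno, spec) {
    df <- data.frame(
      subject_id = sprintf("%s%04d", prefix, seq_len(n)),
      status = if (prefix == "case") "case" else "control",
      age = cov_fill(n, spec$age_n, c(45L, 55L, 65L, 75L), 7L),
      sex = cov_fill(n, spec$sex_n, c("male", "female"), 11L),
      smoking = NA_character_, pack_years_cat = NA_character_,
      drinking = cov_fill(n, spec$drink_n, c("never", "ever"), 17L),
      bmi_cat = cov_fill(n, spec$bmi_n, c("under", "normal", "high"), 19L),
      site = cov_fill(n, spec$site_n,
                      c("cardia", "non_cardia", "not_applicable"), 23L),
      stage = cov_fill(n, spec$stage_n,
                       c("I_II", "III_IV", "not_applicable"), 29L),
      stringsAsFactors = FALSE)
    # pack-years nests within smoking: never smokers have pack_years none
    py <- cov_fill(n, spec$py_n, c("none", "le_mean", "gt_mean"), 13L)
    df$pack_years_cat <- py
    df$smoking <- ifelse(py == "none", "never", "ever")
    for (j in seq_along(ids)) df[[ids[j]]] <- geno[, j]
    df
  }
  cases <- mk_subjects(692L, "case", g_case, list(
    age_n = c(134L, 225L, 226L, 107L), sex_n = c(492L, 200L),
    py_n = c(427L, 133L, 132L), drink_n = c(539L, 153L),
    bmi_n = c(53L, 423L, 216L), site_n = c(199L, 493L, 0L),
    stage_n = c(274L, 418L, 0L)))
  controls <- mk_subjects(774L, "ctrl", g_ctrl, list(
    age_n = c(151L, 242L, 249L, 132L), sex_n = c(549L, 225L),
    py_n = c(362L, 250L, 162L), drink_n = c(542L, 232L),
    bmi_n = c(5L, 244L, 525L), site_n = c(0L, 0L, 774L),
    stage_n = c(0L, 0L, 774L)))
  cohort_table(rbind(cases, controls), panel)
}

lengths2 <- function(x) if (is.list(x)) lengths(x) else x

# Gale-Ryser style greedy realization of a 0/1 matrix with given row and
# column sums; errors if the margins are not realizable
realize_binary_matrix <- function(row_sums, col_sums) {
  n <- length(row_sums); k <- length(col_sums)
  stopifnot(sum(row_sums) == sum(col_sums), all(row_sums <= k))
  M <- matrix(0L, n, k)
  remaining <- as.integer(col_sums)
  for (i in order(row_sums, decreasing = TRUE)) {
    r <- row_sums[i]
    if (r == 0L) next
    pick <- order(remaining, decreasing = TRUE)[seq_len(r)]
    if (any(remaining[pick] <= 0L))
      stop("margins not realizable as a binary matrix", call. = FALSE)
    M[i, pick] <- 1L
    remaining[pick] <- remaining[pick] - 1L
  }
  stopifnot(all(remaining == 0L))
  M
}
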
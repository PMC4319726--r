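#' Combined risk-genotype profiles
#'
#' Counts, for every subject, how many panel SNPs carry a risk genotype
#' (each SNP's `risk_genotypes` set from its [snp_def]) and groups subjects
#' into carriers of few (`low`, below the threshold) versus many (`high`)
#' risk genotypes. Subjects missing any panel genotype are flagged
#' incomplete and carry `NA` group membership; they are excluded from the
#' group contrast.
#'
#' @param cohort a [cohort_table].
#' @param threshold minimum risk-genotype count for the `high` group;
#'   default 2 (the usual 0-1 vs 2+ split for a four-SNP panel).
#' @return Data frame: `subject_id`, `status`, `n_risk`, `n_typed`,
#'   `complete`, `group` (`"low"`/`"high"`, `NA` if incomplete).
#' @export
profile_subjects <- function(cohort, threshold = 2L) {
  stopifnot(inherits(cohort, "cohort_table"), threshold >= 1L)
  ids <- names(cohort$panel)
  s <- cohort$subjects
  risk_mat <- vapply(ids, function(id) {
    g <- s[[id]]
    ifelse(is.na(g), NA, g %in% cohort$panel[[id]]$risk_genotypes)
  }, logical(nrow(s)))
  risk_mat <- matrix(risk_mat, nrow = nrow(s))
  n_typed <- rowSums(!is.na(risk_mat))
  n_risk <- rowSums(risk_mat, na.rm = TRUE)
  complete <- n_typed == length(ids)
  group <- ifelse(complete, ifelse(n_risk >= threshold, "high", "low"), NA)
  data.frame(subject_id = s$subject_id, status = s$status,
             n_risk = as.integer(n_risk), n_typed = as.integer(n_typed),
             complete = complete, group = group, stringsAsFactors = FALSE)
}

#' Group contrast of combined risk genotypes
#'
#' 2x2 contrast of the `high` risk-genotype group against the `low` group
#' (complete profiles only) with its crude odds ratio.
#'
#' @inheritParams profile_subjects
#' @return List with `table` (a [two_by_two]) and `estimate` (an
#'   [effect_estimate]).
#' @export
risk_group_contrast <- function(cohort, threshold = 2L) {
  pr <- profile_subjects(cohort, threshold)
  pr <- pr[pr$complete, ]
  a <- sum(pr$status == "case" & pr$group == "high")
  b <- sum(pr$status == "case" & pr$group == "low")
  cc <- sum(pr$status == "control" & pr$group == "high")
  d <- sum(pr$status == "control" & pr$group == "low")
  k <- length(cohort$panel)
  t <- two_by_two(a, b, cc, d,
                  exposed = sprintf("%d-%d", threshold, k),
                  unexposed = sprintf("0-%d", threshold - 1L))
  list(table = t, estimate = crude_or(t))
}
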
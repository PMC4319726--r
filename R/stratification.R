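#' Stratum assignment for subgroup analysis
#'
#' Built-in stratifiers mirror the usual epidemiological subgroup set:
#' `age_median` (at/below vs above the cohort median age), `sex`,
#' `smoking`, `pack_years` (none / at-or-below mean / above mean),
#' `drinking`, `bmi`, `site` and `stage`. Tumour site and stage exist only
#' for cases, so those analyses are case-only strata each contrasted
#' against the full control group.
#'
#' @param cohort a [cohort_table].
#' @param by stratifier name.
#' @return Character vector of stratum labels per subject (`NA` excludes a
#'   subject from all strata). For `site`/`stage`, controls get the special
#'   label `".all_controls"` and join every stratum.
#' @export
stratum_assign <- function(cohort,
                           by = c("age_median", "sex", "smoking",
                                  "pack_years", "drinking", "bmi",
                                  "site", "stage")) {
  by <- match.arg(by)
  s <- cohort$subjects
  switch(by,
    age_median = {
      med <- stats::median(s$age)
      ifelse(s$age <= med, sprintf("age<=%d", med), sprintf("age>%d", med))
    },
    sex = s$sex,
    smoking = paste0("smoking_", s$smoking),
    pack_years = paste0("pack_years_", s$pack_years_cat),
    drinking = paste0("drinking_", s$drinking),
    bmi = paste0("bmi_", s$bmi_cat),
    site = ifelse(s$status == "control", ".all_controls",
                  ifelse(s$site == "not_applicable", NA, s$site)),
    stage = ifelse(s$status == "control", ".all_controls",
                   ifelse(s$stage == "not_applicable", NA, s$stage)))
}

#' Stratified genetic-model estimates
#'
#' Splits the cohort by a stratifier, tabulates the genetic-model 2x2 in
#' each stratum, and estimates the OR (crude, or covariate-adjusted via
#' logistic regression). The stratification variable is removed from the
#' adjustment set within its own strata; stratifying on smoking or
#' pack-years also drops the other of the two (they are nested).
#' Strata with a zero margin are omitted with a warning.
#'
#' @inheritParams stratum_assign
#' @param snp_id declared SNP, or `"risk_genotypes"` for the combined
#'   risk-genotype group contrast.
#' @param model genetic model (ignored for `"risk_genotypes"`).
#' @param covariates adjustment set; `NULL` or empty for crude estimates.
#' @param threshold risk-genotype threshold for `"risk_genotypes"`.
#' @return Object of class `stratified_result`: list with one element per
#'   stratum, each holding `stratum`, `table`, `estimate`.
#' @export
stratified_estimates <- function(cohort, snp_id, model = "dominant",
                                 by = "age_median", covariates = NULL,
                                 threshold = 2L) {
  stopifnot(inherits(cohort, "cohort_table"))
  lab <- stratum_assign(cohort, by)
  adj <- setdiff(covariates, strat_covariate(by))
  if (by %in% c("smoking", "pack_years"))
    adj <- setdiff(adj, c("smoking", "pack_years"))
  strata <- setdiff(sort(unique(lab[!is.na(lab)])), ".all_controls")
  out <- list()
  for (st in strata) {
    keep <- !is.na(lab) & (lab == st | lab == ".all_controls")
    sub <- cohort
    sub$subjects <- cohort$subjects[keep, , drop = FALSE]
    if (identical(snp_id, "risk_genotypes")) {
      rc <- try(risk_group_contrast(sub, threshold), silent = TRUE)
      if (inherits(rc, "try-error")) {
        warning("stratum ", st, " omitted: ", attr(rc, "condition")$message)
        next
      }
      t <- rc$table; est <- rc$estimate
    } else {
      t <- make_contrast(tabulate_genotypes(sub, snp_id), model)
      est <- try(if (length(adj)) fit_logistic(sub, snp_id, model, adj)
                 else crude_or(t), silent = TRUE)
      if (inherits(est, "try-error")) {
        warning("stratum ", st, " omitted: ",
                conditionMessage(attr(est, "condition")))
        next
      }
    }
    out[[st]] <- list(stratum = st, table = t, estimate = est)
  }
  structure(out, class = "stratified_result", by = by, snp_id = snp_id)
}

strat_covariate <- function(by) {
  switch(by, age_median = "age", sex = "sex", smoking = "smoking",
         pack_years = "pack_years", drinking = "drinking", bmi = "bmi",
         character(0))
}

#' @export
print.stratified_result <- function(x, ...) {
  cat(sprintf("<stratified_result> %s by %s\n",
              attr(x, "snp_id"), attr(x, "by")))
  for (e in x) {
    cat(sprintf("  %-16s", e$stratum)); print(e$estimate)
  }
  invisible(x)
}

#' Cochran Q heterogeneity test across stratum estimates
#'
#' Inverse-variance weighted heterogeneity of stratum log odds ratios:
#' `Q = sum w_i (ln OR_i - ln OR_w)^2` with `w_i = 1/se_i^2` and `OR_w`
#' the weighted mean; p from chi-square with `k - 1` df.
#'
#' @param estimates a `stratified_result` or a list of [effect_estimate]s.
#' @return Object of class `heterogeneity_result`: `Q`, `df`, `p`,
#'   `weights`.
#' @export
cochran_q <- function(estimates) {
  if (inherits(estimates, "stratified_result"))
    estimates <- lapply(estimates, `[[`, "estimate")
  ok <- vapply(estimates, function(e)
    inherits(e, "effect_estimate") && is.finite(e$se_log) && e$se_log > 0,
    TRUE)
  estimates <- estimates[ok]
  if (length(estimates) < 2L)
    stop("need at least 2 strata with finite standard errors", call. = FALSE)
  theta <- vapply(estimates, function(e) log(e$or_hat), 0)
  w <- vapply(estimates, function(e) 1 / e$se_log^2, 0)
  mw <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - mw)^2)
  df <- length(theta) - 1L
  structure(list(Q = Q, df = df,
                 p = stats::pchisq(Q, df, lower.tail = FALSE),
                 weights = w),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity_result> Q=%.4f df=%d p=%s\n",
              x$Q, x$df, format_p(x$p)))
  invisible(x)
}

#' Likelihood-ratio test for genotype x covariate interaction
#'
#' Compares adjusted logistic models with and without the product term(s)
#' between the genetic-model genotype indicator and one covariate; the df
#' equals the number of added product terms (1 for binary/continuous
#' covariates, 2 for the three-category ones).
#'
#' @inheritParams fit_logistic
#' @param covariate the interacting covariate (one of the adjustment
#'   covariate names).
#' @param covariates additional adjustment covariates (the interacting one
#'   is always included as a main effect).
#' @return List: `p`, `lrt` (deviance difference), `df`.
#' @export
interaction_lrt <- function(cohort, snp_id, model = "dominant", covariate,
                            covariates = character(0)) {
  stopifnot(inherits(cohort, "cohort_table"))
  def <- cohort$panel[[snp_id]]
  if (is.null(def)) stop_validation("unknown snp_id: ", snp_id)
  labs <- genotype_labels(def)
  s <- cohort$subjects
  g <- s[[snp_id]]
  keep <- !is.na(g)
  geno <- switch(model,
    het_vs_ref = { keep <- keep & g %in% labs[1:2]; g == labs[2] },
    hom_vs_ref = { keep <- keep & g %in% labs[c(1, 3)]; g == labs[3] },
    dominant   = g %in% labs[2:3],
    recessive  = g == labs[3],
    stop_validation("unknown model: ", model))
  enc <- function(v) switch(v,
    age = s$age,
    sex = as.numeric(s$sex == "male"),
    smoking = as.numeric(s$smoking == "ever"),
    drinking = as.numeric(s$drinking == "ever"),
    bmi = cbind(bmi_under = as.numeric(s$bmi_cat == "under"),
                bmi_high = as.numeric(s$bmi_cat == "high")),
    pack_years = cbind(py_le = as.numeric(s$pack_years_cat == "le_mean"),
                       py_gt = as.numeric(s$pack_years_cat == "gt_mean")),
    stop_validation("unknown covariate: ", v))
  Z <- enc(covariate)
  if (!is.matrix(Z)) Z <- matrix(Z, ncol = 1L, dimnames = list(NULL, covariate))
  df0 <- data.frame(y = s$status == "case", genotype = as.numeric(geno))
  df0 <- cbind(df0, as.data.frame(Z))
  for (v in setdiff(covariates, covariate)) {
    W <- enc(v)
    if (!is.matrix(W)) W <- matrix(W, ncol = 1L,
                                   dimnames = list(NULL, v))
    df0 <- cbind(df0, as.data.frame(W))
  }
  df0 <- df0[keep & stats::complete.cases(df0), , drop = FALSE]
  zc <- colnames(Z)
  const <- zc[vapply(df0[zc], function(v) length(unique(v)) < 2L, TRUE)]
  if (length(const) == length(zc))
    stop_validation("covariate '", covariate,
                    "' is constant in the analysis sample; interaction ",
                    "inestimable")
  for (v in zc) df0[[paste0("genotype_x_", v)]] <- df0$genotype * df0[[v]]
  int_terms <- paste0("genotype_x_", zc)
  f1 <- stats::as.formula(paste("y ~", paste(setdiff(names(df0), "y"),
                                             collapse = " + ")))
  f0 <- stats::as.formula(paste("y ~", paste(setdiff(names(df0),
                                                     c("y", int_terms)),
                                             collapse = " + ")))
  fit0 <- stats::glm(f0, data = df0, family = stats::binomial())
  fit1 <- stats::glm(f1, data = df0, family = stats::binomial())
  if (!fit0$converged || !fit1$converged)
    stop_validation("logistic model did not converge in interaction test")
  lrt <- fit0$deviance - fit1$deviance
  dfd <- fit0$df.residual - fit1$df.residual
  list(p = stats::pchisq(max(lrt, 0), dfd, lower.tail = FALSE),
       lrt = lrt, df = dfd)
}
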
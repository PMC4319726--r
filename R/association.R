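#' Odds-ratio effect estimate
#'
#' Container for an odds ratio with the standard error of its log, Wald
#' 95% confidence bounds, and two-sided p-value.
#'
#' @param label contrast description.
#' @param or_hat odds ratio point estimate.
#' @param se_log standard error of `ln(OR)`.
#' @param p two-sided p-value; computed from the Wald z if omitted.
#' @param conf_level confidence level for the bounds.
#' @param adjusted whether the estimate came from a covariate-adjusted fit.
#' @param covariates covariate names used in adjustment.
#' @param n_used number of subjects (complete cases) behind the estimate.
#' @param table optional [two_by_two] of origin (crude estimates).
#' @return Object of class `effect_estimate`.
#' @export
effect_estimate <- function(label, or_hat, se_log, p = NULL,
                            conf_level = 0.95, adjusted = FALSE,
                            covariates = character(0), n_used = NA_integer_,
                            table = NULL) {
  stopifnot(or_hat > 0, se_log >= 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- log(or_hat)
  if (is.null(p))
    p <- if (se_log == 0) 1 else 2 * stats::pnorm(-abs(lo / se_log))
  structure(list(label = label, or_hat = or_hat, se_log = se_log,
                 ci_low = exp(lo - z * se_log), ci_high = exp(lo + z * se_log),
                 conf_level = conf_level, p = p, adjusted = adjusted,
                 covariates = covariates, n_used = n_used, table = table),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s: OR %.2f (%.2f-%.2f), p %s%s\n",
              x$label, x$or_hat, x$ci_low, x$ci_high, format_p(x$p),
              if (x$adjusted)
                paste0(" [adjusted: ", paste(x$covariates, collapse = ","), "]")
              else " [crude]"))
  invisible(x)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' `OR = ad/bc`, `SE(ln OR) = sqrt(1/a + 1/b + 1/c + 1/d)` (Woolf), Wald
#' 95% CI `exp(ln OR +/- 1.96 SE)`, and two-sided Wald p from
#' `z = ln(OR)/SE`. No continuity correction by default: a zero cell is an
#' error advising the optional Haldane 0.5 correction.
#'
#' @param t a [two_by_two].
#' @param correction add 0.5 to every cell (Haldane-Anscombe); off by
#'   default.
#' @param conf_level confidence level.
#' @return An [effect_estimate].
#' @examples
#' crude_or(two_by_two(308, 319, 299, 403))  # OR 1.30 (1.05-1.62)
#' @export
crude_or <- function(t, correction = FALSE, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0) && !correction)
    stop("2x2 table has a zero cell; rerun with correction = TRUE to apply ",
         "the 0.5 continuity correction", call. = FALSE)
  x <- cells + if (correction) 0.5 else 0
  or_hat <- (x[1] * x[4]) / (x[2] * x[3])
  se_log <- sqrt(sum(1 / x))
  effect_estimate(paste(t$exposed, "vs", t$unexposed), or_hat, se_log,
                  conf_level = conf_level, adjusted = FALSE,
                  n_used = sum(cells), table = t)
}

#' Chi-square test of the genotype distribution (2 x 3)
#'
#' Pearson chi-square comparing the 3-genotype distribution between cases
#' and controls, df = 2, expected counts from the margins, no continuity
#' correction. A genotype absent from both groups is dropped with a warning
#' and the df reduced.
#'
#' @param counts a [genotype_counts].
#' @return Object of class `genotype_test_result`: `chi2`, `df`, `p`.
#' @export
genotype_distribution_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  pearson_chisq(counts$counts)
}

#' Chi-square test of a 2 x 2 contrast
#'
#' Pearson chi-square without continuity correction, df = 1. Degenerate
#' margins give `chi2 = 0`, `p = 1` with a warning.
#'
#' @param t a [two_by_two].
#' @return A `genotype_test_result`.
#' @export
chisq_2x2 <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- matrix(c(t$a, t$c, t$b, t$d), 2L, 2L)
  pearson_chisq(m)
}

pearson_chisq <- function(m) {
  if (sum(m) <= 0) stop("empty table", call. = FALSE)
  zero_col <- colSums(m) == 0
  if (any(zero_col)) {
    warning("dropping ", sum(zero_col),
            " category(ies) absent from both groups; df reduced")
    m <- m[, !zero_col, drop = FALSE]
  }
  if (ncol(m) < 2L || any(rowSums(m) == 0)) {
    warning("degenerate margins; returning chi2 = 0, p = 1")
    res <- list(chi2 = 0, df = max(ncol(m) - 1L, 1L), p = 1)
    return(structure(res, class = "genotype_test_result"))
  }
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2 <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "genotype_test_result")
}

#' @export
print.genotype_test_result <- function(x, ...) {
  cat(sprintf("<genotype_test_result> chi2=%.4f df=%d p=%s\n",
              x$chi2, x$df, format_p(x$p)))
  invisible(x)
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in case proportion across the three genotypes
#' with scores 0/1/2 (variant-allele dosage). Note: the "additive model" p
#' printed beside genotype rows in this field's tables is usually the 2-df
#' distribution test ([genotype_distribution_test()]), not this trend test.
#'
#' @param counts a [genotype_counts].
#' @return A `genotype_test_result` with df = 1.
#' @export
trend_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  m <- counts$counts
  s <- c(0, 1, 2)
  n <- sum(m); r <- sum(m[1, ]); cj <- colSums(m)
  num <- sum(s * (m[1, ] - r * cj / n))
  chi2 <- num^2 / (r * (n - r) / n^3 * (n * sum(s^2 * cj) - sum(s * cj)^2))
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, 1L, lower.tail = FALSE)),
            class = "genotype_test_result")
}

#' Covariate-adjusted logistic regression for a genotype contrast
#'
#' Maximum-likelihood logistic regression of case status on a genetic-model
#' genotype term plus encoded covariates, returning the Wald OR, CI and p
#' for the genotype term. Codominant contrasts (`het_vs_ref`,
#' `hom_vs_ref`) restrict to subjects with the two genotypes involved.
#'
#' Covariate encoding: `age` in years (continuous); `sex`, `smoking`,
#' `drinking` as binary indicators; `bmi` and `pack_years` as two
#' indicators for their three categories.
#'
#' @param cohort a [cohort_table].
#' @param snp_id declared SNP.
#' @param model genetic model, as in [make_contrast()].
#' @param covariates subset of `c("age", "sex", "bmi", "smoking",
#'   "drinking", "pack_years")`; empty for a crude (univariate) fit.
#' @return An [effect_estimate] for the genotype term.
#' @export
fit_logistic <- function(cohort, snp_id,
                         model = c("het_vs_ref", "hom_vs_ref",
                                   "dominant", "recessive"),
                         covariates = character(0)) {
  stopifnot(inherits(cohort, "cohort_table"))
  model <- match.arg(model)
  def <- cohort$panel[[snp_id]]
  if (is.null(def)) stop_validation("unknown snp_id: ", snp_id)
  known <- c("age", "sex", "bmi", "smoking", "drinking", "pack_years")
  bad <- setdiff(covariates, known)
  if (length(bad))
    stop_validation("unknown covariate(s): ", paste(bad, collapse = ", "))
  labs <- genotype_labels(def)
  s <- cohort$subjects
  g <- s[[snp_id]]
  keep <- !is.na(g)
  geno_term <- switch(model,
    het_vs_ref = { keep <- keep & g %in% labs[1:2]; g == labs[2] },
    hom_vs_ref = { keep <- keep & g %in% labs[c(1, 3)]; g == labs[3] },
    dominant   = g %in% labs[2:3],
    recessive  = g == labs[3])
  df <- data.frame(y = s$status == "case", genotype = as.numeric(geno_term))
  if ("age" %in% covariates) df$age <- s$age
  if ("sex" %in% covariates) df$sex_male <- as.numeric(s$sex == "male")
  if ("smoking" %in% covariates)
    df$smoking_ever <- as.numeric(s$smoking == "ever")
  if ("drinking" %in% covariates)
    df$drinking_ever <- as.numeric(s$drinking == "ever")
  if ("bmi" %in% covariates) {
    df$bmi_under <- as.numeric(s$bmi_cat == "under")
    df$bmi_high <- as.numeric(s$bmi_cat == "high")
  }
  if ("pack_years" %in% covariates) {
    df$py_le <- as.numeric(s$pack_years_cat == "le_mean")
    df$py_gt <- as.numeric(s$pack_years_cat == "gt_mean")
  }
  df <- df[keep & stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$y)) < 2L)
    stop_validation("need at least one case and one control after ",
                    "complete-case filtering")
  preds <- setdiff(names(df), "y")
  const <- preds[vapply(df[preds], function(v) length(unique(v)) < 2L, TRUE)]
  if (length(const))
    stop_validation("constant predictor(s) in fitting sample: ",
                    paste(const, collapse = ", "))
  X <- as.matrix(df[preds])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    drop_idx <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X) + 1L)] - 1L
    stop_validation("collinear predictor column(s): ",
                    paste(preds[drop_idx], collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!fit$converged || any(abs(co[-1L, "Estimate"]) > 15))
    stop_validation("logistic fit did not converge (possible separation in ",
                    "term: ",
                    rownames(co)[-1L][which.max(abs(co[-1L, "Estimate"]))],
                    ")")
  mu <- fit$fitted.values
  if (any(mu < 1e-10 | mu > 1 - 1e-10))
    stop_validation("perfect separation detected in logistic fit ",
                    "(fitted probabilities of 0 or 1); term: genotype model")
  b <- co["genotype", "Estimate"]; se <- co["genotype", "Std. Error"]
  contrast <- switch(model,
    het_vs_ref = paste(labs[2], "vs", labs[1]),
    hom_vs_ref = paste(labs[3], "vs", labs[1]),
    dominant = paste(paste(labs[2], labs[3], sep = "/"), "vs", labs[1]),
    recessive = paste(labs[3], "vs", paste(labs[1], labs[2], sep = "/")))
  effect_estimate(contrast, exp(b), se,
                  p = 2 * stats::pnorm(-abs(b / se)),
                  adjusted = length(covariates) > 0L,
                  covariates = covariates, n_used = nrow(df))
}

#' Association table across SNPs and genetic models
#'
#' Convenience wrapper producing one row per SNP x contrast with counts,
#' the crude OR/CI/p, the 2-df genotype-distribution p, and (optionally)
#' adjusted estimates.
#'
#' @param cohort a [cohort_table].
#' @param models contrasts to evaluate per SNP.
#' @param adjust covariates for an adjusted column; `NULL` for crude only.
#' @return Data frame, one row per SNP x contrast.
#' @export
association_table <- function(cohort,
                              models = c("het_vs_ref", "hom_vs_ref",
                                         "dominant"),
                              adjust = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  rows <- list()
  for (id in names(cohort$panel)) {
    cn <- tabulate_genotypes(cohort, id)
    p2df <- genotype_distribution_test(cn)$p
    for (m in models) {
      t <- make_contrast(cn, m)
      est <- crude_or(t)
      row <- data.frame(
        snp_id = id, model = m, contrast = est$label,
        a = t$a, b = t$b, c = t$c, d = t$d,
        or = est$or_hat, l95 = est$ci_low, u95 = est$ci_high, p = est$p,
        p_genotype_2df = p2df, p_chisq = chisq_2x2(t)$p,
        adjusted = FALSE, stringsAsFactors = FALSE)
      if (!is.null(adjust)) {
        aest <- fit_logistic(cohort, id, m, covariates = adjust)
        row$or_adj <- aest$or_hat
        row$l95_adj <- aest$ci_low
        row$u95_adj <- aest$ci_high
        row$p_adj <- aest$p
        row$adjusted <- TRUE
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

format_p <- function(p, digits = 3) {
  ifelse(p < 1e-4, "<0.0001", formatC(p, digits = digits, format = "f"))
}
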
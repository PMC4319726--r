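#' Variant-allele frequency from a genotype triple
#'
#' @param g integer triple `(ref hom, het, var hom)` or a
#'   [genotype_counts] (control row used).
#' @return Variant-allele frequency `q = (het + 2 var_hom) / (2 n)`.
#' @export
allele_frequency <- function(g) {
  g <- as_triple(g)
  n <- sum(g)
  if (n <= 0) stop("zero genotype total", call. = FALSE)
  unname((g[2L] + 2 * g[3L]) / (2 * n))
}

as_triple <- function(g, group = "control") {
  if (inherits(g, "genotype_counts")) g <- g$counts[group, ]
  g <- as.numeric(g)
  stopifnot(length(g) == 3L)
  if (any(g < 0)) stop("negative genotype counts", call. = FALSE)
  g
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Chi-square goodness-of-fit of observed genotype counts against the
#' Hardy-Weinberg expectation `n * (p^2, 2pq, q^2)` with the variant-allele
#' frequency `q` estimated from the data; 1 degree of freedom (3 cells,
#' minus 1, minus 1 estimated frequency), no continuity correction.
#' Conventionally applied to the control group of a case-control study as a
#' genotyping/population sanity check.
#'
#' Degenerate monomorphic input (`q` of 0 or 1) returns `chi2 = 0`,
#' `p = 1` by convention.
#'
#' @param g genotype triple `(ref hom, het, var hom)` or a
#'   [genotype_counts].
#' @param group when `g` is a [genotype_counts]: `"control"` (default) or
#'   `"case"`.
#' @return Object of class `hwe_result`: `snp_id`, `q`, `expected` (triple),
#'   `chi2`, `df`, `p`.
#' @examples
#' hwe_chisq(c(405, 297, 72))  # p ~ 0.105
#' @export
hwe_chisq <- function(g, group = c("control", "case")) {
  group <- match.arg(group)
  snp_id <- if (inherits(g, "genotype_counts")) g$snp_id else NA_character_
  g <- as_triple(g, group)
  n <- sum(g)
  if (n <= 0) stop("zero genotype total", call. = FALSE)
  q <- (g[2L] + 2 * g[3L]) / (2 * n)
  p_allele <- 1 - q
  expected <- n * c(p_allele^2, 2 * p_allele * q, q^2)
  if (q == 0 || q == 1) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- sum((g - expected)^2 / expected)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(snp_id = snp_id, q = q, expected = expected,
                 chi2 = chi2, df = 1L, p = p),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("<hwe_result> %s q=%.4f chi2=%.4f df=%d p=%.4g\n",
              if (is.na(x$snp_id)) "" else x$snp_id, x$q, x$chi2, x$df, x$p))
  invisible(x)
}

#' Exact Hardy-Weinberg test
#'
#' Conditional exact test on the heterozygote count given the minor-allele
#' count (Wigginton-style): the p-value sums the probabilities of all
#' heterozygote counts no more probable than the observed one. Offered as a
#' small-sample alternative; the chi-square form is the default used
#' elsewhere in this package.
#'
#' @inheritParams hwe_chisq
#' @return Two-sided exact p-value.
#' @export
hwe_exact <- function(g, group = c("control", "case")) {
  group <- match.arg(group)
  g <- as_triple(g, group)
  n <- sum(g)
  n_minor <- min(g[2L] + 2 * g[3L], g[2L] + 2 * g[1L])
  if (n == 0) stop("zero genotype total", call. = FALSE)
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | n, n_minor) up to a constant
  lp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lfactorial(h) - lfactorial(hom_min) - lfactorial(hom_maj)
  }, 0)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- which(hets == g[2L])
  if (!length(obs)) stop("heterozygote count inconsistent with allele count",
                         call. = FALSE)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' HWE tests across a cohort's SNP panel
#'
#' @param cohort a [cohort_table].
#' @param group subjects to test: `"controls"` (the standard choice),
#'   `"cases"`, or `"all"`.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return Data frame with one row per SNP: `snp_id`, `q`, `chi2`, `p`.
#' @export
hwe_table <- function(cohort, group = c("controls", "cases", "all"),
                      method = c("chisq", "exact")) {
  group <- match.arg(group); method <- match.arg(method)
  stopifnot(inherits(cohort, "cohort_table"))
  rows <- lapply(names(cohort$panel), function(id) {
    cn <- tabulate_genotypes(cohort, id)
    triple <- switch(group,
                     controls = cn$counts["control", ],
                     cases = cn$counts["case", ],
                     all = colSums(cn$counts))
    if (method == "chisq") {
      h <- hwe_chisq(triple)
      data.frame(snp_id = id, q = h$q, chi2 = h$chi2, p = h$p)
    } else {
      data.frame(snp_id = id, q = allele_frequency(triple), chi2 = NA_real_,
                 p = hwe_exact(triple))
    }
  })
  do.call(rbind, rows)
}
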
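#' Genotype count table for one SNP
#'
#' The 2 (case/control) x 3 (reference homozygote, heterozygote, variant
#' homozygote) count table that association tables print.
#'
#' @param snp_id SNP identifier.
#' @param cases,controls integer triples in genotype order (ref hom, het,
#'   var hom).
#' @param labels optional genotype labels, e.g. from [genotype_labels()].
#' @return Object of class `genotype_counts` with fields `snp_id`, `counts`
#'   (2x3 matrix), `n_cases`, `n_controls`.
#' @export
genotype_counts <- function(snp_id, cases, controls, labels = NULL) {
  cases <- as.integer(cases); controls <- as.integer(controls)
  stopifnot(length(cases) == 3L, length(controls) == 3L)
  if (any(c(cases, controls) < 0L))
    stop("genotype counts must be non-negative", call. = FALSE)
  m <- rbind(case = cases, control = controls)
  if (!is.null(labels)) colnames(m) <- labels
  else colnames(m) <- c("ref_hom", "het", "var_hom")
  structure(list(snp_id = snp_id, counts = m,
                 n_cases = sum(cases), n_controls = sum(controls)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> %s (cases N=%d, controls N=%d)\n",
              x$snp_id, x$n_cases, x$n_controls))
  print(x$counts)
  invisible(x)
}

#' A 2x2 exposure-disease table
#'
#' Cells follow the epidemiological convention: `a` exposed cases, `b`
#' unexposed cases, `c` exposed controls, `d` unexposed controls.
#'
#' @param a,b,c,d non-negative integer cells.
#' @param exposed,unexposed labels for the exposure categories.
#' @return Object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, exposed = "exposed",
                       unexposed = "unexposed") {
  cells <- as.integer(c(a, b, c, d))
  if (any(is.na(cells)) || any(cells < 0L))
    stop("2x2 cells must be non-negative integers", call. = FALSE)
  structure(list(a = cells[1L], b = cells[2L], c = cells[3L], d = cells[4L],
                 exposed = exposed, unexposed = unexposed),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("case", "control"),
                              c(x$exposed, x$unexposed)))
  cat("<two_by_two>\n"); print(m)
  invisible(x)
}

#' Tabulate genotype counts for one SNP in a cohort
#'
#' Complete-case tabulation: subjects missing this SNP's genotype are
#' excluded from both margins.
#'
#' @param cohort a [cohort_table].
#' @param snp_id declared SNP identifier.
#' @return A [genotype_counts].
#' @export
tabulate_genotypes <- function(cohort, snp_id) {
  stopifnot(inherits(cohort, "cohort_table"))
  def <- cohort$panel[[snp_id]]
  if (is.null(def))
    stop_validation("unknown snp_id: ", snp_id)
  labs <- genotype_labels(def)
  g <- cohort$subjects[[snp_id]]
  st <- cohort$subjects$status
  tab <- function(group) {
    v <- g[st == group & !is.na(g)]
    vapply(labs, function(l) sum(v == l), 0L)
  }
  genotype_counts(snp_id, tab("case"), tab("control"), labels = labs)
}

#' Resolve printed percentages into counts
#'
#' Published tables sometimes print counts inconsistent with their own
#' percentages and column totals; this reconstructs category counts as
#' `round(pct/100 * total)` and insists they add back up to the total.
#'
#' @param total positive integer column total.
#' @param percentages numeric vector of category percentages (summing to
#'   about 100).
#' @return Integer vector of counts summing to `total`.
#' @export
counts_from_percentages <- function(total, percentages) {
  stopifnot(length(total) == 1L, total > 0)
  cnt <- round(percentages / 100 * total)
  if (sum(cnt) != total) {
    resid <- percentages / 100 * total - cnt
    dir <- if (sum(cnt) < total) 1L else -1L
    k <- order(dir * resid, decreasing = TRUE)[seq_len(abs(total - sum(cnt)))]
    cand <- cnt; cand[k] <- cand[k] + dir
    stop("rounded counts (", paste(cnt, collapse = ", "), ") sum to ",
         sum(cnt), " != total ", total, "; candidate correction: (",
         paste(cand, collapse = ", "), ")", call. = FALSE)
  }
  as.integer(cnt)
}

#' Build a genetic-model 2x2 contrast from genotype counts
#'
#' `het_vs_ref` and `hom_vs_ref` drop the third genotype (codominant
#' contrasts); `dominant` pools heterozygote + variant homozygote as
#' exposed against the reference homozygote; `recessive` pools reference
#' homozygote + heterozygote as unexposed against the variant homozygote.
#'
#' @param counts a [genotype_counts].
#' @param model one of `"het_vs_ref"`, `"hom_vs_ref"`, `"dominant"`,
#'   `"recessive"`.
#' @return A [two_by_two].
#' @export
make_contrast <- function(counts,
                          model = c("het_vs_ref", "hom_vs_ref",
                                    "dominant", "recessive")) {
  stopifnot(inherits(counts, "genotype_counts"))
  model <- match.arg(model)
  m <- counts$counts
  labs <- colnames(m)
  switch(model,
    het_vs_ref = two_by_two(m[1, 2], m[1, 1], m[2, 2], m[2, 1],
                            exposed = labs[2], unexposed = labs[1]),
    hom_vs_ref = two_by_two(m[1, 3], m[1, 1], m[2, 3], m[2, 1],
                            exposed = labs[3], unexposed = labs[1]),
    dominant   = two_by_two(m[1, 2] + m[1, 3], m[1, 1],
                            m[2, 2] + m[2, 3], m[2, 1],
                            exposed = paste(labs[2], labs[3], sep = "/"),
                            unexposed = labs[1]),
    recessive  = two_by_two(m[1, 3], m[1, 1] + m[1, 2],
                            m[2, 3], m[2, 1] + m[2, 2],
                            exposed = labs[3],
                            unexposed = paste(labs[1], labs[2], sep = "/")))
}
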
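#' Subject-level case-control cohort
#'
#' A `cohort_table` couples a subject data frame (one row per participant)
#' with the [snp_panel] declaring the genotype columns. Fixed columns:
#' `subject_id`, `status` (case/control), `age` (years), `sex`
#' (male/female), `smoking` (never/ever), `pack_years_cat`
#' (none/le_mean/gt_mean), `drinking` (never/ever), `bmi_cat`
#' (under/normal/high; cut points 18.5 and 24.0 kg/m2), `site`
#' (cardia/non_cardia/not_applicable), `stage` (I_II/III_IV/not_applicable),
#' then one column per SNP holding a two-letter genotype or `NA`.
#'
#' @param subjects data frame with the columns above.
#' @param panel a [snp_panel].
#' @return An object of class `cohort_table` with elements `subjects` and
#'   `panel`.
#' @export
cohort_table <- function(subjects, panel) {
  stopifnot(is.data.frame(subjects), inherits(panel, "snp_panel"))
  fixed <- cohort_fixed_columns()
  miss <- setdiff(fixed, names(subjects))
  if (length(miss))
    stop_validation("subject table missing column(s): ",
                    paste(miss, collapse = ", "))
  extra <- setdiff(names(subjects), c(fixed, names(panel)))
  if (length(extra))
    stop_validation("unknown column(s) in subject table: ",
                    paste(extra, collapse = ", "),
                    " (genotype columns must be declared in the SNP panel)")
  gmiss <- setdiff(names(panel), names(subjects))
  if (length(gmiss))
    stop_validation("subject table lacks genotype column(s) for declared ",
                    "SNP(s): ", paste(gmiss, collapse = ", "))
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    dup <- subjects$subject_id[duplicated(subjects$subject_id)][1L]
    row <- which(subjects$subject_id == dup)[2L]
    stop_validation("duplicate subject_id '", dup, "' at row ", row)
  }
  check_levels <- function(col, levels, allow_na = FALSE) {
    v <- as.character(subjects[[col]])
    bad <- which(!(v %in% levels | (allow_na & is.na(v))))
    if (length(bad))
      stop_validation("invalid value '", v[bad[1L]], "' in column '", col,
                      "' at row ", bad[1L], "; expected one of: ",
                      paste(levels, collapse = ", "))
    v
  }
  subjects$status <- check_levels("status", c("case", "control"))
  subjects$sex <- check_levels("sex", c("male", "female"))
  subjects$smoking <- check_levels("smoking", c("never", "ever"))
  subjects$pack_years_cat <-
    check_levels("pack_years_cat", c("none", "le_mean", "gt_mean"))
  subjects$drinking <- check_levels("drinking", c("never", "ever"))
  subjects$bmi_cat <- check_levels("bmi_cat", c("under", "normal", "high"))
  subjects$site <-
    check_levels("site", c("cardia", "non_cardia", "not_applicable"))
  subjects$stage <-
    check_levels("stage", c("I_II", "III_IV", "not_applicable"))
  subjects$age <- as.integer(subjects$age)
  ctl <- subjects$status == "control"
  bad <- which(ctl & (subjects$site != "not_applicable" |
                        subjects$stage != "not_applicable"))
  if (length(bad))
    stop_validation("control at row ", bad[1L],
                    " must have site and stage 'not_applicable'")
  for (id in names(panel))
    subjects[[id]] <- canonicalize_genotypes(subjects[[id]], panel[[id]])
  structure(list(subjects = subjects, panel = panel), class = "cohort_table")
}

cohort_fixed_columns <- function() {
  c("subject_id", "status", "age", "sex", "smoking", "pack_years_cat",
    "drinking", "bmi_cat", "site", "stage")
}

#' @export
print.cohort_table <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("<cohort_table> %d subjects (%d cases / %d controls), %d SNPs\n",
              nrow(s), sum(s$status == "case"), sum(s$status == "control"),
              length(x$panel)))
  invisible(x)
}

# normalize genotype strings against a snp_def; NA passes through
canonicalize_genotypes <- function(g, def) {
  g <- as.character(g)
  out <- rep(NA_character_, length(g))
  ok <- !is.na(g) & g != "NA" & g != ""
  if (!any(ok)) return(out)
  gg <- g[ok]
  if (any(nchar(gg) != 2L)) {
    i <- which(ok)[which(nchar(gg) != 2L)[1L]]
    stop_validation("malformed genotype '", g[i], "' for ", def$snp_id,
                    " at row ", i)
  }
  a1 <- substr(gg, 1L, 1L); a2 <- substr(gg, 2L, 2L)
  valid <- c(def$allele_ref, def$allele_var)
  badal <- !(a1 %in% valid) | !(a2 %in% valid)
  if (any(badal)) {
    i <- which(ok)[which(badal)[1L]]
    off <- setdiff(unique(c(substr(g[i], 1, 1), substr(g[i], 2, 2))), valid)
    stop_validation("genotype '", g[i], "' for ", def$snp_id, " at row ", i,
                    " contains allele(s) not in {",
                    paste(valid, collapse = ","), "}: ",
                    paste(off, collapse = ","))
  }
  canon <- ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
  out[ok] <- canon
  out
}

#' Read a subject table from TSV
#'
#' Reads a tab-separated subject table (header row required, `NA` for
#' missing genotypes) and validates it against a SNP panel. Genotypes are
#' canonicalized to alphabetical allele order; malformed genotypes or
#' unknown alleles are hard errors naming the offending row.
#'
#' @param file path to a TSV file, or a character vector of lines.
#' @param panel a [snp_panel].
#' @return A [cohort_table].
#' @export
read_subject_table <- function(file, panel) {
  if (is.character(file) && length(file) > 1L)
    file <- textConnection(file)
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = "NA",
                          check.names = FALSE, quote = "")
  if (nrow(df) == 0L)
    stop_validation("subject table is empty")
  cohort_table(df, panel)
}

#' Write a cohort to TSV
#'
#' Inverse of [read_subject_table()]: writes the canonical-form subject
#' table with `NA` for missing genotypes.
#'
#' @param cohort a [cohort_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.table(cohort$subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
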
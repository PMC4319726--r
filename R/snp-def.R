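#' Define a SNP for case-control analysis
#'
#' A `snp_def` records a SNP's identity, its two alleles (written in the
#' usual `"C>T"` reference>variant notation), the reference genotype used as
#' baseline in genetic-model contrasts, the set of genotypes counted as
#' "risk" when profiling combined risk genotypes, and the direction of the
#' hypothesised allele effect (used to pick the target odds ratio in FPRP
#' power calculations).
#'
#' Genotype labels are canonicalized alphabetically (`"AG"`, never `"GA"`),
#' which matches how association tables in this field label heterozygotes
#' regardless of which allele is the reference.
#'
#' @param snp_id dbSNP-style identifier, e.g. `"rs2294008"`.
#' @param gene gene symbol label.
#' @param alleles two alleles as a `"C>T"`-style string, reference first.
#' @param risk_genotypes character vector of genotype labels counted as risk
#'   carriers; non-empty strict subset or full set of the three genotypes.
#'   Defaults to the two variant-carrying genotypes.
#' @param direction `"risk"` or `"protective"`; the assumed direction of the
#'   variant-allele effect.
#' @param reference_genotype baseline genotype; defaults to the reference
#'   homozygote.
#' @return An object of class `snp_def`.
#' @examples
#' snp_def("rs2294008", "PSCA", "C>T", risk_genotypes = c("CT", "TT"))
#' @export
snp_def <- function(snp_id, gene, alleles, risk_genotypes = NULL,
                    direction = c("risk", "protective"),
                    reference_genotype = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.character(snp_id), length(snp_id) == 1L, nzchar(snp_id))
  al <- strsplit(alleles, ">", fixed = TRUE)[[1L]]
  if (length(al) != 2L || any(nchar(al) != 1L) || al[1L] == al[2L])
    stop("alleles must be a \"C>T\"-style string of two distinct single ",
         "characters, got: ", alleles, call. = FALSE)
  ref <- al[1L]; var <- al[2L]
  labels <- c(
    ref_hom = paste0(ref, ref),
    het     = canonical_pair(ref, var),
    var_hom = paste0(var, var)
  )
  if (is.null(reference_genotype)) reference_genotype <- labels[["ref_hom"]]
  if (!reference_genotype %in% labels)
    stop("reference_genotype ", reference_genotype,
         " is not one of the possible genotypes: ",
         paste(labels, collapse = ", "), call. = FALSE)
  if (is.null(risk_genotypes))
    risk_genotypes <- unname(labels[c("het", "var_hom")])
  if (length(risk_genotypes) == 0L || !all(risk_genotypes %in% labels))
    stop("risk_genotypes must be a non-empty subset of {",
         paste(labels, collapse = ", "), "}", call. = FALSE)
  structure(
    list(snp_id = snp_id, gene = gene,
         allele_ref = ref, allele_var = var,
         genotypes = labels,
         reference_genotype = reference_genotype,
         risk_genotypes = unique(risk_genotypes),
         direction = direction),
    class = "snp_def")
}

canonical_pair <- function(a, b) paste(sort(c(a, b)), collapse = "")

#' @export
print.snp_def <- function(x, ...) {
  cat(sprintf("<snp_def> %s (%s) %s>%s  ref=%s  risk={%s}  %s\n",
              x$snp_id, x$gene, x$allele_ref, x$allele_var,
              x$reference_genotype,
              paste(x$risk_genotypes, collapse = ","), x$direction))
  invisible(x)
}

#' Ordered genotype labels of a SNP
#'
#' @param def a [snp_def].
#' @return Character vector `(reference homozygote, heterozygote, variant
#'   homozygote)`.
#' @export
genotype_labels <- function(def) {
  stopifnot(inherits(def, "snp_def"))
  unname(def$genotypes)
}

#' Assemble a SNP panel
#'
#' @param ... [snp_def] objects.
#' @return A named list of class `snp_panel`, keyed by `snp_id`.
#' @export
snp_panel <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && is.list(defs[[1L]]) &&
      !inherits(defs[[1L]], "snp_def")) defs <- defs[[1L]]
  if (!length(defs) || !all(vapply(defs, inherits, TRUE, "snp_def")))
    stop("snp_panel() takes one or more snp_def objects", call. = FALSE)
  ids <- vapply(defs, `[[`, "", "snp_id")
  if (anyDuplicated(ids))
    stop("duplicate snp_id in panel: ", ids[duplicated(ids)][1L], call. = FALSE)
  names(defs) <- ids
  structure(defs, class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> of", length(x), "SNPs\n")
  for (d in x) print(d)
  invisible(x)
}

#' Read or write a SNP panel configuration file
#'
#' The configuration is a JSON array with one object per SNP holding
#' `id`, `gene`, `alleles` (`"C>T"` style), `reference_genotype`,
#' `risk_genotypes` and `direction`.
#'
#' @param path file path.
#' @return `read_snp_config()` returns a [snp_panel];
#'   `write_snp_config()` returns `path` invisibly.
#' @export
read_snp_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  defs <- lapply(cfg, function(x) {
    need <- c("id", "gene", "alleles")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop_validation("SNP config entry missing field(s): ",
                      paste(miss, collapse = ", "))
    snp_def(x$id, x$gene, x$alleles,
            risk_genotypes = if (!is.null(x$risk_genotypes))
              unlist(x$risk_genotypes),
            direction = if (!is.null(x$direction)) x$direction else "risk",
            reference_genotype = x$reference_genotype)
  })
  snp_panel(defs)
}

#' @rdname read_snp_config
#' @param panel a [snp_panel] to serialize.
#' @export
write_snp_config <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  cfg <- lapply(panel, function(d) list(
    id = d$snp_id, gene = d$gene,
    alleles = paste0(d$allele_ref, ">", d$allele_var),
    reference_genotype = d$reference_genotype,
    risk_genotypes = d$risk_genotypes,
    direction = d$direction))
  jsonlite::write_json(unname(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# condition helpers: validation errors carry their own class so the CLI can
# map them to exit code 2
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("snpcc_validation_error",
                                             "error", "condition")))
}
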
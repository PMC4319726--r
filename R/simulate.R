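#' Simulation configuration for synthetic case-control cohorts
#'
#' Two generating modes:
#' * `marginal` — each group's genotype and covariate distributions are
#'   specified directly and sampled (or, with `exact = TRUE`, reproduced
#'   deterministically by largest-remainder rounding). This regenerates
#'   published table margins without any causal claim.
#' * `causal` — population individuals carry HWE(`q`) genotypes and
#'   covariates at stated prevalences; disease status follows a logistic
#'   model with per-genotype odds ratios (`or_het`, `or_hom` relative to
#'   the reference homozygote) and per-covariate-level odds ratios; cases
#'   and controls are then sampled to the requested sizes. The true
#'   parameters are emitted alongside so estimator recovery can be tested.
#'
#' Defaults are the bundled gastric study's world: 692 cases, 774
#' controls, its four SNPs with control-derived allele frequencies and
#' crude genotype ORs, and its characteristics-table covariate margins
#' (including the study's visible case-control imbalance in smoking,
#' drinking and BMI).
#'
#' @param mode `"marginal"` or `"causal"`.
#' @param n_cases,n_controls target group sizes.
#' @param snps named per-SNP list; marginal mode needs `case_probs` and
#'   `control_probs` (genotype triples), causal mode needs `q`, `or_het`,
#'   `or_hom`, optionally `q_levels` + `confounder` (allele frequency per
#'   level of one covariate, making that covariate a genuine confounder).
#' @param covariates named per-variable list with `levels`, and either
#'   `case_probs`/`control_probs` (marginal) or `pop_probs` + `or`
#'   (causal; `or` has one value per level, reference level 1).
#' @param panel [snp_panel] declaring the SNPs; defaults to the gastric
#'   panel when `snps` is left at its default.
#' @param baseline_odds causal mode: disease odds for the reference
#'   profile; default 0.08 (roughly a 7% baseline risk).
#' @param copy_pairs optional list of `list(from=, to=, rho=)` entries:
#'   SNP `to` copies SNP `from`'s genotype index with probability `rho`
#'   (a crude stand-in for tight linkage disequilibrium).
#' @param max_pop_factor causal mode: give up after drawing
#'   `max_pop_factor * (n_cases + n_controls)` population individuals.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(mode = c("marginal", "causal"),
                       n_cases = 692L, n_controls = 774L,
                       snps = NULL, covariates = NULL, panel = NULL,
                       baseline_odds = 0.08, copy_pairs = list(),
                       max_pop_factor = 200) {
  mode <- match.arg(mode)
  if (is.null(panel)) panel <- gastric_snp_panel()
  if (is.null(snps)) snps <- default_sim_snps(mode, panel)
  if (is.null(covariates)) covariates <- default_sim_covariates(mode)
  stopifnot(n_cases >= 0, n_controls >= 0, baseline_odds > 0)
  bad <- setdiff(names(snps), names(panel))
  if (length(bad))
    stop_validation("snps not declared in panel: ", paste(bad, collapse = ", "))
  for (id in names(snps)) {
    sp <- snps[[id]]
    if (mode == "marginal") {
      if (is.null(sp$case_probs) || is.null(sp$control_probs))
        stop_validation("marginal mode needs case_probs/control_probs for ", id)
      for (p in list(sp$case_probs, sp$control_probs))
        if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
          stop_validation("genotype probabilities for ", id,
                          " must be a length-3 simplex")
    } else {
      if (!is.null(sp$q_levels)) {
        if (is.null(sp$confounder) || !sp$confounder %in% names(covariates))
          stop_validation("q_levels for ", id,
                          " needs a declared confounder covariate")
        if (any(is.na(sp$q_levels)) || any(sp$q_levels < 0 | sp$q_levels > 1))
          stop_validation("q_levels for ", id, " must lie in [0,1]")
      } else if (is.null(sp$q) || is.na(sp$q) || sp$q < 0 || sp$q > 1)
        stop_validation("causal mode needs q in [0,1] for ", id)
      if (is.null(sp$or_het) || is.null(sp$or_hom) ||
          sp$or_het <= 0 || sp$or_hom <= 0)
        stop_validation("causal mode needs positive or_het/or_hom for ", id)
    }
  }
  structure(list(mode = mode, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), snps = snps,
                 covariates = covariates, panel = panel,
                 baseline_odds = baseline_odds, copy_pairs = copy_pairs,
                 max_pop_factor = max_pop_factor),
            class = "sim_config")
}

default_sim_snps <- function(mode, panel) {
  cnts <- gastric_genotype_counts()
  ids <- intersect(names(panel), names(cnts))
  # crude codominant ORs of the bundled study, used as the causal world's
  # genotype effects
  ors <- list(rs2294008 = c(1.31, 1.07), rs2976392 = c(1.30, 1.14),
              rs2274223 = c(1.43, 1.23), rs4072037 = c(0.75, 1.10))
  out <- lapply(ids, function(id) {
    cn <- cnts[[id]]$counts
    if (mode == "marginal")
      list(case_probs = unname(cn[1, ] / sum(cn[1, ])),
           control_probs = unname(cn[2, ] / sum(cn[2, ])))
    else
      list(q = allele_frequency(cn[2, ]),
           or_het = ors[[id]][1], or_hom = ors[[id]][2])
  })
  names(out) <- ids
  out
}

default_sim_covariates <- function(mode) {
  tab <- list(
    age = list(levels = c(45L, 55L, 65L, 75L),
               case_probs = c(134, 225, 226, 107) / 692,
               control_probs = c(151, 242, 249, 132) / 774),
    sex = list(levels = c("male", "female"),
               case_probs = c(492, 200) / 692,
               control_probs = c(549, 225) / 774),
    pack_years_cat = list(levels = c("none", "le_mean", "gt_mean"),
                          case_probs = c(427, 133, 132) / 692,
                          control_probs = c(362, 250, 162) / 774),
    drinking = list(levels = c("never", "ever"),
                    case_probs = c(539, 153) / 692,
                    control_probs = c(542, 232) / 774),
    bmi_cat = list(levels = c("under", "normal", "high"),
                   case_probs = c(53, 423, 216) / 692,
                   control_probs = c(5, 244, 525) / 774),
    site = list(levels = c("cardia", "non_cardia"),
                case_probs = c(199, 493) / 692),
    stage = list(levels = c("I_II", "III_IV"),
                 case_probs = c(274, 418) / 692))
  if (mode == "causal") {
    # population taken as the control world; covariate effects neutral by
    # default — confounding is injected explicitly via q_levels/or
    for (v in names(tab)) {
      if (v %in% c("site", "stage")) next
      tab[[v]]$pop_probs <- tab[[v]]$control_probs
      tab[[v]]$or <- rep(1, length(tab[[v]]$levels))
    }
  }
  tab
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# largest-remainder apportionment of n into round(p*n) with exact total
apportion <- function(n, probs) {
  x <- floor(probs * n)
  rem <- probs * n - x
  k <- n - sum(x)
  if (k > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(k)]
    x[idx] <- x[idx] + 1
  }
  as.integer(x)
}

# deterministic stride permutation (coprime stride) for exact-mode layout
stride_perm <- function(n, stride) order((seq_len(n) * stride) %% n,
                                         seq_len(n))

draw_categories <- function(n, levels, probs, exact, stride = 7L) {
  if (n == 0L) return(levels[0])
  if (exact) {
    v <- rep(levels, apportion(n, probs))
    v[stride_perm(n, stride)]
  } else {
    levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
  }
}

#' Simulate a cohort from group-wise marginal distributions
#'
#' Samples each subject's genotypes and covariates independently from the
#' group-specific distributions of the configuration. With `exact = TRUE`
#' the draw is replaced by deterministic largest-remainder rounding, so
#' the realized per-variable margins equal the target counts exactly (the
#' joint distribution is then a deterministic interleaving).
#'
#' @param cfg a [sim_config] with `mode = "marginal"`.
#' @param seed integer seed; the (seed, config) pair fully determines the
#'   output.
#' @param exact deterministic margin-exact mode.
#' @return A [cohort_table].
#' @export
simulate_marginal <- function(cfg, seed = 1L, exact = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mode != "marginal")
    stop_validation("simulate_marginal needs a marginal-mode config")
  with_seed(seed, {
    groups <- list(case = cfg$n_cases, control = cfg$n_controls)
    parts <- lapply(names(groups), function(grp) {
      n <- groups[[grp]]
      if (n == 0L) return(NULL)
      df <- data.frame(
        subject_id = sprintf("%s%05d", if (grp == "case") "case" else "ctrl",
                             seq_len(n)),
        status = grp, stringsAsFactors = FALSE)
      stride <- 5L
      pick <- function(v) {
        p <- if (grp == "case") v$case_probs else v$control_probs
        stride <<- stride + 2L
        draw_categories(n, v$levels, p, exact, stride)
      }
      cv <- cfg$covariates
      df$age <- as.integer(pick(cv$age))
      df$sex <- pick(cv$sex)
      df$pack_years_cat <- pick(cv$pack_years_cat)
      df$smoking <- ifelse(df$pack_years_cat == "none", "never", "ever")
      df$drinking <- pick(cv$drinking)
      df$bmi_cat <- pick(cv$bmi_cat)
      df$site <- if (grp == "case") pick(cv$site) else "not_applicable"
      df$stage <- if (grp == "case") pick(cv$stage) else "not_applicable"
      gidx <- list()
      for (id in names(cfg$snps)) {
        p <- if (grp == "case") cfg$snps[[id]]$case_probs
             else cfg$snps[[id]]$control_probs
        stride <- stride + 2L
        gidx[[id]] <- as.integer(draw_categories(n, 1:3, p, exact, stride))
      }
      gidx <- apply_copy_pairs(gidx, cfg$copy_pairs, n)
      for (id in names(gidx))
        df[[id]] <- genotype_labels(cfg$panel[[id]])[gidx[[id]]]
      df
    })
    subjects <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
    if (is.null(subjects))
      stop_validation("empty simulation: both group sizes are zero")
    cohort_table(subjects, cfg$panel)
  })
}

apply_copy_pairs <- function(gidx, pairs, n) {
  for (cp in pairs) {
    stopifnot(!is.null(gidx[[cp$from]]), !is.null(gidx[[cp$to]]),
              cp$rho >= 0, cp$rho <= 1)
    copy <- stats::runif(n) < cp$rho
    gidx[[cp$to]][copy] <- gidx[[cp$from]][copy]
  }
  gidx
}

hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Simulate a cohort from a causal disease model
#'
#' Draws population individuals (HWE genotypes, independent covariates),
#' assigns disease by the logistic model, and accumulates cases and
#' controls until the requested sizes are met. Returns the cohort together
#' with the generating truth, so that estimator recovery (crude and
#' adjusted ORs, interaction tests) can be benchmarked against known
#' parameters.
#'
#' @param cfg a [sim_config] with `mode = "causal"`.
#' @param seed integer seed.
#' @return List with elements `cohort` (a [cohort_table]) and `truth`
#'   (the generating parameters: `baseline_odds`, per-SNP `q`/ORs,
#'   covariate prevalences and ORs).
#' @export
simulate_causal <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mode != "causal")
    stop_validation("simulate_causal needs a causal-mode config")
  with_seed(seed, {
    need_cases <- cfg$n_cases; need_controls <- cfg$n_controls
    cases <- list(); controls <- list()
    drawn <- 0L
    cap <- cfg$max_pop_factor * (need_cases + need_controls)
    batch <- max(1000L, 2L * (need_cases + need_controls))
    got_cases <- 0L; got_controls <- 0L
    while (got_cases < need_cases || got_controls < need_controls) {
      if (drawn >= cap)
        stop("exceeded population cap of ", cap, " individuals before ",
             "reaching the requested case count; the disease is too rare ",
             "for this cap — raise max_pop_factor", call. = FALSE)
      b <- min(batch, cap - drawn)
      pop <- draw_population(cfg, b)
      drawn <- drawn + b
      is_case <- pop$disease
      if (got_cases < need_cases) {
        take <- which(is_case)[seq_len(min(need_cases - got_cases,
                                           sum(is_case)))]
        if (length(take)) {
          cases[[length(cases) + 1L]] <- pop$df[take, , drop = FALSE]
          got_cases <- got_cases + length(take)
        }
      }
      if (got_controls < need_controls) {
        take <- which(!is_case)[seq_len(min(need_controls - got_controls,
                                            sum(!is_case)))]
        if (length(take)) {
          controls[[length(controls) + 1L]] <- pop$df[take, , drop = FALSE]
          got_controls <- got_controls + length(take)
        }
      }
    }
    df <- rbind(do.call(rbind, cases), do.call(rbind, controls))
    df$status <- rep(c("case", "control"), c(need_cases, need_controls))
    df$site <- ifelse(df$status == "case", "non_cardia", "not_applicable")
    df$stage <- ifelse(df$status == "case", "III_IV", "not_applicable")
    df$subject_id <- sprintf("sim%06d", seq_len(nrow(df)))
    cohort <- cohort_table(df[, c(cohort_fixed_columns(),
                                  names(cfg$snps))], cfg$panel)
    truth <- list(mode = "causal", baseline_odds = cfg$baseline_odds,
                  snps = cfg$snps, covariates = cfg$covariates,
                  copy_pairs = cfg$copy_pairs)
    list(cohort = cohort, truth = truth)
  })
}

# one population batch: covariates, genotypes, disease indicator
draw_population <- function(cfg, n) {
  cv <- cfg$covariates
  draw <- function(v) v$levels[sample.int(length(v$levels), n, TRUE,
                                          prob = v$pop_probs)]
  df <- data.frame(subject_id = "tmp", status = "control",
                   age = as.integer(draw(cv$age)),
                   sex = draw(cv$sex),
                   smoking = NA_character_,
                   pack_years_cat = draw(cv$pack_years_cat),
                   drinking = draw(cv$drinking),
                   bmi_cat = draw(cv$bmi_cat),
                   site = "not_applicable", stage = "not_applicable",
                   stringsAsFactors = FALSE)
  df$smoking <- ifelse(df$pack_years_cat == "none", "never", "ever")
  eta <- rep(log(cfg$baseline_odds), n)
  for (v in names(cv)) {
    sp <- cv[[v]]
    if (is.null(sp$or)) next
    lev <- df[[v]]
    eta <- eta + log(sp$or)[match(lev, sp$levels)]
  }
  gidx <- list()
  for (id in names(cfg$snps)) {
    sp <- cfg$snps[[id]]
    if (!is.null(sp$q_levels)) {
      lev <- df[[sp$confounder]]
      qv <- sp$q_levels[match(lev, names(sp$q_levels))]
      u1 <- stats::runif(n) < qv; u2 <- stats::runif(n) < qv
      gidx[[id]] <- 1L + as.integer(u1) + as.integer(u2)
    } else {
      gidx[[id]] <- sample.int(3L, n, TRUE, prob = hwe_probs(sp$q))
    }
  }
  gidx <- apply_copy_pairs(gidx, cfg$copy_pairs, n)
  for (id in names(gidx)) {
    sp <- cfg$snps[[id]]
    eta <- eta + c(0, log(sp$or_het), log(sp$or_hom))[gidx[[id]]]
    df[[id]] <- genotype_labels(cfg$panel[[id]])[gidx[[id]]]
  }
  list(df = df, disease = stats::runif(n) < stats::plogis(eta))
}

#' Analytic case genotype distribution under a causal truth
#'
#' For a causal simulation truth, computes the exact marginal genotype
#' distribution among cases for one SNP by enumerating covariate
#' combinations: `P(g | case) ~ P(g) E_x[ P(D | g, x) ]`. Used to check
#' that simulated case margins agree with the generating model.
#'
#' @param truth the `truth` element returned by [simulate_causal()].
#' @param snp_id SNP of interest.
#' @return Genotype probability triple among cases.
#' @export
case_genotype_probs <- function(truth, snp_id) {
  sp <- truth$snps[[snp_id]]
  cov_or <- 1
  # enumerate covariate levels with non-neutral odds ratios
  active <- Filter(function(v) !is.null(v$or) && any(v$or != 1),
                   truth$covariates)
  enum <- data.frame(w = 1, or = 1)
  for (v in active)
    enum <- do.call(rbind, lapply(seq_along(v$levels), function(i)
      transform(enum, w = w * v$pop_probs[i], or = or * v$or[i])))
  gp <- if (!is.null(sp$q_levels)) {
    stop("case_genotype_probs does not support q_levels confounding",
         call. = FALSE)
  } else hwe_probs(sp$q)
  # other SNPs' effects act as an independent multiplicative frailty on the
  # odds; enumerate them too (small: 3^k combos)
  others <- truth$snps[names(truth$snps) != snp_id]
  ofr <- data.frame(w = 1, or = 1)
  for (o in others) {
    op <- hwe_probs(o$q); oo <- c(1, o$or_het, o$or_hom)
    ofr <- do.call(rbind, lapply(1:3, function(i)
      transform(ofr, w = w * op[i], or = or * oo[i])))
  }
  gor <- c(1, sp$or_het, sp$or_hom)
  pd <- vapply(1:3, function(g) {
    mix <- 0
    for (i in seq_len(nrow(enum)))
      for (j in seq_len(nrow(ofr)))
        mix <- mix + enum$w[i] * ofr$w[j] *
          stats::plogis(log(truth$baseline_odds * enum$or[i] *
                              ofr$or[j] * gor[g]))
    mix
  }, 0)
  w <- gp * pd
  w / sum(w)
}

#' Fast multinomial genotype-count replicates
#'
#' Counts-level fast path of the marginal generator for calibration
#' studies: per replicate, case and control genotype counts are drawn as
#' independent multinomials — exactly the sampling distribution the
#' subject-level marginal simulator induces per SNP — without building
#' subject tables.
#'
#' @param n_reps number of replicates.
#' @param n_cases,n_controls group sizes.
#' @param case_probs,control_probs genotype probability triples.
#' @param seed integer seed.
#' @return List of two `n_reps x 3` integer matrices, `cases` and
#'   `controls`.
#' @export
simulate_null_counts <- function(n_reps, n_cases, n_controls,
                                 case_probs, control_probs = case_probs,
                                 seed = 1L) {
  with_seed(seed, list(
    cases = t(stats::rmultinom(n_reps, n_cases, case_probs)),
    controls = t(stats::rmultinom(n_reps, n_controls, control_probs))))
}
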
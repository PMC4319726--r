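#' FPRP analysis configuration
#'
#' Defaults follow the convention of candidate-gene association studies:
#' a prior-probability grid from 0.25 down to 0.0001, a noteworthiness
#' cutoff of FPRP < 0.2 at the headline prior 0.1, and a target OR of 1.50
#' for risk alleles (0.67 for protective alleles).
#'
#' @param priors strictly decreasing prior probabilities in (0,1).
#' @param threshold FPRP noteworthiness cutoff.
#' @param headline_prior the prior at which noteworthiness is declared.
#' @param or1_risk,or1_protective target ORs for power, by effect direction.
#' @param power_alpha two-sided significance level used in the power
#'   column.
#' @param se_source where to take the log-OR standard error from:
#'   `"ci"` (reconstructed from the confidence bounds, usable when only
#'   OR + CI are published) or `"counts"` (Woolf SE from the 2x2 cells).
#' @return Object of class `fprp_config`.
#' @export
fprp_config <- function(priors = c(0.25, 0.1, 0.01, 0.001, 0.0001),
                        threshold = 0.2, headline_prior = 0.1,
                        or1_risk = 1.50, or1_protective = 0.67,
                        power_alpha = 0.05,
                        se_source = c("ci", "counts")) {
  se_source <- match.arg(se_source)
  stopifnot(all(priors > 0 & priors < 1), !is.unsorted(rev(priors),
                                                       strictly = TRUE),
            threshold > 0, threshold < 1,
            headline_prior %in% priors,
            or1_risk > 1, or1_protective < 1, or1_protective > 0,
            power_alpha > 0, power_alpha < 1)
  structure(list(priors = priors, threshold = threshold,
                 headline_prior = headline_prior, or1_risk = or1_risk,
                 or1_protective = or1_protective, power_alpha = power_alpha,
                 se_source = se_source),
            class = "fprp_config")
}

#' Log-OR standard error from a reported confidence interval
#'
#' `se = (ln U - ln L) / (2 z)`, `z` the normal 97.5% quantile for the
#' usual 95% interval — the standard reconstruction when a publication
#' reports only the OR and CI.
#'
#' @param l,u lower and upper CI bounds, `0 < l < u`.
#' @param conf_level the interval's confidence level.
#' @return Standard error of `ln(OR)`.
#' @export
se_from_ci <- function(l, u, conf_level = 0.95) {
  if (any(l <= 0) || any(l >= u))
    stop("need 0 < l < u", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  (log(u) - log(l)) / (2 * z)
}

#' Power to detect a target odds ratio
#'
#' Two-sided normal (Wald) power of the log-OR test at level `alpha`
#' against a true OR of `or1`, given the estimate's standard error:
#' `1 - Phi(z_{1-alpha/2} - delta) + Phi(-z_{1-alpha/2} - delta)` with
#' `delta = |ln or1| / se_log`.
#'
#' @param or1 target odds ratio (use e.g. 0.67 for protective effects; the
#'   absolute log is taken).
#' @param se_log standard error of the log OR.
#' @param alpha two-sided significance level.
#' @return Power in (0,1).
#' @export
power_detect <- function(or1, se_log, alpha = 0.05) {
  stopifnot(se_log > 0, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  delta <- abs(log(or1)) / se_log
  1 - stats::pnorm(z - delta) + stats::pnorm(-z - delta)
}

#' False-positive report probability
#'
#' `FPRP = alpha (1 - pi) / [alpha (1 - pi) + (1 - beta) pi]`, where
#' `alpha` is the observed two-sided p-value (at full precision, never the
#' rounded printed value), `1 - beta` the power to detect the target OR,
#' and `pi` the prior probability that the association is real.
#'
#' @param alpha observed p-value in (0,1).
#' @param power power in (0,1).
#' @param prior prior probability (vectorized) in (0,1).
#' @return FPRP value(s) in (0,1).
#' @export
fprp_value <- function(alpha, power, prior) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power <= 1,
            all(prior > 0 & prior < 1))
  alpha * (1 - prior) / (alpha * (1 - prior) + power * prior)
}

#' FPRP across the prior grid for one effect estimate
#'
#' Computes the observed `alpha` (the estimate's two-sided p at full
#' precision), the power against the direction-appropriate target OR
#' (`or1_risk` when the estimated OR is at or above 1, `or1_protective`
#' below 1), one FPRP per prior, and the noteworthiness call (FPRP below
#' the threshold at the headline prior).
#'
#' @param estimate an [effect_estimate]; needs its origin [two_by_two]
#'   when `cfg$se_source = "counts"`.
#' @param cfg an [fprp_config].
#' @param power optional externally supplied power (e.g. a published
#'   value); overrides the computed power column.
#' @return Object of class `fprp_result`: `estimate`, `alpha`, `se_log`,
#'   `or1`, `power`, `fprp_by_prior` (named by prior), `noteworthy`.
#' @export
fprp_grid <- function(estimate, cfg = fprp_config(), power = NULL) {
  stopifnot(inherits(estimate, "effect_estimate"),
            inherits(cfg, "fprp_config"))
  se <- switch(cfg$se_source,
    ci = se_from_ci(estimate$ci_low, estimate$ci_high,
                    estimate$conf_level),
    counts = {
      t <- estimate$table
      if (is.null(t))
        stop("se_source = \"counts\" needs the estimate's 2x2 table",
             call. = FALSE)
      sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
    })
  or1 <- if (estimate$or_hat >= 1) cfg$or1_risk else cfg$or1_protective
  pw <- if (is.null(power)) power_detect(or1, se, cfg$power_alpha) else power
  alpha <- estimate$p
  grid <- fprp_value(alpha, pw, cfg$priors)
  names(grid) <- formatC(cfg$priors, format = "g")
  headline <- grid[which(cfg$priors == cfg$headline_prior)]
  structure(list(estimate = estimate, alpha = alpha, se_log = se,
                 or1 = or1, power = pw, fprp_by_prior = grid,
                 noteworthy = unname(headline) < cfg$threshold,
                 config = cfg),
            class = "fprp_result")
}

#' @export
print.fprp_result <- function(x, ...) {
  cat(sprintf(
    "<fprp_result> %s: OR %.2f, p %s, power %.3f vs OR1 %.2f%s\n",
    x$estimate$label, x$estimate$or_hat, format_p(x$alpha), x$power, x$or1,
    if (x$noteworthy) " [noteworthy]" else ""))
  print(round(x$fprp_by_prior, 3))
  invisible(x)
}

#' FPRP table across association results
#'
#' @param assoc data frame from [association_table()] (needs columns
#'   `snp_id`, `contrast`, `a`..`d`, `or`, `l95`, `u95`, `p`).
#' @param cfg an [fprp_config].
#' @param only_significant restrict to rows with `p < 0.05` (FPRP is
#'   defined for reported significant findings).
#' @return Data frame with p, power, one FPRP column per prior, and the
#'   noteworthy flag.
#' @export
fprp_table <- function(assoc, cfg = fprp_config(), only_significant = TRUE) {
  rows <- assoc
  if (only_significant) rows <- rows[rows$p < 0.05, , drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    t <- two_by_two(r$a, r$b, r$c, r$d)
    est <- effect_estimate(r$contrast, r$or, se_log = se_from_ci(r$l95, r$u95),
                           p = r$p, table = t)
    # keep reported CI bounds rather than re-deriving them
    est$ci_low <- r$l95; est$ci_high <- r$u95
    g <- fprp_grid(est, cfg)
    cbind(data.frame(snp_id = r$snp_id, contrast = r$contrast, or = r$or,
                     l95 = r$l95, u95 = r$u95, p = r$p, power = g$power,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(g$fprp_by_prior),
                        col.names = paste0("fprp_", names(g$fprp_by_prior))),
          data.frame(noteworthy = g$noteworthy))
  })
  do.call(rbind, out)
}
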
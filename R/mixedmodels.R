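#' Fit a random-intercept linear mixed model
#'
#' Maximum-likelihood fit (not REML, so likelihood-ratio tests on fixed
#' effects are valid) of `response ~ fixed + (1 | fly_id)`. Supports the
#' null (intercept-only), single-factor, and two-factor-with-interaction
#' forms used across the model families (periodicity, crepuscular and
#' hourly movement, hourly power, epoch-by-channel spectra, PE counts).
#'
#' @param table long-format data.frame with a `fly_id` column and a
#'   numeric `response` column (names configurable).
#' @param fixed_factors character vector of fixed-effect column names
#'   (length 0 = null model); two factors are crossed with interaction.
#' @param response name of the response column.
#' @param fly name of the grouping column.
#' @param interaction include the interaction when two factors are given.
#' @return a `mixed_fit`: list with `model` (lmerModLmerTest), `formula`,
#'   `fixed_factors`, `loglik`, `n_params`, `fixef`, `ranef_var`,
#'   `resid_var`, `boundary` (TRUE when the fly variance hit zero),
#'   `data`.
#' @export
fit_random_intercept <- function(table, fixed_factors = character(0),
                                 response = "response", fly = "fly_id",
                                 interaction = TRUE) {
  if (length(unique(table[[fly]])) < 2) stop("need at least 2 flies")
  for (f in fixed_factors) table[[f]] <- factor(table[[f]])
  rhs <- if (!length(fixed_factors)) "1" else {
    paste(fixed_factors, collapse = if (interaction) " * " else " + ")
  }
  fml <- stats::as.formula(paste0(response, " ~ ", rhs, " + (1 | ", fly, ")"))
  fit <- tryCatch(
    lmerTest::lmer(fml, data = table, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE)),
    error = function(e) stop("mixed-model fit failed (singular design?): ",
                             conditionMessage(e))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == fly]
  sig2 <- vc$vcov[vc$grp == "Residual"]
  out <- list(
    model = fit, formula = fml, fixed_factors = fixed_factors,
    loglik = as.numeric(stats::logLik(fit)),
    n_params = attr(stats::logLik(fit), "df"),
    fixef = lme4::fixef(fit), ranef_var = tau2, resid_var = sig2,
    boundary = tau2 < 1e-10, data = table,
    response = response, fly = fly, interaction = interaction
  )
  class(out) <- "mixed_fit"
  out
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' chi-square = 2 (loglik_alt - loglik_null) with df = difference in
#' parameter counts; the winner is the alternative iff p < alpha, else the
#' null (ties and non-significant improvements go to the simpler model).
#'
#' @param null_fit,alt_fit nested `mixed_fit` objects on the same data.
#' @param alpha winner threshold.
#' @return an `lrt_result`: list with `chi2`, `delta_df`, `p`, `winner`
#'   ("null" or "alt").
#' @export
compare_lrt <- function(null_fit, alt_fit, alpha = 0.05) {
  if (stats::nobs(null_fit$model) != stats::nobs(alt_fit$model)) {
    stop("models fit to different data")
  }
  if (!all(null_fit$fixed_factors %in% alt_fit$fixed_factors) ||
      alt_fit$n_params < null_fit$n_params) {
    stop("models are not nested (null must be the smaller model)")
  }
  chi2 <- max(2 * (alt_fit$loglik - null_fit$loglik), 0)
  delta_df <- alt_fit$n_params - null_fit$n_params
  p <- if (delta_df >= 1) stats::pchisq(chi2, delta_df, lower.tail = FALSE)
  else 1
  out <- list(chi2 = chi2, delta_df = delta_df, p = p,
              winner = if (delta_df >= 1 && p < alpha) "alt" else "null")
  class(out) <- "lrt_result"
  out
}

#' Main-effect tests for a fitted mixed model
#'
#' Per-term likelihood-ratio chi-square tests respecting marginality: the
#' interaction (if any) is tested against the additive model; each main
#' effect is tested by dropping it from the additive model. `type = "F"`
#' instead returns the Satterthwaite F table.
#'
#' @param fit a `mixed_fit` with at least one fixed factor.
#' @param type `"chisq"` (default) or `"F"`.
#' @return data.frame `term`, `statistic`, `df`, `p` (empty for an
#'   intercept-only fit).
#' @export
anova_main_effects <- function(fit, type = c("chisq", "F")) {
  type <- match.arg(type)
  if (!length(fit$fixed_factors)) {
    return(data.frame(term = character(), statistic = numeric(),
                      df = numeric(), p = numeric()))
  }
  if (type == "F") {
    a <- stats::anova(fit$model)
    return(data.frame(term = rownames(a), statistic = a[["F value"]],
                      df = a[["NumDF"]], p = a[["Pr(>F)"]]))
  }
  refit <- function(factors, interaction) {
    fit_random_intercept(fit$data, factors, response = fit$response,
                         fly = fit$fly, interaction = interaction)
  }
  rows <- list()
  two <- length(fit$fixed_factors) == 2 && fit$interaction
  base <- if (two) refit(fit$fixed_factors, interaction = FALSE) else fit
  if (two) {
    lr <- compare_lrt(base, fit)
    rows[[1]] <- data.frame(term = paste(fit$fixed_factors, collapse = ":"),
                            statistic = lr$chi2, df = lr$delta_df, p = lr$p)
  }
  for (f in fit$fixed_factors) {
    reduced <- refit(setdiff(fit$fixed_factors, f), interaction = FALSE)
    lr <- compare_lrt(reduced, base)
    rows[[length(rows) + 1]] <- data.frame(term = f, statistic = lr$chi2,
                                           df = lr$delta_df, p = lr$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tukey-adjusted pairwise post hocs
#'
#' All pairwise contrasts between the levels of one fixed factor, with
#' studentized-range (Tukey) adjustment, via estimated marginal means
#' (Satterthwaite degrees of freedom).
#'
#' @param fit a `mixed_fit`.
#' @param factor_name factor to contrast (must have >= 2 levels).
#' @return data.frame `contrast`, `estimate`, `SE`, `p_adj`.
#' @export
posthoc_tukey <- function(fit, factor_name) {
  if (!factor_name %in% fit$fixed_factors) {
    stop("factor not in the model: ", factor_name)
  }
  if (nlevels(factor(fit$data[[factor_name]])) < 2) {
    stop("factor has a single level")
  }
  em <- emmeans::emmeans(fit$model, stats::as.formula(paste0("~", factor_name)),
                         lmer.df = "satterthwaite")
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  data.frame(contrast = pr$contrast, estimate = pr$estimate, SE = pr$SE,
             p_adj = pr$p.value)
}
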
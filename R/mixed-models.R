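# Linear mixed-effects modelling of vertical habitat use: one model for the
# mean depth per individual x date x diel period, one for the count of
# records deeper than the bank-edge threshold, both log(x + 1)-transformed
# (right-skewed responses; +1 keeps zero counts finite), with a random
# intercept per individual.

FULL_FIXED_EFFECTS <- c("moon_bin", "season", "diel", "sex", "site",
                        "length_stl")

#' Aggregate annotated records into period summaries
#'
#' One row per tag x local date x diel period: mean depth over the period's
#' records and the count of records deeper than `threshold`, with the
#' modelling covariates (moon bin, season, sex, length, site) attached.
#' Period cells with no records are simply absent.
#'
#' @param annotated Annotated record tibble from [annotate_context()].
#' @param metadata The tag's [tag_metadata()] row.
#' @param threshold Deep-record depth threshold, m (default 50).
#' @return A tibble of period summaries.
#' @export
aggregate_periods <- function(annotated, metadata, threshold = 50) {
  annotated %>%
    group_by(date = .data$local_date, diel = .data$diel) %>%
    summarise(
      mean_depth = mean(.data$depth),
      deep_count = sum(.data$depth > threshold),
      moon_fraction = dplyr::first(.data$moon_fraction),
      moon_bin = dplyr::first(.data$moon_bin),
      season = dplyr::first(.data$season),
      n_records = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      tag_id = metadata$tag_id,
      sex = factor(metadata$sex, levels = SEXES),
      site = factor(metadata$site, levels = SITES),
      length_stl = metadata$length_stl,
      .before = 1
    )
}

make_formula <- function(response, fixed) {
  rhs <- if (length(fixed) == 0) "1" else paste(fixed, collapse = " + ")
  as.formula(paste0("log1p_response ~ ", rhs, " + (1 | tag_id)"))
}

prepare_model_frame <- function(summaries, response) {
  resp_col <- switch(response, MEAN_DEPTH = "mean_depth",
                     DEEP_COUNT = "deep_count")
  df <- summaries
  df$log1p_response <- log(df[[resp_col]] + 1)
  # centred length: interpretable intercept, identical tests
  if ("length_stl" %in% names(df)) {
    df$length_stl <- df$length_stl - mean(df$length_stl)
  }
  df <- df[complete.cases(df[, c("log1p_response", "tag_id")]), ]
  df
}

drop_unusable_effects <- function(df, fixed) {
  usable <- purrr::keep(fixed, function(f) {
    v <- df[[f]]
    if (is.null(v)) return(FALSE)
    if (is.factor(v)) length(unique(droplevels(v))) > 1 else sd(v) > 0
  })
  dropped <- setdiff(fixed, usable)
  if (length(dropped) > 0) {
    warn(paste0("Dropping fixed effect(s) with no variation: ",
                paste(dropped, collapse = ", ")))
  }
  usable
}

#' Corrected Akaike information criterion
#'
#' `AICc = AIC + 2 p (p + 1) / (n - p - 1)` with `p` the number of fitted
#' parameters and `n` the number of rows.
#'
#' @param fit A fitted model with `logLik` and `AIC` methods.
#' @return Numeric scalar.
#' @export
aicc <- function(fit) {
  ll <- logLik(fit)
  p <- attr(ll, "df")
  n <- stats::nobs(fit)
  AIC(fit) + 2 * p * (p + 1) / (n - p - 1)
}

#' Fit a mixed model of period-level vertical habitat use
#'
#' `log(response + 1)` modelled with the requested fixed effects and a
#' random intercept per individual, fitted by REML (default) with
#' [lme4::lmer()]. At least two individuals are required. If moon phase is
#' among the fixed effects but some individual's deployment is shorter than
#' 59 days (two synodic months), the moon term is dropped with a warning.
#'
#' @param summaries Period-summary tibble ([aggregate_periods()] rows, all
#'   tags bound together).
#' @param response `"MEAN_DEPTH"` or `"DEEP_COUNT"`.
#' @param fixed Character vector of fixed-effect names (default: moon bin,
#'   season, diel, sex, site, centred length).
#' @param reml Fit by REML (`TRUE`, default) or ML.
#' @param deployment_days Optional named vector of deployment durations per
#'   tag, used for the moon-phase eligibility check.
#' @return An object of class `habitat_mixed_fit` wrapping the `lmerMod`
#'   fit; see [tidy.habitat_mixed_fit()] and [glance.habitat_mixed_fit()].
#' @export
fit_mixed <- function(summaries,
                      response = c("MEAN_DEPTH", "DEEP_COUNT"),
                      fixed = FULL_FIXED_EFFECTS,
                      reml = TRUE,
                      deployment_days = NULL) {
  response <- match.arg(response)
  df <- prepare_model_frame(summaries, response)
  if (length(unique(df$tag_id)) < 2) {
    abort("At least 2 individuals are required for a random-intercept model.")
  }
  if ("moon_bin" %in% fixed && !is.null(deployment_days)) {
    if (any(deployment_days < MOON_ELIGIBLE_DAYS)) {
      warn(paste0(
        "Some deployments are shorter than ", MOON_ELIGIBLE_DAYS,
        " days; moon phase dropped from the fixed effects."))
      fixed <- setdiff(fixed, "moon_bin")
    }
  }
  fixed <- drop_unusable_effects(df, fixed)
  fml <- make_formula(response, fixed)
  environment(fml) <- environment()
  fit <- lme4::lmer(fml, data = df, REML = reml)
  vc <- as.data.frame(lme4::VarCorr(fit))
  singular <- lme4::isSingular(fit)
  if (singular) warn("Random-effect fit is singular; variance reported as 0.")
  structure(list(
    fit = fit, response = response, fixed = fixed, reml = reml,
    data = df,
    random_intercept_var = vc$vcov[vc$grp == "tag_id"],
    residual_var = vc$vcov[vc$grp == "Residual"],
    aicc = aicc(fit), aic = AIC(fit), bic = BIC(fit),
    n = nrow(df),
    formula = deparse(fml)
  ), class = "habitat_mixed_fit")
}

#' @exportS3Method base::print
print.habitat_mixed_fit <- function(x, ...) {
  cat(sprintf("<habitat_mixed_fit> %s ~ %s\n", x$response,
              paste(x$fixed, collapse = " + ")))
  cat(sprintf("  n = %d, AICc = %.1f, BIC = %.1f, individual SD = %.3f\n",
              x$n, x$aicc, x$bic, sqrt(x$random_intercept_var)))
  invisible(x)
}

#' Fixed-effect coefficient table
#'
#' @param x A `habitat_mixed_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `t_value`.
#' @export
tidy.habitat_mixed_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co), estimate = co[, "Estimate"],
         std_error = co[, "Std. Error"], t_value = co[, "t value"])
}

#' One-row fit summary
#'
#' @param x A `habitat_mixed_fit`.
#' @param ... Unused.
#' @return A tibble: response, n, df, AICc, BIC, variance components.
#' @export
glance.habitat_mixed_fit <- function(x, ...) {
  tibble(
    response = x$response,
    n = x$n,
    df = attr(logLik(x$fit), "df"),
    aicc = x$aicc, aic = x$aic, bic = x$bic,
    random_intercept_sd = sqrt(x$random_intercept_var),
    residual_sd = sqrt(x$residual_var)
  )
}

# Whole-factor p-values by likelihood-ratio test on ML refits: REML
# likelihoods are not comparable across fixed-effect structures.
whole_factor_pvalues <- function(df, response, fixed) {
  fml <- make_formula(response, fixed)
  environment(fml) <- environment() # drop1 refits resolve `df` here
  fit_ml <- lme4::lmer(fml, data = df, REML = FALSE)
  d1 <- drop1(fit_ml, test = "Chisq")
  terms <- rownames(d1)[-1]
  setNames(d1[["Pr(Chi)"]][-1], terms)
}

#' Backward elimination of non-significant fixed effects
#'
#' Iteratively refits the model by maximum likelihood and drops the least
#' significant fixed effect (whole-factor likelihood-ratio test) while its
#' p-value exceeds `alpha`, then reports the full and reduced models (both
#' refitted by REML) with their AICc/BIC so the parsimony claim can be
#' checked directly.
#'
#' @param summaries Period-summary tibble.
#' @param response `"MEAN_DEPTH"` or `"DEEP_COUNT"`.
#' @param fixed Full fixed-effect set.
#' @param alpha Retention threshold (default 0.05).
#' @param deployment_days Optional per-tag deployment durations (see
#'   [fit_mixed()]).
#' @return A list: `full` and `reduced` (`habitat_mixed_fit`s), `trail`
#'   (tibble of the eliminated terms in order, with the p-value at removal),
#'   `retained` (character).
#' @export
backward_eliminate <- function(summaries,
                               response = c("MEAN_DEPTH", "DEEP_COUNT"),
                               fixed = FULL_FIXED_EFFECTS,
                               alpha = 0.05,
                               deployment_days = NULL) {
  response <- match.arg(response)
  full <- fit_mixed(summaries, response, fixed, reml = TRUE,
                    deployment_days = deployment_days)
  fixed <- full$fixed # after eligibility / variation filtering
  df <- full$data

  current <- fixed
  trail <- tibble(step = integer(), dropped = character(),
                  p_value = numeric())
  step <- 0L
  while (length(current) > 0) {
    pv <- whole_factor_pvalues(df, response, current)
    worst <- names(pv)[which.max(pv)]
    if (pv[worst] <= alpha) break
    step <- step + 1L
    trail <- bind_rows(trail, tibble(step = step, dropped = worst,
                                     p_value = unname(pv[worst])))
    current <- setdiff(current, worst)
  }
  if (length(current) == 0) {
    warn("All fixed effects eliminated; returning intercept-only model.")
  }
  reduced <- fit_mixed(summaries, response, current, reml = TRUE,
                       deployment_days = deployment_days)
  list(full = full, reduced = reduced, trail = trail, retained = current)
}

#' Family-wise Tukey contrasts for a factor
#'
#' All pairwise level differences for a fixed factor, with single-step
#' multivariate-t ("Tukey") family-wise adjustment via
#' [multcomp::glht()]; unadjusted p-values are reported alongside.
#'
#' @param x A `habitat_mixed_fit` whose model retains `factor`.
#' @param factor Name of the factor.
#' @return A tibble: `contrast`, `estimate`, `std_error`, `p_value`
#'   (adjusted), `p_unadjusted`.
#' @export
pairwise_contrasts <- function(x, factor) {
  if (!factor %in% x$fixed) {
    abort(paste0("`", factor, "` is not among the model's fixed effects."))
  }
  linfct <- do.call(multcomp::mcp, setNames(list("Tukey"), factor))
  gh <- multcomp::glht(x$fit, linfct = linfct)
  s_adj <- summary(gh, test = multcomp::adjusted("single-step"))
  s_raw <- summary(gh, test = multcomp::adjusted("none"))
  tibble(
    contrast = names(s_adj$test$coefficients),
    estimate = unname(s_adj$test$coefficients),
    std_error = unname(s_adj$test$sigma),
    p_value = unname(as.numeric(s_adj$test$pvalues)),
    p_unadjusted = unname(as.numeric(s_raw$test$pvalues))
  )
}

#' Model comparison table (full vs reduced)
#'
#' @param elim Result of [backward_eliminate()].
#' @return A tibble with one row per model: formula, df, BIC, AICc —
#'   the layout of a published model-comparison table.
#' @export
model_comparison <- function(elim) {
  purrr::map_dfr(list(full = elim$full, reduced = elim$reduced),
                 function(m) {
    tibble(
      response = m$response,
      fixed_effects = paste(m$fixed, collapse = " + "),
      df = attr(logLik(m$fit), "df"),
      bic = m$bic,
      aicc = m$aicc
    )
  }, .id = "model")
}
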
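#' Mixed-model specification for the G x E x M analysis
#'
#' Fixed effects are built from the factors `trait` (G_T), `maturity`
#' (G_M), `planting` (M_P) and `env_w` (water-stress environment E_W);
#' the random structure is always a year-within-location intercept,
#' `(1 | location/year)`. Four presets mirror the models used for the
#' simulated outcome variables:
#'
#' \describe{
#'   \item{eq1}{main effects + trait:env_w + maturity:planting +
#'     env_w:planting + maturity:env_w + maturity:env_w:planting
#'     (grain yield, total transpiration, soil water).}
#'   \item{eq2}{eq1 + trait:maturity (biomass at flowering).}
#'   \item{eq3}{main effects + trait:maturity + trait:env_w +
#'     env_w:planting + maturity:env_w + trait:env_w:planting
#'     (transpiration at flowering).}
#'   \item{eq4}{main effects + trait:env_w + maturity:env_w +
#'     maturity:planting (water productivity).}
#' }
#'
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms (use `:` for
#'   interactions).
#' @return an object of class `lt_modelspec`.
#' @export
model_spec <- function(response, fixed) {
  stopifnot(is.character(response), length(response) == 1,
            is.character(fixed), length(fixed) >= 1)
  structure(list(response = response, fixed = unique(fixed)),
            class = "lt_modelspec")
}

#' @rdname model_spec
#' @param preset one of `"eq1"`, `"eq2"`, `"eq3"`, `"eq4"`, or
#'   `"full"` (the complete four-way crossing).
#' @export
preset_spec <- function(preset = c("eq1", "eq2", "eq3", "eq4", "full"),
                        response = "yield") {
  preset <- match.arg(preset)
  main <- c("trait", "maturity", "env_w", "planting")
  fixed <- switch(preset,
    eq1 = c(main, "trait:env_w", "maturity:planting", "env_w:planting",
            "maturity:env_w", "maturity:env_w:planting"),
    eq2 = c(main, "trait:maturity", "trait:env_w", "maturity:planting",
            "env_w:planting", "maturity:env_w", "maturity:env_w:planting"),
    eq3 = c(main, "trait:maturity", "trait:env_w", "env_w:planting",
            "maturity:env_w", "trait:env_w:planting"),
    eq4 = c(main, "trait:env_w", "maturity:env_w", "maturity:planting"),
    full = "trait*maturity*env_w*planting"
  )
  model_spec(response, fixed)
}

spec_formula <- function(spec) {
  stats::as.formula(paste(spec$response, "~",
                          paste(spec$fixed, collapse = " + "),
                          "+ (1 | location/year)"))
}

#' Fit the linear mixed model of a specification
#'
#' Delegates to `lmerTest::lmer` (random intercepts for location and
#' year-within-location). Use `method = "ML"` whenever models are compared
#' (AIC, likelihood ratio), `"REML"` for final estimates. Non-convergence
#' is flagged, never silently ignored.
#'
#' @param spec an [model_spec()] / [preset_spec()].
#' @param table a data frame with the response, the fixed-effect factors,
#'   and `location` and `year` columns (>= 2 locations, >= 2 years).
#' @param method `"REML"` or `"ML"`.
#' @return an object of class `lt_fit`: list with the `lmerModLmerTest`
#'   object (`fit`), `AIC`, `logLik`, `anova` (Satterthwaite F tests),
#'   `converged`, `spec` and `method`.
#' @export
fit_mixed <- function(spec, table, method = c("REML", "ML")) {
  method <- method[1]
  need <- unique(c(all.vars(stats::as.formula(
    paste("~", paste(spec$fixed, collapse = "+")))), "location", "year",
    spec$response))
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  table <- stats::na.omit(table[need])
  fit <- lmerTest::lmer(spec_formula(spec), data = table,
                        REML = identical(method, "REML"))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  structure(list(
    fit = fit,
    AIC = stats::AIC(fit),
    logLik = as.numeric(stats::logLik(fit)),
    anova = stats::anova(fit),
    converged = converged,
    spec = spec,
    method = method
  ), class = "lt_fit")
}

# factors making up one model term
term_factors <- function(term) sort(strsplit(term, ":", fixed = TRUE)[[1]])

# a term is removable if no *other* retained term contains all its factors
removable_terms <- function(fixed) {
  keep <- vapply(fixed, function(t) {
    f <- term_factors(t)
    !any(vapply(setdiff(fixed, t), function(o) {
      all(f %in% term_factors(o))
    }, logical(1)))
  }, logical(1))
  fixed[keep]
}

#' Backward AIC-stepwise selection over the fixed effects
#'
#' Starting from the full four-way crossing (or any given spec), repeatedly
#' drops the removable term — one whose factors are not contained in any
#' retained higher-order interaction, so marginality is never violated —
#' that yields the largest AIC decrease on ML fits; stops when no removal
#' improves AIC.
#'
#' @param spec starting specification (use `preset_spec("full", response)`
#'   for the four-way model).
#' @param table model data.
#' @param trace print the removal path.
#' @return list with the selected `spec`, its ML `fit` (an `lt_fit`), the
#'   starting and final `AIC`, and the removal `path` data frame.
#' @export
stepwise_backward_aic <- function(spec, table, trace = FALSE) {
  # expand any crossing shorthand (a*b) into explicit terms
  tl <- attr(stats::terms(stats::as.formula(
    paste("~", paste(spec$fixed, collapse = "+")))), "term.labels")
  cur <- model_spec(spec$response, tl)
  fit <- fit_mixed(cur, table, method = "ML")
  path <- data.frame(dropped = "<none>", AIC = fit$AIC)
  repeat {
    cands <- removable_terms(cur$fixed)
    if (!length(cands) || length(cur$fixed) == 1) break
    trials <- lapply(cands, function(tm) {
      fit_mixed(model_spec(cur$response, setdiff(cur$fixed, tm)), table,
                method = "ML")
    })
    aics <- vapply(trials, `[[`, numeric(1), "AIC")
    best <- which.min(aics)
    if (aics[best] >= fit$AIC) break
    if (trace) message("drop ", cands[best], ": AIC ", round(aics[best], 2))
    cur <- model_spec(cur$response, setdiff(cur$fixed, cands[best]))
    fit <- trials[[best]]
    path <- rbind(path, data.frame(dropped = cands[best], AIC = fit$AIC))
  }
  list(spec = cur, fit = fit, start_AIC = path$AIC[1], final_AIC = fit$AIC,
       path = path)
}

#' Likelihood-ratio test between nested ML fits
#'
#' @param reduced,full `lt_fit` objects fitted by ML; the reduced model's
#'   fixed terms must be a subset of the full model's.
#' @return list with `statistic` (2 delta logLik), `df` and `p`.
#' @export
likelihood_ratio <- function(reduced, full) {
  if (!identical(reduced$method, "ML") || !identical(full$method, "ML")) {
    stop("likelihood-ratio comparison requires ML fits", call. = FALSE)
  }
  exp_red <- attr(stats::terms(stats::as.formula(
    paste("~", paste(reduced$spec$fixed, collapse = "+")))), "term.labels")
  exp_full <- attr(stats::terms(stats::as.formula(
    paste("~", paste(full$spec$fixed, collapse = "+")))), "term.labels")
  if (!all(exp_red %in% exp_full)) {
    stop("models are not nested: reduced spec has terms absent from full",
         call. = FALSE)
  }
  df <- attr(stats::logLik(full$fit), "df") -
    attr(stats::logLik(reduced$fit), "df")
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  list(statistic = stat, df = df, p = p)
}

#' Tukey HSD post-hoc comparisons for one factor
#'
#' Gated on the factor's Satterthwaite F test: comparisons are only
#' carried out when the F test is significant at `alpha`. Pairwise
#' contrasts are Tukey-adjusted estimated marginal means with a compact
#' letter display.
#'
#' @param fit an `lt_fit` (REML recommended).
#' @param factor factor name among the fixed effects.
#' @param alpha gate significance level (default 0.05).
#' @return list with `f_p` (gate p-value), `performed`, and when
#'   performed, `pairs` and `letters` data frames.
#' @export
tukey_hsd <- function(fit, factor, alpha = 0.05) {
  an <- fit$anova
  if (!factor %in% rownames(an)) {
    stop("'", factor, "' is not a fixed-effect term of the fit",
         call. = FALSE)
  }
  f_p <- an[factor, "Pr(>F)"]
  if (is.na(f_p) || f_p >= alpha) {
    return(list(f_p = f_p, performed = FALSE))
  }
  emm <- emmeans::emmeans(fit$fit, specs = factor)
  prs <- as.data.frame(summary(
    emmeans::contrast(emm, method = "pairwise"), adjust = "tukey"))
  # letter display via multcomp's general linear hypotheses on the same
  # factor (single-step Tukey adjustment)
  lf <- list(factor = "Tukey")
  names(lf) <- factor
  g <- suppressWarnings(
    multcomp::glht(fit$fit, linfct = do.call(multcomp::mcp, lf)))
  lets <- multcomp::cld(g, level = alpha)$mcletters$Letters
  list(f_p = f_p, performed = TRUE, pairs = prs,
       letters = data.frame(level = names(lets), letter = unname(lets)))
}

#' Root mean square error
#'
#' @param observed,simulated equal-length numeric vectors.
#' @return `sqrt(mean((observed - simulated)^2))`.
#' @examples
#' rmse(52, 53) # 1 day
#' @export
rmse <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 1) {
    stop("observed and simulated must be equal-length, non-empty",
         call. = FALSE)
  }
  sqrt(mean((observed - simulated)^2))
}

#' Simulate a G x E x M outcome table with known effects
#'
#' Generates a balanced trait x maturity x planting x location x year table
#' whose response follows the year-within-location mixed-model structure
#' with user-specified fixed effects — the testbed for parameter recovery
#' and model selection.
#'
#' @param n_loc,n_year numbers of locations and years.
#' @param mu grand mean.
#' @param trait_eff named effects for `c(nonLT, LT)`.
#' @param maturity_eff named effects for `c(short, medium, full)`.
#' @param planting_eff named effects for the three planting dates.
#' @param env_eff named effects for `c(WW, LD, MD, ED)`; the environment of
#'   each location-year is drawn uniformly.
#' @param trait_env two-way interaction matrix (trait x env), or `NULL`.
#' @param sd_loc,sd_year,sd_res standard deviations of the location,
#'   year-within-location and residual terms.
#' @param seed RNG seed.
#' @return a data frame with factors `trait`, `maturity`, `planting`,
#'   `env_w`, `location`, `year` and response `yield`.
#' @export
simulate_gxe_table <- function(n_loc = 4, n_year = 6, mu = 4,
                               trait_eff = c(nonLT = 0, LT = 0.3),
                               maturity_eff = c(short = -0.2, medium = 0,
                                                full = 0.2),
                               planting_eff = c("05-01" = 0.1, "05-15" = 0,
                                                "06-01" = -0.1),
                               env_eff = c(WW = 1, LD = 0, MD = -0.6,
                                           ED = -1),
                               trait_env = NULL,
                               sd_loc = 0.2, sd_year = 0.1, sd_res = 0.3,
                               seed = 1L) {
  with_seed(derive_seed(seed, 7001L), {
    locs <- paste0("L", seq_len(n_loc))
    yrs <- seq_len(n_year)
    b_loc <- stats::setNames(stats::rnorm(n_loc, 0, sd_loc), locs)
    b_yr <- matrix(stats::rnorm(n_loc * n_year, 0, sd_year), n_loc, n_year,
                   dimnames = list(locs, yrs))
    env_ly <- matrix(sample(names(env_eff), n_loc * n_year, replace = TRUE),
                     n_loc, n_year, dimnames = list(locs, yrs))
    g <- expand.grid(trait = names(trait_eff),
                     maturity = names(maturity_eff),
                     planting = names(planting_eff),
                     location = locs, year = yrs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$env_w <- env_ly[cbind(g$location, g$year)]
    y <- mu + trait_eff[g$trait] + maturity_eff[g$maturity] +
      planting_eff[g$planting] + env_eff[g$env_w] +
      b_loc[g$location] + b_yr[cbind(g$location, g$year)] +
      stats::rnorm(nrow(g), 0, sd_res)
    if (!is.null(trait_env)) y <- y + trait_env[cbind(g$trait, g$env_w)]
    g$yield <- as.numeric(y)
    g$year <- factor(g$year)
    g
  })
}
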
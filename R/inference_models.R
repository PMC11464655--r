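#' Standardise a covariate
#'
#' Centres to mean 0 and scales to sample SD 1. Continuous covariates enter
#' both mixed models standardised within the analysis sample, so their
#' coefficients read as response units per SD.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return the scaled vector.
#' @export
scaleCovariate <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("cannot scale a constant covariate")
  (values - mean(values)) / s
}

# shared preparation: complete cases, factor coding (male / first year as
# reference so reported contrasts are "Sex (F)" and the later year), scaling
prepareRecords <- function(records, needed) {
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  rec <- records[stats::complete.cases(records[, needed]), , drop = FALSE]
  nCol <- length(unique(rec$colony))
  if (nCol < 2)
    stop("random colony intercept inestimable with ", nCol,
         " colony (need >= 2); refusing to fall back to a fixed-effects fit")
  rec$colony <- factor(rec$colony)
  rec$sex <- factor(rec$sex, levels = c("M", "F"))
  rec$year <- factor(rec$year, levels = sort(unique(as.character(rec$year))))
  if (nlevels(droplevels(rec$year)) < 2)
    stop("year has a single level in the analysis sample; the year contrast is inestimable")
  if (length(unique(rec$sex)) < 2)
    stop("sex has a single level in the analysis sample; the sex contrast is inestimable")
  rec
}

termLabels <- function(coefNames, rec, covariateLabels) {
  out <- coefNames
  out[out == "(Intercept)"] <- "Intercept"
  yr2 <- levels(rec$year)[2]
  out[out == paste0("year", yr2)] <- sprintf("Year (%s)", yr2)
  out[out == "sexF"] <- "Sex (F)"
  for (nm in names(covariateLabels)) out[out == nm] <- covariateLabels[[nm]]
  out
}

buildFit <- function(model, rec, covariateLabels, reml, response) {
  sm <- summary(model)$coefficients  # Satterthwaite df by lmerTest default
  coefTable <- data.frame(
    term = termLabels(rownames(sm), rec, covariateLabels),
    estimate = sm[, "Estimate"], se = sm[, "Std. Error"], df = sm[, "df"],
    t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
    significant = sm[, "Pr(>|t|)"] < 0.05,
    row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(model))
  ranefTable <- data.frame(
    effect = c("colony (intercept)", "residual"),
    sd = c(vc$sdcor[vc$grp == "colony" & vc$var1 == "(Intercept)" &
                      is.na(vc$var2)],
           vc$sdcor[vc$grp == "Residual"]),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(model = model, response = response, coefTable = coefTable,
              ranefTable = ranefTable,
              anovaType3 = stats::anova(model, type = 3),
              reml = reml, n = nrow(rec), nColonies = nlevels(rec$colony),
              singular = lme4::isSingular(model),
              dfMethod = "Satterthwaite")
  class(out) <- "phenMixedFit"
  out
}

#' Mixed model for migration distance
#'
#' Fits `migration_distance_km ~ year + sex + wintering latitude (scaled) +
#' (1 | colony)` by REML, with Satterthwaite denominator degrees of freedom
#' for the fixed-effect t-tests and a type-III ANOVA table alongside.
#'
#' @param records data.frame of one-bird rows with columns `colony`, `sex`
#'   (`F`/`M`), `year`, `migration_distance_km`, `wintering_latitude`.
#'   Incomplete rows are dropped; the covariate is re-scaled within the
#'   analysis sample.
#' @param reml fit by REML (default) or ML.
#' @return object of class `phenMixedFit`: the `lmerTest` model, a
#'   fixed-effects `coefTable` (term, estimate, SE, df, t, p), a
#'   `ranefTable` with the among-colony and residual SDs (km), the type-III
#'   ANOVA, and fit metadata (`n`, `nColonies`, `singular`).
#' @export
fitDistanceModel <- function(records, reml = TRUE) {
  rec <- prepareRecords(records, c("colony", "sex", "year",
                                   "migration_distance_km",
                                   "wintering_latitude"))
  rec$wlat_scaled <- scaleCovariate(rec$wintering_latitude)
  model <- withCallingHandlers(
    lmerTest::lmer(migration_distance_km ~ year + sex + wlat_scaled +
                     (1 | colony), data = rec, REML = reml),
    message = function(m) invokeRestart("muffleMessage"))
  fit <- buildFit(model, rec, c(wlat_scaled = "Wintering latitude (scaled)"),
                  reml, "migration_distance_km")
  if (fit$singular)
    warning("singular fit: a variance component is estimated at zero")
  fit
}

#' Mixed model for lay date
#'
#' Fits `lay_doy ~ year + sex + migration distance (scaled) + colony
#' latitude (scaled) + (1 | colony)` by REML, as [fitDistanceModel()].
#'
#' @param records as in [fitDistanceModel()], additionally requiring
#'   `lay_doy`, `colony_latitude`.
#' @inheritParams fitDistanceModel
#' @return `phenMixedFit`, random-effect SDs in days.
#' @export
fitLaydateModel <- function(records, reml = TRUE) {
  rec <- prepareRecords(records, c("colony", "sex", "year", "lay_doy",
                                   "migration_distance_km",
                                   "colony_latitude"))
  rec$dist_scaled <- scaleCovariate(rec$migration_distance_km)
  rec$clat_scaled <- scaleCovariate(rec$colony_latitude)
  model <- withCallingHandlers(
    lmerTest::lmer(lay_doy ~ year + sex + dist_scaled + clat_scaled +
                     (1 | colony), data = rec, REML = reml),
    message = function(m) invokeRestart("muffleMessage"))
  fit <- buildFit(model, rec,
                  c(dist_scaled = "Migration distance (scaled)",
                    clat_scaled = "Colony latitude (scaled)"),
                  reml, "lay_doy")
  if (fit$singular)
    warning("singular fit: a variance component is estimated at zero")
  fit
}

#' @export
print.phenMixedFit <- function(x, digits = 3, ...) {
  cat(sprintf("Linear mixed model (%s, %s df): %s, n = %d birds, %d colonies%s\n",
              if (x$reml) "REML" else "ML", x$dfMethod, x$response, x$n,
              x$nColonies, if (x$singular) " [singular fit]" else ""))
  tab <- x$coefTable
  tab$term <- paste0(tab$term, ifelse(tab$significant, "*", ""))
  tab$significant <- NULL
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("Random effects: colony SD = %.1f, residual SD = %.1f\n",
              x$ranefTable$sd[1], x$ranefTable$sd[2]))
  invisible(x)
}

#' Screen two-way fixed-effect interactions
#'
#' Fits the requested model with all two-way interactions among its fixed
#' effects (sum-to-zero contrasts, type-III tests). If every interaction has
#' p above `threshold` (0.200 by default) the main-effects formula is
#' returned as the reduced model; otherwise the full formula is retained and
#' the surviving interactions are flagged.
#'
#' @param records as in the model fitters.
#' @param model `"distance"` or `"laydate"`.
#' @param threshold p-value above which an interaction is dropped.
#' @param reml fit by REML (default) or ML.
#' @return list: `reduced` (logical), `formula` (the retained formula),
#'   `interactions` (data.frame of interaction terms, p-values and
#'   `retained` flags), `fit` (the full-interaction `lmerTest` model).
#' @export
screenInteractions <- function(records, model = c("distance", "laydate"),
                               threshold = 0.200, reml = TRUE) {
  model <- match.arg(model)
  if (model == "distance") {
    rec <- prepareRecords(records, c("colony", "sex", "year",
                                     "migration_distance_km",
                                     "wintering_latitude"))
    rec$wlat_scaled <- scaleCovariate(rec$wintering_latitude)
    terms <- c("year", "sex", "wlat_scaled")
    response <- "migration_distance_km"
  } else {
    rec <- prepareRecords(records, c("colony", "sex", "year", "lay_doy",
                                     "migration_distance_km",
                                     "colony_latitude"))
    rec$dist_scaled <- scaleCovariate(rec$migration_distance_km)
    rec$clat_scaled <- scaleCovariate(rec$colony_latitude)
    terms <- c("year", "sex", "dist_scaled", "clat_scaled")
    response <- "lay_doy"
  }
  # sum-to-zero contrasts so type-III marginal tests are well defined in the
  # presence of the interactions
  rec$sex <- stats::C(rec$sex, stats::contr.sum)
  rec$year <- stats::C(rec$year, stats::contr.sum)
  fullFormula <- stats::as.formula(paste(
    response, "~ (", paste(terms, collapse = " + "), ")^2 + (1 | colony)"))
  fit <- suppressWarnings(withCallingHandlers(
    lmerTest::lmer(fullFormula, data = rec, REML = reml),
    message = function(m) invokeRestart("muffleMessage")))
  a3 <- stats::anova(fit, type = 3)
  inter <- grepl(":", rownames(a3), fixed = TRUE)
  interactions <- data.frame(term = rownames(a3)[inter],
                             p = a3[inter, "Pr(>F)"],
                             retained = a3[inter, "Pr(>F)"] <= threshold,
                             row.names = NULL, stringsAsFactors = FALSE)
  reduced <- !any(interactions$retained)
  mainFormula <- stats::as.formula(paste(
    response, "~", paste(terms, collapse = " + "), "+ (1 | colony)"))
  list(reduced = reduced,
       formula = if (reduced) mainFormula else fullFormula,
       interactions = interactions, fit = fit)
}

#' Likelihood-ratio test for a colony-specific migration-distance slope
#'
#' Compares the random-intercept lay-date model with the model additionally
#' carrying a random migration-distance slope by colony (slope variance plus
#' intercept-slope correlation: 2 extra parameters, so df = 2). Both models
#' share identical fixed effects, so REML likelihoods are comparable
#' (default); `reml = FALSE` refits by ML.
#'
#' @param records as in [fitLaydateModel()].
#' @param reml compare REML fits (default) or ML fits.
#' @return object of class `lrtResult`: `chi2`, `df`, `p`, and both models.
#' @export
lrtRandomSlope <- function(records, reml = TRUE) {
  rec <- prepareRecords(records, c("colony", "sex", "year", "lay_doy",
                                   "migration_distance_km",
                                   "colony_latitude"))
  rec$dist_scaled <- scaleCovariate(rec$migration_distance_km)
  rec$clat_scaled <- scaleCovariate(rec$colony_latitude)
  fitOne <- function(f, label) {
    tryCatch(
      suppressWarnings(withCallingHandlers(
        lme4::lmer(f, data = rec, REML = reml),
        message = function(m) invokeRestart("muffleMessage"))),
      error = function(e) stop("model '", label, "' failed to converge: ",
                               conditionMessage(e)))
  }
  m0 <- fitOne(lay_doy ~ year + sex + dist_scaled + clat_scaled + (1 | colony),
               "random intercept")
  m1 <- fitOne(lay_doy ~ year + sex + dist_scaled + clat_scaled +
                 (1 + dist_scaled | colony), "random slope")
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                        as.numeric(stats::logLik(m0))))
  out <- list(chi2 = chi2, df = 2L,
              p = stats::pchisq(chi2, df = 2, lower.tail = FALSE),
              reduced = m0, full = m1, reml = reml)
  class(out) <- "lrtResult"
  out
}

#' @export
print.lrtResult <- function(x, ...) {
  cat(sprintf("Random-slope LRT: chi2 = %.2f, df = %d, p = %.2f (%s)\n",
              x$chi2, x$df, x$p, if (x$reml) "REML" else "ML"))
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return list with `r`, `p`, `n`.
#' @export
pearsonCor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Residual diagnostics for a mixed-model fit
#'
#' Shapiro-Wilk normality test on the residuals, a fitted-vs-residual
#' spread summary (residual SD within fitted-value tertiles and the
#' correlation between absolute residuals and fitted values), and a pass
#' flag at the screening criterion p > 0.001.
#'
#' @param fit a `phenMixedFit`, a `merMod`/`lm`, or a numeric vector of
#'   residuals.
#' @param passAlpha normality screening level.
#' @return list of class `residDiagnostics`: `shapiroW`, `shapiroP`,
#'   `pass`, `spread` (per-tertile SD table or `NULL` when no fitted values
#'   are available), `absCor`.
#' @export
residualDiagnostics <- function(fit, passAlpha = 0.001) {
  if (inherits(fit, "phenMixedFit")) fit <- fit$model
  if (is.numeric(fit)) {
    r <- fit
    f <- NULL
  } else {
    r <- stats::residuals(fit)
    f <- stats::fitted(fit)
  }
  if (length(r) < 3) stop("need at least 3 residuals")
  sw <- stats::shapiro.test(if (length(r) > 5000) sample(r, 5000) else r)
  spread <- NULL
  absCor <- NA_real_
  if (!is.null(f)) {
    tert <- cut(f, stats::quantile(f, c(0, 1 / 3, 2 / 3, 1)),
                include.lowest = TRUE, labels = c("low", "mid", "high"))
    spread <- data.frame(fitted_tertile = levels(tert),
                         residual_sd = as.numeric(tapply(r, tert, stats::sd)),
                         stringsAsFactors = FALSE)
    absCor <- stats::cor(abs(r), f)
  }
  out <- list(shapiroW = unname(sw$statistic), shapiroP = sw$p.value,
              pass = sw$p.value > passAlpha, spread = spread, absCor = absCor)
  class(out) <- "residDiagnostics"
  out
}

#' @export
print.residDiagnostics <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk W = %.3f, p = %.3g -> %s (criterion p > 0.001)\n",
              x$shapiroW, x$shapiroP,
              if (x$pass) "residuals consistent with normality"
              else "normality rejected"))
  invisible(x)
}
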
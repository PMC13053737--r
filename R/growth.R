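#' Two-slope age basis
#'
#' Centers age at `center` (75 years) and scales per `scale` (10 years,
#' i.e. per decade), then splits the centered/scaled time `t` into the
#' two-piece linear spline `s1 = min(t, 0)` (change up to the knot) and
#' `s2 = max(t, 0)` (change after the knot).  Always `s1 + s2 = t` and at
#' most one of the two is nonzero.
#'
#' @param age numeric vector of ages in years.
#' @param center knot/centering age, default 75.
#' @param scale time scale in years, default 10 (slopes then estimate change
#'   per decade).
#' @return data frame with columns `t`, `s1`, `s2`.
#' @export
age_basis <- function(age, center = 75, scale = 10) {
  stopifnot(all(is.finite(age)))
  t <- (age - center) / scale
  data.frame(t = t, s1 = pmin(t, 0), s2 = pmax(t, 0))
}

#' Specify a two-slope latent growth curve model
#'
#' Describes the fixed and random structure of the growth model fitted by
#' [fit_lgcm()].  The outcome is modeled as
#' `intercept + slope1 * s1 + slope2 * s2` plus covariates; a named SES
#' covariate (or its between/within pair decomposition) can enter as a
#' covariate of any subset of `{intercept, slope1, slope2}`.  Random effects
#' sit at two levels, pair and person-within-pair, so phenotypic models are
#' corrected for twinness; each level carries an intercept or an
#' intercept + slopes covariance depending on `random`.
#'
#' @param outcome name of the outcome column on visits (default `"fai"`).
#' @param ses optional name of a person-level SES covariate.
#' @param ses_targets which growth parameters the SES covariate loads on;
#'   subset of `c("intercept", "slope1", "slope2")`.
#' @param decompose if `TRUE` the SES covariate enters as its between-pair
#'   mean (`<ses>_between`) and within-pair deviation (`<ses>_within`); the
#'   cohort must already carry those columns (see
#'   [add_pair_decomposition()]).
#' @param sex include a sex covariate of the intercept (female indicator).
#' @param parental_sei include parental SEI as an intercept covariate.
#' @param sex_interaction intercept-only sex-interaction layout: women are
#'   the base level and male adjustments enter as interactions of a male
#'   indicator with the between/within SES terms (requires `decompose`).
#' @param study_effect include fixed study-label effects (off by default).
#' @param random random-effect structure, one of `"full"` (unstructured
#'   intercept + s1 + s2 covariance at both levels), `"pair"` (unstructured
#'   at pair level, intercept-only at person level), `"diagonal"`
#'   (uncorrelated intercept + s1 + s2 at both levels) or `"intercept"`
#'   (intercepts only at both levels).
#' @return an object of class `lgcm_spec`.
#' @export
lgcm_spec <- function(outcome = "fai",
                      ses = NULL,
                      ses_targets = c("intercept", "slope1", "slope2"),
                      decompose = FALSE,
                      sex = TRUE,
                      parental_sei = FALSE,
                      sex_interaction = FALSE,
                      study_effect = FALSE,
                      random = c("full", "pair", "diagonal", "intercept")) {
  random <- match.arg(random)
  ses_targets <- match.arg(ses_targets,
                           c("intercept", "slope1", "slope2"),
                           several.ok = TRUE)
  if (sex_interaction && !decompose)
    stop("sex_interaction requires decompose = TRUE", call. = FALSE)
  structure(list(outcome = outcome, ses = ses, ses_targets = ses_targets,
                 decompose = decompose, sex = sex,
                 parental_sei = parental_sei,
                 sex_interaction = sex_interaction,
                 study_effect = study_effect, random = random),
            class = "lgcm_spec")
}

.ses_terms <- function(var, targets) {
  unlist(lapply(targets, function(tg)
    switch(tg,
           intercept = var,
           slope1 = paste0("s1:", var),
           slope2 = paste0("s2:", var))))
}

.random_formula <- function(random) {
  switch(random,
         full = "(1 + s1 + s2 | pair_id) + (1 + s1 + s2 | person_id)",
         pair = "(1 + s1 + s2 | pair_id) + (1 | person_id)",
         diagonal = "(1 + s1 + s2 || pair_id) + (1 + s1 + s2 || person_id)",
         intercept = "(1 | pair_id) + (1 | person_id)")
}

#' Build the model frame and formula for a growth model
#'
#' Merges persons and visits, computes the two-slope age basis, assembles
#' the covariate columns required by the spec and drops rows with a missing
#' outcome or missing covariates (listwise within row).  Observations are
#' grouped by pair through the `pair_id`/`person_id` grouping factors of the
#' random-effect formula; singleton persons keep both a pair-level and a
#' person-level effect of their own, whose variances simply add in their
#' marginal covariance.
#'
#' @param cohort a `cohort_table`; the outcome must be present on visits
#'   (e.g. after [add_fai()] or from [simulate_cohort()]).
#' @param spec an [lgcm_spec()].
#' @return an object of class `lgcm_design`: list with `data` (model
#'   frame), `formula`, `fixed_terms` and counts `n_obs`, `n_persons`,
#'   `n_pairs`.
#' @export
build_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "lgcm_spec"))
  frame <- cohort_frame(cohort)
  if (!spec$outcome %in% names(frame))
    stop("outcome column not found on visits: ", spec$outcome,
         call. = FALSE)
  basis <- age_basis(frame$age_years)
  d <- data.frame(y = frame[[spec$outcome]],
                  s1 = basis$s1, s2 = basis$s2,
                  pair_id = factor(frame$pair_id),
                  person_id = factor(frame$person_id),
                  stringsAsFactors = FALSE)

  fixed <- c("s1", "s2")
  if (spec$sex && !spec$sex_interaction) {
    d$sex_female <- as.numeric(frame$sex == "female")
    fixed <- c(fixed, "sex_female")
  }
  if (spec$parental_sei) {
    if (!"parental_sei" %in% names(frame))
      stop("parental_sei column not found", call. = FALSE)
    d$parental_sei <- frame$parental_sei
    fixed <- c(fixed, "parental_sei")
  }
  if (spec$study_effect) {
    d$study_label <- factor(frame$study_label)
    if (nlevels(d$study_label) > 1L) fixed <- c(fixed, "study_label")
  }

  if (!is.null(spec$ses)) {
    if (spec$decompose) {
      bcol <- paste0(spec$ses, "_between")
      wcol <- paste0(spec$ses, "_within")
      if (!all(c(bcol, wcol) %in% names(frame)))
        stop("between/within columns not found (run add_pair_decomposition",
             " first): ", bcol, ", ", wcol, call. = FALSE)
      d[[bcol]] <- frame[[bcol]]
      d[[wcol]] <- frame[[wcol]]
      if (spec$sex_interaction) {
        d$sex_male <- as.numeric(frame$sex == "male")
        fixed <- c(fixed, "sex_male", bcol, wcol,
                   paste0(bcol, ":sex_male"), paste0(wcol, ":sex_male"))
      } else {
        fixed <- c(fixed, .ses_terms(bcol, spec$ses_targets),
                   .ses_terms(wcol, spec$ses_targets))
      }
    } else {
      if (!spec$ses %in% names(frame))
        stop("SES column not found: ", spec$ses, call. = FALSE)
      d[[spec$ses]] <- frame[[spec$ses]]
      fixed <- c(fixed, .ses_terms(spec$ses, spec$ses_targets))
    }
  }

  used <- setdiff(unique(unlist(strsplit(fixed, ":", fixed = TRUE))),
                  c("s1", "s2"))
  keep <- !is.na(d$y)
  for (col in used) keep <- keep & !is.na(d[[col]])
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("empty design after missingness filtering", call. = FALSE)
  d <- droplevels(d)

  form <- stats::as.formula(paste(
    "y ~", paste(fixed, collapse = " + "), "+", .random_formula(spec$random)))
  structure(list(data = d, formula = form, fixed_terms = fixed,
                 spec = spec,
                 n_obs = nrow(d),
                 n_persons = nlevels(d$person_id),
                 n_pairs = nlevels(d$pair_id)),
            class = "lgcm_design")
}

.lgcm_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  is.null(msgs) || !any(grepl("failed to converge", msgs, ignore.case = TRUE))
}

#' Fit a two-slope latent growth curve model by maximum likelihood
#'
#' Maximizes the exact marginal Gaussian likelihood of the two-level
#' random-effects growth model (pair and person-within-pair) over fixed
#' effects and variance parameters, via [lme4::lmer()] with `REML = FALSE`
#' so that fixed-effect likelihood ratio tests between nested fits are
#' valid.  Covariance matrices are kept positive semi-definite by lme4's
#' Cholesky-factor parameterization.  On failure to converge the random
#' structure falls back automatically (`full` -> `diagonal` ->
#' `intercept`), and the structure actually used is recorded.  Wald p-values
#' use a normal reference.
#'
#' @param x a `cohort_table` or a prebuilt [build_design()] object.
#' @param spec an [lgcm_spec()] (ignored when `x` is already a design).
#' @param REML fit by REML instead of ML (default `FALSE`; REML fits are
#'   refused by [lrt()]).
#' @param fallback allow the random-structure fallback chain (default
#'   `TRUE`).
#' @return an object of class `lgcm_fit` with elements `coefficients`
#'   (term / estimate / se / z / p table), `vcov`, `varcorr`, `sigma`,
#'   `logLik`, `df` (number of estimated parameters), `n_obs`, `n_persons`,
#'   `n_pairs`, `converged`, `random_structure`, `fallback_path`, `REML`
#'   and the underlying `merMod` in `$fit`.
#' @export
fit_lgcm <- function(x, spec = lgcm_spec(), REML = FALSE, fallback = TRUE) {
  design <- if (inherits(x, "lgcm_design")) x else build_design(x, spec)
  spec <- design$spec

  # rank check on the fixed design
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(design$fixed_terms, collapse = "+"))),
    design$data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient fixed design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "), call. = FALSE)

  chain <- spec$random
  if (fallback)
    chain <- unique(c(chain, switch(spec$random,
                                    full = c("diagonal", "intercept"),
                                    pair = "intercept",
                                    diagonal = "intercept",
                                    intercept = NULL)))
  tried <- character(0)
  fit <- NULL
  used <- NA_character_
  for (rs in chain) {
    form <- stats::as.formula(paste(
      "y ~", paste(design$fixed_terms, collapse = " + "), "+",
      .random_formula(rs)))
    cand <- tryCatch(
      suppressMessages(lme4::lmer(
        form, data = design$data, REML = REML,
        control = lme4::lmerControl(
          check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
          check.conv.singular = "ignore", calc.derivs = TRUE))),
      error = function(e) e)
    tried <- c(tried, rs)
    if (inherits(cand, "merMod")) {
      fit <- cand
      used <- rs
      if (.lgcm_converged(cand)) break
      # keep as best-so-far but try a simpler structure
      if (rs != chain[length(chain)]) next else break
    }
  }
  if (is.null(fit))
    stop("growth model failed to fit under all random structures tried (",
         paste(tried, collapse = " -> "), ")", call. = FALSE)

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  z <- beta / se
  coefs <- data.frame(term = names(beta),
                      estimate = unname(beta),
                      se = unname(se),
                      z = unname(z),
                      p = 2 * stats::pnorm(-abs(unname(z))),
                      row.names = NULL, stringsAsFactors = FALSE)
  ll <- stats::logLik(fit)

  structure(list(coefficients = coefs,
                 vcov = V,
                 varcorr = lme4::VarCorr(fit),
                 sigma = stats::sigma(fit),
                 logLik = as.numeric(ll),
                 df = attr(ll, "df"),
                 n_obs = design$n_obs,
                 n_persons = design$n_persons,
                 n_pairs = design$n_pairs,
                 converged = .lgcm_converged(fit),
                 random_structure = used,
                 fallback_path = tried,
                 REML = REML,
                 spec = spec,
                 fit = fit),
            class = "lgcm_fit")
}

#' @export
print.lgcm_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Two-slope LGCM (%s), logLik %.2f (%d parameters)\n",
    if (x$REML) "REML" else "ML", x$logLik, x$df))
  cat(sprintf("  %d observations, %d persons, %d pairs; random: %s%s\n",
              x$n_obs, x$n_persons, x$n_pairs, x$random_structure,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract a coefficient row from a growth-model fit
#'
#' @param fit an `lgcm_fit`.
#' @param term coefficient name as in `fit$coefficients$term` (interaction
#'   order is normalized, so `"s1:x"` and `"x:s1"` both match).
#' @return one-row data frame (estimate, se, z, p) or `NULL` if absent.
#' @export
coef_row <- function(fit, term) {
  tab <- fit$coefficients
  norm <- function(s) vapply(strsplit(s, ":", fixed = TRUE),
                             function(p) paste(sort(p), collapse = ":"), "")
  hit <- which(norm(tab$term) == norm(term))
  if (length(hit) == 0L) return(NULL)
  tab[hit[1L], , drop = FALSE]
}

#' Likelihood ratio test between nested growth-model fits
#'
#' Computes `2 * (logLik_full - logLik_null)` and refers it to a chi-square
#' with degrees of freedom equal to the difference in number of estimated
#' parameters.  Both fits must be ML (not REML) and on the same
#' observations; a meaningfully negative statistic signals a convergence
#' problem in the full fit and is an error, while tiny negative values
#' (within numerical tolerance) are clamped to zero.
#'
#' @param fit_null,fit_full nested `lgcm_fit` objects (null within full).
#' @param tol negative-statistic tolerance, default `1e-6 * |logLik|`.
#' @return list of class `lgcm_lrt` with `statistic`, `df`, `p`.
#' @export
lrt <- function(fit_null, fit_full, tol = NULL) {
  stopifnot(inherits(fit_null, "lgcm_fit"), inherits(fit_full, "lgcm_fit"))
  if (fit_null$REML || fit_full$REML)
    stop("LRT requires ML fits (REML = FALSE)", call. = FALSE)
  if (fit_null$n_obs != fit_full$n_obs)
    stop("fits are on different observation sets (", fit_null$n_obs,
         " vs ", fit_full$n_obs, " rows)", call. = FALSE)
  df <- fit_full$df - fit_null$df
  if (df < 0L)
    stop("models not nested in the expected direction (df difference ",
         df, ")", call. = FALSE)
  stat <- 2 * (fit_full$logLik - fit_null$logLik)
  if (is.null(tol)) tol <- 1e-6 * max(1, abs(fit_full$logLik))
  if (stat < -tol)
    stop("negative LRT statistic (", format(stat),
         "): full model apparently not converged", call. = FALSE)
  stat <- max(stat, 0)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p), class = "lgcm_lrt")
}

#' @export
print.lgcm_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}
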
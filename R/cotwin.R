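#' Between-/within-pair decomposition of a person-level variable
#'
#' Splits a variable measured on complete twin pairs into the pair mean
#' (between-pair component) and each member's deviation from that mean
#' (within-pair component).  The two within values of a pair sum to zero and
#' `between + within` reconstructs each member's value exactly.
#'
#' @param cohort a `cohort_table` restricted to complete pairs on `var`
#'   (run [complete_pairs()] first; an incomplete pair is an error).
#' @param var name of the person-level column to decompose.
#' @return data frame with `person_id`, `pair_id`, `value`, `between`,
#'   `within` (one row per person).
#' @seealso [add_pair_decomposition()] to attach the components as columns.
#' @export
decompose_between_within <- function(cohort, var) {
  stopifnot(inherits(cohort, "cohort_table"))
  p <- cohort$persons
  if (!var %in% names(p))
    stop("person-level column not found: ", var, call. = FALSE)
  size <- table(p$pair_id)
  bad <- names(size)[size != 2L]
  if (length(bad) > 0L)
    stop("incomplete pair(s) encountered (run complete_pairs first): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  if (any(is.na(p[[var]])))
    stop("missing '", var, "' inside complete pairs; run ",
         "complete_pairs(cohort, require = \"", var, "\")", call. = FALSE)
  pm <- tapply(p[[var]], p$pair_id, mean)
  between <- as.numeric(pm[as.character(p$pair_id)])
  data.frame(person_id = p$person_id,
             pair_id = p$pair_id,
             value = p[[var]],
             between = between,
             within = p[[var]] - between,
             stringsAsFactors = FALSE)
}

#' Attach between/within components to the persons table
#'
#' Runs [decompose_between_within()] and stores the components as
#' `<var>_between` and `<var>_within` columns, ready for a decomposed
#' [lgcm_spec()].
#'
#' @inheritParams decompose_between_within
#' @return the cohort with the two extra person-level columns.
#' @export
add_pair_decomposition <- function(cohort, var) {
  dec <- decompose_between_within(cohort, var)
  idx <- match(cohort$persons$person_id, dec$person_id)
  cohort$persons[[paste0(var, "_between")]] <- dec$between[idx]
  cohort$persons[[paste0(var, "_within")]] <- dec$within[idx]
  cohort
}

.subset_cohort <- function(cohort, person_keep) {
  persons <- cohort$persons[person_keep, , drop = FALSE]
  visits <- cohort$visits[cohort$visits$person_id %in% persons$person_id, ,
                          drop = FALSE]
  cohort_table(persons, visits, validate = FALSE)
}

.cotwin_term <- function(comp_col, target) {
  switch(target,
         intercept = comp_col,
         slope1 = paste0("s1:", comp_col),
         slope2 = paste0("s2:", comp_col))
}

#' Stratified co-twin control growth models
#'
#' Fits the between-/within-pair covariate growth model on complete pairs,
#' in the full co-twin sample and separately by zygosity, for a chosen SES
#' variable and target growth parameters.  The MZ and DZ strata partition
#' the full sample.  Comparing the attenuation of the within-pair effect
#' across strata is the engine of the co-twin control design: a causal
#' SES effect survives within pairs at every level of relatedness, genetic
#' confounding suppresses it in MZ pairs only, and shared-environmental
#' confounding suppresses it equally in both zygosities.
#'
#' @param cohort a scored `cohort_table` (outcome present on visits).
#' @param ses person-level SES column name.
#' @param targets growth parameters the SES components load on, subset of
#'   `c("intercept", "slope1", "slope2")`; chosen from a prior phenotypic
#'   fit (default intercept only).
#' @param strata subset of `c("full", "MZ", "DZ")`.
#' @param outcome outcome column, default `"fai"`.
#' @param parental_sei include parental SEI as a covariate (the analysis
#'   convention is to include it only for the financial-strain model).
#' @param random random-effect structure passed to [lgcm_spec()]; default
#'   `"full"`.
#' @param min_pairs strata with fewer complete pairs are skipped with a
#'   warning (default 10).
#' @param sex include the sex covariate (default `TRUE`).
#' @return object of class `cotwin_result`: `table` (stratum x target x
#'   between/within estimates), `n_pairs`, `fits`, `ses`, `targets`.
#' @export
fit_cotwin_models <- function(cohort, ses,
                              targets = "intercept",
                              strata = c("full", "MZ", "DZ"),
                              outcome = "fai",
                              parental_sei = FALSE,
                              random = "full",
                              min_pairs = 10L,
                              sex = TRUE) {
  targets <- match.arg(targets, c("intercept", "slope1", "slope2"),
                       several.ok = TRUE)
  strata <- match.arg(strata, c("full", "MZ", "DZ"), several.ok = TRUE)
  cc <- complete_pairs(cohort, require = ses)
  if (parental_sei) cc <- complete_pairs(cc, require = "parental_sei")
  if (nrow(cc$persons) == 0L)
    stop("no complete pairs on '", ses, "'", call. = FALSE)
  cc <- add_pair_decomposition(cc, ses)
  bcol <- paste0(ses, "_between")
  wcol <- paste0(ses, "_within")

  spec <- lgcm_spec(outcome = outcome, ses = ses, ses_targets = targets,
                    decompose = TRUE, sex = sex,
                    parental_sei = parental_sei, random = random)

  fits <- list()
  rows <- list()
  n_pairs <- stats::setNames(integer(length(strata)), strata)
  for (st in strata) {
    sub <- if (st == "full") cc else
      .subset_cohort(cc, cc$persons$zygosity == st)
    np <- length(unique(sub$persons$pair_id))
    n_pairs[[st]] <- np
    if (np < min_pairs) {
      warning("stratum ", st, " skipped: ", np, " < ", min_pairs,
              " complete pairs", call. = FALSE)
      next
    }
    fit <- fit_lgcm(sub, spec)
    fits[[st]] <- fit
    for (tg in targets) {
      for (eff in c("between", "within")) {
        col <- if (eff == "between") bcol else wcol
        cr <- coef_row(fit, .cotwin_term(col, tg))
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, target = tg, effect = eff,
          estimate = cr$estimate, se = cr$se, z = cr$z, p = cr$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    stop("no stratum could be fitted", call. = FALSE)
  structure(list(table = do.call(rbind, rows),
                 n_pairs = n_pairs,
                 fits = fits,
                 ses = ses, targets = targets, outcome = outcome,
                 parental_sei = parental_sei),
            class = "cotwin_result")
}

#' @export
print.cotwin_result <- function(x, digits = 3, ...) {
  cat("Co-twin control estimates for", x$ses, "on",
      paste(x$targets, collapse = ", "), "\n")
  cat("  complete pairs:",
      paste(names(x$n_pairs), x$n_pairs, sep = " = ", collapse = ", "),
      "\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

.cotwin_cell <- function(cotwin, stratum, target, effect) {
  tab <- cotwin$table
  row <- tab[tab$stratum == stratum & tab$target == target &
               tab$effect == effect, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  row
}

#' Compare the MZ and DZ within-pair estimates
#'
#' Tests whether the within-pair SES effect is smaller in MZ than in DZ
#' pairs (the genetic-confounding signature).  The default combines the two
#' stratified estimates,
#' `z = (within_DZ - within_MZ) / sqrt(SE_MZ^2 + SE_DZ^2)`,
#' with a two-sided normal p-value.  Alternatively a single joint model on
#' MZ + DZ pairs with a zygosity-by-within interaction supplies the Wald z
#' of the interaction.
#'
#' @param cotwin a `cotwin_result` with both zygosity strata fitted.
#' @param target growth parameter, default `"intercept"`.
#' @param method `"se"` (stratified SE combination, default) or `"joint"`.
#' @param cohort required for `method = "joint"`: the cohort the result was
#'   computed from.
#' @return list with `z`, `p`, `method`, `within_mz`, `within_dz` (each
#'   estimate with SE).
#' @export
compare_within_mz_dz <- function(cotwin, target = "intercept",
                                 method = c("se", "joint"),
                                 cohort = NULL) {
  stopifnot(inherits(cotwin, "cotwin_result"))
  method <- match.arg(method)
  wmz <- .cotwin_cell(cotwin, "MZ", target, "within")
  wdz <- .cotwin_cell(cotwin, "DZ", target, "within")
  if (is.null(wmz) || is.null(wdz))
    stop("both MZ and DZ strata must be fitted for the comparison",
         call. = FALSE)
  if (method == "se") {
    z <- (wdz$estimate - wmz$estimate) / sqrt(wmz$se^2 + wdz$se^2)
  } else {
    if (is.null(cohort))
      stop("method = \"joint\" needs the cohort", call. = FALSE)
    z <- .joint_zygosity_z(cohort, cotwin, target)
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)), method = method,
       within_mz = c(estimate = wmz$estimate, se = wmz$se),
       within_dz = c(estimate = wdz$estimate, se = wdz$se))
}

# joint model: within and between terms plus zygosity interaction with the
# within term; returns the Wald z of the DZ-vs-MZ within difference
.joint_zygosity_z <- function(cohort, cotwin, target) {
  cc <- complete_pairs(cohort, require = cotwin$ses)
  if (cotwin$parental_sei) cc <- complete_pairs(cc, require = "parental_sei")
  cc <- add_pair_decomposition(cc, cotwin$ses)
  frame <- cohort_frame(cc)
  basis <- age_basis(frame$age_years)
  bcol <- paste0(cotwin$ses, "_between")
  wcol <- paste0(cotwin$ses, "_within")
  d <- data.frame(y = frame[[cotwin$outcome]],
                  s1 = basis$s1, s2 = basis$s2,
                  sex_female = as.numeric(frame$sex == "female"),
                  b = frame[[bcol]], w = frame[[wcol]],
                  dz = as.numeric(frame$zygosity == "DZ"),
                  pair_id = factor(frame$pair_id),
                  person_id = factor(frame$person_id))
  if (cotwin$parental_sei) d$parental_sei <- frame$parental_sei
  tgt <- switch(target, intercept = "", slope1 = "s1:", slope2 = "s2:")
  fixed <- c("s1", "s2", "sex_female",
             if (cotwin$parental_sei) "parental_sei",
             paste0(tgt, "b"), paste0(tgt, "w"), "dz",
             paste0(tgt, "w:dz"))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  form <- stats::as.formula(paste(
    "y ~", paste(fixed, collapse = " + "),
    "+ (1 | pair_id) + (1 | person_id)"))
  fit <- suppressMessages(lme4::lmer(
    form, data = d, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  nm <- names(beta)
  hit <- grepl("w:dz|dz:.*w|w.*:dz", nm) & grepl("w", nm) & grepl("dz", nm)
  hit <- which(hit)[1L]
  unname(beta[hit] / se[hit])
}

#' Default thresholds for the confounding classification
#'
#' The classification of [classify_confounding()] is driven by attenuation
#' ratios `r_g = within_g / between_g` per zygosity stratum and by the
#' MZ-vs-DZ comparison.  These numeric thresholds make the verbal
#' attenuation logic reproducible; they are configurable defaults, not
#' estimates.
#'
#' @param ratio_keep minimum ratio counted as "no attenuation" (0.7).
#' @param ratio_drop maximum ratio counted as "effect gone" (0.3).
#' @param equal_band maximum `|r_MZ - r_DZ|` counted as "equal attenuation"
#'   (0.2).
#' @param alpha significance level for the within-effect Wald tests (0.05).
#' @param z_thresh one-sided z threshold for the MZ-vs-DZ comparison (1.64).
#' @return named list of thresholds.
#' @export
confounding_thresholds <- function(ratio_keep = 0.7, ratio_drop = 0.3,
                                   equal_band = 0.2, alpha = 0.05,
                                   z_thresh = 1.64) {
  list(ratio_keep = ratio_keep, ratio_drop = ratio_drop,
       equal_band = equal_band, alpha = alpha, z_thresh = z_thresh)
}

#' Classify an SES-outcome association as causal or confounded
#'
#' Applies the attenuation decision rule to a stratified co-twin result.
#' Writing `r_g = within_g / between_g` for the attenuation ratio in
#' stratum `g` and `z` for the sign-aligned MZ-vs-DZ within comparison:
#'
#' 1. *consistent_causal* - within effect significant in both MZ and DZ
#'    strata and `r_MZ, r_DZ >= ratio_keep` (no attenuation at any level of
#'    relatedness);
#' 2. *genetic_confounding* - within effect non-significant in MZ, the
#'    comparison favors DZ (`z > z_thresh`) or `r_MZ < ratio_drop`, while
#'    `r_DZ >= ratio_keep` (attenuation only where genes are fully shared);
#' 3. *shared_env_confounding* - within effect non-significant in both
#'    strata with `|r_MZ - r_DZ| < equal_band` (equal attenuation,
#'    untouched by relatedness);
#' 4. otherwise *indeterminate*.
#'
#' The rule is invariant to a sign reversal of the SES variable: ratios are
#' scale-free and the comparison z is aligned with the sign of the full
#' between-pair effect.  The verdict is reproducible from the returned
#' evidence and thresholds alone.
#'
#' @param cotwin a `cotwin_result` with `full`, `MZ` and `DZ` strata.
#' @param target growth parameter, default `"intercept"`.
#' @param thresholds see [confounding_thresholds()].
#' @return object of class `confounding_verdict` with `verdict`, `evidence`
#'   (estimates, ratios, significance flags, comparison z, low-power flag)
#'   and `thresholds`.
#' @export
classify_confounding <- function(cotwin, target = "intercept",
                                 thresholds = confounding_thresholds()) {
  stopifnot(inherits(cotwin, "cotwin_result"))
  need <- c("full", "MZ", "DZ")
  have <- vapply(need, function(st)
    !is.null(.cotwin_cell(cotwin, st, target, "within")), TRUE)
  if (!all(have))
    stop("classification needs full, MZ and DZ strata (missing: ",
         paste(need[!have], collapse = ", "), ")", call. = FALSE)

  cell <- function(st, eff) .cotwin_cell(cotwin, st, target, eff)
  wmz <- cell("MZ", "within"); bmz <- cell("MZ", "between")
  wdz <- cell("DZ", "within"); bdz <- cell("DZ", "between")
  bfull <- cell("full", "between"); wfull <- cell("full", "within")

  ratio <- function(w, b)
    if (abs(b$estimate) < 1e-12) NA_real_ else w$estimate / b$estimate
  r_mz <- ratio(wmz, bmz)
  r_dz <- ratio(wdz, bdz)
  sig_mz <- wmz$p < thresholds$alpha
  sig_dz <- wdz$p < thresholds$alpha
  sgn <- sign(bfull$estimate)
  if (sgn == 0) sgn <- 1
  z_cmp <- sgn * (wdz$estimate - wmz$estimate) /
    sqrt(wmz$se^2 + wdz$se^2)
  low_power <- max(wmz$se, wdz$se) > abs(bfull$estimate)

  verdict <- if (sig_mz && sig_dz &&
                 !is.na(r_mz) && !is.na(r_dz) &&
                 r_mz >= thresholds$ratio_keep &&
                 r_dz >= thresholds$ratio_keep) {
    "consistent_causal"
  } else if (!sig_mz &&
             (z_cmp > thresholds$z_thresh ||
              (!is.na(r_mz) && r_mz < thresholds$ratio_drop)) &&
             !is.na(r_dz) && r_dz >= thresholds$ratio_keep) {
    "genetic_confounding"
  } else if (!sig_mz && !sig_dz &&
             !is.na(r_mz) && !is.na(r_dz) &&
             abs(r_mz - r_dz) < thresholds$equal_band) {
    "shared_env_confounding"
  } else {
    "indeterminate"
  }

  structure(list(
    verdict = verdict,
    evidence = list(
      target = target,
      between_full = c(estimate = bfull$estimate, se = bfull$se),
      within_full = c(estimate = wfull$estimate, se = wfull$se),
      within_mz = c(estimate = wmz$estimate, se = wmz$se, p = wmz$p),
      within_dz = c(estimate = wdz$estimate, se = wdz$se, p = wdz$p),
      ratio_mz = r_mz, ratio_dz = r_dz,
      sig_mz = sig_mz, sig_dz = sig_dz,
      z_mz_vs_dz = z_cmp,
      low_power = low_power),
    thresholds = thresholds),
    class = "confounding_verdict")
}

#' @export
print.confounding_verdict <- function(x, ...) {
  ev <- x$evidence
  cat("Confounding classification (", ev$target, "): ", x$verdict, "\n",
      sep = "")
  cat(sprintf("  within MZ %.3f (SE %.3f, p %.3g); within DZ %.3f (SE %.3f, p %.3g)\n",
              ev$within_mz["estimate"], ev$within_mz["se"], ev$within_mz["p"],
              ev$within_dz["estimate"], ev$within_dz["se"], ev$within_dz["p"]))
  cat(sprintf("  attenuation ratios: MZ %.2f, DZ %.2f; MZ-vs-DZ z = %.2f\n",
              ev$ratio_mz, ev$ratio_dz, ev$z_mz_vs_dz))
  if (isTRUE(ev$low_power)) cat("  note: low power (wide within SEs)\n")
  invisible(x)
}

#' Sex-interaction co-twin models
#'
#' Fits, per stratum, the between/within covariate model with sex
#' interactions on the intercept only: women form the base level and male
#' adjustments enter as interactions of a male indicator with the between-
#' and within-pair SES components.  Swapping the roles of the sexes flips
#' the corrections onto the other base level.
#'
#' @inheritParams fit_cotwin_models
#' @return object of class `sexdiff_result` with `table` (stratum x effect
#'   with effects `between_women`, `between_men_correction`, `within_women`,
#'   `within_men_correction`, `sex_main`), `n_pairs`, `fits`,
#'   `inestimable` (strata where a single sex made the interaction
#'   inestimable).
#' @export
fit_sex_interaction <- function(cohort, ses,
                                strata = c("full", "MZ", "DZ"),
                                outcome = "fai",
                                parental_sei = FALSE,
                                random = "full",
                                min_pairs = 10L) {
  strata <- match.arg(strata, c("full", "MZ", "DZ"), several.ok = TRUE)
  cc <- complete_pairs(cohort, require = ses)
  if (parental_sei) cc <- complete_pairs(cc, require = "parental_sei")
  cc <- add_pair_decomposition(cc, ses)
  bcol <- paste0(ses, "_between")
  wcol <- paste0(ses, "_within")
  spec <- lgcm_spec(outcome = outcome, ses = ses, ses_targets = "intercept",
                    decompose = TRUE, sex = FALSE,
                    parental_sei = parental_sei,
                    sex_interaction = TRUE, random = random)
  fits <- list(); rows <- list()
  inestimable <- character(0)
  n_pairs <- stats::setNames(integer(length(strata)), strata)
  for (st in strata) {
    sub <- if (st == "full") cc else
      .subset_cohort(cc, cc$persons$zygosity == st)
    np <- length(unique(sub$persons$pair_id))
    n_pairs[[st]] <- np
    if (np < min_pairs) {
      warning("stratum ", st, " skipped: ", np, " < ", min_pairs,
              " complete pairs", call. = FALSE)
      next
    }
    if (length(unique(sub$persons$sex)) < 2L) {
      inestimable <- c(inestimable, st)
      warning("stratum ", st, " has a single sex: interaction inestimable",
              call. = FALSE)
      next
    }
    fit <- fit_lgcm(sub, spec)
    fits[[st]] <- fit
    grab <- function(term, label) {
      cr <- coef_row(fit, term)
      data.frame(stratum = st, effect = label,
                 estimate = cr$estimate, se = cr$se, z = cr$z, p = cr$p,
                 stringsAsFactors = FALSE)
    }
    rows <- c(rows, list(
      grab(bcol, "between_women"),
      grab(paste0(bcol, ":sex_male"), "between_men_correction"),
      grab(wcol, "within_women"),
      grab(paste0(wcol, ":sex_male"), "within_men_correction"),
      grab("sex_male", "sex_main")))
  }
  if (length(rows) == 0L)
    stop("no stratum could be fitted", call. = FALSE)
  structure(list(table = do.call(rbind, rows),
                 n_pairs = n_pairs, fits = fits,
                 inestimable = inestimable,
                 ses = ses, outcome = outcome),
            class = "sexdiff_result")
}

#' @export
print.sexdiff_result <- function(x, digits = 3, ...) {
  cat("Sex-interaction co-twin estimates for", x$ses,
      "(women base, male corrections)\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  if (length(x$inestimable) > 0L)
    cat("  inestimable (single sex):",
        paste(x$inestimable, collapse = ", "), "\n")
  invisible(x)
}

#' Twin intraclass correlations and Falconer components
#'
#' Computes the double-entered Pearson (intraclass) correlation of a
#' person-level variable within complete pairs, per zygosity, and the
#' Falconer point estimates derived from them via [solve_ace()].
#'
#' @param cohort a `cohort_table`.
#' @param var person-level column name.
#' @param min_pairs minimum complete pairs per zygosity (default 3).
#' @return list with `r_mz`, `r_dz`, `n_mz`, `n_dz` (pair counts) and
#'   `ace` (an `ace_components` object, possibly boundary-flagged).
#' @export
twin_correlations <- function(cohort, var, min_pairs = 3L) {
  cc <- complete_pairs(cohort, require = var)
  p <- cc$persons
  r_for <- function(zyg) {
    sub <- p[p$zygosity == zyg, , drop = FALSE]
    sub <- sub[order(sub$pair_id), , drop = FALSE]
    np <- nrow(sub) / 2L
    if (np < min_pairs)
      stop("fewer than ", min_pairs, " complete ", zyg, " pairs",
           call. = FALSE)
    x1 <- sub[[var]][seq(1L, nrow(sub), by = 2L)]
    x2 <- sub[[var]][seq(2L, nrow(sub), by = 2L)]
    # double entry: each pair contributes both orderings
    list(r = stats::cor(c(x1, x2), c(x2, x1)), n = np)
  }
  mz <- r_for("MZ"); dz <- r_for("DZ")
  ace <- if (abs(mz$r) < 1 && abs(dz$r) < 1) solve_ace(mz$r, dz$r)
  list(r_mz = mz$r, r_dz = dz$r, n_mz = mz$n, n_dz = dz$n, ace = ace)
}

#' Fisher z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.  Swapping the two groups flips the sign of z.
#'
#' @param r1,r2 correlations (strictly inside (-1, 1)).
#' @param n1,n2 group sizes (> 3).
#' @return list with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  if (any(c(n1, n2) <= 3))
    stop("group sizes must exceed 3", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
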
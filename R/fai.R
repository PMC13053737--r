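#' Sex-adjust grip strength
#'
#' Residualizes raw grip strength on sex, using an intercept + sex linear
#' model estimated on a declared reference (baseline) subset.  A grip value
#' equal to its sex-specific reference mean therefore maps to 0.
#'
#' @param grip numeric vector of raw grip values to adjust (may contain `NA`).
#' @param sex `"male"`/`"female"` vector aligned with `grip`.
#' @param reference data frame with columns `grip` and `sex`, the baseline
#'   subset on which the adjustment is estimated; needs both sexes with at
#'   least two observations each.
#' @return numeric vector of residuals, `NA` where `grip` or `sex` is
#'   missing.
#' @export
adjust_grip <- function(grip, sex, reference) {
  ref <- reference[!is.na(reference$grip) & !is.na(reference$sex), ,
                   drop = FALSE]
  counts <- table(factor(ref$sex, levels = c("male", "female")))
  if (any(counts < 2L))
    stop("grip adjustment needs >= 2 reference observations per sex ",
         "(got male = ", counts[["male"]], ", female = ", counts[["female"]],
         ")", call. = FALSE)
  fit <- stats::lm(grip ~ sex, data = ref)
  pred <- rep(NA_real_, length(grip))
  known <- !is.na(sex)
  pred[known] <- stats::predict(fit, newdata = data.frame(sex = sex[known]))
  grip - pred
}

#' Volume-adjust peak expiratory flow
#'
#' Divides peak expiratory flow by squared height in meters.  Missing height
#' propagates to a missing adjusted value (component-level missingness);
#' non-positive heights are rejected.
#'
#' @param pef numeric vector of raw peak-flow values.
#' @param height_m numeric vector of heights in meters.
#' @return `pef / height_m^2`.
#' @export
adjust_pef <- function(pef, height_m) {
  bad <- !is.na(height_m) & height_m <= 0
  if (any(bad))
    stop("non-positive height_m at position(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "), call. = FALSE)
  pef / height_m^2
}

.fai_components <- c("grip", "pef", "gait", "sensory")

#' Estimate a frozen FAI standardization from a baseline reference
#'
#' Builds the standardization used by [score_fai()]: grip is sex-adjusted
#' (coefficients estimated here), peak flow is height-squared-adjusted, and
#' each of the four components (grip, peak flow, gait, sensory) gets a
#' baseline mean and SD.  The sensory component is the average of the
#' baseline z-scores of self-reported vision and hearing.  Components whose
#' `reverse` flag is `TRUE` (higher raw value = better function) are sign
#' flipped so that higher always means poorer.  Finally the baseline
#' distribution of the composite (mean of available component z-scores) is
#' recorded so that composites can be mapped to the T metric (mean 50, SD 10
#' on the baseline reference).
#'
#' The spec is estimated once on the reference subset and then frozen;
#' follow-up waves are scored against it.  It can be saved with
#' [write_fai_spec()] and reloaded with [read_fai_spec()].
#'
#' @param cohort a `cohort_table` with biomarker columns `grip`, `pef`,
#'   `height_m`, `gait`, `vision_self`, `hearing_self` on visits.
#' @param baseline which visits form the reference: `"first"` (default, each
#'   person's earliest visit) or a logical vector over `cohort_frame(cohort)`
#'   rows.
#' @param reverse named logical vector over components `grip`, `pef`,
#'   `gait`, `sensory`; `TRUE` flips the component so higher = poorer.
#'   Defaults reverse grip and peak flow (higher raw = better) and leave
#'   gait (time to walk) and sensory difficulty unreversed.
#' @param min_components minimum number of non-missing components for a
#'   composite (default 3); fewer gives a missing FAI, not an error.
#' @return an object of class `fai_spec`.
#' @export
fai_standardization <- function(cohort,
                                baseline = "first",
                                reverse = c(grip = TRUE, pef = TRUE,
                                            gait = FALSE, sensory = FALSE),
                                min_components = 3L) {
  frame <- cohort_frame(cohort)
  base_idx <- .baseline_index(frame, baseline)
  ref <- frame[base_idx, , drop = FALSE]
  reverse <- .check_reverse(reverse)

  grip_ref <- ref[!is.na(ref$grip) & !is.na(ref$sex), c("grip", "sex")]
  counts <- table(factor(grip_ref$sex, levels = c("male", "female")))
  if (any(counts < 2L))
    stop("baseline reference must contain both sexes (>= 2 each) for the ",
         "grip adjustment", call. = FALSE)
  grip_fit <- stats::lm(grip ~ sex, data = grip_ref)
  grip_coef <- stats::coef(grip_fit)

  raw <- .fai_raw_components(ref, grip_coef)
  stats_tab <- lapply(raw[c("grip", "pef", "gait", "vision", "hearing")],
                      function(x) {
                        m <- mean(x, na.rm = TRUE)
                        s <- stats::sd(x, na.rm = TRUE)
                        if (!is.finite(s) || s <= 0)
                          stop("degenerate baseline SD for an FAI component",
                               call. = FALSE)
                        c(mean = m, sd = s)
                      })

  spec <- structure(
    list(grip_coef = grip_coef,
         component_stats = stats_tab,
         reverse = reverse,
         min_components = as.integer(min_components),
         composite_mean = 0, composite_sd = 1,
         tscore_mean = 50, tscore_sd = 10),
    class = "fai_spec")

  comp <- .fai_composite(ref, spec)
  ok <- !is.na(comp$composite)
  if (sum(ok) < 2L)
    stop("fewer than 2 scorable baseline composites", call. = FALSE)
  spec$composite_mean <- mean(comp$composite[ok])
  spec$composite_sd <- stats::sd(comp$composite[ok])
  if (spec$composite_sd <= 0)
    stop("degenerate baseline composite SD", call. = FALSE)
  spec
}

.check_reverse <- function(reverse) {
  if (is.null(names(reverse)) ||
      !all(.fai_components %in% names(reverse)))
    stop("'reverse' must be a named logical vector over components ",
         paste(.fai_components, collapse = ", "), call. = FALSE)
  as.logical(reverse[.fai_components])
}

.baseline_index <- function(frame, baseline) {
  if (is.logical(baseline)) {
    stopifnot(length(baseline) == nrow(frame))
    return(which(baseline))
  }
  if (identical(baseline, "first")) {
    first_age <- tapply(frame$age_years, frame$person_id, min)
    return(which(frame$age_years ==
                   first_age[as.character(frame$person_id)]))
  }
  stop("'baseline' must be \"first\" or a logical vector", call. = FALSE)
}

# raw (adjusted, un-standardized) component values for a visit frame
.fai_raw_components <- function(frame, grip_coef) {
  pred <- unname(grip_coef[1]) +
    unname(grip_coef["sexmale"] %||% 0) * (frame$sex == "male")
  list(grip = frame$grip - pred,
       pef = adjust_pef(frame$pef, frame$height_m),
       gait = frame$gait,
       vision = frame$vision_self,
       hearing = frame$hearing_self)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# component z-scores (orientation applied) and composite for a visit frame
.fai_composite <- function(frame, spec) {
  raw <- .fai_raw_components(frame, spec$grip_coef)
  z <- function(x, name) {
    st <- spec$component_stats[[name]]
    (x - st["mean"]) / st["sd"]
  }
  sgn <- ifelse(spec$reverse, -1, 1)
  names(sgn) <- .fai_components
  zv <- z(raw$vision, "vision")
  zh <- z(raw$hearing, "hearing")
  sens <- rowMeans(cbind(zv, zh), na.rm = TRUE)
  sens[is.na(zv) & is.na(zh)] <- NA_real_
  zmat <- cbind(grip = sgn["grip"] * z(raw$grip, "grip"),
                pef = sgn["pef"] * z(raw$pef, "pef"),
                gait = sgn["gait"] * z(raw$gait, "gait"),
                sensory = sgn["sensory"] * sens)
  n_used <- rowSums(!is.na(zmat))
  composite <- rowMeans(zmat, na.rm = TRUE)
  composite[n_used < spec$min_components] <- NA_real_
  list(z = zmat, composite = composite, n_components_used = n_used)
}

#' Score the Functional Aging Index
#'
#' Applies a frozen [fai_standardization()] to every visit: each available
#' component is z-scored against its baseline mean/SD and oriented so higher
#' = poorer, the composite is the mean of available component z-scores
#' (missing tolerated down to `min_components`), the composite is
#' re-standardized against the baseline composite distribution, and mapped
#' to the T metric `50 + 10 z`.  Higher FAI means poorer functioning.
#'
#' @param cohort a `cohort_table`.
#' @param spec a `fai_spec` from [fai_standardization()].
#' @return a data frame with one row per visit: `person_id`, `age_years`,
#'   `fai` (T-score, `NA` when fewer than `min_components` components are
#'   available) and `n_components_used`.
#' @export
score_fai <- function(cohort, spec) {
  stopifnot(inherits(spec, "fai_spec"))
  frame <- cohort_frame(cohort)
  comp <- .fai_composite(frame, spec)
  zc <- (comp$composite - spec$composite_mean) / spec$composite_sd
  data.frame(person_id = frame$person_id,
             age_years = frame$age_years,
             fai = spec$tscore_mean + spec$tscore_sd * zc,
             n_components_used = comp$n_components_used,
             stringsAsFactors = FALSE)
}

#' Attach FAI scores to a cohort
#'
#' Convenience wrapper: scores the cohort with [score_fai()] and merges the
#' `fai` column onto the visits table.
#'
#' @inheritParams score_fai
#' @return `cohort` with `fai` (and `n_components_used`) on visits.
#' @export
add_fai <- function(cohort, spec) {
  sc <- score_fai(cohort, spec)
  v <- cohort$visits
  v$fai <- NULL
  v$n_components_used <- NULL
  v <- merge(v, sc, by = c("person_id", "age_years"), sort = FALSE)
  cohort$visits <- v
  cohort
}

#' @export
print.fai_spec <- function(x, ...) {
  cat("FAI standardization (frozen baseline reference)\n")
  cat(sprintf("  grip sex adjustment: intercept %.3f, male offset %.3f\n",
              x$grip_coef[1], x$grip_coef["sexmale"] %||% 0))
  for (nm in names(x$component_stats))
    cat(sprintf("  %-8s mean %8.3f  sd %7.3f\n", nm,
                x$component_stats[[nm]]["mean"],
                x$component_stats[[nm]]["sd"]))
  cat(sprintf("  reversed: %s\n",
              paste(.fai_components[x$reverse], collapse = ", ")))
  cat(sprintf("  composite mean %.4f sd %.4f -> T(%g, %g); min components %d\n",
              x$composite_mean, x$composite_sd, x$tscore_mean, x$tscore_sd,
              x$min_components))
  invisible(x)
}

#' Save / load a frozen FAI standardization
#'
#' Serializes an `fai_spec` to YAML so that follow-up waves can be scored
#' against the frozen baseline parameters.
#'
#' @param spec an `fai_spec`.
#' @param path YAML file path.
#' @return `write_fai_spec` returns `path` invisibly; `read_fai_spec`
#'   returns the `fai_spec`.
#' @export
write_fai_spec <- function(spec, path) {
  stopifnot(inherits(spec, "fai_spec"))
  out <- list(
    grip_coef = as.list(spec$grip_coef),
    component_stats = lapply(spec$component_stats, as.list),
    reverse = as.list(stats::setNames(spec$reverse, .fai_components)),
    min_components = spec$min_components,
    composite_mean = spec$composite_mean,
    composite_sd = spec$composite_sd,
    tscore_mean = spec$tscore_mean,
    tscore_sd = spec$tscore_sd)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_fai_spec
#' @export
read_fai_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(
    list(grip_coef = unlist(raw$grip_coef),
         component_stats = lapply(raw$component_stats, unlist),
         reverse = unlist(raw$reverse)[.fai_components],
         min_components = as.integer(raw$min_components),
         composite_mean = raw$composite_mean,
         composite_sd = raw$composite_sd,
         tscore_mean = raw$tscore_mean,
         tscore_sd = raw$tscore_sd),
    class = "fai_spec")
}
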
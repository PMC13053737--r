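#' Phenotypic analysis: SES covariates of the growth trajectory
#'
#' For each SES variable, fits the base two-slope growth model (intercept,
#' slopes, sex and optionally parental SEI) and the model additionally
#' including the SES variable as a covariate of intercept, slope 1 and
#' slope 2, and compares the two by likelihood ratio test (df = 3).  Rows
#' with a missing SES value are dropped from both members of a comparison
#' so the fits are nested on identical observations.
#'
#' @param cohort a scored `cohort_table`.
#' @param ses_vars character vector of person-level SES column names.
#' @param outcome outcome column, default `"fai"`.
#' @param parental_sei named logical (or single logical) saying per SES
#'   variable whether parental SEI enters as a covariate.
#' @param random random structure for [lgcm_spec()], default `"full"`.
#' @return object of class `phenotypic_report` with `estimates` (long
#'   table: ses, term, estimate, se, z, p), `lrt` (ses, statistic, df, p)
#'   and the underlying `fits`.
#' @export
phenotypic_analysis <- function(cohort, ses_vars, outcome = "fai",
                                parental_sei = FALSE, random = "full") {
  if (length(parental_sei) == 1L && is.null(names(parental_sei)))
    parental_sei <- stats::setNames(rep(parental_sei, length(ses_vars)),
                                    ses_vars)
  fits <- list(); est <- list(); lr <- list()
  for (ses in ses_vars) {
    psei <- isTRUE(parental_sei[[ses]])
    keep <- !is.na(cohort$persons[[ses]])
    if (psei) keep <- keep & !is.na(cohort$persons$parental_sei)
    sub <- .subset_cohort(cohort, keep)
    spec0 <- lgcm_spec(outcome = outcome, ses = NULL, sex = TRUE,
                       parental_sei = psei, random = random)
    spec1 <- lgcm_spec(outcome = outcome, ses = ses,
                       ses_targets = c("intercept", "slope1", "slope2"),
                       sex = TRUE, parental_sei = psei, random = random)
    f0 <- fit_lgcm(sub, spec0)
    f1 <- fit_lgcm(sub, spec1)
    test <- lrt(f0, f1)
    fits[[ses]] <- list(base = f0, full = f1, lrt = test)
    tab <- f1$coefficients
    tab <- cbind(ses = ses, tab)
    est[[ses]] <- tab
    lr[[ses]] <- data.frame(ses = ses, statistic = test$statistic,
                            df = test$df, p = test$p,
                            stringsAsFactors = FALSE)
  }
  structure(list(estimates = do.call(rbind, c(est, make.row.names = FALSE)),
                 lrt = do.call(rbind, c(lr, make.row.names = FALSE)),
                 fits = fits, outcome = outcome),
            class = "phenotypic_report")
}

#' @export
print.phenotypic_report <- function(x, digits = 3, ...) {
  cat("Phenotypic growth models with SES covariates\n")
  for (i in seq_len(nrow(x$lrt)))
    cat(sprintf("  %s: LRT chi-square %.2f (df %d), p = %.3g\n",
                x$lrt$ses[i], x$lrt$statistic[i], x$lrt$df[i], x$lrt$p[i]))
  tab <- x$estimates
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Co-twin control analysis with confounding verdict
#'
#' Wraps [fit_cotwin_models()], [compare_within_mz_dz()] and
#' [classify_confounding()] into one step per target parameter.
#'
#' @inheritParams fit_cotwin_models
#' @param thresholds see [confounding_thresholds()].
#' @return object of class `cotwin_report` with the `cotwin_result`, the
#'   per-target MZ-vs-DZ `comparisons` and `verdicts`.
#' @export
cotwin_analysis <- function(cohort, ses, targets = "intercept",
                            outcome = "fai", parental_sei = FALSE,
                            random = "full", min_pairs = 10L,
                            thresholds = confounding_thresholds()) {
  cotwin <- fit_cotwin_models(cohort, ses, targets = targets,
                              outcome = outcome,
                              parental_sei = parental_sei,
                              random = random, min_pairs = min_pairs)
  comparisons <- list(); verdicts <- list()
  strata_fitted <- unique(cotwin$table$stratum)
  for (tg in targets) {
    if (all(c("MZ", "DZ") %in% strata_fitted)) {
      comparisons[[tg]] <- compare_within_mz_dz(cotwin, target = tg)
      if ("full" %in% strata_fitted)
        verdicts[[tg]] <- classify_confounding(cotwin, target = tg,
                                               thresholds = thresholds)
    }
  }
  structure(list(cotwin = cotwin, comparisons = comparisons,
                 verdicts = verdicts, thresholds = thresholds),
            class = "cotwin_report")
}

#' @export
print.cotwin_report <- function(x, ...) {
  print(x$cotwin)
  for (tg in names(x$comparisons))
    cat(sprintf("  MZ-vs-DZ within comparison (%s): z = %.2f, p = %.3g\n",
                tg, x$comparisons[[tg]]$z, x$comparisons[[tg]]$p))
  for (tg in names(x$verdicts)) print(x$verdicts[[tg]])
  if (!"MZ" %in% unique(x$cotwin$table$stratum))
    cat("  note: MZ stratum absent (e.g. opposite-sex-pair cohort);",
        "DZ-only report\n")
  invisible(x)
}

#' Write an analysis table as delimited text
#'
#' Reports are plain tab-separated tables (readable back with
#' [utils::read.delim()] or the package's own reader), mirroring the
#' published table layouts: long rows of term, estimate, SE, z, p.
#'
#' @param x a `phenotypic_report`, `cotwin_report`, `sexdiff_result` or
#'   plain data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  tab <- if (is.data.frame(x)) x
  else if (inherits(x, "phenotypic_report")) x$estimates
  else if (inherits(x, "cotwin_report")) x$cotwin$table
  else if (inherits(x, "cotwin_result")) x$table
  else if (inherits(x, "sexdiff_result")) x$table
  else stop("unsupported report object", call. = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Verdicts as a structured YAML block
#'
#' Emits the confounding verdicts of a [cotwin_analysis()] with their full
#' evidence and thresholds to YAML.
#'
#' @param report a `cotwin_report`.
#' @param path output YAML file.
#' @export
write_verdicts <- function(report, path) {
  stopifnot(inherits(report, "cotwin_report"))
  out <- lapply(report$verdicts, function(v)
    list(verdict = v$verdict,
         evidence = lapply(v$evidence, function(e)
           if (is.numeric(e)) as.list(e) else e),
         thresholds = v$thresholds))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

.stage_seed <- function(seed, stage) {
  # documented splitting rule: one top-level seed, fixed per-stage offsets
  offsets <- c(simulate = 101L, phenotypic = 211L, cotwin = 307L,
               sexdiff = 401L, score = 503L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full config-driven pipeline
#'
#' Ties the stages together: obtain a cohort (simulate from a `sim_config`
#' block, or read from files), optionally score FAI and financial strain,
#' then run the phenotypic, co-twin and sex-interaction analyses and write
#' their tables, the verdict block and a provenance record (config, seed,
#' package version) to the output directory.  All randomness flows from the
#' single top-level seed through fixed per-stage offsets.
#'
#' @param config a list (or path to a YAML file) with elements
#'   `input` (path prefix for [read_cohort()]) *or* `simulate` (arguments
#'   for [sim_config()]; `scenario`/`effect` instead select a
#'   [scenario_config()] preset), plus optional `ses` (character vector,
#'   default `"ses"`), `targets`, `parental_sei`, `random`, `min_pairs`,
#'   `score_fai` (logical; construct the index from raw biomarkers),
#'   `sexdiff` (logical).
#' @param out_dir output directory, created if needed.
#' @param seed top-level integer seed.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the cohort and the three analysis objects.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  if (!is.null(config$input) && !is.null(config$simulate))
    stop("config must have exactly one of 'input' or 'simulate'",
         call. = FALSE)
  if (!is.null(config$input)) {
    cohort <- read_cohort(config$input, schema = config$schema)
    say("read cohort: ", nrow(cohort$persons), " persons")
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!is.null(sim$n_pairs)) sim$n_pairs <- unlist(sim$n_pairs)
    cfg <- if (!is.null(sim$scenario)) {
      do.call(scenario_config, sim)
    } else {
      if (!is.null(sim$ses_ace) && !inherits(sim$ses_ace, "ace_components"))
        sim$ses_ace <- do.call(ace_components, as.list(sim$ses_ace))
      if (!is.null(sim$n_pairs)) sim$n_pairs <- unlist(sim$n_pairs)
      do.call(sim_config, sim)
    }
    cohort <- simulate_cohort(cfg, seed = .stage_seed(seed, "simulate"))
    write_cohort(cohort, file.path(out_dir, "cohort"))
    utils::write.table(attr(cohort, "truth"),
                       file.path(out_dir, "cohort_truth.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    say("simulated cohort: ", nrow(cohort$persons), " persons")
  } else stop("config needs 'input' or 'simulate'", call. = FALSE)

  if (isTRUE(config$score_fai)) {
    spec <- fai_standardization(cohort)
    write_fai_spec(spec, file.path(out_dir, "fai_spec.yaml"))
    cohort <- add_fai(cohort, spec)
    say("scored FAI against baseline standardization")
  }

  ses_vars <- config$ses %||NULL% "ses"
  targets <- config$targets %||NULL% "intercept"
  parental_sei <- isTRUE(config$parental_sei)
  random <- config$random %||NULL% "full"
  min_pairs <- config$min_pairs %||NULL% 10L

  phen <- NULL
  cot <- NULL
  if (length(ses_vars) > 0L) {
  phen <- phenotypic_analysis(cohort, ses_vars,
                              parental_sei = parental_sei, random = random)
  write_report(phen, file.path(out_dir, "phenotypic.tsv"))
  write_report(phen$lrt, file.path(out_dir, "phenotypic_lrt.tsv"))
  say("phenotypic analysis written")

  cot <- lapply(ses_vars, function(ses)
    cotwin_analysis(cohort, ses, targets = targets,
                    parental_sei = parental_sei, random = random,
                    min_pairs = min_pairs))
  names(cot) <- ses_vars
  for (ses in ses_vars) {
    write_report(cot[[ses]], file.path(out_dir,
                                       paste0("cotwin_", ses, ".tsv")))
    write_verdicts(cot[[ses]], file.path(out_dir,
                                         paste0("verdict_", ses, ".yaml")))
  }
  say("co-twin analysis written")
  }

  sexd <- NULL
  if (isTRUE(config$sexdiff) && length(ses_vars) > 0L) {
    sexd <- lapply(ses_vars, function(ses)
      tryCatch(fit_sex_interaction(cohort, ses, random = random,
                                   parental_sei = parental_sei,
                                   min_pairs = min_pairs),
               error = function(e) e))
    names(sexd) <- ses_vars
    for (ses in ses_vars)
      if (inherits(sexd[[ses]], "sexdiff_result"))
        write_report(sexd[[ses]],
                     file.path(out_dir, paste0("sexdiff_", ses, ".tsv")))
    say("sex-interaction analysis written")
  }

  provenance <- list(
    package = "cotwinlgcm",
    version = as.character(utils::packageVersion("cotwinlgcm")),
    seed = as.integer(seed),
    stage_seeds = lapply(c("simulate", "phenotypic", "cotwin", "sexdiff"),
                         function(s) .stage_seed(seed, s)),
    config = .serializable(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))

  invisible(list(cohort = cohort, phenotypic = phen, cotwin = cot,
                 sexdiff = sexd))
}

`%||NULL%` <- function(a, b) if (is.null(a)) b else a

.serializable <- function(x) {
  if (inherits(x, "ace_components"))
    return(list(a2 = x$a2, c2 = x$c2, e2 = x$e2))
  if (is.list(x)) return(lapply(x, .serializable))
  # named atomic vectors must become maps, or YAML drops the names
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}
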
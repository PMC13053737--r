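#' ACE variance components
#'
#' Standardized biometrical variance components of a latent trait:
#' additive-genetic `a2`, shared-environment `c2` and unique-environment
#' `e2`, nonnegative and summing to one.  They imply latent twin
#' correlations `a2 + c2` (MZ) and `0.5 a2 + c2` (DZ), since MZ twins share
#' all their segregating genes and DZ twins on average half.
#'
#' @param a2,c2,e2 nonnegative components summing to 1 (tolerance 1e-8).
#' @param boundary logical flag marking a truncated (boundary) solution.
#' @return object of class `ace_components`.
#' @export
ace_components <- function(a2, c2, e2, boundary = FALSE) {
  stopifnot(a2 >= 0, c2 >= 0, e2 >= 0)
  if (abs(a2 + c2 + e2 - 1) > 1e-8)
    stop("a2 + c2 + e2 must equal 1", call. = FALSE)
  structure(list(a2 = a2, c2 = c2, e2 = e2, boundary = boundary,
                 r_mz = a2 + c2, r_dz = 0.5 * a2 + c2),
            class = "ace_components")
}

#' @export
print.ace_components <- function(x, ...) {
  cat(sprintf("ACE components: a2 = %.3f, c2 = %.3f, e2 = %.3f%s\n",
              x$a2, x$c2, x$e2,
              if (x$boundary) "  [boundary solution]" else ""))
  cat(sprintf("  implied twin correlations: MZ %.3f, DZ %.3f\n",
              x$r_mz, x$r_dz))
  invisible(x)
}

#' Falconer decomposition of twin correlations
#'
#' Solves `a2 = 2 (r_MZ - r_DZ)`, `c2 = r_MZ - a2`, `e2 = 1 - r_MZ`.  When
#' the raw solution is inadmissible (a component below 0, e.g. `r_MZ >
#' 2 r_DZ` giving `c2 < 0`, or `r_MZ < r_DZ` giving `a2 < 0`), components
#' are truncated to zero and the remainder renormalized to sum to one, with
#' the boundary flag set.
#'
#' @param r_mz,r_dz twin correlations, strictly inside (-1, 1).
#' @return an [ace_components()] object (check `$boundary`).
#' @export
solve_ace <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) < 1, abs(r_dz) < 1)
  a2 <- 2 * (r_mz - r_dz)
  c2 <- r_mz - a2
  e2 <- 1 - r_mz
  raw <- c(a2 = a2, c2 = c2, e2 = e2)
  if (all(raw >= 0))
    return(ace_components(a2, c2, e2, boundary = FALSE))
  trunc <- pmax(raw, 0)
  trunc <- trunc / sum(trunc)
  out <- ace_components(unname(trunc["a2"]), unname(trunc["c2"]),
                        unname(trunc["e2"]), boundary = TRUE)
  out$raw <- raw
  out
}

#' Configuration of the biometrical twin-cohort simulator
#'
#' Collects everything [simulate_cohort()] needs.  Defaults emulate the
#' Swedish twin-study conditions the pipeline is designed for: 142 MZ and
#' 371 DZ pairs (about half the DZ pairs opposite-sex), SES with an
#' ISEI-like marginal scale (mean 36.3, SD 19.2) and ACE structure solved
#' from MZ/DZ correlations 0.53/0.29, trajectories on a T-score outcome
#' metric with intercept near 47 at age 75, pre-knot slope ~4.4 and
#' post-knot slope ~9.9 per decade (the post-75 rate about twice the
#' pre-75 rate), female intercept offset ~2.9, baseline ages uniform on
#' 42-93 years, up to 8 waves spaced 2-4 years apart (follow-up up to
#' about 27 years) and a per-wave dropout probability.
#'
#' Cross-paths define the generating scenario on the intercept (and, if
#' configured, on slope 1): `delta` is the direct (causal) path from
#' standardized SES, `kappa_a` a shared additive-genetic path and `kappa_c`
#' a shared-environment path from the same latent A and C that build SES.
#'
#' @param n_pairs named vector `c(MZ = ..., DZ = ...)`.
#' @param dz_opposite_sex fraction of DZ pairs that are opposite-sex.
#' @param ses_ace an [ace_components()] for the SES variable.
#' @param ses_mean,ses_sd observed-scale SES mean and SD.
#' @param mu_intercept,mu_slope1,mu_slope2 fixed growth effects (T units;
#'   slopes per decade).
#' @param beta_sex_female female intercept offset.
#' @param sd_pair,sd_person length-3 SDs of the pair-level and
#'   person-level random intercept, slope-1, slope-2 effects.
#' @param sd_resid residual SD.
#' @param delta,kappa_a,kappa_c intercept cross-paths (per SD of latent
#'   SES for `delta`; per SD of latent A / C for the kappas).
#' @param delta_slope1,kappa_a_slope1,kappa_c_slope1 slope-1 cross-paths.
#' @param baseline_age_range baseline age range (years), within 42-93.
#' @param n_waves maximum number of waves.
#' @param wave_spacing range of the uniform wave spacing in years.
#' @param dropout per-wave probability (after baseline) that a wave is
#'   missed, independently per wave.
#' @param emit_components also generate the four raw FAI biomarkers
#'   (noisy affine images of the latent outcome) so the scoring pipeline
#'   can be exercised end-to-end.
#' @param component_noise_sd biomarker noise SD on the z scale.
#' @param emit_isced also emit an ISCED-like 0-8 ordinal column obtained by
#'   thresholding SES at the deciles of its configured normal marginal.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = c(MZ = 142, DZ = 371),
                       dz_opposite_sex = 0.5,
                       ses_ace = solve_ace(0.53, 0.29),
                       ses_mean = 36.3, ses_sd = 19.2,
                       mu_intercept = 47.3,
                       mu_slope1 = 4.4,
                       mu_slope2 = 9.9,
                       beta_sex_female = 2.9,
                       sd_pair = c(5, 1.5, 2),
                       sd_person = c(5, 1.5, 2),
                       sd_resid = 5,
                       delta = 0, kappa_a = 0, kappa_c = 0,
                       delta_slope1 = 0, kappa_a_slope1 = 0,
                       kappa_c_slope1 = 0,
                       baseline_age_range = c(42, 93),
                       n_waves = 8L,
                       wave_spacing = c(2, 4),
                       dropout = 0.12,
                       emit_components = FALSE,
                       component_noise_sd = 0.5,
                       emit_isced = FALSE) {
  stopifnot(inherits(ses_ace, "ace_components"),
            all(n_pairs >= 0), all(c("MZ", "DZ") %in% names(n_pairs)),
            dz_opposite_sex >= 0, dz_opposite_sex <= 1,
            ses_sd >= 0, length(sd_pair) == 3L, length(sd_person) == 3L,
            all(sd_pair >= 0), all(sd_person >= 0), sd_resid >= 0,
            diff(baseline_age_range) >= 0, n_waves >= 1L,
            all(wave_spacing > 0), dropout >= 0, dropout <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# bivariate standard normal pair with correlation rho (vectorized, n pairs)
.corr_pair <- function(n, rho) {
  shared <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  u2 <- stats::rnorm(n)
  sq <- sqrt(rho); sr <- sqrt(1 - rho)
  cbind(sq * shared + sr * u1, sq * shared + sr * u2)
}

#' Simulate a longitudinal twin cohort
#'
#' Generates a cohort under the biometrical model of [sim_config()]: per
#' pair, latent additive-genetic scores A correlated 1 (MZ) or 0.5 (DZ),
#' one shared-environment score C, independent unique scores E, all unit
#' variance; standardized latent SES `a A + c C + e E`; person-specific
#' growth parameters built from the fixed effects, the cross-paths
#' (`delta` from SES, `kappa_a` from A, `kappa_c` from C) and pair- plus
#' person-level random effects; and wave-wise outcomes on the two-slope
#' basis with residual noise.  Dropout removes non-baseline waves
#' independently.  The generated outcome column is `fai`; the latent truth
#' (A, C, E, standardized SES and the true person intercept/slopes) is
#' attached as `attr(cohort, "truth")` for recovery tests.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; the run is fully reproducible from it.
#' @return a `cohort_table` with attributes `truth` (data frame) and
#'   `config`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_mz <- as.integer(config$n_pairs[["MZ"]])
  n_dz <- as.integer(config$n_pairs[["DZ"]])
  n_pairs <- n_mz + n_dz
  if (n_pairs == 0L) stop("no pairs to simulate", call. = FALSE)
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))

  A <- rbind(if (n_mz > 0L) {a <- stats::rnorm(n_mz); cbind(a, a)},
             if (n_dz > 0L) .corr_pair(n_dz, 0.5))
  Cc <- stats::rnorm(n_pairs)
  E <- matrix(stats::rnorm(2L * n_pairs), ncol = 2L)

  ace <- config$ses_ace
  al <- sqrt(ace$a2); cl <- sqrt(ace$c2); el <- sqrt(ace$e2)
  ses_lat <- al * A + cl * Cc + el * E

  # sexes: MZ same-sex; DZ opposite-sex with the configured probability
  sex1 <- ifelse(stats::runif(n_pairs) < 0.5, "male", "female")
  sex2 <- sex1
  if (n_dz > 0L) {
    dz_idx <- which(zyg == "DZ")
    opp <- stats::runif(n_dz) < config$dz_opposite_sex
    sex2[dz_idx[opp]] <- ifelse(sex1[dz_idx[opp]] == "male",
                                "female", "male")
  }

  draw_re <- function(sds) {
    m <- matrix(stats::rnorm(n_pairs * 3L), nrow = n_pairs)
    sweep(m, 2L, sds, "*")
  }
  u_pair <- draw_re(config$sd_pair)
  u1 <- draw_re(config$sd_person)
  u2 <- draw_re(config$sd_person)

  person_level <- function(member, sexm, u_ind) {
    fem <- as.numeric(sexm == "female")
    int <- config$mu_intercept + config$beta_sex_female * fem +
      config$delta * ses_lat[, member] +
      config$kappa_a * A[, member] + config$kappa_c * Cc +
      u_pair[, 1L] + u_ind[, 1L]
    s1 <- config$mu_slope1 +
      config$delta_slope1 * ses_lat[, member] +
      config$kappa_a_slope1 * A[, member] + config$kappa_c_slope1 * Cc +
      u_pair[, 2L] + u_ind[, 2L]
    s2 <- config$mu_slope2 + u_pair[, 3L] + u_ind[, 3L]
    cbind(int, s1, s2)
  }
  lev1 <- person_level(1L, sex1, u1)
  lev2 <- person_level(2L, sex2, u2)

  pair_id <- sprintf("PAIR%05d", seq_len(n_pairs))
  pid <- cbind(paste0(pair_id, "_1"), paste0(pair_id, "_2"))

  age0 <- stats::runif(n_pairs, config$baseline_age_range[1],
                       config$baseline_age_range[2])

  persons <- data.frame(
    person_id = c(pid[, 1L], pid[, 2L]),
    pair_id = rep(pair_id, 2L),
    zygosity = rep(zyg, 2L),
    sex = c(sex1, sex2),
    birth_year = rep(round(1990 - age0), 2L),
    study_label = "SIM",
    ses = c(config$ses_mean + config$ses_sd * ses_lat[, 1L],
            config$ses_mean + config$ses_sd * ses_lat[, 2L]),
    stringsAsFactors = FALSE)
  if (config$emit_isced) {
    qs <- stats::qnorm(seq_len(8L) / 9, config$ses_mean,
                       max(config$ses_sd, 1e-12))
    persons$isced <- findInterval(persons$ses, qs)
  }

  # visit grid: shared baseline age per pair, person-specific spacing
  nw <- config$n_waves
  build_visits <- function(member, lev) {
    gaps <- matrix(stats::runif(n_pairs * max(nw - 1L, 0L),
                                config$wave_spacing[1],
                                config$wave_spacing[2]),
                   nrow = n_pairs)
    if (nw > 2L)
      for (j in 2L:(nw - 1L)) gaps[, j] <- gaps[, j - 1L] + gaps[, j]
    ages <- cbind(age0, if (nw > 1L) age0 + gaps, deparse.level = 0L)
    keep <- cbind(rep(TRUE, n_pairs),
                  if (nw > 1L)
                    matrix(stats::runif(n_pairs * (nw - 1L)) >=
                             config$dropout, nrow = n_pairs))
    idx <- which(keep, arr.ind = TRUE)
    pr <- idx[, 1L]
    age <- ages[idx]
    b <- age_basis(age)
    y <- lev[pr, 1L] + lev[pr, 2L] * b$s1 + lev[pr, 3L] * b$s2 +
      stats::rnorm(length(age), 0, config$sd_resid)
    data.frame(person_id = pid[pr, member],
               age_years = age, fai = y, stringsAsFactors = FALSE)
  }
  visits <- rbind(build_visits(1L, lev1), build_visits(2L, lev2))
  visits <- visits[order(visits$person_id, visits$age_years), , drop = FALSE]
  rownames(visits) <- NULL

  if (config$emit_components) {
    sexes <- persons$sex[match(visits$person_id, persons$person_id)]
    zfun <- (visits$fai - 50) / 10
    ns <- config$component_noise_sd
    n <- nrow(visits)
    height <- 1.62 + 0.12 * (sexes == "male") +
      stats::rnorm(n, 0, 0.05)
    visits$grip <- 26 + 12 * (sexes == "male") - 5 * zfun +
      stats::rnorm(n, 0, 5 * ns)
    visits$height_m <- height
    visits$pef <- (130 - 15 * zfun + stats::rnorm(n, 0, 15 * ns)) * height^2
    visits$gait <- 10 + 2 * zfun + stats::rnorm(n, 0, 2 * ns)
    visits$vision_self <- pmin(pmax(round(2 + 0.6 * zfun +
                                            stats::rnorm(n, 0, ns)), 1), 5)
    visits$hearing_self <- pmin(pmax(round(2 + 0.6 * zfun +
                                             stats::rnorm(n, 0, ns)), 1), 5)
  }

  truth <- data.frame(
    person_id = c(pid[, 1L], pid[, 2L]),
    pair_id = rep(pair_id, 2L),
    A = c(A[, 1L], A[, 2L]),
    C = rep(Cc, 2L),
    E = c(E[, 1L], E[, 2L]),
    ses_latent = c(ses_lat[, 1L], ses_lat[, 2L]),
    intercept = c(lev1[, 1L], lev2[, 1L]),
    slope1 = c(lev1[, 2L], lev2[, 2L]),
    slope2 = c(lev1[, 3L], lev2[, 3L]),
    stringsAsFactors = FALSE)

  cohort <- cohort_table(persons, visits, validate = FALSE)
  attr(cohort, "truth") <- truth
  attr(cohort, "config") <- config
  cohort
}

#' Expected between/within coefficients under the simulator's model
#'
#' Closed-form population regression coefficients of the person intercept
#' (and, if slope-1 cross-paths are set, of slope 1) on the between- and
#' within-pair components of standardized SES, per zygosity.  With SES
#' loadings `(a, c, e)` and unit-variance latents:
#' `within_MZ = delta` (MZ differences carry no A or C, so the within-MZ
#' coefficient is always the direct path);
#' `within_DZ = delta + kappa_a * a / (a^2 + 2 e^2)`;
#' `between_MZ = delta + (kappa_a a + kappa_c c) / (a^2 + c^2 + e^2 / 2)`;
#' `between_DZ = delta + (0.75 kappa_a a + kappa_c c) /
#'   (0.75 a^2 + c^2 + e^2 / 2)`.
#' These formulas formalize the attenuation logic: a genetic confound
#' inflates the DZ but not the MZ within effect, a shared-environment
#' confound inflates neither, and both inflate the between effects.
#'
#' Coefficients are per SD of latent SES; divide by `ses_sd` for the
#' observed scale.
#'
#' @param config a `sim_config`.
#' @return data frame with columns `parameter` (`intercept`, possibly
#'   `slope1`), `zygosity`, `between`, `within`.
#' @export
oracle_coefficients <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ace <- config$ses_ace
  a <- sqrt(ace$a2); cl <- sqrt(ace$c2); e <- sqrt(ace$e2)
  if (a == 0 && cl == 0 && e == 0)
    stop("degenerate SES loadings", call. = FALSE)
  one <- function(delta, ka, kc) {
    wd_den <- a^2 + 2 * e^2
    bm_den <- a^2 + cl^2 + e^2 / 2
    bd_den <- 0.75 * a^2 + cl^2 + e^2 / 2
    data.frame(
      zygosity = c("MZ", "DZ"),
      between = c(delta + (ka * a + kc * cl) / bm_den,
                  delta + (0.75 * ka * a + kc * cl) / bd_den),
      within = c(delta,
                 if (wd_den > 0) delta + ka * a / wd_den else NA_real_),
      stringsAsFactors = FALSE)
  }
  out <- cbind(parameter = "intercept",
               one(config$delta, config$kappa_a, config$kappa_c))
  if (config$delta_slope1 != 0 || config$kappa_a_slope1 != 0 ||
      config$kappa_c_slope1 != 0)
    out <- rbind(out, cbind(parameter = "slope1",
                            one(config$delta_slope1,
                                config$kappa_a_slope1,
                                config$kappa_c_slope1)))
  out
}

#' Scenario presets for the confounding-classification experiments
#'
#' Three generating scenarios spanning the design's signature patterns -
#' `"causal"` (direct path only), `"genetic"` (genetic confound only) and
#' `"shared_env"` (shared-environment confound only) - at two effect sizes.
#' The presets use an SES ACE structure of (0.2, 0.6, 0.2), paths of 2
#' (strong) or 1 (moderate) T-units per SD (comparable in standardized
#' magnitude to published co-twin SES effects on functional aging), and
#' deliberately small trajectory noise, so that the non-capped conditions
#' of the decision rule are checked at high power.  See the methods
#' vignette for why the significance conditions cap per-scenario recovery
#' near 95%.
#'
#' @param scenario `"causal"`, `"genetic"` or `"shared_env"`.
#' @param effect `"strong"` (paths of 2) or `"moderate"` (paths of 1).
#' @param n_pairs pairs per zygosity (default 2000 each).
#' @param n_waves number of waves (default 2).
#' @return a [sim_config()].
#' @export
scenario_config <- function(scenario = c("causal", "genetic", "shared_env"),
                            effect = c("strong", "moderate"),
                            n_pairs = c(MZ = 2000, DZ = 2000),
                            n_waves = 2L) {
  scenario <- match.arg(scenario)
  effect <- match.arg(effect)
  path <- if (effect == "strong") 2 else 1
  sim_config(
    n_pairs = n_pairs,
    dz_opposite_sex = 0.5,
    ses_ace = ace_components(0.2, 0.6, 0.2),
    ses_mean = 0, ses_sd = 1,
    delta = if (scenario == "causal") path else 0,
    kappa_a = if (scenario == "genetic") path else 0,
    kappa_c = if (scenario == "shared_env") path else 0,
    sd_pair = c(2, 0, 0),
    sd_person = c(1, 0, 0),
    sd_resid = 1,
    baseline_age_range = c(60, 90),
    n_waves = n_waves,
    wave_spacing = c(2, 4),
    dropout = 0)
}
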
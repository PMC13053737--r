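# build a cotwin_result by hand so decision-rule cases can be constructed
# directly from printed-style estimate/SE patterns
fake_cotwin <- function(rows) {
  tab <- do.call(rbind, lapply(rows, function(r) {
    z <- r$estimate / r$se
    data.frame(stratum = r$stratum, target = "intercept",
               effect = r$effect, estimate = r$estimate, se = r$se,
               z = z, p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, n_pairs = c(full = 500, MZ = 150, DZ = 350),
                 fits = list(), ses = "x", targets = "intercept",
                 outcome = "fai", parental_sei = FALSE),
            class = "cotwin_result")
}
rw <- function(stratum, effect, estimate, se)
  list(stratum = stratum, effect = effect, estimate = estimate, se = se)

test_that("pair decomposition: arithmetic, zero-sum, reconstruction", {
  p <- toy_persons(2)
  p$ses <- c(2, 4, 5, 5)
  co <- cohort_table(p, toy_visits(p))
  d <- decompose_between_within(co, "ses")
  expect_equal(d$between[d$pair_id == "PR01"], c(3, 3))
  expect_equal(d$within[d$pair_id == "PR01"], c(-1, 1))
  expect_equal(d$within[d$pair_id == "PR02"], c(0, 0))

  # identity and zero-sum on simulated data
  co2 <- simulate_cohort(sim_config(n_pairs = c(MZ = 40, DZ = 40),
                                    n_waves = 1), seed = 2)
  d2 <- decompose_between_within(co2, "ses")
  expect_equal(d2$between + d2$within, d2$value)
  sums <- tapply(d2$within, d2$pair_id, sum)
  expect_true(all(abs(sums) < 1e-12))
})

test_that("decomposition refuses incomplete pairs and missing values", {
  p <- toy_persons(1, singletons = 1)
  p$ses <- c(1, 2, 3)
  co <- cohort_table(p, toy_visits(p))
  expect_error(decompose_between_within(co, "ses"), "incomplete pair")
  p2 <- toy_persons(2)
  p2$ses <- c(1, NA, 3, 4)
  co2 <- cohort_table(p2, toy_visits(p2))
  expect_error(decompose_between_within(co2, "ses"), "complete_pairs")
})

test_that("the MZ-vs-DZ comparison follows the SE-combination formula", {
  # printed-style values: within MZ 0.01 (0.06), within DZ 0.14 (0.04)
  ct <- fake_cotwin(list(
    rw("full", "between", 0.21, 0.03), rw("full", "within", 0.11, 0.03),
    rw("MZ", "between", 0.25, 0.06), rw("MZ", "within", 0.01, 0.06),
    rw("DZ", "between", 0.17, 0.04), rw("DZ", "within", 0.14, 0.04)))
  cmp <- compare_within_mz_dz(ct)
  expect_equal(cmp$z, (0.14 - 0.01) / sqrt(0.06^2 + 0.04^2),
               tolerance = 1e-12)
  expect_equal(cmp$z, 1.803, tolerance = 1e-3)

  # identical estimates -> z = 0, p = 1
  ct0 <- fake_cotwin(list(
    rw("MZ", "between", 0.2, 0.05), rw("MZ", "within", 0.1, 0.05),
    rw("DZ", "between", 0.2, 0.05), rw("DZ", "within", 0.1, 0.05)))
  cmp0 <- compare_within_mz_dz(ct0)
  expect_equal(cmp0$z, 0)
  expect_equal(cmp0$p, 1)
})

test_that("the attenuation rule reproduces the signature patterns", {
  # financial-strain-style pattern: between ~0.2 everywhere, within gone in
  # MZ but retained in DZ -> genetic confounding
  genetic <- fake_cotwin(list(
    rw("full", "between", 0.21, 0.03), rw("full", "within", 0.11, 0.03),
    rw("MZ", "between", 0.25, 0.06), rw("MZ", "within", 0.01, 0.06),
    rw("DZ", "between", 0.17, 0.04), rw("DZ", "within", 0.14, 0.04)))
  v <- classify_confounding(genetic)
  expect_equal(v$verdict, "genetic_confounding")

  # fully-powered causal pattern: within significant and unattenuated in
  # both strata
  causal <- fake_cotwin(list(
    rw("full", "between", -0.40, 0.05), rw("full", "within", -0.42, 0.05),
    rw("MZ", "between", -0.38, 0.08), rw("MZ", "within", -0.36, 0.08),
    rw("DZ", "between", -0.41, 0.06), rw("DZ", "within", -0.44, 0.06)))
  expect_equal(classify_confounding(causal)$verdict, "consistent_causal")

  # equal attenuation, both non-significant -> shared environment
  shared <- fake_cotwin(list(
    rw("full", "between", 0.30, 0.04), rw("full", "within", 0.09, 0.05),
    rw("MZ", "between", 0.30, 0.06), rw("MZ", "within", 0.08, 0.06),
    rw("DZ", "between", 0.28, 0.05), rw("DZ", "within", 0.07, 0.06)))
  expect_equal(classify_confounding(shared)$verdict,
               "shared_env_confounding")

  # occupation-style printed pattern: point estimates similar but the MZ
  # within effect is non-significant -> indeterminate with low power noted
  isei <- fake_cotwin(list(
    rw("full", "between", -0.04, 0.02), rw("full", "within", -0.05, 0.02),
    rw("MZ", "between", -0.08, 0.04), rw("MZ", "within", -0.08, 0.05),
    rw("DZ", "between", -0.07, 0.03), rw("DZ", "within", -0.04, 0.03)))
  vi <- classify_confounding(isei)
  expect_equal(vi$verdict, "indeterminate")
  expect_true(vi$evidence$low_power)
})

test_that("the verdict is invariant to sign reversal of the SES variable", {
  rows <- list(
    rw("full", "between", 0.21, 0.03), rw("full", "within", 0.11, 0.03),
    rw("MZ", "between", 0.25, 0.06), rw("MZ", "within", 0.01, 0.06),
    rw("DZ", "between", 0.17, 0.04), rw("DZ", "within", 0.14, 0.04))
  flipped <- lapply(rows, function(r) {
    r$estimate <- -r$estimate; r
  })
  v1 <- classify_confounding(fake_cotwin(rows))
  v2 <- classify_confounding(fake_cotwin(flipped))
  expect_equal(v2$verdict, v1$verdict)
  expect_equal(v2$evidence$ratio_mz, v1$evidence$ratio_mz)
  expect_equal(v2$evidence$z_mz_vs_dz, v1$evidence$z_mz_vs_dz)
})

test_that("stratified fits recover the analytic oracle per scenario", {
  # one moderate-size replicate per scenario; the acceptance suite runs the
  # high-precision version
  for (sc in c("causal", "genetic", "shared_env")) {
    cfg <- scenario_config(sc, "strong", n_pairs = c(MZ = 400, DZ = 400))
    co <- simulate_cohort(cfg, seed = 100 + match(sc, c("causal", "genetic",
                                                        "shared_env")))
    res <- fit_cotwin_models(co, "ses", random = "intercept")
    oc <- oracle_coefficients(cfg)
    for (zg in c("MZ", "DZ")) {
      for (eff in c("between", "within")) {
        row <- res$table[res$table$stratum == zg &
                           res$table$effect == eff, ]
        expect_lt(abs(row$estimate - oc[[eff]][oc$zygosity == zg]),
                  4 * row$se)
      }
    }
  }
})

test_that("joint-model and SE-combination comparisons agree on balanced data", {
  cfg <- scenario_config("genetic", "strong",
                         n_pairs = c(MZ = 500, DZ = 500))
  co <- simulate_cohort(cfg, seed = 55)
  res <- fit_cotwin_models(co, "ses", random = "intercept")
  z_se <- compare_within_mz_dz(res)$z
  z_joint <- compare_within_mz_dz(res, method = "joint", cohort = co)$z
  expect_lt(abs(z_joint - z_se) / abs(z_se), 0.10)
})

test_that("sex-interaction model: null corrections and relabeling", {
  cfg <- scenario_config("causal", "strong", n_pairs = c(MZ = 300, DZ = 300))
  co <- simulate_cohort(cfg, seed = 60)
  sx <- fit_sex_interaction(co, "ses", random = "intercept")
  tab <- sx$table
  corr <- tab[grepl("correction", tab$effect), ]
  # no sex-specific structure was generated: corrections near zero
  expect_true(all(abs(corr$z) < 3.5))
  # women's within estimate tracks the causal path
  ww <- tab[tab$stratum == "full" & tab$effect == "within_women", ]
  expect_lt(abs(ww$estimate - 2), 4 * ww$se)

  # relabeling: swapping the sex coding moves the base level
  co2 <- co
  co2$persons$sex <- ifelse(co2$persons$sex == "male", "female", "male")
  sx2 <- fit_sex_interaction(co2, "ses", random = "intercept")
  b1 <- tab[tab$stratum == "full" & tab$effect == "between_women", "estimate"]
  c1 <- tab[tab$stratum == "full" & tab$effect == "between_men_correction",
            "estimate"]
  b2 <- sx2$table[sx2$table$stratum == "full" &
                    sx2$table$effect == "between_women", "estimate"]
  c2 <- sx2$table[sx2$table$stratum == "full" &
                    sx2$table$effect == "between_men_correction", "estimate"]
  expect_equal(b2, b1 + c1, tolerance = 1e-4)
  expect_equal(c2, -c1, tolerance = 1e-4)
})

test_that("sex-specific genetic confounding is detected for that sex only", {
  # construct sex-specific confounding from the latent truth: males get a
  # genetic path into the outcome, females do not
  cfg <- scenario_config("causal", "strong", n_pairs = c(MZ = 800, DZ = 800))
  cfg$delta <- 0
  co <- simulate_cohort(cfg, seed = 65)
  tr <- attr(co, "truth")
  males <- co$persons$person_id[co$persons$sex == "male"]
  bump <- 2 * tr$A[match(co$visits$person_id, tr$person_id)]
  bump[!co$visits$person_id %in% males] <- 0
  co$visits$fai <- co$visits$fai + bump

  sx <- fit_sex_interaction(co, "ses", random = "intercept")
  mz <- sx$table[sx$table$stratum == "MZ", ]
  ww <- mz[mz$effect == "within_women", ]
  bm <- mz[mz$effect == "between_men_correction", ]
  # women's MZ within effect stays at zero (no path for them) and the male
  # between-pair correction picks up the genetic confound
  expect_lt(abs(ww$estimate), 3 * ww$se)
  expect_gt(bm$z, 3)
})

test_that("single-sex strata are flagged inestimable", {
  cfg <- sim_config(n_pairs = c(MZ = 0, DZ = 30), dz_opposite_sex = 0,
                    n_waves = 2)
  co <- simulate_cohort(cfg, seed = 70)
  co$persons$sex <- "male"
  expect_warning(
    expect_error(fit_sex_interaction(co, "ses", strata = "DZ",
                                     random = "intercept"),
                 "no stratum"),
    "single sex")
})

test_that("twin correlations: concordance, double entry, Falconer", {
  p <- toy_persons(4, zygosity = "MZ")
  p$sex <- rep("female", 8)
  p$x <- rep(c(1, 3, 5, 7), each = 2)  # perfectly concordant pairs
  co <- cohort_table(p, toy_visits(p))
  tcm <- suppressWarnings(twin_correlations(
    cohort_table(rbind(p, within(toy_persons(4, zygosity = "DZ"), {
      x <- c(1, 2, 3, 5, 5, 8, 7, 11)
      person_id <- paste0("D", person_id)
      pair_id <- paste0("D", pair_id)
    })), toy_visits(p), validate = FALSE), "x"))
  expect_equal(tcm$r_mz, 1)

  # double-entered estimate equals the manual symmetric correlation
  x1 <- c(1, 3, 5, 7); x2 <- c(2, 5, 8, 11)
  expect_equal(suppressWarnings(cor(c(x1, x2), c(x2, x1))),
               tcm$r_dz, tolerance = 1e-12)
})

test_that("fewer than 3 pairs in a stratum is an error", {
  p <- toy_persons(2, zygosity = "MZ")
  p$sex <- "female"
  p$x <- rnorm(4)
  co <- cohort_table(p, toy_visits(p))
  expect_error(twin_correlations(co, "x"), "fewer than 3")
})

test_that("Fisher z comparison: zero, antisymmetry, printed-style values", {
  expect_equal(compare_correlations(0.4, 100, 0.4, 200)$z, 0)
  a <- compare_correlations(0.3, 150, 0.5, 120)
  b <- compare_correlations(0.5, 120, 0.3, 150)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # women-vs-men comparison of an occupation-by-strain correlation
  z <- compare_correlations(-0.21, 721, -0.10, 648)$z
  expect_equal(abs(z), 2.08, tolerance = 0.01)
  expect_error(compare_correlations(1, 10, 0.5, 10), "inside")
  expect_error(compare_correlations(0.2, 3, 0.5, 10), "exceed 3")
})
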
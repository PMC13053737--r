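test_that("grip adjustment residualizes on sex against the reference fit", {
  ref <- data.frame(grip = c(38, 42, 40, 40, 24, 28, 26, 26),
                    sex = rep(c("male", "female"), each = 4))
  # value at the sex-specific reference mean -> residual 0
  expect_equal(adjust_grip(c(40, 26), c("male", "female"), ref), c(0, 0))
  # closed-form two-group regression oracle: female mean 26, grip 30 -> +4
  expect_equal(adjust_grip(30, "female", ref), 4)
  # constant reference -> all residuals 0
  refc <- data.frame(grip = rep(33, 6), sex = rep(c("male", "female"), 3))
  expect_equal(adjust_grip(rep(33, 4),
                           c("male", "male", "female", "female"), refc),
               rep(0, 4))
  # single-sex reference is degenerate
  expect_error(adjust_grip(30, "female",
                           data.frame(grip = c(30, 31, 32),
                                      sex = "female")),
               ">= 2 reference observations per sex")
})

test_that("peak-flow adjustment divides by squared height", {
  expect_equal(adjust_pef(400, 2.0), 100)
  expect_equal(adjust_pef(0, 1.7), 0)
  expect_true(is.na(adjust_pef(400, NA)))
  expect_error(adjust_pef(400, -1.7), "non-positive height")
})

test_that("baseline FAI is calibrated to mean 50, SD 10 exactly", {
  co <- biomarker_cohort(n_pairs = 15)
  spec <- fai_standardization(co)
  sc <- score_fai(co, spec)
  base <- !duplicated(sc$person_id)  # earliest visit rows come first
  expect_equal(mean(sc$fai[base]), 50, tolerance = 1e-8)
  expect_equal(sd(sc$fai[base]), 10, tolerance = 1e-8)
})

test_that("a person uniformly 1 baseline-SD poorer matches the hand oracle", {
  co <- biomarker_cohort(n_pairs = 15)
  spec <- fai_standardization(co)

  # step-by-step spreadsheet-style recomputation on one constructed visit:
  frame <- cohort_frame(co)
  first_age <- tapply(frame$age_years, frame$person_id, min)
  ref <- frame[frame$age_years == first_age[frame$person_id], ]
  grip_fit <- lm(grip ~ sex, data = ref)
  grip_res <- ref$grip - predict(grip_fit)
  pef_adj <- ref$pef / ref$height_m^2
  zstats <- function(x) c(mean(x), sd(x))
  gs <- zstats(grip_res); ps <- zstats(pef_adj); ws <- zstats(ref$gait)
  vs <- zstats(ref$vision_self); hs <- zstats(ref$hearing_self)

  # construct a male visit sitting exactly 1 baseline SD poorer on all four
  # components (grip and pef lower, gait and sensory higher)
  male_mean_grip <- mean(ref$grip[ref$sex == "male"]) -
    mean(grip_res[ref$sex == "male"])
  target <- data.frame(
    person_id = "X1", age_years = 70,
    grip = (gs[1] - gs[2]) + predict(grip_fit,
                                     newdata = data.frame(sex = "male")),
    height_m = 1, pef = ps[1] - ps[2],
    gait = ws[1] + ws[2],
    vision_self = vs[1] + vs[2], hearing_self = hs[1] + hs[2])
  persons <- data.frame(person_id = "X1", pair_id = "PX", zygosity = "MZ",
                        sex = "male", birth_year = 1930,
                        study_label = "TOY")
  got <- score_fai(cohort_table(persons, target, validate = FALSE), spec)

  # oracle: all four z-scores are +1 (poorer), composite = 1, then the
  # T-map against the baseline composite distribution
  comp_base <- rowMeans(cbind(-(grip_res - gs[1]) / gs[2],
                              -(pef_adj - ps[1]) / ps[2],
                              (ref$gait - ws[1]) / ws[2],
                              ((ref$vision_self - vs[1]) / vs[2] +
                                 (ref$hearing_self - hs[1]) / hs[2]) / 2))
  expected <- 50 + 10 * (1 - mean(comp_base)) / sd(comp_base)
  expect_equal(got$fai, expected, tolerance = 1e-10)
  expect_gt(got$fai, 50)
  expect_equal(got$n_components_used, 4)
})

test_that("worsening any single component never decreases FAI", {
  co <- biomarker_cohort(n_pairs = 12)
  spec <- fai_standardization(co)
  base_scores <- score_fai(co, spec)
  set.seed(11)
  worsen <- list(grip = function(v, i) {v$grip[i] <- v$grip[i] - runif(1, 0, 8); v},
                 pef = function(v, i) {v$pef[i] <- v$pef[i] - runif(1, 0, 60); v},
                 gait = function(v, i) {v$gait[i] <- v$gait[i] + runif(1, 0, 3); v},
                 vision = function(v, i) {v$vision_self[i] <- v$vision_self[i] + 1; v},
                 hearing = function(v, i) {v$hearing_self[i] <- v$hearing_self[i] + 1; v})
  for (k in 1:25) {
    i <- sample(nrow(co$visits), 1)
    f <- worsen[[sample(names(worsen), 1)]]
    co2 <- co
    co2$visits <- f(co$visits, i)
    s2 <- score_fai(co2, spec)  # same frozen spec
    expect_true(all(s2$fai - base_scores$fai >= -1e-10, na.rm = TRUE))
  }
})

test_that("reverse flags give each component its poorer direction", {
  co <- biomarker_cohort(n_pairs = 12)
  spec <- fai_standardization(co)
  s0 <- score_fai(co, spec)
  tweak <- function(col, delta) {
    co2 <- co
    co2$visits[[col]][1] <- co2$visits[[col]][1] + delta
    score_fai(co2, spec)$fai[1] - s0$fai[1]
  }
  expect_lt(tweak("grip", +5), 0)   # more strength -> better
  expect_lt(tweak("pef", +50), 0)   # more flow -> better
  expect_gt(tweak("gait", +2), 0)   # more time -> poorer
  expect_gt(tweak("vision_self", +1), 0)  # more difficulty -> poorer
})

test_that("FAI is invariant to a constant shift of one component", {
  co <- biomarker_cohort(n_pairs = 12)
  spec0 <- fai_standardization(co)
  s0 <- score_fai(co, spec0)
  co2 <- co
  co2$visits$gait <- co2$visits$gait + 7.5  # shift baseline AND follow-up
  spec2 <- fai_standardization(co2)
  s2 <- score_fai(co2, spec2)
  expect_equal(s2$fai, s0$fai, tolerance = 1e-10)
})

test_that("too few components gives a missing FAI, not an error", {
  co <- biomarker_cohort(n_pairs = 10)
  spec <- fai_standardization(co)
  co$visits$grip[1] <- NA
  co$visits$pef[1] <- NA
  sc <- score_fai(co, spec)
  expect_true(is.na(sc$fai[1]))
  expect_equal(sc$n_components_used[1], 2)
  expect_false(anyNA(sc$fai[-1]))
})

test_that("a frozen standardization round-trips through YAML", {
  co <- biomarker_cohort(n_pairs = 10)
  spec <- fai_standardization(co)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_fai_spec(spec, f)
  spec2 <- read_fai_spec(f)
  expect_equal(score_fai(co, spec2)$fai, score_fai(co, spec)$fai,
               tolerance = 1e-9)
})
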
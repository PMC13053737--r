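# small hand-built cohorts used across test files

# n_pairs complete pairs with deterministic ids; optional singleton tail
toy_persons <- function(n_pairs, zygosity = "DZ", singletons = 0L,
                        sex = NULL) {
  pid <- sprintf("T%03d", seq_len(2L * n_pairs + singletons))
  pair <- c(rep(sprintf("PR%02d", seq_len(n_pairs)), each = 2L),
            sprintf("PR%02d", n_pairs + seq_len(singletons)))
  zyg <- rep(zygosity, length.out = length(pid))
  if (is.null(sex)) {
    sex <- rep(c("male", "female"), length.out = length(pid))
    # MZ pairs must be same-sex
    for (pr in unique(pair)) {
      idx <- which(pair == pr)
      if (length(idx) == 2L && zyg[idx[1L]] == "MZ")
        sex[idx[2L]] <- sex[idx[1L]]
    }
  }
  data.frame(person_id = pid, pair_id = pair, zygosity = zyg, sex = sex,
             birth_year = 1930L, study_label = "TOY",
             stringsAsFactors = FALSE)
}

toy_visits <- function(persons, ages = c(70, 74)) {
  do.call(rbind, lapply(persons$person_id, function(id)
    data.frame(person_id = id, age_years = ages,
               stringsAsFactors = FALSE)))
}

# cohort with all four FAI biomarkers; biomarkers are deterministic
# functions of person index so hand oracles stay simple
biomarker_cohort <- function(n_pairs = 10L) {
  persons <- toy_persons(n_pairs)
  visits <- toy_visits(persons, ages = c(68, 72, 76))
  n <- nrow(visits)
  set.seed(99)
  sexes <- persons$sex[match(visits$person_id, persons$person_id)]
  visits$grip <- 26 + 12 * (sexes == "male") + rnorm(n, 0, 4)
  visits$height_m <- 1.6 + 0.1 * (sexes == "male") + rnorm(n, 0, 0.04)
  visits$pef <- 340 + rnorm(n, 0, 40)
  visits$gait <- 10 + rnorm(n, 0, 1.5)
  visits$vision_self <- sample(1:5, n, replace = TRUE)
  visits$hearing_self <- sample(1:5, n, replace = TRUE)
  cohort_table(persons, visits)
}
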
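#' Twin-cohort data container
#'
#' A `cohort_table` holds a longitudinal twin cohort in long format: one
#' person-level table (`persons`) and one person-occasion table (`visits`).
#' Person-level columns carry pair structure (`pair_id`, `zygosity`), `sex`,
#' `birth_year`, `study_label` and socioeconomic measures (`isced`, `isei`,
#' `parental_sei`, financial-strain items `fs1`..`fs4`, or a generic `ses`
#' column).  Visit-level columns carry `age_years` and the functional
#' biomarkers (`grip`, `pef`, `height_m`, `gait`, `vision_self`,
#' `hearing_self`) and/or a pre-computed outcome such as `fai`.  Only
#' `person_id`, `pair_id`, `zygosity` and `sex` (persons) and `person_id`,
#' `age_years` (visits) are mandatory; all other columns are optional and
#' extra columns are preserved.
#'
#' Structural invariants enforced by [validate_cohort()]:
#' * every visit's `person_id` exists in `persons`, and `person_id` is unique
#'   in `persons`;
#' * a `pair_id` groups at most two persons, both members share `zygosity`,
#'   and MZ pairs share `sex`;
#' * `zygosity` is `"MZ"` or `"DZ"`, `sex` is `"male"` or `"female"`;
#' * no duplicated `(person_id, age_years)` visit;
#' * every person has at least one visit (persons without visits are allowed
#'   but flagged by `summary()`; they are dropped by model-frame builders).
#'
#' @param persons data frame of person-level records.
#' @param visits data frame of person-occasion records.
#' @param validate run [validate_cohort()] on the result (default `TRUE`).
#' @return An object of class `cohort_table`: a list with elements `persons`
#'   and `visits`.
#' @seealso [read_cohort()], [write_cohort()], [complete_pairs()],
#'   [simulate_cohort()]
#' @export
cohort_table <- function(persons, visits, validate = TRUE) {
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)
  obj <- structure(list(persons = persons, visits = visits),
                   class = "cohort_table")
  if (validate) validate_cohort(obj)
  obj
}

.mandatory_person_cols <- c("person_id", "pair_id", "zygosity", "sex")
.mandatory_visit_cols <- c("person_id", "age_years")

#' Validate a twin cohort
#'
#' Checks the structural invariants documented in [cohort_table()] and stops
#' with an informative message (naming offending pair or person ids) on the
#' first violated class of invariant.
#'
#' @param cohort a `cohort_table`.
#' @return `cohort`, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  p <- cohort$persons
  v <- cohort$visits

  miss <- setdiff(.mandatory_person_cols, names(p))
  if (length(miss) > 0L)
    stop("persons table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(.mandatory_visit_cols, names(v))
  if (length(miss) > 0L)
    stop("visits table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  if (anyDuplicated(p$person_id))
    stop("duplicated person_id in persons: ",
         paste(unique(p$person_id[duplicated(p$person_id)]), collapse = ", "),
         call. = FALSE)

  bad <- !p$zygosity %in% c("MZ", "DZ")
  if (any(bad))
    stop("invalid zygosity (must be \"MZ\" or \"DZ\") for person(s): ",
         paste(p$person_id[bad], collapse = ", "), call. = FALSE)
  bad <- !p$sex %in% c("male", "female")
  if (any(bad))
    stop("invalid sex (must be \"male\" or \"female\") for person(s): ",
         paste(p$person_id[bad], collapse = ", "), call. = FALSE)

  size <- table(p$pair_id)
  if (any(size > 2L))
    stop("pair_id groups more than 2 persons: ",
         paste(names(size)[size > 2L], collapse = ", "), call. = FALSE)
  nzyg <- tapply(p$zygosity, p$pair_id, function(z) length(unique(z)))
  if (any(nzyg > 1L))
    stop("pair members disagree on zygosity for pair(s): ",
         paste(names(nzyg)[nzyg > 1L], collapse = ", "), call. = FALSE)
  mz <- p[p$zygosity == "MZ", , drop = FALSE]
  if (nrow(mz) > 0L) {
    nsex <- tapply(mz$sex, mz$pair_id, function(s) length(unique(s)))
    if (any(nsex > 1L))
      stop("MZ pair of discordant sex: pair(s) ",
           paste(names(nsex)[nsex > 1L], collapse = ", "), call. = FALSE)
  }

  orphan <- !v$person_id %in% p$person_id
  if (any(orphan))
    stop("visits reference unknown person_id: ",
         paste(unique(v$person_id[orphan]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(v$age_years)))
    stop("non-finite age_years in visits", call. = FALSE)
  dup <- duplicated(v[, c("person_id", "age_years")])
  if (any(dup))
    stop("duplicated (person_id, age_years) visit for person(s): ",
         paste(unique(v$person_id[dup]), collapse = ", "), call. = FALSE)

  invisible(cohort)
}

#' @export
print.cohort_table <- function(x, ...) {
  np <- nrow(x$persons)
  cat("Twin cohort: ", np, " persons in ",
      length(unique(x$persons$pair_id)), " pairs (",
      sum(x$persons$zygosity == "MZ"), " MZ / ",
      sum(x$persons$zygosity == "DZ"), " DZ persons), ",
      nrow(x$visits), " visits\n", sep = "")
  if (np > 0L) {
    ar <- range(x$visits$age_years)
    cat(sprintf("  age range %.1f-%.1f years; %.1f visits/person on average\n",
                ar[1], ar[2], nrow(x$visits) / np))
  }
  invisible(x)
}

.cohort_files <- function(path) {
  if (dir.exists(path) || grepl("/$", path)) {
    c(persons = file.path(path, "persons.csv"),
      visits = file.path(path, "visits.csv"))
  } else {
    c(persons = paste0(path, "_persons.csv"),
      visits = paste0(path, "_visits.csv"))
  }
}

.read_table <- function(file, sep) {
  if (is.null(sep)) {
    # sniff: tab wins over comma if present in the header line
    hdr <- readLines(file, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                    na.strings = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.apply_schema <- function(df, mapping, what) {
  if (is.null(mapping)) return(df)
  mapping <- unlist(mapping)
  missing_src <- setdiff(unname(mapping), names(df))
  if (length(missing_src) > 0L)
    stop("schema maps ", what, " column(s) absent from file: ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  idx <- match(unname(mapping), names(df))
  names(df)[idx] <- names(mapping)
  df
}

.coerce_types <- function(df, numeric_cols, what) {
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    if (is.numeric(raw)) next
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0L)
      stop("column '", col, "' of ", what,
           " fails numeric coercion at row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    df[[col]] <- num
  }
  df
}

.person_numeric_cols <- c("birth_year", "isced", "isei", "parental_sei",
                          "ses", paste0("fs", 1:4))
.visit_numeric_cols <- c("age_years", "grip", "pef", "height_m", "gait",
                         "vision_self", "hearing_self", "fai")

#' Read a twin cohort from delimited text
#'
#' Reads a persons table and a visits table.  `path` is either a directory
#' (containing `persons.csv` and `visits.csv`) or a file prefix (reading
#' `<path>_persons.csv` and `<path>_visits.csv`).  The delimiter is sniffed
#' from the header (tab or comma) unless given.  Missing cells are empty
#' fields.  A schema mapping can rename arbitrary source columns onto the
#' canonical column names; it is a list with elements `persons` and `visits`,
#' each a named character vector `c(canonical = "source_name", ...)`, or the
#' path to a YAML file holding the same structure.
#'
#' @param path directory or file prefix (see Details).
#' @param schema optional column-mapping list or YAML file path.
#' @param sep field separator; `NULL` (default) sniffs tab vs. comma.
#' @param validate validate the result (default `TRUE`).
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, schema = NULL, sep = NULL, validate = TRUE) {
  files <- .cohort_files(path)
  for (f in files)
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  if (is.character(schema) && length(schema) == 1L)
    schema <- yaml::read_yaml(schema)
  persons <- .read_table(files["persons"], sep)
  visits <- .read_table(files["visits"], sep)
  persons <- .apply_schema(persons, schema$persons, "persons")
  visits <- .apply_schema(visits, schema$visits, "visits")
  persons <- .coerce_types(persons, .person_numeric_cols, "persons")
  visits <- .coerce_types(visits, .visit_numeric_cols, "visits")
  for (col in c("person_id", "pair_id"))
    if (col %in% names(persons)) persons[[col]] <- as.character(persons[[col]])
  if ("person_id" %in% names(visits))
    visits$person_id <- as.character(visits$person_id)
  cohort_table(persons, visits, validate = validate)
}

#' Write a twin cohort to delimited text
#'
#' Inverse of [read_cohort()]: writes `<path>_persons.csv` and
#' `<path>_visits.csv` (or `persons.csv`/`visits.csv` inside `path` if it is
#' an existing directory).  Missing values are written as empty fields, so
#' `read_cohort(write_cohort(x))` round-trips exactly.  Visits are written
#' sorted by person and age.
#'
#' @param cohort a `cohort_table`.
#' @param path directory or file prefix.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "cohort_table"))
  files <- .cohort_files(path)
  v <- cohort$visits
  if (nrow(v) > 0L) v <- v[order(v$person_id, v$age_years), , drop = FALSE]
  utils::write.table(cohort$persons, files["persons"], sep = sep, na = "",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(v, files["visits"], sep = sep, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a cohort to complete twin pairs
#'
#' Keeps only pairs with exactly two members; when `require` names a
#' person-level variable, both members must additionally have a non-missing
#' value on it.  Singletons (and their visits) are removed.  This is the
#' analysis split used for co-twin control models, which are run on complete
#' pairs only, while phenotypic models retain singletons.
#'
#' @param cohort a `cohort_table`.
#' @param require optional name of a person-level column that must be
#'   non-missing for both members.
#' @return a `cohort_table` (possibly with zero rows).
#' @export
complete_pairs <- function(cohort, require = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  p <- cohort$persons
  ok <- rep(TRUE, nrow(p))
  if (!is.null(require)) {
    if (!require %in% names(p))
      stop("person-level column not found: ", require, call. = FALSE)
    ok <- !is.na(p[[require]])
  }
  eligible <- p[ok, , drop = FALSE]
  size <- table(eligible$pair_id)
  keep_pairs <- names(size)[size == 2L]
  persons <- eligible[eligible$pair_id %in% keep_pairs, , drop = FALSE]
  visits <- cohort$visits[cohort$visits$person_id %in% persons$person_id, ,
                          drop = FALSE]
  rownames(persons) <- NULL
  rownames(visits) <- NULL
  cohort_table(persons, visits, validate = FALSE)
}

#' Merge persons and visits into one long model frame
#'
#' Joins visit rows to their person-level records, giving the one-row-per
#' person-occasion table that design construction works from.  Persons
#' without visits are dropped.
#'
#' @param cohort a `cohort_table`.
#' @return a data frame with one row per visit and all person-level columns
#'   repeated on each of the person's rows.
#' @export
cohort_frame <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- merge(cohort$visits, cohort$persons, by = "person_id",
               sort = FALSE)
  out <- out[order(out$person_id, out$age_years), , drop = FALSE]
  rownames(out) <- NULL
  out
}
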
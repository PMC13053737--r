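#' Fit a single-factor model to the financial-strain items
#'
#' Fits a one-factor model by maximum likelihood (via [stats::factanal()])
#' to the four financial-strain items, treated as numeric and oriented so
#' that higher = more strain.  Items are standardized before factoring;
#' loadings are sign-fixed so their sum is positive.  Heywood cases are
#' handled by the optimizer's uniqueness floor (0.005) and flagged.  A fit
#' warning is recorded when the inter-item correlations are near zero
#' (essentially independent items), since maximum likelihood then tends to
#' a meaningless boundary solution rather than to all-zero loadings.
#'
#' @param items data frame or matrix with 4 numeric item columns; rows with
#'   any missing item are dropped for estimation (scoring tolerates
#'   missingness, see [score_fs()]).
#' @param min_n minimum number of complete rows (default 20).
#' @return an object of class `fs_factor_model` with elements `loadings`,
#'   `uniquenesses` (both length 4, on the standardized item scale),
#'   `item_means`, `item_sds`, `heywood` (logical), `weak_fit` (logical)
#'   and `n_used`.
#' @export
fit_single_factor <- function(items, min_n = 20L) {
  items <- as.data.frame(items)
  if (ncol(items) != 4L)
    stop("expected 4 item columns, got ", ncol(items), call. = FALSE)
  items[] <- lapply(items, as.numeric)
  item_means <- vapply(items, mean, 0, na.rm = TRUE)
  item_sds <- vapply(items, stats::sd, 0, na.rm = TRUE)
  if (any(!is.finite(item_sds)) || any(item_sds <= 0))
    stop("constant or empty item column(s): ",
         paste(names(items)[!is.finite(item_sds) | item_sds <= 0],
               collapse = ", "), call. = FALSE)
  complete <- stats::complete.cases(items)
  if (sum(complete) < min_n)
    stop("need >= ", min_n, " complete rows to fit the factor model (got ",
         sum(complete), ")", call. = FALSE)
  z <- scale(items[complete, , drop = FALSE], center = item_means,
             scale = item_sds)

  R <- stats::cor(z)
  # a singular correlation matrix (e.g. duplicated items) gets a tiny ridge
  # so the ML optimizer can run; the offending item then hits the floor
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    R <- (R + diag(1e-6, ncol(R))) / (1 + 1e-6)
  fa <- tryCatch(
    stats::factanal(covmat = R, factors = 1L, n.obs = sum(complete),
                    rotation = "none", control = list(lower = 0.005)),
    error = function(e)
      stop("single-factor estimation failed: ", conditionMessage(e),
           call. = FALSE))
  lambda <- as.numeric(fa$loadings)
  if (sum(lambda) < 0) lambda <- -lambda
  psi <- as.numeric(fa$uniquenesses)
  heywood <- any(psi <= 0.005 + 1e-8)
  # near-zero inter-item correlation: the ML solution is a meaningless
  # boundary fit, so flag the structure itself as weak
  weak <- mean(abs(R[upper.tri(R)])) < 0.1
  if (heywood)
    warning("Heywood case: uniqueness floored at 0.005 for item(s) ",
            paste(names(items)[psi <= 0.005 + 1e-8], collapse = ", "),
            call. = FALSE)
  if (weak)
    warning("weak single-factor structure: near-zero inter-item ",
            "correlations", call. = FALSE)
  structure(list(loadings = stats::setNames(lambda, names(items)),
                 uniquenesses = stats::setNames(psi, names(items)),
                 item_means = item_means,
                 item_sds = item_sds,
                 heywood = heywood,
                 weak_fit = weak,
                 n_used = sum(complete)),
            class = "fs_factor_model")
}

#' @export
print.fs_factor_model <- function(x, ...) {
  cat("Single-factor financial strain model (ML, n =", x$n_used, ")\n")
  tab <- cbind(loading = x$loadings, uniqueness = x$uniquenesses)
  print(round(tab, 3))
  if (x$heywood) cat("  note: Heywood case, uniqueness floored at 0.005\n")
  if (x$weak_fit) cat("  note: weak fit, items nearly independent\n")
  invisible(x)
}

# regression (Thomson) factor score from the observed-item submodel:
# f_hat = lambda_o' (lambda_o lambda_o' + Psi_o)^{-1} z_o
.fs_raw_score <- function(zrow, lambda, psi) {
  o <- which(!is.na(zrow))
  if (length(o) == 0L) return(NA_real_)
  lo <- lambda[o]
  sigma_oo <- tcrossprod(lo) + diag(psi[o], nrow = length(o))
  as.numeric(crossprod(lo, solve(sigma_oo, zrow[o])))
}

#' Score financial strain with missing-item tolerance
#'
#' Computes regression-method (Thomson) factor scores from the fitted
#' single-factor model.  For a respondent with a subset of observed items
#' the score uses the submodel restricted to those items, which equals the
#' conditional expectation of the factor given the observed items under the
#' fitted Gaussian model.  Scores are then affinely mapped to the T metric
#' (mean 50, SD 10) within each declared sample; with `sample = NULL` the
#' whole table is one sample.  Higher scores indicate more financial strain.
#'
#' @param items data frame/matrix of the 4 items (missing allowed; a row
#'   with all items missing gets a missing score).
#' @param model an `fs_factor_model` from [fit_single_factor()].
#' @param sample optional vector (e.g. `study_label`) defining the samples
#'   within which the T-scaling is applied.
#' @param tscore map to T metric (default `TRUE`); `FALSE` returns raw
#'   factor scores.
#' @return data frame with `fs` (score) and `n_items_used`.
#' @export
score_fs <- function(items, model, sample = NULL, tscore = TRUE) {
  stopifnot(inherits(model, "fs_factor_model"))
  items <- as.data.frame(items)
  if (ncol(items) != 4L)
    stop("expected 4 item columns", call. = FALSE)
  z <- sweep(sweep(as.matrix(items), 2L, model$item_means, "-"),
             2L, model$item_sds, "/")
  raw <- apply(z, 1L, .fs_raw_score, lambda = unname(model$loadings),
               psi = unname(model$uniquenesses))
  n_used <- rowSums(!is.na(z))
  out <- data.frame(fs = raw, n_items_used = n_used)
  if (!tscore) return(out)
  grp <- if (is.null(sample)) rep("all", nrow(out)) else as.character(sample)
  for (g in unique(grp)) {
    idx <- which(grp == g & !is.na(out$fs))
    if (length(idx) < 2L) next
    m <- mean(out$fs[idx]); s <- stats::sd(out$fs[idx])
    if (s > 0) out$fs[idx] <- 50 + 10 * (out$fs[idx] - m) / s
  }
  out
}

#' Save / load a financial-strain factor model
#'
#' YAML round-trip for `fs_factor_model`, so scoring can be frozen (e.g.
#' loadings estimated on one sample and applied to another).
#'
#' @param model an `fs_factor_model`.
#' @param path YAML file path.
#' @export
write_fs_model <- function(model, path) {
  stopifnot(inherits(model, "fs_factor_model"))
  yaml::write_yaml(list(loadings = as.list(model$loadings),
                        uniquenesses = as.list(model$uniquenesses),
                        item_means = as.list(model$item_means),
                        item_sds = as.list(model$item_sds),
                        heywood = model$heywood,
                        weak_fit = model$weak_fit,
                        n_used = model$n_used),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_fs_model
#' @export
read_fs_model <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(list(loadings = unlist(raw$loadings),
                 uniquenesses = unlist(raw$uniquenesses),
                 item_means = unlist(raw$item_means),
                 item_sds = unlist(raw$item_sds),
                 heywood = isTRUE(raw$heywood),
                 weak_fit = isTRUE(raw$weak_fit),
                 n_used = raw$n_used),
            class = "fs_factor_model")
}
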
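#' Min-max normalization
#'
#' Affine rescaling of a sample onto `[0, 1]`. Optionally applies limits
#' frozen from another sample (e.g. a training set) so verification and
#' prediction data are scaled consistently.
#'
#' @param values Numeric vector.
#' @param limits Optional `c(min, max)` to use instead of `range(values)`.
#' @return Rescaled vector; attribute `"limits"` records the limits used.
#' @export
minmax_normalize <- function(values, limits = NULL) {
  if (is.null(limits)) limits <- range(values, na.rm = TRUE)
  if (limits[2] <= limits[1])
    stop("constant input: min-max normalization undefined")
  out <- (values - limits[1]) / (limits[2] - limits[1])
  attr(out, "limits") <- limits
  out
}

#' Chronological build/verify split with outlier screening
#'
#' Splits each season's paired samples chronologically: the first `build_n`
#' rows build the model, the remainder verify it. Optionally removes
#' abnormal rows from the verification portion: rows whose absolute
#' standardized residual under the best preliminary fit (by build R-squared
#' across all families) exceeds `outlier_sd`. The eliminated count is
#' reported so splits can be compared with published bookkeeping.
#'
#' @param pairs Paired samples (`date`, `x`, `y`, `season`).
#' @param build_n Named vector/list of per-season build counts, or a single
#'   count, or `NULL` to use `build_fraction`.
#' @param build_fraction Fraction of rows used for building when `build_n`
#'   is `NULL` (default 2/3).
#' @param outlier_sd Standardized-residual threshold; `Inf` disables
#'   screening.
#' @return Named list per season: `build`, `verify`, `eliminated` (rows),
#'   `n_eliminated`.
#' @export
split_by_season <- function(pairs, build_n = NULL, build_fraction = 2 / 3,
                            outlier_sd = 3) {
  pairs <- pairs[!is.na(pairs$season), , drop = FALSE]
  out <- list()
  for (s in unique(pairs$season)) {
    d <- pairs[pairs$season == s, , drop = FALSE]
    d <- d[order(d$date), , drop = FALSE]
    nb <- if (is.null(build_n)) floor(build_fraction * nrow(d))
          else if (length(build_n) == 1 && is.null(names(build_n))) build_n
          else build_n[[s]]
    nb <- min(max(1L, as.integer(nb)), nrow(d) - 1L)
    build <- d[seq_len(nb), , drop = FALSE]
    verify <- d[-seq_len(nb), , drop = FALSE]
    eliminated <- verify[0, , drop = FALSE]
    if (is.finite(outlier_sd) && nrow(verify) > 2) {
      prelim <- fit_all_families(build$x, build$y)
      best <- prelim[[which.max(vapply(prelim, function(m)
        m$diagnostics$r2_build, 0))]]
      res <- verify$y - predict_family(best, verify$x)
      ok <- is.finite(res)
      z <- rep(0, length(res))
      z[ok] <- (res[ok] - mean(res[ok])) / max(stats::sd(res[ok]),
                                               .Machine$double.eps)
      drop <- abs(z) > outlier_sd
      eliminated <- verify[drop, , drop = FALSE]
      verify <- verify[!drop, , drop = FALSE]
    }
    out[[s]] <- list(build = build, verify = verify,
                     eliminated = eliminated,
                     n_eliminated = nrow(eliminated))
  }
  out
}

n_coefficients <- function(family) {
  switch(family, linear = 2L, logarithmic = 2L, exponential = 2L,
         power = 2L, quadratic = 3L, cubic = 4L,
         stop(sprintf("unknown model family '%s'", family)))
}

#' Fit one AOD-PM2.5 regression family
#'
#' The six candidate relations between AOD (x) and PM2.5 (y): linear,
#' logarithmic `a0 + a1 ln x`, exponential `a0 e^(a1 x)`, power `a0 x^a1`,
#' and quadratic/cubic polynomials. Polynomial and logarithmic families are
#' ordinary least squares on the transformed predictors; exponential and
#' power are least squares on `log(y)` against `x` or `log(x)` and
#' back-transformed, which recovers noise-free generating coefficients
#' exactly and is the standard practice for these families.
#'
#' @param family Family name.
#' @param x,y Numeric samples (x > 0 for logarithmic/power; y > 0 for
#'   exponential/power).
#' @param refine If `TRUE`, polish exponential/power coefficients by
#'   Gauss-Newton nonlinear least squares on the original scale, seeded from
#'   the log-scale fit.
#' @return A `pm25_model`: `family`, `coef` (a0, a1, ...), `season` (unset),
#'   `diagnostics` (filled by [goodness()]/[select_model()]).
#' @export
fit_family <- function(family, x, y, refine = FALSE) {
  if (!family %in% MODEL_FAMILIES)
    stop("`family` must be one of: ", paste(MODEL_FAMILIES, collapse = ", "))
  p <- n_coefficients(family)
  if (length(x) <= p) stop("not enough samples to fit this family")
  if (family %in% c("logarithmic", "power") && any(x <= 0))
    stop(sprintf("the %s family requires x > 0", family))
  if (family %in% c("exponential", "power") && any(y <= 0))
    stop(sprintf("the %s family requires y > 0", family))
  cf <- switch(family,
    linear = stats::coef(stats::lm(y ~ x)),
    logarithmic = stats::coef(stats::lm(y ~ log(x))),
    quadratic = stats::coef(stats::lm(y ~ x + I(x^2))),
    cubic = stats::coef(stats::lm(y ~ x + I(x^2) + I(x^3))),
    exponential = {
      f <- stats::coef(stats::lm(log(y) ~ x))
      c(exp(f[1]), f[2])
    },
    power = {
      f <- stats::coef(stats::lm(log(y) ~ log(x)))
      c(exp(f[1]), f[2])
    }
  )
  cf <- unname(cf)
  if (refine && family %in% c("exponential", "power")) {
    form <- if (family == "exponential") y ~ a0 * exp(a1 * x) else y ~ a0 * x^a1
    fit <- try(stats::nls(form, data = data.frame(x = x, y = y),
                          start = list(a0 = cf[1], a1 = cf[2])),
               silent = TRUE)
    if (!inherits(fit, "try-error")) cf <- unname(stats::coef(fit))
  }
  structure(list(family = family, coef = cf, season = NA_character_,
                 diagnostics = list()),
            class = "pm25_model")
}

#' Evaluate a fitted model
#'
#' @param model A `pm25_model`.
#' @param x Predictor values.
#' @return Predicted PM2.5; `NaN`/`-Inf` possible outside the family domain.
#' @export
predict_family <- function(model, x) {
  cf <- c(model$coef, 0, 0, 0)[1:4]
  family_eval(model$family, x, cf[1], cf[2], cf[3], cf[4])
}

fit_all_families <- function(x, y, families = MODEL_FAMILIES,
                             refine = FALSE) {
  fits <- list()
  for (f in families) {
    m <- try(fit_family(f, x, y, refine = refine), silent = TRUE)
    if (inherits(m, "try-error")) next
    g <- goodness(m, x, y)
    m$diagnostics$r2_build <- g$r2
    m$diagnostics$f_build <- g$f_stat
    fits[[f]] <- m
  }
  if (length(fits) == 0) stop("no family could be fitted")
  fits
}

#' Goodness of fit: R-squared and F statistic
#'
#' R-squared is computed on the original concentration scale as
#' `1 - SSE/SST`, which coincides with the regression-sum-of-squares ratio
#' for least-squares linear fits and is bounded above by 1 for every family
#' (the raw regression-SS ratio can exceed 1 for back-transformed nonlinear
#' fits). F is the regression F statistic
#' `(R2/p) / ((1-R2)/(n-p-1))` with `p` predictor terms.
#'
#' @param model A `pm25_model`.
#' @param x,y Evaluation sample.
#' @return A list `r2`, `f_stat`.
#' @export
goodness <- function(model, x, y) {
  p <- n_coefficients(model$family) - 1L
  if (length(y) <= p + 1) stop("sample too small for the F statistic")
  yhat <- predict_family(model, x)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero total sum of squares")
  r2 <- 1 - sum((yhat - y)^2) / sst
  f_stat <- (r2 / p) / ((1 - r2) / (length(y) - p - 1))
  list(r2 = r2, f_stat = f_stat)
}

#' Root mean square error
#'
#' `sqrt(mean((yhat - y)^2))` (n denominator), in ug/m3.
#'
#' @param model A `pm25_model`.
#' @param x,y Evaluation sample.
#' @return RMSE.
#' @export
rmse <- function(model, x, y) {
  if (length(y) < 1) stop("empty sample")
  yhat <- predict_family(model, x)
  sqrt(mean((yhat - y)^2))
}

#' Fit all families and select the best by verification skill
#'
#' Fits every candidate family on the build set, evaluates each on the
#' verification set, and ranks by verification R-squared (descending), then
#' lower verification RMSE, then fewer coefficients.
#'
#' @param build,verify Data frames with columns `x`, `y`.
#' @param families Candidate family names.
#' @param refine Passed to [fit_family()].
#' @return The winning `pm25_model` with full diagnostics
#'   (`r2_build`, `f_build`, `r2_verify`, `rmse_verify`) and an attribute
#'   `"candidates"` holding all scored fits.
#' @export
select_model <- function(build, verify, families = MODEL_FAMILIES,
                         refine = FALSE) {
  fits <- fit_all_families(build$x, build$y, families, refine)
  for (nm in names(fits)) {
    m <- fits[[nm]]
    g <- try(goodness(m, verify$x, verify$y), silent = TRUE)
    if (inherits(g, "try-error")) {
      fits[[nm]] <- NULL
      next
    }
    m$diagnostics$r2_verify <- g$r2
    m$diagnostics$rmse_verify <- rmse(m, verify$x, verify$y)
    fits[[nm]] <- m
  }
  if (length(fits) == 0) stop("no candidate could be verified")
  r2v <- vapply(fits, function(m) m$diagnostics$r2_verify, 0)
  rms <- vapply(fits, function(m) m$diagnostics$rmse_verify, 0)
  ncf <- vapply(fits, function(m) n_coefficients(m$family), 0L)
  best <- fits[[order(-r2v, rms, ncf)[1]]]
  attr(best, "candidates") <- fits
  best
}

#' Map an AOD field to a PM2.5 grid
#'
#' Cellwise evaluation of a fitted seasonal model. Nodata propagates;
#' negative predictions are floored at 0; cells with non-positive AOD under
#' power/logarithmic families (outside the family domain) become nodata.
#'
#' @param model A `pm25_model`.
#' @param aod An `aod_field` or AOD matrix.
#' @return PM2.5 matrix (ug/m3) with `NA` nodata.
#' @export
predict_grid <- function(model, aod) {
  m <- if (inherits(aod, "aod_field")) aod$tau550 else aod
  out <- matrix(NA_real_, nrow(m), ncol(m))
  ok <- !is.na(m)
  if (model$family %in% c("power", "logarithmic")) ok <- ok & m > 0
  out[ok] <- pmax(predict_family(model, m[ok]), 0)
  out
}

#' Save / load fitted seasonal models
#'
#' One flat JSON file holding, per season, the family, coefficients and
#' diagnostics.
#'
#' @param models Named list (season -> `pm25_model`).
#' @param path File path.
#' @return `models_save` returns `path` invisibly; `models_load` the list.
#' @export
models_save <- function(models, path) {
  payload <- lapply(models, function(m)
    list(family = m$family, coef = m$coef, season = m$season,
         diagnostics = m$diagnostics))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname models_save
#' @export
models_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(p, function(m) structure(
    list(family = m$family, coef = as.numeric(m$coef), season = m$season,
         diagnostics = as.list(m$diagnostics)),
    class = "pm25_model"))
}
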
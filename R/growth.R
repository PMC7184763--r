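#' Trait time series
#'
#' Observations of one trait of one variety over the growth period.
#'
#' @param variety Variety id (character).
#' @param trait Trait name (character).
#' @param days Numeric vector, days after seedling emergence; strictly
#'   increasing.
#' @param values Numeric trait values, all >= 0.
#' @param stages Optional growth-stage labels (e.g. "V3".."R8"), kept as
#'   opaque strings.
#' @return Object of class `"trait_series"`.
#' @export
trait_series <- function(variety, trait, days, values, stages = NULL) {
  stopifnot(length(days) == length(values), all(diff(days) > 0),
            all(values >= 0))
  if (!is.null(stages)) stopifnot(length(stages) == length(days))
  structure(list(variety = as.character(variety), trait = as.character(trait),
                 days = as.numeric(days), values = as.numeric(values),
                 stages = stages),
            class = "trait_series")
}

check_logistic_params <- function(n0, k, r) {
  if (!all(is.finite(c(n0, k, r))) || n0 <= 0 || k <= 0 || r <= 0)
    stop("invalid parameters: N0, K, r must all be positive")
}

#' Three-parameter logistic growth curve
#'
#' \deqn{N(t) = \frac{K}{1 + (K/N_0 - 1) e^{-rt}}}
#' where `N0` is the initial trait value (at t = 0), `K` the environmental
#' capacity (upper asymptote) and `r` the maximal relative growth rate
#' (1/day).
#'
#' @param params List or named vector with elements `n0`, `k`, `r` (a
#'   [fit_logistic()] result works directly).
#' @param t Days after seedling emergence (vectorized).
#' @return Trait value(s) at `t`.
#' @export
logistic_value <- function(params, t) {
  n0 <- params[["n0"]]; k <- params[["k"]]; r <- params[["r"]]
  check_logistic_params(n0, k, r)
  k / (1 + (k / n0 - 1) * exp(-r * t))
}

#' Logistic growth rate
#'
#' The rate form of the logistic model,
#' \deqn{\frac{dN}{dt} = r (1 - N/K) N,}
#' evaluated at the curve value `N(t)`. The rate is maximal (`r K / 4`) when
#' `N = K/2`, i.e. at the inflection time returned by [max_rate_time()].
#'
#' @inheritParams logistic_value
#' @return Growth rate(s) in trait units per day.
#' @export
growth_rate <- function(params, t) {
  n <- logistic_value(params, t)
  params[["r"]] * (1 - n / params[["k"]]) * n
}

#' Fit the logistic growth model to a trait series
#'
#' Minimizes the residual sum of squares over `(N0, K, r)` by gradient
#' descent on log-transformed parameters (which enforces positivity), with
#' the observations scaled by their maximum so one learning rate suits all
#' traits. Initial values: `K = 1.05 * max(value)`, `N0 =` first observation,
#' `r` from the slope of `logit(value/K)` against time. An optional
#' Levenberg-Marquardt refinement is available behind `refine` but is off by
#' default so plain gradient descent is the default estimation path.
#'
#' @param series A [trait_series()], or anything with `$days` and `$values`.
#' @param learning_rate Gradient-descent learning rate on the scaled problem.
#' @param max_iter Iteration budget.
#' @param ftol Relative decrease in RSS below which iteration stops.
#' @param refine If `TRUE`, polish the gradient-descent solution with
#'   Levenberg-Marquardt ([minpack.lm::nls.lm]).
#' @return Object of class `"logistic_fit"`: `n0`, `k`, `r`, `rss`,
#'   `t_inflection` (days, `NA` flagged when `K <= 2 N0`), `rate_max`
#'   (`r K / 4`), `fitted_max` (fitted value at the last observed day),
#'   `converged`, `iterations`, plus the input `series`.
#' @export
fit_logistic <- function(series, learning_rate = 1e-2, max_iter = 50000,
                         ftol = 1e-14, refine = FALSE) {
  t <- series$days; y <- series$values
  if (length(t) < 4) stop("need at least 4 observations to fit")
  if (any(y < 0)) stop("trait values must be non-negative")
  scale <- max(y)
  if (scale <= 0) stop("all-zero series cannot be fitted")
  degenerate <- stats::sd(y) == 0
  ys <- y / scale
  k0 <- 1.05
  n00 <- max(ys[1], 1e-4)
  # slope of logit(y/K0) vs t gives r; guard the degenerate flat case
  z <- pmin(pmax(ys / k0, 1e-6), 1 - 1e-6)
  lg <- log(z / (1 - z))
  r0 <- tryCatch(stats::coef(stats::lm(lg ~ t))[2], error = function(e) NA)
  if (!is.finite(r0) || r0 <= 1e-6) r0 <- 1e-3
  res <- .logistic_gd(t, ys, n00, k0, r0, learning_rate, max_iter, ftol)
  n0 <- res$n0 * scale; k <- res$k * scale; r <- res$r
  rss <- res$rss * scale^2
  converged <- isTRUE(res$converged) && !degenerate
  if (degenerate)
    warning("constant series: growth rate unidentifiable, fit did not converge")
  if (refine) {
    lmres <- tryCatch(minpack.lm::nls.lm(
      par = log(c(n0 = n0, k = k, r = r)),
      fn = function(p) {
        pp <- exp(p)
        pp[["k"]] / (1 + (pp[["k"]] / pp[["n0"]] - 1) * exp(-pp[["r"]] * t)) - y
      }), error = function(e) NULL)
    if (!is.null(lmres)) {
      pp <- exp(lmres$par)
      rss2 <- sum(lmres$fvec^2)
      if (rss2 < rss) {
        n0 <- pp[["n0"]]; k <- pp[["k"]]; r <- pp[["r"]]; rss <- rss2
      }
    }
  }
  if (!converged && !degenerate)
    warning("logistic fit did not converge within the iteration budget (RSS ",
            signif(rss, 6), ")")
  params <- list(n0 = n0, k = k, r = r)
  tstar <- if (k > 2 * n0) log(k / n0 - 1) / r else NA_real_
  structure(list(n0 = n0, k = k, r = r, rss = rss,
                 t_inflection = tstar,
                 inflection_flagged = k <= 2 * n0,
                 rate_max = r * k / 4,
                 fitted_max = logistic_value(params, max(t)),
                 converged = converged, iterations = res$iterations,
                 series = series),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit [%s / %s]: N0=%.4g  K=%.4g  r=%.4g 1/day\n",
              x$series$variety %||% "?", x$series$trait %||% "?",
              x$n0, x$k, x$r))
  cat(sprintf("  RSS=%.4g  t*=%.2f days  max rate=%.4g /day  fitted max=%.4g\n",
              x$rss, x$t_inflection, x$rate_max, x$fitted_max))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time of maximum growth rate
#'
#' The logistic growth rate peaks when `N(t) = K/2`, at
#' \deqn{t^* = \ln(K/N_0 - 1) / r.}
#' Negative `t*` (when `K <= 2 N0`, i.e. the inflection precedes emergence)
#' is returned as-is but was already flagged by [fit_logistic()].
#'
#' @param fit A [fit_logistic()] result or a list with `n0`, `k`, `r`.
#' @param round_days If `TRUE`, round to the nearest whole day for
#'   presentation.
#' @return Days after seedling emergence.
#' @export
max_rate_time <- function(fit, round_days = FALSE) {
  n0 <- fit[["n0"]]; k <- fit[["k"]]; r <- fit[["r"]]
  check_logistic_params(n0, k, r)
  if (k <= n0) stop("invalid fit: K must exceed N0")
  tstar <- log(k / n0 - 1) / r
  if (round_days) round(tstar) else tstar
}

#' Phenotypic fingerprint matrix
#'
#' Normalizes the four fingerprint traits (plant height, plant length, plant
#' width, canopy height) to \[0, 1\] for radar-chart display: one row per
#' (variety, stage), one column per trait. Default normalization divides each
#' trait by its global maximum over all varieties and stages, so every column
#' attains 1 somewhere in the matrix; `per_stage = TRUE` normalizes within
#' each stage instead.
#'
#' @param traits Data frame with columns `variety`, `stage` and the four
#'   trait columns `plant_height_cm`, `plant_length_cm`, `plant_width_cm`,
#'   `canopy_height_cm`.
#' @param group_by `"stage"` or `"variety"`; controls row ordering (stage- or
#'   variety-major) for downstream radar plotting.
#' @param per_stage Normalize within each stage rather than globally.
#' @return Object of class `"fingerprint_matrix"`: `$values` (numeric matrix
#'   rows = variety x stage, columns = traits), `$meta` (data.frame variety,
#'   stage), `$group_by`.
#' @export
fingerprint <- function(traits, group_by = c("stage", "variety"),
                        per_stage = FALSE) {
  group_by <- match.arg(group_by)
  cols <- c("plant_height_cm", "plant_length_cm", "plant_width_cm",
            "canopy_height_cm")
  missing_cols <- setdiff(c("variety", "stage", cols), names(traits))
  if (length(missing_cols))
    stop("incomplete table: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  ord <- if (group_by == "stage")
    order(match(traits$stage, unique(traits$stage)),
          match(traits$variety, unique(traits$variety)))
  else
    order(match(traits$variety, unique(traits$variety)),
          match(traits$stage, unique(traits$stage)))
  tr <- traits[ord, , drop = FALSE]
  vals <- as.matrix(tr[, cols])
  if (per_stage) {
    for (s in unique(tr$stage)) {
      idx <- tr$stage == s
      mx <- apply(vals[idx, , drop = FALSE], 2, max)
      mx[mx <= 0] <- 1
      vals[idx, ] <- sweep(vals[idx, , drop = FALSE], 2, mx, "/")
    }
  } else {
    mx <- apply(vals, 2, max)
    mx[mx <= 0] <- 1
    vals <- sweep(vals, 2, mx, "/")
  }
  structure(list(values = vals,
                 meta = data.frame(variety = tr$variety, stage = tr$stage),
                 group_by = group_by, per_stage = per_stage),
            class = "fingerprint_matrix")
}

#' Pearson correlation of two value lists
#'
#' Sample Pearson correlation, used to compare model-extracted trait values
#' with reference (e.g. manually measured) values.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test, as used to compare field- and
#' barrel-planted phenotype distributions.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && isTRUE(all.equal(mean(a), mean(b))))
    return(list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Fit logistic growth curves for every (variety, trait) in a trait table
#'
#' @param traits Trait table as from [read_traits_csv()]: columns `variety`,
#'   `days` and one column per trait.
#' @param trait_cols Trait columns to fit (default: all `*_cm`, `*_cm2`,
#'   `*_dm3` columns).
#' @param ... Passed to [fit_logistic()].
#' @return Named list of [fit_logistic()] results, names `variety.trait`.
#' @export
fit_growth_table <- function(traits, trait_cols = NULL, ...) {
  if (is.null(trait_cols))
    trait_cols <- grep("_(cm|cm2|dm3)$", names(traits), value = TRUE)
  fits <- list()
  for (v in unique(traits$variety)) {
    sub <- traits[traits$variety == v, , drop = FALSE]
    sub <- sub[order(sub$days), , drop = FALSE]
    for (tc in trait_cols) {
      s <- trait_series(v, tc, sub$days, pmax(sub[[tc]], 0),
                        stages = sub$stage)
      fits[[paste(v, tc, sep = ".")]] <- fit_logistic(s, ...)
    }
  }
  fits
}
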
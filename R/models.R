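# Chronosequence models: von Bertalanffy biomass growth and the linear
# soil-accumulation trend, with uncertainty for age-specific point
# estimates.

#' Filter sites for age-based regression
#'
#' Failed revegetation projects fail within a year or two of planting, so a
#' "40-year-old" failure carries no information about 40 years of growth;
#' such sites are excluded from every age-based regression. Unrestored
#' sites are retained and represent an age of zero.
#'
#' @param sites Data frame with at least `status` and `age_years` columns.
#' @return The filtered data frame, with unrestored ages forced to 0.
#' @export
select_for_age_regression <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("status", "age_years") %in% names(sites)))
  keep <- sites$status != "restored_failure"
  out <- sites[keep, , drop = FALSE]
  out$age_years[out$status == "unrestored"] <- 0
  if (nrow(out) == 0L) {
    warning("all sites are failed restorations; nothing left to regress",
            call. = FALSE)
  }
  out
}

#' Evaluate the von Bertalanffy growth curve
#'
#' `a * (1 - exp(-b * age))^3`: a saturating accumulation curve with
#' asymptote `a` (maximum stand-level carbon or biomass) and rate `b`
#' controlling how quickly the stand approaches it. Zero at age 0,
#' monotone increasing, bounded above by `a`.
#'
#' @param a Asymptotic maximum (> 0), in the units of the response.
#' @param b Growth rate, 1/yr (> 0).
#' @param age Stand age(s), years (>= 0).
#' @return Curve value(s) in the units of `a`.
#' @examples
#' eval_vb(229.5, 0.12, 20)  # 172.5
#' @export
eval_vb <- function(a, b, age) {
  stopifnot(a > 0, b > 0, all(age >= 0))
  a * (1 - exp(-b * age))^3
}

#' Fit the von Bertalanffy curve by nonlinear least squares
#'
#' Estimates `(a, b)` of [eval_vb()] from per-site aboveground carbon vs.
#' age. Starting values follow a coarse but reproducible rule: `a0` is 1.05
#' times the largest observed response and `b0` the value on a grid
#' 0.05-1.0 minimising the residual sum at `a0` (a stand-in for choosing
#' starting values from graphical previews). Fitting uses
#' Levenberg-Marquardt least squares with bounds `a` in (0, 10 max(y)],
#' `b` in (0, 5], parameter tolerance 1e-8 and at most 500 iterations.
#' Non-convergence is reported in the `converged` flag rather than thrown.
#'
#' @param ages Site ages, years; at least one must be positive.
#' @param abg_c Aboveground carbon densities, Mg C/ha.
#' @param landform Optional label carried through to the result.
#' @return An object of class `growth_fit`: list with `a`, `b`,
#'   `residual_sd`, `n`, `converged`, `landform`, and the data used.
#' @examples
#' ages <- c(0, 2, 5, 10, 20, 40)
#' fit <- fit_vb(ages, eval_vb(200, 0.15, ages))
#' c(fit$a, fit$b)  # 200, 0.15
#' @export
fit_vb <- function(ages, abg_c, landform = NA_character_) {
  stopifnot(length(ages) == length(abg_c))
  ok <- is.finite(ages) & is.finite(abg_c)
  ages <- ages[ok]; abg_c <- abg_c[ok]
  if (length(ages) < 4L) {
    stop("need at least 4 observations to fit the growth curve",
         call. = FALSE)
  }
  if (!any(ages > 0)) stop("need at least one positive age", call. = FALSE)
  if (all(abg_c <= 0)) {
    stop("response is identically zero; no stand to fit", call. = FALSE)
  }
  ymax <- max(abg_c)
  a0 <- 1.05 * ymax
  b_grid <- seq(0.05, 1.0, by = 0.05)
  rss <- vapply(b_grid,
                function(b) sum((abg_c - eval_vb(a0, b, ages))^2),
                numeric(1))
  b0 <- b_grid[which.min(rss)]
  dat <- data.frame(age = ages, y = abg_c)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * (1 - exp(-b * age))^3,
      data = dat,
      start = list(a = a0, b = b0),
      lower = c(a = 1e-8, b = 1e-8),
      upper = c(a = 10 * ymax, b = 5),
      control = minpack.lm::nls.lm.control(ptol = 1e-8, maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    res <- list(a = NA_real_, b = NA_real_, residual_sd = NA_real_,
                n = length(ages), converged = FALSE, landform = landform,
                ages = ages, abg_c = abg_c)
    return(structure(res, class = "growth_fit"))
  }
  est <- stats::coef(fit)
  info <- fit$convInfo
  converged <- is.null(info) || isTRUE(info$isConv)
  res <- list(
    a = unname(est["a"]), b = unname(est["b"]),
    residual_sd = sqrt(sum(stats::resid(fit)^2) /
                         max(1, length(ages) - 2)),
    n = length(ages), converged = converged, landform = landform,
    ages = ages, abg_c = abg_c
  )
  structure(res, class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("von Bertalanffy growth fit",
      if (!is.na(x$landform)) sprintf("(%s)", x$landform), "\n")
  cat(sprintf("  a = %.3f Mg C/ha, b = %.4f /yr  [n = %d, %s]\n",
              x$a, x$b, x$n,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  residual sd %.3f Mg C/ha\n", x$residual_sd))
  invisible(x)
}

#' Uncertainty interval for the growth curve at a target age
#'
#' Default method: nonparametric bootstrap. Sites (age, response pairs) are
#' resampled with replacement, the curve refit, and the curve value at
#' `target_age` collected; the percentile interval of those draws is
#' reported. The alternative `"posterior"` method mirrors a Bayesian
#' refit: a random-walk Metropolis sampler over `(a, b)` with a Gaussian
#' likelihood and independent Gaussian priors centred on the least-squares
#' estimates (sd = 50% of each estimate), whose posterior draws give the
#' credible interval at `target_age`. Both are reproducible under a fixed
#' seed and leave the global random state untouched.
#'
#' @param fit A converged [fit_vb()] result.
#' @param target_age Age at which the point estimate is evaluated, years.
#' @param n_draws Bootstrap replicates or posterior draws (default 2000).
#' @param seed Integer seed; required.
#' @param level Nominal interval level (default 0.95).
#' @param method `"bootstrap"` (default) or `"posterior"`.
#' @return An `interval_estimate`: list with `point`, `low`, `high`,
#'   `level`, `method`, `n_draws`, `seed`.
#' @export
vb_point_interval <- function(fit, target_age = 20, n_draws = 2000, seed,
                              level = 0.95,
                              method = c("bootstrap", "posterior")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "growth_fit"))
  if (!fit$converged) stop("growth fit did not converge", call. = FALSE)
  if (missing(seed)) stop("an integer seed is required", call. = FALSE)
  ages <- fit$ages; y <- fit$abg_c
  if (length(ages) < 4L) {
    stop("too few sites to resample for an interval", call. = FALSE)
  }
  point <- eval_vb(fit$a, fit$b, target_age)
  draws <- with_seed(seed, {
    if (method == "bootstrap") {
      vapply(seq_len(n_draws), function(i) {
        repeat {
          idx <- sample.int(length(ages), replace = TRUE)
          # a resample with no positive age or all-zero response cannot be fit
          if (any(ages[idx] > 0) && any(y[idx] > 0)) break
        }
        f <- tryCatch(fit_vb(ages[idx], y[idx]), error = function(e) NULL)
        if (is.null(f) || !f$converged) return(NA_real_)
        eval_vb(f$a, f$b, target_age)
      }, numeric(1))
    } else {
      posterior_vb_draws(fit, n_draws, target_age)
    }
  })
  draws <- draws[is.finite(draws)]
  if (!length(draws)) stop("no usable draws", call. = FALSE)
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(point = point, low = qs[1], high = qs[2], level = level,
                 method = method, n_draws = n_draws, seed = seed),
            class = "interval_estimate")
}

# Random-walk Metropolis over (a, b); Gaussian likelihood with sd fixed at
# the NLS residual sd, priors N(a_hat, 0.5 a_hat), N(b_hat, 0.5 b_hat).
# Returns curve values at target_age for the retained draws.
posterior_vb_draws <- function(fit, n_draws, target_age) {
  ages <- fit$ages; y <- fit$abg_c
  sd_lik <- max(fit$residual_sd, 1e-6)
  log_post <- function(a, b) {
    if (a <= 0 || b <= 0 || b > 5) return(-Inf)
    sum(stats::dnorm(y, eval_vb(a, b, ages), sd_lik, log = TRUE)) +
      stats::dnorm(a, fit$a, 0.5 * fit$a, log = TRUE) +
      stats::dnorm(b, fit$b, 0.5 * fit$b, log = TRUE)
  }
  n_burn <- 500L
  n_iter <- n_burn + n_draws
  cur <- c(fit$a, fit$b)
  cur_lp <- log_post(cur[1], cur[2])
  step <- c(0.05 * fit$a, 0.05 * fit$b)
  out <- numeric(n_draws)
  for (i in seq_len(n_iter)) {
    prop <- cur + stats::rnorm(2, 0, step)
    lp <- log_post(prop[1], prop[2])
    if (log(stats::runif(1)) < lp - cur_lp) {
      cur <- prop; cur_lp <- lp
    }
    if (i > n_burn) out[i - n_burn] <- eval_vb(cur[1], cur[2], target_age)
  }
  out
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.3f  [%g%% %s interval %.3f, %.3f]  (%d draws, seed %d)\n",
              x$point, 100 * x$level, x$method, x$low, x$high,
              x$n_draws, x$seed))
  invisible(x)
}

#' Linear soil-carbon accumulation trend
#'
#' Ordinary least squares regression of soil stock (kg C/m2) on
#' restoration age, the a priori model for soil carbon in the
#' chronosequence. Reports intercept, slope, r2, the two-sided p-value for
#' the slope, residual degrees of freedom (n - 2) and the slope's 95%
#' confidence interval, which serves as the uncertainty around age-specific
#' point estimates.
#'
#' @param ages Site ages, years.
#' @param stocks_kg_m2 Soil carbon stocks, kg C/m2.
#' @param landform Optional label carried through.
#' @return An object of class `soil_trend`: list with `intercept`, `slope`,
#'   `r2`, `p_value`, `df`, `slope_ci_95`, `n`, `landform`.
#' @export
fit_soil_trend <- function(ages, stocks_kg_m2, landform = NA_character_) {
  stopifnot(length(ages) == length(stocks_kg_m2))
  ok <- is.finite(ages) & is.finite(stocks_kg_m2)
  ages <- ages[ok]; stocks_kg_m2 <- stocks_kg_m2[ok]
  if (length(ages) < 3L) {
    stop("need at least 3 observations for the soil trend", call. = FALSE)
  }
  if (stats::var(ages) == 0) {
    stop("ages have zero variance; slope is unidentifiable", call. = FALSE)
  }
  if (stats::var(stocks_kg_m2) == 0) {
    # constant response: flat line, no explained variance
    return(structure(list(
      intercept = stocks_kg_m2[1], slope = 0, r2 = 0, p_value = 1,
      df = length(ages) - 2L, slope_ci_95 = c(0, 0), n = length(ages),
      landform = landform), class = "soil_trend"))
  }
  fit <- stats::lm(stocks_kg_m2 ~ ages)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- stats::confint(fit, "ages", level = 0.95)
  structure(list(
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope = unname(co["ages", "Estimate"]),
    r2 = sm$r.squared,
    p_value = unname(co["ages", "Pr(>|t|)"]),
    df = fit$df.residual,
    slope_ci_95 = c(ci[1, 1], ci[1, 2]),
    n = length(ages),
    landform = landform
  ), class = "soil_trend")
}

#' @export
print.soil_trend <- function(x, ...) {
  cat("Soil C trend",
      if (!is.na(x$landform)) sprintf("(%s)", x$landform), "\n")
  cat(sprintf(
    "  stock = %.4f + %.4f * age kg C/m2  (r2 = %.4f, p = %.4f, df = %d)\n",
    x$intercept, x$slope, x$r2, x$p_value, x$df))
  cat(sprintf("  slope 95%% CI [%.4f, %.4f]\n",
              x$slope_ci_95[1], x$slope_ci_95[2]))
  invisible(x)
}

# Run code under a local RNG state seeded with `seed`; the caller's global
# state is untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
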
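# Probabilistic ILCR: parameter distributions, Monte Carlo propagation
# through the dose and risk equations, and exposure-distribution fitting with
# Kolmogorov-Smirnov family selection.

#' Parameter distribution specification
#'
#' Describes one uncertain (or constant) exposure parameter. For
#' `"lognormal"`, `p1`/`p2` are the mean and sd of the natural-log-transformed
#' data (draws are `exp(rnorm(p1, p2))`). For `"normal"` they are the
#' arithmetic mean and sd; draws below `lower` are rejected and redrawn, so a
#' physical floor (default 0) is always respected. `"constant"` repeats `p1`.
#'
#' @param kind One of `"lognormal"`, `"normal"`, `"constant"`.
#' @param p1,p2 Distribution parameters (`p2` ignored for constants).
#' @param lower Truncation floor for normal draws (default 0).
#' @return Object of class `param_spec`.
#' @examples
#' param_spec("lognormal", 2.7, 0.4)  # heating BaPeq, ng/m3
#' param_spec("normal", 35.1, 15.0)   # heating inhalation rate, m3/day
#' @export
param_spec <- function(kind = c("lognormal", "normal", "constant"),
                       p1, p2 = NULL, lower = 0) {
  kind <- match.arg(kind)
  if (kind != "constant") {
    if (is.null(p2) || !is.finite(p2) || p2 < 0) {
      stop("p2 (sd) must be a nonnegative number for ", kind, call. = FALSE)
    }
  }
  structure(list(kind = kind, p1 = p1, p2 = p2, lower = lower),
            class = "param_spec")
}

#' Draw from a parameter specification
#'
#' Uses the current RNG stream; seed at the caller (e.g. through
#' [run_ilcr_simulation()]'s scenario seed) for reproducibility.
#'
#' @param spec A [param_spec()].
#' @param n Number of draws, `>= 1`.
#' @return Numeric vector of `n` draws.
#' @export
sample_parameter <- function(spec, n) {
  if (!inherits(spec, "param_spec")) stop("spec must be a param_spec",
                                          call. = FALSE)
  stopifnot(n >= 1)
  switch(spec$kind,
    constant = rep(spec$p1, n),
    lognormal = exp(rnorm(n, spec$p1, spec$p2)),
    normal = {
      x <- rnorm(n, spec$p1, spec$p2)
      guard <- 0L
      while (any(bad <- x < spec$lower)) {
        x[bad] <- rnorm(sum(bad), spec$p1, spec$p2)
        guard <- guard + 1L
        if (guard > 1000L) {
          stop("truncation floor rejects nearly all draws", call. = FALSE)
        }
      }
      x
    },
    stop("invalid parameter kind", call. = FALSE)
  )
}

#' Seasonal Monte Carlo scenario
#'
#' Bundles the measured parameter distributions and the scenario constants
#' for one season. Defaults are the study conditions: heating BaPeq
#' ~ lognormal(log-mean 2.7, log-sd 0.4) ng/m3, IR ~ normal(35.1, 15.0) m3/d,
#' EF 140 d/yr; non-heating BaPeq ~ lognormal(-2.4, 1), IR ~ normal(42.1,
#' 12.5), EF 220 d/yr; BW ~ normal(29.9, 5.6) kg in both seasons; ED 10 yr,
#' AT 25500 d, CF 1e-6 mg/ng, SF 3.14 (mg/kg/day)^-1. Normal parameters are
#' floored at 0 by resampling.
#'
#' @param season `"heating"` or `"non-heating"`.
#' @param n_iterations Number of Monte Carlo iterations (default 10000).
#' @param seed Integer seed (default 1).
#' @param bapeq,ir,bw Optional [param_spec()] overrides.
#' @param ef,ed,at,cf,sf,acceptable_risk Optional constant overrides.
#' @return Object of class `ilcr_scenario`.
#' @export
ilcr_scenario <- function(season = c("heating", "non-heating"),
                          n_iterations = 10000L, seed = 1L,
                          bapeq = NULL, ir = NULL, bw = NULL,
                          ef = NULL, ed = 10, at = 25500, cf = 1e-6,
                          sf = 3.14, acceptable_risk = 1e-6) {
  season <- match.arg(season)
  stopifnot(n_iterations >= 1)
  if (is.null(bapeq)) {
    bapeq <- if (season == "heating") param_spec("lognormal", 2.7, 0.4)
             else param_spec("lognormal", -2.4, 1)
  }
  if (is.null(ir)) {
    ir <- if (season == "heating") param_spec("normal", 35.1, 15.0)
          else param_spec("normal", 42.1, 12.5)
  }
  if (is.null(bw)) bw <- param_spec("normal", 29.9, 5.6)
  consts <- exposure_scenario(season, ef = ef, ed = ed, at = at, cf = cf,
                              sf = sf, acceptable_risk = acceptable_risk)
  structure(
    list(season = season, n_iterations = as.integer(n_iterations),
         seed = as.integer(seed), bapeq = bapeq, ir = ir, bw = bw,
         ef = consts$ef, ed = ed, at = at, cf = cf, sf = sf,
         acceptable_risk = acceptable_risk),
    class = "ilcr_scenario"
  )
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Run the ILCR Monte Carlo simulation
#'
#' Draws C (BaPeq), IR and BW independently -- in that fixed order -- from the
#' scenario's distributions and propagates each iteration through
#' `ILCR_i = SF * CF * EF * ED / AT * C_i * IR_i / BW_i`. The scenario seed
#' makes the draw vector bit-reproducible.
#'
#' @param spec An [ilcr_scenario()].
#' @return Object of class `ilcr_sim`: list with `ilcr` (all draws), the
#'   parameter draws `c`, `ir`, `bw`, the `spec`, and summary statistics
#'   (`mean`, `median`, `sd`, `p5`, `p95`, `exceedance` vs the acceptable
#'   risk).
#' @examples
#' sim <- run_ilcr_simulation(ilcr_scenario("heating", 2000, seed = 7))
#' print(sim)
#' @export
run_ilcr_simulation <- function(spec) {
  stopifnot(inherits(spec, "ilcr_scenario"))
  n <- spec$n_iterations
  draws <- with_seed(spec$seed, {
    cc <- sample_parameter(spec$bapeq, n)
    ir <- sample_parameter(spec$ir, n)
    bw <- sample_parameter(spec$bw, n)
    list(c = cc, ir = ir, bw = bw)
  })
  risk <- spec$sf * spec$cf * spec$ef * spec$ed / spec$at *
    draws$c * draws$ir / draws$bw
  q <- quantile(risk, c(0.05, 0.5, 0.95), names = FALSE)
  structure(
    list(ilcr = risk, c = draws$c, ir = draws$ir, bw = draws$bw,
         spec = spec, mean = mean(risk), median = q[2], sd = sd(risk),
         p5 = q[1], p95 = q[3],
         exceedance = mean(risk > spec$acceptable_risk)),
    class = "ilcr_sim"
  )
}

#' Exceedance probability of a simulated risk distribution
#'
#' Fraction of Monte Carlo draws strictly greater than the threshold.
#'
#' @param result An `ilcr_sim`.
#' @param threshold Risk threshold (default the scenario's acceptable risk).
#' @return Fraction in `[0, 1]`.
#' @export
exceedance_probability <- function(result,
                                   threshold = result$spec$acceptable_risk) {
  stopifnot(inherits(result, "ilcr_sim"), length(result$ilcr) >= 1)
  mean(result$ilcr > threshold)
}

#' @export
print.ilcr_sim <- function(x, ...) {
  cat(sprintf(
    "ILCR Monte Carlo (%s season, %d iterations, seed %d)\n",
    x$spec$season, x$spec$n_iterations, x$spec$seed))
  cat(sprintf("  mean %.3g  median %.3g  sd %.3g\n", x$mean, x$median, x$sd))
  cat(sprintf("  P5 %.3g  P95 %.3g  P(ILCR > %.0e) = %.3f\n",
              x$p5, x$p95, x$spec$acceptable_risk, x$exceedance))
  invisible(x)
}

#' @export
summary.ilcr_sim <- function(object, threshold = object$spec$acceptable_risk,
                             ...) {
  data.frame(
    statistic = c("mean", "median", "sd", "p5", "p95", "exceedance"),
    value = c(object$mean, object$median, object$sd, object$p5, object$p95,
              exceedance_probability(object, threshold)),
    stringsAsFactors = FALSE
  )
}

#' @export
quantile.ilcr_sim <- function(x, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                              ...) {
  quantile(x$ilcr, probs = probs, ...)
}

#' @export
plot.ilcr_sim <- function(x, breaks = 40, ...) {
  hist(log10(x$ilcr), breaks = breaks,
       main = sprintf("ILCR distribution (%s season)", x$spec$season),
       xlab = "log10 ILCR", ...)
  abline(v = log10(x$spec$acceptable_risk), col = "red", lwd = 2)
  invisible(x)
}

#' Tabular report of a simulation (with histogram bins)
#'
#' @param result An `ilcr_sim`.
#' @param threshold Exceedance threshold (default 1e-6).
#' @param bins Number of histogram bins over log10(ILCR).
#' @return List with `stats` (statistic/value rows, always including the
#'   exceedance against `threshold`) and `histogram` (bin midpoints on the
#'   log10 scale with counts), both plain data frames ready for CSV.
#' @export
simulation_report <- function(result, threshold = 1e-6, bins = 30) {
  stats <- summary(result, threshold = threshold)
  h <- hist(log10(result$ilcr), breaks = bins, plot = FALSE)
  list(
    stats = cbind(season = result$spec$season, stats),
    histogram = data.frame(season = result$spec$season,
                           log10_ilcr_mid = h$mids, count = h$counts)
  )
}

#' Fit and select an exposure distribution
#'
#' Fits a normal distribution to the raw values and (for positive values) a
#' normal to the log values by maximum likelihood, then selects the family
#' with the larger Kolmogorov-Smirnov p-value -- lognormal exposure data
#' should select lognormal. Both fits are returned.
#'
#' @param values Numeric vector, `n >= 8`.
#' @return Object of class `exposure_fit`: `selected` (`"normal"`,
#'   `"lognormal"` or `NA` for degenerate input), `normal` (mean, sd, ks_p),
#'   `lognormal` (log_mean, log_sd, ks_p; `NULL` when no positive values),
#'   `n`, `n_nonpositive` (excluded from the log fit, with a flag),
#'   `degenerate`.
#' @examples
#' set.seed(1)
#' fit <- fit_exposure_distribution(exp(rnorm(500, 2.7, 0.4)))
#' fit$selected # "lognormal"
#' coef(fit)
#' @export
fit_exposure_distribution <- function(values) {
  n <- length(values)
  if (n < 8L) stop("distribution fitting requires n >= 8", call. = FALSE)
  if (anyNA(values)) stop("values must be non-missing", call. = FALSE)
  if (sd(values) == 0) {
    out <- list(selected = NA_character_, normal = NULL, lognormal = NULL,
                n = n, n_nonpositive = sum(values <= 0), degenerate = TRUE)
    class(out) <- "exposure_fit"
    return(out)
  }
  norm_fit <- list(mean = mean(values), sd = sd(values))
  norm_fit$ks_p <- suppressWarnings(
    ks.test(values, "pnorm", norm_fit$mean, norm_fit$sd)$p.value)

  pos <- values[values > 0]
  n_nonpos <- n - length(pos)
  logn_fit <- NULL
  if (length(pos) >= 8L && sd(log(pos)) > 0) {
    lv <- log(pos)
    logn_fit <- list(log_mean = mean(lv), log_sd = sd(lv))
    logn_fit$ks_p <- suppressWarnings(
      ks.test(lv, "pnorm", logn_fit$log_mean, logn_fit$log_sd)$p.value)
  }
  selected <- if (is.null(logn_fit) || norm_fit$ks_p >= logn_fit$ks_p) {
    "normal"
  } else {
    "lognormal"
  }
  out <- list(selected = selected, normal = norm_fit, lognormal = logn_fit,
              n = n, n_nonpositive = n_nonpos, degenerate = FALSE)
  class(out) <- "exposure_fit"
  out
}

#' @export
print.exposure_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Exposure distribution fit: degenerate (constant) input, ",
        "no family selected\n", sep = "")
    return(invisible(x))
  }
  cat("Exposure distribution fit (n =", x$n, ")\n")
  cat(sprintf("  normal:    mean %.4g, sd %.4g (KS p = %.3g)\n",
              x$normal$mean, x$normal$sd, x$normal$ks_p))
  if (!is.null(x$lognormal)) {
    cat(sprintf("  lognormal: log-mean %.4g, log-sd %.4g (KS p = %.3g)\n",
                x$lognormal$log_mean, x$lognormal$log_sd,
                x$lognormal$ks_p))
  }
  if (x$n_nonpositive > 0) {
    cat("  (", x$n_nonpositive, " nonpositive values excluded from the ",
        "log fit)\n", sep = "")
  }
  cat("  selected family:", x$selected, "\n")
  invisible(x)
}

#' @export
coef.exposure_fit <- function(object, ...) {
  if (object$degenerate) return(c(selected = NA_real_))
  if (identical(object$selected, "lognormal")) {
    c(log_mean = object$lognormal$log_mean, log_sd = object$lognormal$log_sd)
  } else {
    c(mean = object$normal$mean, sd = object$normal$sd)
  }
}
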
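# BaP-equivalent exposure, seasonal summaries, indoor/outdoor ratios and the
# standard statistical comparisons (t-tests, Pearson correlation).

#' BaP-equivalent concentration of a congener mixture
#'
#' Collapses a vector of per-congener concentrations to a single
#' carcinogenicity-weighted concentration, `BaPeq = sum_i C_i * TEF_i`, with
#' per-congener contributions and shares.
#'
#' @param concentrations Named numeric vector of concentrations (ng/m3),
#'   names matching the TEF table (order-independent).
#' @param tefs Named numeric TEF vector, e.g. [tef_table()] of a registry.
#'
#' @return Object of class `bapeq`: list with `total` (ng/m3),
#'   `contributions` (ng/m3, per congener), `shares` (fractions summing to 1
#'   when the total is positive, otherwise `NA`) and `defined` (logical;
#'   `FALSE` for an all-zero mixture).
#'
#' @examples
#' tefs <- tef_table(load_registry())
#' conc <- setNames(rep(1, length(tefs)), names(tefs))
#' bap_equivalent(conc, tefs)$total # sum of the TEFs
#' @export
bap_equivalent <- function(concentrations, tefs) {
  if (is.null(names(concentrations)) ||
      !setequal(names(concentrations), names(tefs)) ||
      length(concentrations) != length(tefs)) {
    stop("concentration vector is not aligned to the TEF table ",
         "(names must match the registry)", call. = FALSE)
  }
  conc <- concentrations[names(tefs)]
  if (any(is.na(conc)) || any(conc < 0)) {
    stop("concentrations must be nonnegative and non-missing", call. = FALSE)
  }
  contributions <- conc * as.numeric(tefs)
  total <- sum(contributions)
  shares <- if (total > 0) contributions / total else
    setNames(rep(NA_real_, length(tefs)), names(tefs))
  structure(
    list(total = total, contributions = contributions, shares = shares,
         defined = total > 0),
    class = "bapeq"
  )
}

#' @export
print.bapeq <- function(x, ...) {
  cat("BaP-equivalent concentration:", format(x$total, digits = 4), "ng/m3\n")
  if (x$defined) {
    top <- sort(x$shares, decreasing = TRUE)[1:3]
    cat("Top contributors:",
        paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "),
        "\n")
  } else {
    cat("(all-zero mixture; shares undefined)\n")
  }
  invisible(x)
}

#' Per-sample BaP-equivalent totals
#'
#' @param samples A `pah_samples` data frame.
#' @param registry A `pah_registry`.
#' @return Numeric vector of total BaPeq (ng/m3), one value per row.
#' @export
bapeq_by_sample <- function(samples, registry = load_registry()) {
  tefs <- tef_table(registry)
  conc <- as.matrix(samples[, names(tefs), drop = FALSE])
  as.numeric(conc %*% as.numeric(tefs))
}

#' Seasonal exposure summary
#'
#' Moments (mean, sample sd, min, max) of total PAH, PM2.5, BaP and total
#' BaPeq over the valid personal samples of one season, plus the PAH-to-PM
#' mass fraction (ratio of the seasonal means).
#'
#' @param samples A `pah_samples` data frame.
#' @param season `"heating"` or `"non-heating"`.
#' @param registry A `pah_registry`.
#' @param personal_only Restrict to personal samples (default `TRUE`).
#' @param valid_only Apply the 22-26 h personal validity rule first
#'   (default `TRUE`).
#' @param shapiro_log When `TRUE`, also runs a Shapiro-Wilk normality test on
#'   log-transformed positive BaPeq values (lognormality check).
#'
#' @return Object of class `season_summary`: list with `season`, `n`, a
#'   `stats` data frame (metric, mean, sd, min, max), `pah_pm_fraction`, and
#'   optionally `shapiro_log_p`. With a single sample the sd is `NA`.
#' @export
season_summary <- function(samples, season, registry = load_registry(),
                           personal_only = TRUE, valid_only = TRUE,
                           shapiro_log = FALSE) {
  season <- match.arg(season, SEASONS)
  if (valid_only) samples <- filter_valid_personal(samples)
  sub <- samples[samples$season == season, , drop = FALSE]
  if (personal_only) sub <- sub[sub$sampler_kind == "personal", , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no samples for season '", season, "'", call. = FALSE)
  }
  conc <- as.matrix(sub[, registry$abbreviation, drop = FALSE])
  metrics <- list(
    sigma_pah = rowSums(conc),
    pm25 = sub$pm25,
    bap = conc[, "BaP"],
    bapeq = bapeq_by_sample(sub, registry)
  )
  stats_df <- do.call(rbind, lapply(names(metrics), function(m) {
    v <- metrics[[m]]
    data.frame(metric = m, mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  out <- list(
    season = season,
    n = nrow(sub),
    stats = stats_df,
    pah_pm_fraction = mean(metrics$sigma_pah) / mean(metrics$pm25)
  )
  if (shapiro_log) {
    pos <- metrics$bapeq[metrics$bapeq > 0]
    out$shapiro_log_p <- if (length(pos) >= 3L)
      shapiro.test(log(pos))$p.value else NA_real_
  }
  class(out) <- "season_summary"
  out
}

#' @export
print.season_summary <- function(x, ...) {
  cat("Season:", x$season, " (n =", x$n, "valid samples)\n")
  print(transform(x$stats,
                  mean = signif(mean, 4), sd = signif(sd, 4),
                  min = signif(min, 4), max = signif(max, 4)),
        row.names = FALSE)
  cat("PAH/PM2.5 mass fraction:", signif(x$pah_pm_fraction, 4), "\n")
  if (!is.null(x$shapiro_log_p)) {
    cat("Shapiro-Wilk p on log(BaPeq):", signif(x$shapiro_log_p, 3), "\n")
  }
  invisible(x)
}

summary_metric_mean <- function(s, metric) {
  if (metric == "pah_pm_fraction") return(s$pah_pm_fraction)
  row <- s$stats[s$stats$metric == metric, ]
  if (nrow(row) == 0L) stop("summary does not contain metric '", metric, "'",
                            call. = FALSE)
  row$mean
}

#' Fold change between two seasonal summaries
#'
#' Ratio of the metric means of two [season_summary()] objects, e.g. the
#' heating/non-heating total-PAH fold change or the fold change of the
#' PAH-to-PM mass fraction.
#'
#' @param summary_a,summary_b `season_summary` objects (numerator, denominator).
#' @param metric One of `"sigma_pah"`, `"pm25"`, `"bap"`, `"bapeq"`,
#'   `"pah_pm_fraction"`.
#' @return The fold change; `NA` with attribute `undefined = TRUE` when the
#'   denominator mean is zero.
#' @export
season_ratio <- function(summary_a, summary_b, metric = "sigma_pah") {
  stopifnot(inherits(summary_a, "season_summary"),
            inherits(summary_b, "season_summary"))
  num <- summary_metric_mean(summary_a, metric)
  den <- summary_metric_mean(summary_b, metric)
  if (!is.finite(den) || den == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  num / den
}

#' Indoor/outdoor concentration ratio per congener
#'
#' `I/O > 1` points to an indoor source, `I/O < 1` to an outdoor source;
#' exactly 1 (or an undefined ratio) is indeterminate.
#'
#' @param indoor_sample,outdoor_sample Single-row `pah_samples` subsets with
#'   `sampler_kind` `"fixed_indoor"` / `"fixed_outdoor"`, same season.
#' @param registry A `pah_registry`.
#' @return Data frame of class `io_ratio`: one row per congener with
#'   `indoor`, `outdoor`, `ratio` (`NA` when outdoor is 0) and `call`
#'   (`indoor_source` / `outdoor_source` / `indeterminate`).
#' @export
io_ratio <- function(indoor_sample, outdoor_sample,
                     registry = load_registry()) {
  if (nrow(indoor_sample) != 1L || nrow(outdoor_sample) != 1L) {
    stop("io_ratio expects one indoor and one outdoor sample row",
         call. = FALSE)
  }
  if (indoor_sample$sampler_kind != "fixed_indoor" ||
      outdoor_sample$sampler_kind != "fixed_outdoor") {
    stop("samples must be fixed_indoor and fixed_outdoor", call. = FALSE)
  }
  if (indoor_sample$season != outdoor_sample$season) {
    stop("indoor and outdoor samples must come from the same season",
         call. = FALSE)
  }
  cg <- registry$abbreviation
  ind <- as.numeric(indoor_sample[1, cg])
  out <- as.numeric(outdoor_sample[1, cg])
  ratio <- ifelse(out > 0, ind / out, NA_real_)
  # 0/0 as well as >0/0 are undefined-flagged
  call <- ifelse(is.na(ratio), "indeterminate",
          ifelse(ratio > 1, "indoor_source",
          ifelse(ratio < 1, "outdoor_source", "indeterminate")))
  res <- data.frame(congener = cg, indoor = ind, outdoor = out,
                    ratio = ratio, call = call, stringsAsFactors = FALSE)
  class(res) <- c("io_ratio", "data.frame")
  res
}

#' Season-level indoor/outdoor ratio table
#'
#' Averages the fixed indoor and fixed outdoor samples of each season and
#' computes the per-congener I/O ratio of the means.
#'
#' @param samples A `pah_samples` data frame containing fixed-site samples.
#' @param registry A `pah_registry`.
#' @return Data frame with columns season, congener, indoor, outdoor, ratio,
#'   call.
#' @export
io_ratio_table <- function(samples, registry = load_registry()) {
  cg <- registry$abbreviation
  out <- list()
  for (season in SEASONS) {
    ind <- samples[samples$season == season &
                     samples$sampler_kind == "fixed_indoor", cg, drop = FALSE]
    outd <- samples[samples$season == season &
                      samples$sampler_kind == "fixed_outdoor", cg,
                    drop = FALSE]
    if (nrow(ind) == 0L || nrow(outd) == 0L) next
    mi <- colMeans(ind)
    mo <- colMeans(outd)
    ratio <- ifelse(mo > 0, mi / mo, NA_real_)
    call <- ifelse(is.na(ratio), "indeterminate",
            ifelse(ratio > 1, "indoor_source",
            ifelse(ratio < 1, "outdoor_source", "indeterminate")))
    out[[season]] <- data.frame(season = season, congener = cg,
                                indoor = as.numeric(mi),
                                outdoor = as.numeric(mo),
                                ratio = as.numeric(ratio), call = call,
                                stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(season = character(), congener = character(),
                      indoor = numeric(), outdoor = numeric(),
                      ratio = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-group comparison (t-test)
#'
#' Welch two-sample t-test, or a paired t-test of the within-pair
#' differences. Degenerate inputs (zero variance of the paired differences,
#' or two constant identical groups) are flagged rather than raising.
#'
#' @param values_a,values_b Numeric vectors (`n >= 2` each; equal length when
#'   paired).
#' @param paired Logical.
#' @return List of class `group_comparison`: `statistic`, `p.value`, `df`,
#'   `method`, `degenerate`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (paired && length(values_a) != length(values_b)) {
    stop("paired comparison requires equal-length vectors", call. = FALSE)
  }
  degenerate <- if (paired) sd(values_a - values_b) == 0 else
    sd(values_a) == 0 && sd(values_b) == 0
  res <- if (degenerate) NULL else tryCatch(
    t.test(values_a, values_b, paired = paired, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    out <- list(statistic = NA_real_, p.value = NA_real_, df = NA_real_,
                method = if (paired) "Paired t-test" else "Welch t-test",
                degenerate = TRUE)
  } else {
    out <- list(statistic = unname(res$statistic),
                p.value = res$p.value, df = unname(res$parameter),
                method = res$method, degenerate = FALSE)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat(x$method, ": degenerate input (zero variance); no test statistic\n")
  } else {
    cat(sprintf("%s: t = %.3f, df = %.2f, two-sided p = %.4g\n",
                x$method, x$statistic, x$df, x$p.value))
  }
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' @param values_a,values_b Equal-length numeric vectors, `n >= 3`.
#' @return List with `r`, `p.value`, `n`, `degenerate` (`TRUE`, with `r = NA`,
#'   when either input is constant).
#' @export
correlate <- function(values_a, values_b) {
  n <- length(values_a)
  if (n != length(values_b)) stop("vectors must have equal length",
                                  call. = FALSE)
  if (n < 3L) stop("correlation requires n >= 3", call. = FALSE)
  if (sd(values_a) == 0 || sd(values_b) == 0) {
    return(list(r = NA_real_, p.value = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- cor.test(values_a, values_b, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = n,
       degenerate = FALSE)
}
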
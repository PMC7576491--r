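# Deterministic dosimetry: inhalation rate from spirometry, lifetime average
# daily dose (LADD) and incremental lifetime cancer risk (ILCR).
#
#   LADD = C * EF * ED * CF * IR / (BW * AT)   [mg / (kg day)]
#   ILCR = SF * LADD                           [dimensionless]
#
# with C the BaP-equivalent concentration (ng/m3), EF the exposure frequency
# (day/year), ED the exposure duration (year), CF the ng-to-mg conversion
# (1e-6 mg/ng), IR the inhalation rate (m3/day), BW the body weight (kg) and
# AT the carcinogenic averaging time (day). SF is the BaP inhalation cancer
# slope factor, 3.14 per (mg/kg/day).

#' Season-specific exposure scenario constants
#'
#' Exposure frequency differs by season (140 day/yr of heating, 220 day/yr
#' otherwise); duration 10 yr, averaging time 25500 day, CF 1e-6 mg/ng,
#' SF 3.14 (mg/kg/day)^-1, acceptable risk 1e-6.
#'
#' @param season `"heating"` or `"non-heating"`.
#' @param ef,ed,at,cf,sf,acceptable_risk Optional overrides.
#' @return Named list of scenario constants.
#' @export
exposure_scenario <- function(season = c("heating", "non-heating"),
                              ef = NULL, ed = 10, at = 25500, cf = 1e-6,
                              sf = 3.14, acceptable_risk = 1e-6) {
  season <- match.arg(season)
  if (is.null(ef)) ef <- if (season == "heating") 140 else 220
  out <- list(season = season, ef = ef, ed = ed, at = at, cf = cf, sf = sf,
              acceptable_risk = acceptable_risk)
  stopifnot(all(vapply(out[-1], function(v) is.numeric(v) && v > 0,
                       logical(1))))
  if (at < ef * ed) {
    stop("averaging time must be at least EF * ED days", call. = FALSE)
  }
  out
}

#' Inhalation rate from spirometry
#'
#' `IR = TV (L/breath) x BF (breaths/min) x 1.44`, where 1.44 converts
#' L/min to m3/day (1440 min/day / 1000 L/m3).
#'
#' @param tidal_volume_L Tidal volume in litres per breath.
#' @param breathing_rate_per_min Breathing frequency per minute.
#' @return Inhalation rate in m3/day.
#' @examples
#' inhalation_rate(0.5, 20) # 14.4 m3/day
#' @export
inhalation_rate <- function(tidal_volume_L, breathing_rate_per_min) {
  if (any(!is.finite(tidal_volume_L)) || any(tidal_volume_L <= 0) ||
      any(!is.finite(breathing_rate_per_min)) ||
      any(breathing_rate_per_min <= 0)) {
    stop("tidal volume and breathing rate must be positive", call. = FALSE)
  }
  tidal_volume_L * breathing_rate_per_min * 1.44
}

#' Size-weighted pooled mean
#'
#' Pools group means by group size, e.g. sex-stratified inhalation-rate means
#' into a seasonal or overall cohort mean.
#'
#' @param group_means Numeric vector of group means.
#' @param group_sizes Numeric vector of group sizes (same length, all > 0).
#' @return The pooled mean `sum(mean_i * n_i) / sum(n_i)`.
#' @examples
#' pooled_mean(c(41.2, 30.4), c(7, 9)) # 35.125
#' @export
pooled_mean <- function(group_means, group_sizes) {
  if (length(group_means) != length(group_sizes)) {
    stop("means and sizes must have equal length", call. = FALSE)
  }
  if (any(group_sizes <= 0) || sum(group_sizes) == 0) {
    stop("group sizes must be positive", call. = FALSE)
  }
  weighted.mean(group_means, group_sizes)
}

#' Lifetime average daily dose
#'
#' Evaluates `LADD = C * EF * ED * CF * IR / (BW * AT)`. Vectorized over all
#' arguments.
#'
#' @param c_ngm3 Exposure concentration C (BaPeq, ng/m3); nonnegative.
#' @param ir_m3d Inhalation rate (m3/day).
#' @param bw_kg Body weight (kg).
#' @param ef_dy Exposure frequency (day/year).
#' @param ed_y Exposure duration (year).
#' @param at_d Averaging time (day).
#' @param cf_mg_ng Mass conversion factor (mg per ng), default 1e-6.
#' @return Dose in mg/(kg day).
#' @examples
#' ladd(16.3, ir_m3d = 35.1, bw_kg = 29.9) # about 1.05e-6 mg/(kg day)
#' @export
ladd <- function(c_ngm3, ir_m3d, bw_kg, ef_dy = 140, ed_y = 10,
                 at_d = 25500, cf_mg_ng = 1e-6) {
  if (any(c_ngm3 < 0)) stop("concentration must be nonnegative",
                            call. = FALSE)
  pos <- list(ir_m3d, bw_kg, ef_dy, ed_y, at_d, cf_mg_ng)
  if (any(vapply(pos, function(v) any(!is.finite(v)) || any(v <= 0),
                 logical(1)))) {
    stop("IR, BW, EF, ED, AT and CF must be strictly positive",
         call. = FALSE)
  }
  c_ngm3 * ef_dy * ed_y * cf_mg_ng * ir_m3d / (bw_kg * at_d)
}

#' Incremental lifetime cancer risk
#'
#' `ILCR = SF * LADD`, with an exceedance flag against the acceptable-risk
#' threshold (strictly greater counts as exceedance).
#'
#' @param dose LADD in mg/(kg day); nonnegative, vectorized.
#' @param sf Cancer slope factor per (mg/kg/day), default 3.14.
#' @param acceptable_risk Threshold, default 1e-6.
#' @return Data frame with columns `ladd`, `ilcr`, `exceeds`.
#' @examples
#' ilcr(1.05e-6)
#' @export
ilcr <- function(dose, sf = 3.14, acceptable_risk = 1e-6) {
  if (any(dose < 0)) stop("dose must be nonnegative", call. = FALSE)
  stopifnot(sf > 0, acceptable_risk > 0)
  risk <- sf * dose
  data.frame(ladd = dose, ilcr = risk, exceeds = risk > acceptable_risk)
}

#' Per-participant deterministic risk
#'
#' Computes each participant's inhalation rate (TV x BF x 1.44), LADD and
#' ILCR from their matched BaP-equivalent exposure, with overall and
#' sex-stratified summaries.
#'
#' @param participants A `pah_participants` data frame.
#' @param bapeq_by_participant Named numeric vector of BaPeq exposure
#'   concentrations (ng/m3), names = participant ids; must cover every
#'   participant.
#' @param scenario Scenario constants from [exposure_scenario()]; when `NULL`
#'   each participant uses the scenario of their own season.
#' @return Object of class `risk_result`: the per-participant data frame
#'   (`participant_id`, `season`, `sex`, `ir_m3d`, `ladd_mg_kg_d`,
#'   `ladd_ng_kg_d`, `ilcr`, `exceeds`) with a `summary` attribute holding
#'   overall and by-sex means and the ILCR range.
#' @export
per_participant_risk <- function(participants, bapeq_by_participant,
                                 scenario = NULL) {
  ids <- participants$participant_id
  if (is.null(names(bapeq_by_participant)) ||
      !all(ids %in% names(bapeq_by_participant))) {
    missing <- setdiff(ids, names(bapeq_by_participant))
    stop("no exposure value for participant(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  conc <- bapeq_by_participant[ids]
  ir <- inhalation_rate(participants$tidal_volume_L,
                        participants$breathing_rate_per_min)
  scen_of <- function(season) {
    if (!is.null(scenario)) scenario else exposure_scenario(season)
  }
  dose <- vapply(seq_along(ids), function(i) {
    sc <- scen_of(participants$season[i])
    ladd(conc[i], ir[i], participants$weight_kg[i],
         ef_dy = sc$ef, ed_y = sc$ed, at_d = sc$at, cf_mg_ng = sc$cf)
  }, numeric(1))
  sf <- if (!is.null(scenario)) scenario$sf else 3.14
  thr <- if (!is.null(scenario)) scenario$acceptable_risk else 1e-6
  risk <- ilcr(dose, sf = sf, acceptable_risk = thr)
  out <- data.frame(
    participant_id = ids,
    season = participants$season,
    sex = participants$sex,
    ir_m3d = ir,
    ladd_mg_kg_d = risk$ladd,
    ladd_ng_kg_d = risk$ladd * 1e6,
    ilcr = risk$ilcr,
    exceeds = risk$exceeds,
    stringsAsFactors = FALSE
  )
  strata <- aggregate(ilcr ~ season + sex, data = out, FUN = mean)
  attr(out, "summary") <- list(
    mean_ilcr = mean(out$ilcr),
    range_ilcr = range(out$ilcr),
    by_stratum = strata,
    exceedance_fraction = mean(out$exceeds)
  )
  class(out) <- c("risk_result", "data.frame")
  out
}

#' @export
print.risk_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Per-participant inhalation cancer risk (n =", nrow(x), ")\n")
  cat(sprintf("Mean ILCR %.3g (range %.3g - %.3g); %0.f%% exceed threshold\n",
              s$mean_ilcr, s$range_ilcr[1], s$range_ilcr[2],
              100 * s$exceedance_fraction))
  cat("Stratum means:\n")
  print(transform(s$by_stratum, ilcr = signif(ilcr, 3)), row.names = FALSE)
  invisible(x)
}
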
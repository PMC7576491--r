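# Isomer-pair diagnostic ratios and threshold-rule source classification.
#
# Each ratio is A/(A+B) for an isomer pair of equal molecular weight, so every
# defined ratio lies in [0,1] and is invariant to rescaling the whole sample.
# BaA/(BaA+Chr) and IcdP/(IcdP+BghiP) drive the source verdict; the other
# three listed pairs are reported for completeness.

DIAGNOSTIC_PAIRS <- list(
  baa_chr = c("BaA", "Chr"),
  icdp_bghip = c("IcdP", "BghiP"),
  ant_phe = c("Ant", "Phe"),
  fla_pyr = c("Fla", "Pyr"),
  bbf_bkf = c("BbF", "BkF")
)

SOURCE_LABELS <- c("petroleum", "mixed", "coal_or_biomass_combustion",
                   "indeterminate")

#' Isomer diagnostic ratios of one sample
#'
#' Computes the five standard isomer-pair ratios `A/(A+B)`:
#' BaA/(BaA+Chr), IcdP/(IcdP+BghiP), Ant/(Ant+Phe), Fla/(Fla+Pyr) and
#' BbF/(BbF+BkF). A pair whose sum is zero yields `NA` (undefined is a value,
#' not an error).
#'
#' @param sample Single-row `pah_samples` subset, or a named numeric vector of
#'   congener concentrations containing the required abbreviations.
#' @return Named numeric vector (`baa_chr`, `icdp_bghip`, `ant_phe`,
#'   `fla_pyr`, `bbf_bkf`), each in `[0, 1]` or `NA`.
#' @examples
#' diagnostic_ratios(c(BaA = 1, Chr = 1, IcdP = 0.51, BghiP = 0.49,
#'                     Ant = 1, Phe = 1, Fla = 1, Pyr = 1, BbF = 1, BkF = 1))
#' @export
diagnostic_ratios <- function(sample) {
  conc <- if (is.data.frame(sample)) {
    if (nrow(sample) != 1L) stop("expected a single sample row", call. = FALSE)
    setNames(as.numeric(sample[1, unlist(DIAGNOSTIC_PAIRS)]),
             unlist(DIAGNOSTIC_PAIRS))
  } else {
    sample
  }
  needed <- unique(unlist(DIAGNOSTIC_PAIRS))
  if (!all(needed %in% names(conc))) {
    stop("sample lacks required congeners: ",
         paste(setdiff(needed, names(conc)), collapse = ", "), call. = FALSE)
  }
  vapply(DIAGNOSTIC_PAIRS, function(pair) {
    a <- conc[[pair[1]]]
    b <- conc[[pair[2]]]
    s <- a + b
    if (is.na(s) || s == 0) NA_real_ else a / s
  }, numeric(1))
}

#' Classify a BaA/(BaA+Chr) ratio
#'
#' `< 0.2` petroleum; `> 0.35` coal or biomass combustion; the closed interval
#' `[0.2, 0.35]` mixed (the strict threshold inequalities leave the boundary
#' points open, so boundaries fall in the middle bin). `NA` is indeterminate.
#'
#' @param ratio Numeric vector of ratios in `[0, 1]` (or `NA`).
#' @return Character vector of source labels.
#' @examples
#' classify_baa(c(0.15, 0.2, 0.45, NA))
#' @export
classify_baa <- function(ratio) {
  check_ratio_domain(ratio)
  ifelse(is.na(ratio), "indeterminate",
  ifelse(ratio < 0.2, "petroleum",
  ifelse(ratio > 0.35, "coal_or_biomass_combustion", "mixed")))
}

#' Classify an IcdP/(IcdP+BghiP) ratio
#'
#' `< 0.2` petroleum; `> 0.5` coal or biomass combustion; `[0.2, 0.5]` mixed;
#' `NA` indeterminate.
#'
#' @inheritParams classify_baa
#' @return Character vector of source labels.
#' @examples
#' classify_icdp(c(0.1, 0.35, 0.51))
#' @export
classify_icdp <- function(ratio) {
  check_ratio_domain(ratio)
  ifelse(is.na(ratio), "indeterminate",
  ifelse(ratio < 0.2, "petroleum",
  ifelse(ratio > 0.5, "coal_or_biomass_combustion", "mixed")))
}

check_ratio_domain <- function(ratio) {
  bad <- !is.na(ratio) & (ratio < 0 | ratio > 1)
  if (any(bad)) stop("diagnostic ratios must lie in [0, 1]", call. = FALSE)
  invisible(ratio)
}

#' Combine the BaA and IcdP source calls into one verdict
#'
#' Agreement gives the shared label; disagreement between two defined labels
#' gives `mixed`; a single indeterminate defers to the other ratio; two
#' indeterminates stay indeterminate.
#'
#' @param baa_label,icdp_label Character vectors of labels from
#'   [classify_baa()] / [classify_icdp()].
#' @return Character vector of combined verdicts.
#' @export
combine_source_calls <- function(baa_label, icdp_label) {
  stopifnot(length(baa_label) == length(icdp_label))
  mapply(function(b, i) {
    if (b == "indeterminate" && i == "indeterminate") return("indeterminate")
    if (b == "indeterminate") return(i)
    if (i == "indeterminate") return(b)
    if (b == i) b else "mixed"
  }, baa_label, icdp_label, USE.NAMES = FALSE)
}

#' Per-sample diagnostic-ratio scatter table
#'
#' One row per sample with the BaA/(BaA+Chr) and IcdP/(IcdP+BghiP) ratios,
#' their labels and the combined verdict -- the table behind the classic
#' two-ratio source-attribution scatter plot. Rows with undefined ratios are
#' retained and flagged indeterminate.
#'
#' @param samples A `pah_samples` data frame.
#' @return Data frame with columns `sample_id`, `season`, `sampler_kind`,
#'   `baa_ratio`, `icdp_ratio`, `baa_call`, `icdp_call`, `verdict`.
#' @export
source_scatter <- function(samples) {
  if (nrow(samples) == 0L) {
    return(data.frame(sample_id = character(), season = character(),
                      sampler_kind = character(), baa_ratio = numeric(),
                      icdp_ratio = numeric(), baa_call = character(),
                      icdp_call = character(), verdict = character(),
                      stringsAsFactors = FALSE))
  }
  ratios <- t(vapply(seq_len(nrow(samples)), function(i) {
    diagnostic_ratios(samples[i, , drop = FALSE])
  }, numeric(length(DIAGNOSTIC_PAIRS))))
  baa_call <- classify_baa(ratios[, "baa_chr"])
  icdp_call <- classify_icdp(ratios[, "icdp_bghip"])
  data.frame(
    sample_id = samples$sample_id,
    season = samples$season,
    sampler_kind = samples$sampler_kind,
    baa_ratio = ratios[, "baa_chr"],
    icdp_ratio = ratios[, "icdp_bghip"],
    baa_call = baa_call,
    icdp_call = icdp_call,
    verdict = combine_source_calls(baa_call, icdp_call),
    stringsAsFactors = FALSE
  )
}
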